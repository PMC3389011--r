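test_that("haplotype genomes differ only by recorded substitutions", {
  g0 <- make_haplotype_genome(2, 1e4, snp_rate = 0, seed = 41)
  expect_identical(as.character(g0$b6), as.character(g0$sd7))
  expect_equal(nrow(g0$snps), 0)
  g <- make_haplotype_genome(1, 1e4, snp_rate = 1e-3, seed = 42)
  # SNP count within 3 binomial SD of the expectation (10)
  expect_lt(abs(nrow(g$snps) - 10), 3 * sqrt(1e4 * 1e-3 * (1 - 1e-3)) + 1)
  expect_true(all(g$snps$ref != g$snps$alt))
  b6 <- as.character(g$b6[[1]])
  sd7 <- as.character(g$sd7[[1]])
  expect_equal(substring(b6, g$snps$pos + 1, g$snps$pos + 1), g$snps$ref)
  expect_equal(substring(sd7, g$snps$pos + 1, g$snps$pos + 1), g$snps$alt)
  # differences are exactly the recorded positions
  diff_pos <- which(strsplit(b6, "")[[1]] != strsplit(sd7, "")[[1]]) - 1L
  expect_equal(diff_pos, g$snps$pos)
  expect_error(make_haplotype_genome(1, 100, snp_rate = 0.5), "0.1")
})

test_that("generators are bit-reproducible under a fixed seed", {
  g1 <- make_haplotype_genome(1, 5e3, 1e-3, seed = 43)
  g2 <- make_haplotype_genome(1, 5e3, 1e-3, seed = 43)
  expect_identical(as.character(g1$b6), as.character(g2$b6))
  expect_identical(g1$snps, g2$snps)
  s1 <- simulate_nuclei(nuclei_config(n_replicates = 1,
                                      nuclei_per_replicate = 50, seed = 44))
  s2 <- simulate_nuclei(nuclei_config(n_replicates = 1,
                                      nuclei_per_replicate = 50, seed = 44))
  expect_identical(s1$spots, s2$spots)
  c1 <- simulate_probe_covariates(n = 30, target_r = 0.6, seed = 45)
  c2 <- simulate_probe_covariates(n = 30, target_r = 0.6, seed = 45)
  expect_identical(c1, c2)
})

fixture_4c <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- make_haplotype_genome(4, 2e5, snp_rate = 1e-3, seed = 46)
      fb <- digest_genome(g$b6)
      fs <- digest_genome(g$sd7)
      f1 <- fb[fb$chrom == "chr1", ]
      bait <- f1$fragment_id[ceiling(nrow(f1) / 2)]
      cache <<- list(g = g, fb = fb, fs = fs, bait = bait)
    }
    cache
  }
})

test_that("pure-cis configuration yields only same-allele cis products", {
  fx <- fixture_4c()
  cfg <- fourc_config(fx$bait, beta = 0, gamma = 0, n_reads = 500, seed = 47)
  sim <- simulate_4c_reads(cfg, list(b6 = fx$fb, sd7 = fx$fs), fx$g)
  expect_true(all(sim$truth$category == "cis"))
  expect_true(all(sim$truth$prey_allele == sim$truth$bait_allele))
  expect_true(all(sim$truth$prey_chrom == "chr1"))
})

test_that("prey category frequencies match the configured mixture", {
  fx <- fixture_4c()
  cfg <- fourc_config(fx$bait, beta = 0.1, gamma = 0.2, n_reads = 2e4, seed = 48)
  sim <- simulate_4c_reads(cfg, list(b6 = fx$fb, sd7 = fx$fs), fx$g)
  freq <- table(sim$truth$category) / nrow(sim$truth)
  want <- c(cis = 0.7, hom_trans = 0.1, bg_trans = 0.2)
  for (k in names(want)) {
    se <- sqrt(want[[k]] * (1 - want[[k]]) / 2e4)
    expect_lt(abs(freq[[k]] - want[[k]]), 4 * se)
  }
  # invariant checks on the truth table
  expect_true(all(sim$truth$prey_chrom[sim$truth$category != "bg_trans"] == "chr1"))
  expect_true(all(sim$truth$prey_chrom[sim$truth$category == "bg_trans"] != "chr1"))
  hom <- sim$truth$category == "hom_trans"
  expect_true(all(sim$truth$prey_allele[hom] != sim$truth$bait_allele[hom]))
})

test_that("allele caller recovers generator truth on error-free reads", {
  fx <- fixture_4c()
  cfg <- fourc_config(fx$bait, beta = 0.1, gamma = 0.3, n_reads = 5000, seed = 49)
  sim <- simulate_4c_reads(cfg, list(b6 = fx$fb, sd7 = fx$fs), fx$g)
  called <- assign_allele(unname(sim$reads), sim$truth$prey_chrom,
                          sim$truth$read_start, fx$g$snps)
  covering <- called != "uninformative"
  expect_gt(sum(covering), 0)
  expect_identical(called[covering], sim$truth$prey_allele[covering])
  expect_false(any(called == "ambiguous"))
})

test_that("read bases are faithful copies of the prey haplotype", {
  fx <- fixture_4c()
  cfg <- fourc_config(fx$bait, n_reads = 200, seed = 50)
  sim <- simulate_4c_reads(cfg, list(b6 = fx$fb, sd7 = fx$fs), fx$g)
  tr <- sim$truth
  hap <- list(B6 = as.character(fx$g$b6), SD7 = as.character(fx$g$sd7))
  for (i in sample(nrow(tr), 25)) {
    want <- substring(hap[[tr$prey_allele[i]]][[tr$prey_chrom[i]]],
                      tr$read_start[i] + 1,
                      tr$read_start[i] + tr$read_width[i])
    expect_identical(unname(sim$reads[tr$read_id[i]]), want)
  }
})

test_that("nuclei generator: spots sit inside nuclei on quantized z planes", {
  cfg <- nuclei_config(n_replicates = 2, nuclei_per_replicate = 100, seed = 51)
  sim <- simulate_nuclei(cfg)
  expect_equal(nrow(sim$nuclei), 200)
  expect_equal(nrow(sim$spots), 200 * 2 * 2)  # 2 probes x 2 spots
  expect_true(all(sim$spots$z_um / 0.5 ==  round(sim$spots$z_um / 0.5)))
  rad <- radial_distance(sim$spots, sim$nuclei)
  # quantization can push spots marginally past the surface
  expect_true(all(rad <= 1 + 0.25 / 5 + 1e-9))
})

test_that("true pairing labels are always recovered; q = 0 with disjoint shells scores near zero", {
  probes <- list(
    sep = list(q = 0, model = radial_model(0.85, 0.02, 0.95, 0.02))
  )
  sim <- simulate_nuclei(nuclei_config(probes = probes, seed = 52))
  sc <- score_pairing(sim$spots, "sep")
  expect_lt(sc$frequency, 1)
  # paired ground truth must always be scored paired (offset < threshold)
  sim2 <- simulate_nuclei(nuclei_config(seed = 53))
  sc2 <- score_pairing(sim2$spots, "kvdmr_liver")
  truth2 <- sim2$truth[sim2$truth$probe_id == "kvdmr_liver", ]
  called <- sc2$nuclei$paired[match(truth2$nucleus_id, sc2$nuclei$nucleus_id)]
  expect_true(all(called[truth2$paired]))
})

test_that("covariate generator approaches the target correlation and guards degeneracy", {
  cov <- simulate_probe_covariates(n = 1000, target_r = 0.9, seed = 54)
  r <- cor(cov$expression_count, cov$pairing_frequency)
  expect_lt(abs(r - 0.9), 0.05)
  expect_true(all(cov$expression_count >= 0))
  expect_true(all(cov$pairing_frequency >= 0 & cov$pairing_frequency <= 10))
  # near-zero target: mean sample r across seeds is centred on zero
  rs <- vapply(1:40, function(s)
    cor(simulate_probe_covariates(n = 50, target_r = 0, seed = s)$expression_count,
        simulate_probe_covariates(n = 50, target_r = 0, seed = s)$pairing_frequency),
    0)
  expect_lt(abs(mean(rs)), 0.08)
  expect_error(simulate_probe_covariates(n = 3, target_r = 0.5), "at least 4")
  expect_error(simulate_probe_covariates(n = 10, target_r = 1), "below 1")
})

test_that("truth tables close over the downstream statistics (no raw re-inspection needed)", {
  fx <- fixture_4c()
  cfg <- fourc_config(fx$bait, beta = 0.05, gamma = 0.1, n_reads = 5000, seed = 55)
  sim <- simulate_4c_reads(cfg, list(b6 = fx$fb, sd7 = fx$fs), fx$g)
  tr <- sim$truth
  hits <- data.frame(prey_chrom = tr$prey_chrom, prey_position = tr$prey_position,
                     bait_allele = tr$bait_allele, prey_allele = tr$prey_allele,
                     prey_fragment_id = tr$prey_fragment_id,
                     category = tr$category)
  dd <- dedupe_positions(hits)
  prof <- cis_window_profile(dd[dd$category == "cis", ], window = 1e5,
                             chrom_lengths = c(chr1 = 2e5))
  expect_equal(sum(prof$count), sum(dd$category == "cis"))
  # permutation invariance: shuffled input reads give identical window counts
  perm <- hits[sample(nrow(hits)), ]
  prof2 <- cis_window_profile(dedupe_positions(perm[perm$category == "cis", ]),
                              window = 1e5, chrom_lengths = c(chr1 = 2e5))
  expect_identical(prof$count, prof2$count)
})

test_that("cis profile decays with distance from the bait", {
  fx <- fixture_4c()
  cfg <- fourc_config(fx$bait, beta = 0, gamma = 0, n_reads = 2e4, seed = 56)
  sim <- simulate_4c_reads(cfg, list(b6 = fx$fb, sd7 = fx$fs), fx$g)
  dd <- dedupe_positions(data.frame(
    prey_chrom = sim$truth$prey_chrom, prey_position = sim$truth$prey_position,
    bait_allele = sim$truth$bait_allele, prey_allele = sim$truth$prey_allele))
  prof <- cis_window_profile(dd, window = 2e4, chrom_lengths = c(chr1 = 2e5))
  bait_mid <- mean(unlist(fx$fb[fx$fb$fragment_id == fx$bait, c("start", "end")]))
  dist <- abs((prof$start + prof$end) / 2 - bait_mid)
  rho <- suppressWarnings(cor(dist, prof$count, method = "spearman"))
  expect_lt(rho, 0)
})
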