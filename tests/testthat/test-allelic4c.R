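make_seq <- function(len, site_at = integer(0), site = "AAGCTT") {
  # deterministic filler avoiding accidental recognition sites
  v <- rep(c("A", "C"), length.out = len)
  for (s in site_at)
    v[(s + 1):(s + nchar(site))] <- strsplit(site, "")[[1]]
  paste(v, collapse = "")
}

test_that("digestion cuts at site + offset and tiles the chromosome", {
  g <- c(chrT = make_seq(50, site_at = c(10, 30)))
  f <- digest_genome(g, "AAGCTT", 1)
  expect_equal(f$start, c(0, 11, 31))
  expect_equal(f$end, c(11, 31, 50))
  expect_equal(f$chrom, rep("chrT", 3))
  # tiling without gaps
  expect_equal(f$start[-1], f$end[-nrow(f)])
})

test_that("siteless sequences give one fragment; terminal cuts drop zero-length fragments", {
  g <- c(chrT = make_seq(40))
  f <- digest_genome(g)
  expect_equal(nrow(f), 1)
  expect_equal(c(f$start, f$end), c(0, 40))
  g0 <- c(chrT = paste0("AAGCTT", make_seq(20)))
  f0 <- digest_genome(g0, "AAGCTT", 0)
  expect_equal(f0$start[1], 0)
  expect_true(all(f0$end > f0$start))
  expect_error(digest_genome(g, "AAGCNT"), "A/C/G/T")
  expect_error(digest_genome(g, "AAGCTT", 7), "within")
})

test_that("identical haplotypes digest to identical maps", {
  set.seed(31)
  g <- make_haplotype_genome(2, 5e4, snp_rate = 0, seed = 31)
  expect_identical(digest_genome(g$b6), digest_genome(g$sd7))
})

test_that("informative classification follows the junction-readability rule", {
  frags <- data.frame(chrom = "chrT", start = c(0, 10000), end = c(10000, 20000),
                      fragment_id = c("f1", "f2"))
  no_snps <- data.frame(chrom = character(0), pos = integer(0),
                        ref = character(0), alt = character(0))
  cls <- classify_informative(frags, no_snps, read_length = 50)
  expect_true(all(cls$class == "uninformative"))
  # SNP 20 bp from the start of f1: readable from the junction -> stringent
  # SNP at the midpoint of f2: present but unreadable -> weak
  snps <- data.frame(chrom = "chrT", pos = c(20, 15000),
                     ref = c("A", "A"), alt = c("G", "G"))
  cls <- classify_informative(frags, snps, read_length = 50)
  expect_equal(as.character(cls$class), c("stringent", "weak"))
  # near the downstream end counts too
  snps2 <- data.frame(chrom = "chrT", pos = 19990, ref = "A", alt = "G")
  cls2 <- classify_informative(frags, snps2, read_length = 50)
  expect_equal(as.character(cls2$class), c("uninformative", "stringent"))
})

test_that("allele calls follow the covered-SNP rule", {
  snps <- data.frame(chrom = "chrT", pos = c(105, 120),
                     ref = c("A", "C"), alt = c("G", "T"))
  reads <- c(
    strrep("A", 50),  # aligned at 0: covers no SNP
    paste0(strrep("A", 5), "A", strrep("A", 9)),    # covers 105 only, ref base
    paste0(strrep("A", 5), "G", strrep("A", 9)),    # covers 105 only, alt -> SD7
    paste0(strrep("A", 5), "A", strrep("A", 14), "T", strrep("A", 4)), # ref at 105, alt at 120
    paste0(strrep("A", 5), "C", strrep("A", 9))     # base matching neither
  )
  starts <- c(0, 100, 100, 100, 100)
  call <- assign_allele(reads, rep("chrT", 5), starts, snps)
  expect_equal(call, c("uninformative", "B6", "SD7", "ambiguous", "ambiguous"))
})

test_that("position-to-fragment lookup is half-open and matches a linear scan", {
  f <- toy_fragment_map(c(0, 11, 31, 50))
  expect_equal(map_prey_fragment("chrT", 5, f), "chrT_F1")
  expect_equal(map_prey_fragment("chrT", 11, f), "chrT_F2")  # boundary -> downstream
  expect_equal(map_prey_fragment("chrT", 30, f), "chrT_F2")
  expect_error(map_prey_fragment("chrT", 50, f), "out of bounds")
  expect_error(map_prey_fragment("chrX", 5, f), "absent")
  set.seed(32)
  pos <- sample(0:49, 1000, replace = TRUE)
  got <- map_prey_fragment("chrT", pos, f)
  want <- vapply(pos, function(p) oracle_find_fragment("chrT", p, f), "")
  expect_equal(got, want)
})

test_that("deduplication keeps one hit per position/allele key and is idempotent", {
  set.seed(33)
  hits <- data.frame(
    prey_chrom = "chr1",
    prey_position = c(10, 10, 10, 20, 20, 30, 30, 30, 30, 10),
    bait_allele = c("B6", "B6", "B6", "B6", "B6", "B6", "B6", "B6", "B6", "B6"),
    prey_allele = c("SD7", "SD7", "SD7", "B6", "B6", "B6", "B6", "B6", "B6", "SD7")
  )
  d1 <- dedupe_positions(hits)
  expect_equal(nrow(d1), 3)
  expect_identical(dedupe_positions(d1), d1)
  expect_false(is.unsorted(d1$prey_position))
  empty <- hits[0, ]
  expect_equal(nrow(dedupe_positions(empty)), 0)
  # distinct alleles at the same position are distinct keys
  h2 <- data.frame(prey_chrom = "chr1", prey_position = 5,
                   bait_allele = c("B6", "SD7"), prey_allele = "SD7")
  expect_equal(nrow(dedupe_positions(h2)), 2)
})

test_that("cis window profile bins unique positions and conserves totals", {
  empty <- data.frame(prey_chrom = character(0), prey_position = numeric(0),
                      bait_allele = character(0), prey_allele = character(0))
  p0 <- cis_window_profile(empty, window = 1e5, chrom_lengths = c(chr1 = 3e5))
  expect_equal(p0$count, c(0L, 0L, 0L))
  hits <- data.frame(prey_chrom = "chr1", prey_position = c(5e4, 1.5e5, 1.5e5),
                     bait_allele = "B6", prey_allele = "B6")
  p <- cis_window_profile(dedupe_positions(hits), window = 1e5,
                          chrom_lengths = c(chr1 = 3e5))
  expect_equal(p$count, c(1L, 1L, 0L))
  set.seed(34)
  rand <- data.frame(prey_chrom = sample(c("chr1", "chr2"), 1000, TRUE),
                     prey_position = sample(0:999999, 1000, TRUE),
                     bait_allele = "B6", prey_allele = "B6")
  dd <- dedupe_positions(rand)
  pr <- cis_window_profile(dd, window = 1e5,
                           chrom_lengths = c(chr1 = 1e6, chr2 = 1e6))
  expect_equal(sum(pr$count), nrow(dd))
})

test_that("trans-allelic rate divides hit fragments by stringent fragments, missing when none", {
  informative <- data.frame(
    fragment_id = paste0("f", 1:6), chrom = "chr1",
    start = c(0, 5e4, 1e5, 1.5e5, 2.5e5, 3.5e5),
    end = c(5e4, 1e5, 1.5e5, 2.5e5, 3.5e5, 4e5),
    n_snps = 1,
    class = factor(c("stringent", "stringent", "stringent", "stringent",
                     "weak", "uninformative"),
                   levels = c("stringent", "weak", "uninformative"))
  )
  hits <- data.frame(prey_fragment_id = c("f2", "f2"))
  r <- trans_allelic_rate(hits, informative, window = 2e5,
                          chrom_lengths = c(chr1 = 4e5))
  expect_equal(r$n_stringent, c(4L, 0L))
  expect_equal(r$rate[1], 0.25)
  expect_true(is.na(r$rate[2]))  # no allelic information, not zero
  # rates never exceed 1
  set.seed(35)
  manyhits <- data.frame(prey_fragment_id = sample(paste0("f", 1:6), 200, TRUE))
  r2 <- trans_allelic_rate(manyhits, informative, window = 1e5,
                           chrom_lengths = c(chr1 = 4e5))
  expect_true(all(r2$rate[!is.na(r2$rate)] <= 1))
})

test_that("genome-wide trans summary counts, boxes, and flags windows", {
  cl <- c(chr1 = 2e6, chr2 = 2e6, chr3 = 2e6)
  hw <- list(chrom = "chr1", start = 0, end = 1.4e6)
  empty <- data.frame(prey_chrom = character(0), prey_position = numeric(0),
                      bait_allele = character(0), prey_allele = character(0))
  gw0 <- genomewide_trans_summary(empty, cl, 1.4e6, hw)
  expect_true(all(gw0$windows$count == 0))
  expect_false(gw0$homologous$outlier)
  set.seed(36)
  hits <- dedupe_positions(data.frame(
    prey_chrom = sample(c("chr2", "chr3"), 300, TRUE),
    prey_position = sample(0:1999999, 300, TRUE),
    bait_allele = "B6", prey_allele = "SD7"
  ))
  gw <- genomewide_trans_summary(hits, cl, 1.4e6, hw)
  # definitional consistency with the Tukey statistics of the count vector
  b <- tukey_box_stats(gw$windows$count)
  expect_equal(gw$box$median, b$median)
  expect_equal(gw$upper_fence, b$upper_hinge + 1.5 * b$iqr)
  expect_equal(gw$windows$outlier, gw$windows$count > gw$upper_fence)
  # misaligned homologous interval snaps to the containing window
  expect_message(
    genomewide_trans_summary(hits, cl, 1.4e6,
                             list(chrom = "chr1", start = 2e5, end = 4e5)),
    "containing window")
})
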