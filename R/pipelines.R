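# End-to-end orchestration of the two analyses. Each pipeline takes a
# configuration (R list or YAML path), fills in defaults, runs the module
# functions, writes deterministic TSV/JSON outputs plus the resolved
# configuration, and returns the report. Re-running from the resolved
# configuration reproduces the outputs byte for byte.

resolve_config <- function(config, defaults) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  out <- utils::modifyList(defaults, config)
  out
}

write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Run the FISH pairing pipeline
#'
#' Generates (or reads) nucleus and spot tables, scores pairing per probe,
#' assigns frequency categories, computes radial and normalized interallelic
#' distance statistics and histograms, optionally fits the radial null model
#' per probe and compares observed interallelic distances against simulated
#' ones, and correlates pairing frequency with probe covariates when
#' supplied. All tables are written under `out_dir` together with a JSON
#' report and the resolved configuration.
#'
#' Config fields (all optional unless noted): `out_dir` (required); `seed`;
#' `tau` (pairing threshold, um); `generator` (list passed to
#' [nuclei_config()]; presets from [pairing_presets()] are used when neither
#' `generator` nor input paths are given); `spots_path`/`nuclei_path` (TSV
#' inputs, alternative to the generator); `fit` (list with `enabled`,
#' `n_sim`, `n_null` and optional `grid`); `covariates_path` (TSV with
#' `probe_id`, `expression_count`, `pairing_frequency`).
#'
#' @param config list or YAML file path.
#' @return The report, invisibly: per-probe frequencies, categories,
#'   distance summaries, fitted models and comparisons.
#' @export
run_fish_pipeline <- function(config) {
  defaults <- list(
    out_dir = NULL, seed = 1L, tau = 0.5,
    generator = NULL, spots_path = NULL, nuclei_path = NULL,
    fit = list(enabled = FALSE, n_sim = 400, n_null = 600),
    covariates_path = NULL
  )
  cfg <- resolve_config(config, defaults)
  if (is.null(cfg$out_dir)) stop("config must name an out_dir")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)

  if (!is.null(cfg$spots_path) || !is.null(cfg$nuclei_path)) {
    spots <- read_tsv_table(cfg$spots_path)
    nuclei <- read_tsv_table(cfg$nuclei_path)
    truth <- NULL
  } else {
    gen_args <- if (is.list(cfg$generator)) cfg$generator else list()
    gen_cfg <- do.call(nuclei_config, gen_args)
    sim <- simulate_nuclei(gen_cfg)
    spots <- sim$spots
    nuclei <- sim$nuclei
    truth <- sim$truth
    write_tsv_table(spots, file.path(cfg$out_dir, "spots.tsv"))
    write_tsv_table(nuclei, file.path(cfg$out_dir, "nuclei.tsv"))
    write_tsv_table(truth, file.path(cfg$out_dir, "truth.tsv"))
  }

  probes <- unique(spots$probe_id)
  report <- list(seed = cfg$seed, tau = cfg$tau,
                 package_version = as.character(utils::packageVersion("homopair")),
                 probes = list())
  per_probe_rows <- list()
  for (probe in probes) {
    sc <- score_pairing(spots, probe, tau = cfg$tau)
    ia <- interallelic_distances(spots, nuclei, probe)
    sp <- spots[spots$probe_id == probe, , drop = FALSE]
    rad <- radial_distance(sp, nuclei)
    hist <- distance_histogram(ia$distance)
    box <- tukey_box_stats(ia$distance)
    entry <- list(
      frequency = sc$frequency,
      category = as.character(classify_frequency(sc$frequency)),
      n_scored = sc$n_scored, n_paired = sc$n_paired,
      per_replicate = sc$per_replicate,
      radial_mean = mean(rad),
      interallelic = list(
        n = nrow(ia), median = box$median,
        histogram_counts = hist$count, histogram_overflow = attr(hist, "overflow")
      )
    )
    if (isTRUE(cfg$fit$enabled)) {
      grid <- if (!is.null(cfg$fit$grid)) do.call(radial_grid, cfg$fit$grid)
              else radial_grid()
      fit <- fit_radial_model(rad, grid = grid, n_sim = cfg$fit$n_sim)
      null_d <- simulate_pair_distances(fit$model, fit$model, n = cfg$fit$n_null)
      cmp <- group_comparison(list(observed = ia$distance, simulated = null_d))
      entry$fit <- list(model = unclass(fit$model), ks_stat = fit$ks_stat)
      entry$null_comparison <- list(t = cmp$t, p = cmp$p,
                                    simulated_median = stats::median(null_d))
      write_tsv_table(data.frame(distance = null_d),
                      file.path(cfg$out_dir, paste0("null_distances_", probe, ".tsv")))
    }
    report$probes[[probe]] <- entry
    per_probe_rows[[probe]] <- data.frame(
      probe_id = probe, n_scored = sc$n_scored, n_paired = sc$n_paired,
      frequency = sc$frequency, category = entry$category,
      stringsAsFactors = FALSE
    )
    write_tsv_table(sc$per_replicate,
                    file.path(cfg$out_dir, paste0("pairing_", probe, ".tsv")))
    write_tsv_table(ia, file.path(cfg$out_dir, paste0("interallelic_", probe, ".tsv")))
  }
  summary_tab <- do.call(rbind, per_probe_rows)
  rownames(summary_tab) <- NULL
  write_tsv_table(summary_tab, file.path(cfg$out_dir, "pairing_summary.tsv"))

  if (!is.null(cfg$covariates_path)) {
    cov <- read_tsv_table(cfg$covariates_path)
    ct <- pearson_correlation(cov$expression_count, cov$pairing_frequency)
    report$covariates <- list(r = ct$r, p = ct$p, n = ct$n)
  }

  writeLines(yaml::as.yaml(cfg[!vapply(cfg, is.null, TRUE)]),
             file.path(cfg$out_dir, "config_resolved.yaml"))
  write_report_json(report, file.path(cfg$out_dir, "fish_report.json"))
  invisible(report)
}

#' Run the allele-specific 4C pipeline
#'
#' Generates (or reads) a two-haplotype genome with SNPs and a 4C read set,
#' digests both haplotypes, classifies fragments by allelic informativeness,
#' calls the allelic origin of each read from its covered SNPs, assembles
#' deduplicated bait-prey hits, and produces the three windowed summaries:
#' the 100 kb cis profile, the 200 kb trans-allelic hit rate, and the
#' genome-wide 1.4 Mb trans comparison with the homologous window flag. When
#' ground truth is available a truth-vs-called allele confusion table is
#' emitted. Outputs (BED fragment map, bedGraph cis profile, TSV summaries,
#' JSON report, resolved config) are written under `out_dir`.
#'
#' Config fields: `out_dir` (required); `seed`; `site`/`cut_offset`
#' (restriction digest, defaults AAGCTT/1); `read_length`; `genome` (list for
#' [make_haplotype_genome()]) or `b6_fasta`/`sd7_fasta`/`vcf_path`; `reads`
#' (list for [fourc_config()]; `bait_fragment_id` defaults to the middle
#' fragment of chr1) or `reads_fastq`+`reads_tsv` (pre-mapped TSV with
#' `read_id`, `bait_allele`, `prey_chrom`, `read_start`); `windows` (list
#' with `cis`, `trans_rate`, `genomewide`).
#'
#' @param config list or YAML file path.
#' @return The report, invisibly.
#' @export
run_4c_pipeline <- function(config) {
  defaults <- list(
    out_dir = NULL, seed = 1L, site = "AAGCTT", cut_offset = 1L,
    read_length = 50L, genome = NULL, b6_fasta = NULL, sd7_fasta = NULL,
    vcf_path = NULL, reads = NULL, reads_fastq = NULL, reads_tsv = NULL,
    windows = list(cis = 100000, trans_rate = 200000, genomewide = 1400000)
  )
  cfg <- resolve_config(config, defaults)
  if (is.null(cfg$out_dir)) stop("config must name an out_dir")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)

  # --- substrate: genome + SNPs -------------------------------------------
  if (!is.null(cfg$b6_fasta)) {
    genome <- read_genome_fasta(cfg$b6_fasta, cfg$sd7_fasta)
    snps <- read_snps_vcf(cfg$vcf_path)
    genome$snps <- snps
  } else {
    gen_args <- if (is.list(cfg$genome)) cfg$genome else list()
    if (is.null(gen_args$seed)) gen_args$seed <- cfg$seed
    genome <- do.call(make_haplotype_genome, gen_args)
    snps <- genome$snps
  }
  frag_b6 <- digest_genome(genome$b6, site = cfg$site, cut_offset = cfg$cut_offset)
  frag_sd7 <- digest_genome(genome$sd7, site = cfg$site, cut_offset = cfg$cut_offset)
  informative <- classify_informative(frag_b6, snps, read_length = cfg$read_length)
  chrom_lengths <- stats::setNames(Biostrings::width(genome$b6), names(genome$b6))

  # --- reads ---------------------------------------------------------------
  truth <- NULL
  if (!is.null(cfg$reads_tsv)) {
    mapped <- read_tsv_table(cfg$reads_tsv)
    reads <- if (!is.null(cfg$reads_fastq)) read_reads_fastq(cfg$reads_fastq) else NULL
    read_cfg <- NULL
  } else {
    read_args <- if (is.list(cfg$reads)) cfg$reads else list()
    if (is.null(read_args$bait_fragment_id)) {
      f1 <- frag_b6[frag_b6$chrom == frag_b6$chrom[1], ]
      read_args$bait_fragment_id <- f1$fragment_id[ceiling(nrow(f1) / 2)]
    }
    if (is.null(read_args$seed)) read_args$seed <- cfg$seed + 1L
    read_cfg <- do.call(fourc_config, read_args)
    sim <- simulate_4c_reads(read_cfg, list(b6 = frag_b6, sd7 = frag_sd7), genome)
    reads <- sim$reads
    truth <- sim$truth
    mapped <- truth[, c("read_id", "bait_allele", "prey_chrom", "read_start")]
    write_reads_fastq(reads, file.path(cfg$out_dir, "reads.fastq"))
    write_tsv_table(truth, file.path(cfg$out_dir, "reads_truth.tsv"))
  }

  bait_id <- if (!is.null(read_cfg)) read_cfg$bait_fragment_id
             else cfg$reads$bait_fragment_id
  if (is.null(bait_id)) stop("bait_fragment_id must be known to classify hits")
  bait_row <- frag_b6[frag_b6$fragment_id == bait_id, ]
  if (nrow(bait_row) != 1) stop("bait fragment not found on the B6 map")

  # --- allele calls and hits ----------------------------------------------
  if (!is.null(reads)) {
    seqs <- unname(reads[mapped$read_id])
    called <- assign_allele(seqs, mapped$prey_chrom, mapped$read_start, snps)
  } else {
    called <- rep("uninformative", nrow(mapped))
  }
  hits <- data.frame(
    read_id = mapped$read_id,
    bait_allele = mapped$bait_allele,
    prey_allele = called,
    prey_chrom = mapped$prey_chrom,
    prey_position = mapped$read_start,
    stringsAsFactors = FALSE
  )
  # reference (B6) coordinates are shared between haplotypes, so one
  # fragment map serves for position-to-fragment lookup
  hits$prey_fragment_id <- map_prey_fragment(hits$prey_chrom,
                                             hits$prey_position, frag_b6)
  known <- hits$prey_allele %in% c("B6", "SD7")
  hits$relation <- ifelse(
    hits$prey_chrom != bait_row$chrom, "trans_chromosomal",
    ifelse(known & hits$prey_allele != hits$bait_allele, "trans_allelic", "cis")
  )
  hits <- dedupe_positions(hits)

  cis_hits <- hits[hits$relation == "cis", ]
  ta_hits <- hits[hits$relation == "trans_allelic", ]
  trans_hits <- hits[hits$relation != "cis", ]

  cis_profile <- cis_window_profile(
    cis_hits, window = cfg$windows$cis,
    chrom_lengths = chrom_lengths[bait_row$chrom]
  )
  ta_rate <- trans_allelic_rate(ta_hits, informative,
                                window = cfg$windows$trans_rate,
                                chrom_lengths = chrom_lengths[bait_row$chrom])
  gw <- genomewide_trans_summary(
    trans_hits, chrom_lengths = chrom_lengths, window = cfg$windows$genomewide,
    homologous_window = list(chrom = bait_row$chrom,
                             start = (bait_row$start %/% cfg$windows$genomewide) *
                                     cfg$windows$genomewide,
                             end = (bait_row$start %/% cfg$windows$genomewide) *
                                   cfg$windows$genomewide + cfg$windows$genomewide)
  )

  # --- outputs -------------------------------------------------------------
  write_bed(frag_b6, file.path(cfg$out_dir, "fragments_B6.bed"),
            name_col = "fragment_id")
  write_tsv_table(informative, file.path(cfg$out_dir, "informative_fragments.tsv"))
  write_bedgraph(cis_profile, file.path(cfg$out_dir, "cis_profile_100kb.bedGraph"))
  write_tsv_table(ta_rate, file.path(cfg$out_dir, "trans_allelic_rate_200kb.tsv"))
  write_tsv_table(gw$windows, file.path(cfg$out_dir, "trans_genomewide_1400kb.tsv"))
  write_tsv_table(hits, file.path(cfg$out_dir, "hits_deduplicated.tsv"))

  report <- list(
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("homopair")),
    bait = list(fragment_id = bait_id, chrom = bait_row$chrom,
                start = bait_row$start, end = bait_row$end),
    n_fragments = nrow(frag_b6),
    n_stringent = sum(informative$class == "stringent"),
    n_reads = nrow(mapped),
    n_hits_unique = nrow(hits),
    n_cis = nrow(cis_hits), n_trans_allelic = nrow(ta_hits),
    n_trans_chromosomal = sum(hits$relation == "trans_chromosomal"),
    cis_profile_total = sum(cis_profile$count),
    homologous_window = gw$homologous,
    trans_box = unclass(gw$box)[c("median", "lower_hinge", "upper_hinge",
                                  "whisker_low", "whisker_high")],
    upper_fence = gw$upper_fence
  )
  if (!is.null(truth)) {
    confusion <- as.data.frame(table(truth = truth$prey_allele,
                                     called = called))
    write_tsv_table(confusion, file.path(cfg$out_dir, "allele_confusion.tsv"))
    covered <- called != "uninformative"
    report$allele_calling <- list(
      n_snp_covering = sum(covered),
      accuracy_snp_covering =
        if (any(covered)) mean(called[covered] == truth$prey_allele[covered])
        else NA_real_
    )
  }
  writeLines(yaml::as.yaml(cfg[!vapply(cfg, is.null, TRUE)]),
             file.path(cfg$out_dir, "config_resolved.yaml"))
  write_report_json(report, file.path(cfg$out_dir, "fourc_report.json"))
  invisible(report)
}
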