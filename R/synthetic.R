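#' Generate a two-haplotype genome with substitution SNPs
#'
#' The first haplotype (B6) is uniform random over A/C/G/T; the second (SD7)
#' differs by independent single-base substitutions at rate `snp_rate`, so
#' coordinates are shared between haplotypes. Every difference is recorded as
#' a SNP (ref = B6 base, alt = SD7 base).
#'
#' @param n_chroms Number of chromosomes (`chr1` ... `chrN`).
#' @param chrom_length Length of each chromosome in bp.
#' @param snp_rate Per-base substitution probability, in `[0, 0.1]`.
#' @param seed Optional seed for reproducibility.
#' @return list with `b6`, `sd7` ([Biostrings::DNAStringSet]) and `snps`
#'   (data.frame `chrom`, `pos` 0-based, `ref`, `alt`).
#' @export
make_haplotype_genome <- function(n_chroms = 20, chrom_length = 2e6,
                                  snp_rate = 2e-4, seed = NULL) {
  if (snp_rate < 0 || snp_rate > 0.1)
    stop("snp_rate must lie in [0, 0.1]")
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  b6 <- character(n_chroms)
  sd7 <- character(n_chroms)
  snps <- vector("list", n_chroms)
  for (k in seq_len(n_chroms)) {
    chrom <- paste0("chr", k)
    v <- sample(bases, chrom_length, replace = TRUE)
    s1 <- paste(v, collapse = "")
    idx <- which(stats::runif(chrom_length) < snp_rate)
    if (length(idx) > 0) {
      ref <- v[idx]
      alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
      raw <- charToRaw(s1)
      raw[idx] <- charToRaw(paste(alt, collapse = ""))
      s2 <- rawToChar(raw)
      snps[[k]] <- data.frame(chrom = chrom, pos = idx - 1L, ref = ref,
                              alt = unname(alt), stringsAsFactors = FALSE)
    } else {
      s2 <- s1
      snps[[k]] <- data.frame(chrom = character(0), pos = integer(0),
                              ref = character(0), alt = character(0))
    }
    b6[k] <- s1
    sd7[k] <- s2
  }
  names(b6) <- names(sd7) <- paste0("chr", seq_len(n_chroms))
  list(
    b6 = Biostrings::DNAStringSet(b6),
    sd7 = Biostrings::DNAStringSet(sd7),
    snps = do.call(rbind, snps)
  )
}

#' Configuration for the 4C read generator
#'
#' The generator emulates the structure of a linear 4C library on a hybrid
#' genome: a bait fragment assayed on both alleles, a cis contact profile
#' decaying with genomic distance as a shifted power law
#' `(|d| + d0)^(-alpha)`, a homologous trans-allelic peak of weight `beta`
#' centred on the bait position of the other haplotype, and a uniform
#' background of heterologous trans contacts of weight `gamma`. The
#' remaining mass `1 - beta - gamma` is cis. Defaults keep trans contacts
#' rare relative to cis and the background sparse enough that most genomic
#' windows collect no association, matching the qualitative structure of a
#' 4C contact map in which the vast majority of ligation products are cis.
#'
#' @param bait_fragment_id Fragment id of the bait (on the B6 map).
#' @param alpha Distance-decay exponent (> 0).
#' @param d0 Decay offset in bp.
#' @param beta Homologous trans-allelic weight in `[0, 1]`.
#' @param gamma Background trans weight in `[0, 1]`; `beta + gamma <= 1`.
#' @param n_reads Number of reads to simulate.
#' @param read_length Read length in bp.
#' @param error_rate Per-base uniform substitution error rate.
#' @param seed Optional seed.
#' @return list of class `fourc_config`.
#' @export
fourc_config <- function(bait_fragment_id, alpha = 1.5, d0 = 1e4,
                         beta = 0.02, gamma = 0.01, n_reads = 1e5,
                         read_length = 50, error_rate = 0, seed = NULL) {
  stopifnot(alpha > 0, d0 >= 0, beta >= 0, beta <= 1, gamma >= 0, gamma <= 1,
            n_reads >= 1, read_length >= 1, error_rate >= 0, error_rate < 1)
  if (beta + gamma > 1)
    stop("beta + gamma must not exceed 1")
  structure(
    list(bait_fragment_id = bait_fragment_id, alpha = alpha, d0 = d0,
         beta = beta, gamma = gamma, n_reads = as.integer(n_reads),
         read_length = as.integer(read_length), error_rate = error_rate,
         seed = seed),
    class = "fourc_config"
  )
}

#' Simulate 4C ligation-product reads on a hybrid genome
#'
#' For each read the bait allele is chosen fairly; the prey category is drawn
#' from {cis, homologous-trans, background-trans} with weights
#' `(1 - beta - gamma, beta, gamma)`; cis and homologous-trans prey fragments
#' are drawn with probability proportional to `(|d| + d0)^(-alpha)` where `d`
#' is the distance from the fragment midpoint to the bait midpoint (on the
#' bait haplotype for cis, on the other haplotype for homologous-trans);
#' background prey are uniform over the fragments of all other chromosomes on
#' a fairly chosen haplotype. Read bases are taken from the prey haplotype
#' starting inward from a randomly chosen ligation-junction fragment end
#' (reads are emitted on the forward strand with their true coordinates), and
#' the read's alignment start is recorded as the prey position. A ground-truth
#' table accompanies the reads so downstream callers can be validated.
#'
#' @param config A [fourc_config()].
#' @param fragments list with elements `b6` and `sd7`: per-haplotype fragment
#'   maps from [digest_genome()].
#' @param genome list with `b6` and `sd7` [Biostrings::DNAStringSet]
#'   haplotype sequences.
#' @return list with `reads` (named character vector of read sequences) and
#'   `truth` (data.frame `read_id`, `bait_allele`, `category`, `prey_allele`,
#'   `prey_chrom`, `prey_fragment_id`, `prey_position`, `read_start`,
#'   `read_width`).
#' @export
simulate_4c_reads <- function(config, fragments, genome) {
  stopifnot(inherits(config, "fourc_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  maps <- list(B6 = fragments$b6, SD7 = fragments$sd7)
  seqs <- list(B6 = as.character(genome$b6), SD7 = as.character(genome$sd7))
  if (any(vapply(maps, nrow, 0L) < 2))
    stop("degenerate fragment map: need at least 2 fragments per haplotype")
  bait_row <- maps$B6[maps$B6$fragment_id == config$bait_fragment_id, , drop = FALSE]
  if (nrow(bait_row) != 1)
    stop("bait fragment not found on the B6 fragment map")
  bait_chrom <- bait_row$chrom
  bait_mid <- (bait_row$start + bait_row$end) / 2
  # bait position exists on both haplotypes (shared coordinates)
  decay_weights <- function(map, centre) {
    mids <- (map$start + map$end) / 2
    (abs(mids - centre) + config$d0)^(-config$alpha)
  }
  n <- config$n_reads
  bait_allele <- sample(c("B6", "SD7"), n, replace = TRUE)
  category <- sample(c("cis", "hom_trans", "bg_trans"), n, replace = TRUE,
                     prob = c(1 - config$beta - config$gamma, config$beta,
                              config$gamma))
  prey_allele <- character(n)
  prey_idx <- integer(n)    # row in the prey haplotype map
  for (hap in c("B6", "SD7")) {
    other <- if (hap == "B6") "SD7" else "B6"
    # cis: prey on the bait haplotype, bait chromosome, decay around bait
    i <- which(bait_allele == hap & category == "cis")
    if (length(i) > 0) {
      rows <- which(maps[[hap]]$chrom == bait_chrom)
      w <- decay_weights(maps[[hap]][rows, ], bait_mid)
      # the bait fragment itself is not a prey
      self <- which(maps[[hap]]$start[rows] <= bait_mid &
                    maps[[hap]]$end[rows] > bait_mid)
      w[self] <- 0
      prey_idx[i] <- rows[sample.int(length(rows), length(i), replace = TRUE, prob = w)]
      prey_allele[i] <- hap
    }
    # homologous trans: prey on the other haplotype around the bait position
    i <- which(bait_allele == hap & category == "hom_trans")
    if (length(i) > 0) {
      rows <- which(maps[[other]]$chrom == bait_chrom)
      w <- decay_weights(maps[[other]][rows, ], bait_mid)
      prey_idx[i] <- rows[sample.int(length(rows), length(i), replace = TRUE, prob = w)]
      prey_allele[i] <- other
    }
  }
  # background: uniform over fragments off the bait chromosome, fair haplotype
  i <- which(category == "bg_trans")
  if (length(i) > 0) {
    hap_bg <- sample(c("B6", "SD7"), length(i), replace = TRUE)
    for (hap in c("B6", "SD7")) {
      ii <- i[hap_bg == hap]
      if (length(ii) == 0) next
      rows <- which(maps[[hap]]$chrom != bait_chrom)
      if (length(rows) == 0)
        stop("background trans requires more than one chromosome")
      prey_idx[ii] <- rows[sample.int(length(rows), length(ii), replace = TRUE)]
      prey_allele[ii] <- hap
    }
  }
  # extract read bases inward from a randomly chosen junction end
  side <- sample(c("left", "right"), n, replace = TRUE)
  read_id <- sprintf("R%06d", seq_len(n))
  prey_chrom <- character(n)
  prey_fragment_id <- character(n)
  prey_position <- numeric(n)
  read_start <- numeric(n)
  read_width <- integer(n)
  bases <- character(n)
  for (hap in c("B6", "SD7")) {
    i <- which(prey_allele == hap)
    if (length(i) == 0) next
    m <- maps[[hap]][prey_idx[i], , drop = FALSE]
    w <- pmin(config$read_length, m$end - m$start)
    s0 <- ifelse(side[i] == "left", m$start, m$end - w)
    prey_chrom[i] <- m$chrom
    prey_fragment_id[i] <- m$fragment_id
    # the read's 5' alignment coordinate identifies the position; it always
    # lies inside the prey fragment, so fragment lookup round-trips
    prey_position[i] <- s0
    read_start[i] <- s0
    read_width[i] <- w
    for (ch in unique(m$chrom)) {
      j <- i[m$chrom == ch]
      bases[j] <- substring(seqs[[hap]][[ch]], read_start[j] + 1,
                            read_start[j] + read_width[j])
    }
  }
  if (config$error_rate > 0) {
    alph <- c("A", "C", "G", "T")
    for (k in seq_len(n)) {
      hit <- which(stats::runif(read_width[k]) < config$error_rate)
      if (length(hit) > 0) {
        v <- strsplit(bases[k], "")[[1]]
        v[hit] <- vapply(v[hit], function(b) sample(setdiff(alph, b), 1), "")
        bases[k] <- paste(v, collapse = "")
      }
    }
  }
  names(bases) <- read_id
  truth <- data.frame(
    read_id = read_id, bait_allele = bait_allele,
    category = factor(category, levels = c("cis", "hom_trans", "bg_trans")),
    prey_allele = prey_allele, prey_chrom = prey_chrom,
    prey_fragment_id = prey_fragment_id, prey_position = prey_position,
    read_start = read_start, read_width = read_width,
    stringsAsFactors = FALSE
  )
  list(reads = bases, truth = truth)
}

#' Built-in probe presets for the nuclei generator
#'
#' Two presets reproduce the operational numbers of the foetal-liver
#' experiment: the KvDMR probe pairs in about 4% of nuclei, twice as often
#' as the myc control probe (2%). The radial models are illustrative biases
#' (KvDMR, near the telomere of its chromosome, is placed more peripherally
#' than myc); the pairing probabilities are the quantities under test.
#'
#' @return Named list; each element has `q` (true pairing probability) and
#'   `model` (a [radial_model()]).
#' @export
pairing_presets <- function() {
  list(
    kvdmr_liver = list(q = 0.04, model = radial_model(0.45, 0.10, 0.95, 0.05)),
    myc_liver   = list(q = 0.02, model = radial_model(0.25, 0.10, 0.85, 0.08))
  )
}

#' Configuration for the nuclei/spot generator
#'
#' @param probes Named list: each element a list with `q` (true pairing
#'   probability) and `model` (a [radial_model()]). Defaults to
#'   [pairing_presets()].
#' @param n_replicates Number of technical replicates (default 4).
#' @param nuclei_per_replicate Nuclei per replicate (default 300), matching
#'   the 4 x 300 scoring panels of the imaging experiment.
#' @param radius_um Nuclear radius in micrometres.
#' @param paired_offset_um Radius of the ball within which the second spot of
#'   a truly paired pair is placed; must be below the 0.5 um scoring
#'   threshold so the paired label is recoverable.
#' @param z_step_um z-plane spacing; spot z coordinates are quantized to this
#'   grid, emulating confocal stack sampling.
#' @param seed Optional seed.
#' @return list of class `nuclei_config`.
#' @export
nuclei_config <- function(probes = pairing_presets(), n_replicates = 4,
                          nuclei_per_replicate = 300, radius_um = 5,
                          paired_offset_um = 0.4, z_step_um = 0.5,
                          seed = NULL) {
  stopifnot(length(probes) >= 1, !is.null(names(probes)),
            n_replicates >= 1, nuclei_per_replicate >= 1, radius_um > 0,
            paired_offset_um > 0, z_step_um > 0)
  for (p in probes) {
    if (p$q < 0 || p$q > 1) stop("pairing probability q must lie in [0, 1]")
    stopifnot(inherits(p$model, "radial_model"))
  }
  if (paired_offset_um >= 0.5)
    stop("paired_offset_um must stay below the 0.5 um pairing threshold")
  structure(
    list(probes = probes, n_replicates = as.integer(n_replicates),
         nuclei_per_replicate = as.integer(nuclei_per_replicate),
         radius_um = radius_um, paired_offset_um = paired_offset_um,
         z_step_um = z_step_um, seed = seed),
    class = "nuclei_config"
  )
}

# uniform draw in a ball of given radius
runif_ball <- function(n, radius) {
  g <- matrix(stats::rnorm(3 * n), ncol = 3)
  nrm <- sqrt(rowSums(g^2))
  nrm[nrm < .Machine$double.eps] <- 1
  r <- radius * stats::runif(n)^(1 / 3)
  g * (r / nrm)
}

#' Simulate nuclei and FISH spot tables with known pairing probability
#'
#' Each nucleus carries two spots per probe. With probability `q` the pair is
#' truly paired: the first spot is placed under the probe's radial model and
#' the second uniformly within `paired_offset_um` of it (redrawn if it would
#' leave the nucleus). Otherwise the two spots are placed independently under
#' the radial model. Coordinates are converted to micrometres around a random
#' nuclear centroid, and z is quantized to `z_step_um` planes. The paired
#' label is defined at imaging resolution: for truly paired spots the offset
#' is redrawn until the post-quantization distance is below 0.5 um, so
#' quantization cannot silently flip ground truth (unpaired spots may still
#' fall within the threshold by chance; the scorer's recovery is therefore
#' exact up to chance proximity, which the test suite measures).
#'
#' @param config A [nuclei_config()].
#' @return list with `nuclei` (data.frame `nucleus_id`, `replicate`, `cx`,
#'   `cy`, `cz`, `radius_um`), `spots` (data.frame `nucleus_id`, `probe_id`,
#'   `replicate`, `x_um`, `y_um`, `z_um`), and `truth` (data.frame
#'   `nucleus_id`, `probe_id`, `paired`).
#' @export
simulate_nuclei <- function(config) {
  stopifnot(inherits(config, "nuclei_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  R <- config$radius_um
  zq <- function(z) round(z / config$z_step_um) * config$z_step_um
  n_nuc <- config$n_replicates * config$nuclei_per_replicate
  nuclei <- data.frame(
    nucleus_id = sprintf("N%05d", seq_len(n_nuc)),
    replicate = rep(seq_len(config$n_replicates),
                    each = config$nuclei_per_replicate),
    cx = stats::runif(n_nuc, 0, 200), cy = stats::runif(n_nuc, 0, 200),
    cz = stats::runif(n_nuc, 0, 20), radius_um = R,
    stringsAsFactors = FALSE
  )
  spots <- list()
  truth <- list()
  for (probe in names(config$probes)) {
    pr <- config$probes[[probe]]
    paired <- stats::runif(n_nuc) < pr$q
    a <- simulate_signals(pr$model, n_nuc)
    b <- simulate_signals(pr$model, n_nuc)  # used for unpaired nuclei
    ax <- nuclei$cx + R * a$x; ay <- nuclei$cy + R * a$y
    az <- zq(nuclei$cz + R * a$z)
    bx <- nuclei$cx + R * b$x; by <- nuclei$cy + R * b$y
    bz <- zq(nuclei$cz + R * b$z)
    for (k in which(paired)) {
      repeat {
        off <- runif_ball(1, config$paired_offset_um)
        pb <- c(ax[k] + off[1], ay[k] + off[2],
                nuclei$cz[k] + R * a$z[k] + off[3])
        # stay inside the nucleus
        if (sum((pb - c(nuclei$cx[k], nuclei$cy[k], nuclei$cz[k]))^2) > R^2) next
        pbz <- zq(pb[3])
        d <- sqrt((pb[1] - ax[k])^2 + (pb[2] - ay[k])^2 + (pbz - az[k])^2)
        if (d < 0.5) {
          bx[k] <- pb[1]; by[k] <- pb[2]; bz[k] <- pbz
          break
        }
      }
    }
    spots[[probe]] <- data.frame(
      nucleus_id = rep(nuclei$nucleus_id, 2), probe_id = probe,
      replicate = rep(nuclei$replicate, 2),
      x_um = c(ax, bx), y_um = c(ay, by), z_um = c(az, bz),
      stringsAsFactors = FALSE
    )
    truth[[probe]] <- data.frame(
      nucleus_id = nuclei$nucleus_id, probe_id = probe, paired = paired,
      stringsAsFactors = FALSE
    )
  }
  spots <- do.call(rbind, spots)
  truth <- do.call(rbind, truth)
  rownames(spots) <- rownames(truth) <- NULL
  list(nuclei = nuclei, spots = spots, truth = truth)
}

#' Simulate jointly correlated expression and pairing-frequency covariates
#'
#' Draws latent bivariate-normal pairs with correlation `target_r`, maps one
#' coordinate to a non-negative expression count (log-normal, rounded) and
#' the other to a pairing frequency clipped to `[0, 10]` percent. The sample
#' Pearson correlation converges (up to a small attenuation from the
#' exponential map, about 2% at the default log-sd of 0.3) to `target_r` as
#' `n` grows.
#'
#' @param probes Optional character vector of probe ids; generated as
#'   `P1...Pn` if omitted.
#' @param target_r Target correlation, `|target_r| < 1`.
#' @param n Number of probes (`>= 4`); defaults to `length(probes)`.
#' @param seed Optional seed.
#' @param log_mu,log_sd Location and scale of the log-normal expression map.
#' @return data.frame `probe_id`, `expression_count`, `pairing_frequency`.
#' @export
simulate_probe_covariates <- function(probes = NULL, target_r = 0.62,
                                      n = NULL, seed = NULL,
                                      log_mu = log(500), log_sd = 0.3) {
  if (is.null(n)) n <- length(probes)
  if (is.null(probes)) probes <- paste0("P", seq_len(n))
  stopifnot(length(probes) == n)
  if (abs(target_r) >= 1) stop("|target_r| must be below 1")
  if (n < 4) stop("need at least 4 probes")
  if (!is.null(seed)) set.seed(seed)
  z1 <- stats::rnorm(n)
  z2 <- target_r * z1 + sqrt(1 - target_r^2) * stats::rnorm(n)
  expr <- round(exp(log_mu + log_sd * z1))
  freq <- pmin(10, pmax(0, 5 + 1.5 * z2))
  if (stats::sd(expr) == 0)
    stop("degenerate expression counts (constant); increase n or log_sd")
  data.frame(probe_id = probes, expression_count = expr,
             pairing_frequency = freq, stringsAsFactors = FALSE)
}
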