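# Independent brute-force oracles and small fixture builders used across the
# suite. Oracles deliberately avoid the code paths they check.

# Tukey box-whisker by explicit sort-and-fence enumeration
oracle_box_stats <- function(x) {
  x <- sort(x)
  n <- length(x)
  med <- if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
  half <- function(v) {
    m <- length(v)
    if (m %% 2 == 1) v[(m + 1) / 2] else (v[m / 2] + v[m / 2 + 1]) / 2
  }
  lo_half <- x[seq_len(ceiling(n / 2))]
  hi_half <- x[seq(n - ceiling(n / 2) + 1, n)]
  lh <- half(lo_half)
  uh <- half(hi_half)
  iqr <- uh - lh
  lo_fence <- lh - 1.5 * iqr
  hi_fence <- uh + 1.5 * iqr
  inside <- x[x >= lo_fence & x <= hi_fence]
  list(median = med, lower_hinge = lh, upper_hinge = uh,
       whisker_low = min(inside), whisker_high = max(inside),
       outliers = x[x < lo_fence | x > hi_fence])
}

# histogram binning by per-value linear scan
oracle_hist_counts <- function(values, bin_width, centers) {
  counts <- integer(length(centers))
  overflow <- 0L
  for (v in values) {
    hit <- which(v >= centers - bin_width / 2 & v < centers + bin_width / 2)
    if (length(hit) == 0) overflow <- overflow + 1L
    else counts[hit[1]] <- counts[hit[1]] + 1L
  }
  list(counts = counts, overflow = overflow)
}

# fragment lookup by linear scan over the map
oracle_find_fragment <- function(chrom, pos, fragments) {
  row <- which(fragments$chrom == chrom & fragments$start <= pos &
               fragments$end > pos)
  fragments$fragment_id[row]
}

# Monte-Carlo estimate of P(c >= p) for clipped-normal exclusion limits
oracle_rejection_prob <- function(model, n = 1e5) {
  c0 <- pmin(pmax(rnorm(n, model$mu_c, model$sigma_c), 0), 1)
  p0 <- pmin(pmax(rnorm(n, model$mu_p, model$sigma_p), 0), 1)
  mean(c0 >= p0)
}

# spot table with prescribed inter-spot distances per nucleus, plus one
# 3-spot and one 1-spot nucleus: the hand-enumerated scoring fixture
toy_spot_table <- function(distances = c(0.1, 0.3, 0.49, 0.5, 0.51, 0.6, 1, 2),
                           probe = "probeA") {
  rows <- list()
  for (i in seq_along(distances)) {
    id <- sprintf("nuc%02d", i)
    rows[[length(rows) + 1]] <- data.frame(
      nucleus_id = id, probe_id = probe,
      x_um = c(0, distances[i]), y_um = 0, z_um = 0,
      stringsAsFactors = FALSE
    )
  }
  rows[[length(rows) + 1]] <- data.frame(
    nucleus_id = "nuc_three", probe_id = probe,
    x_um = c(0, 0.1, 0.2), y_um = 0, z_um = 0, stringsAsFactors = FALSE
  )
  rows[[length(rows) + 1]] <- data.frame(
    nucleus_id = "nuc_one", probe_id = probe,
    x_um = 0, y_um = 0, z_um = 0, stringsAsFactors = FALSE
  )
  do.call(rbind, rows)
}

# tiny deterministic fragment map on one chromosome
toy_fragment_map <- function(breaks = c(0, 11, 31, 50), chrom = "chrT") {
  data.frame(
    chrom = chrom,
    start = breaks[-length(breaks)],
    end = breaks[-1],
    fragment_id = paste0(chrom, "_F", seq_len(length(breaks) - 1)),
    stringsAsFactors = FALSE
  )
}
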