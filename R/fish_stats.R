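#' Score homologous pairing from 3D FISH spot tables
#'
#' Applies the operational pairing criterion: a nucleus is *scored* if it has
#' at least one spot for the probe; it is called *paired* only if it carries
#' exactly two spots for the probe and their 3D Euclidean distance is
#' strictly below `tau` micrometres. Nuclei with three or more spots are
#' scored but never paired (extra signals disqualify the call). The 0.5 um
#' default reflects the axial resolution of 0.5 um z-stacks: paired signals
#' are those less than 0.5 um apart.
#'
#' @param spots data.frame with columns `nucleus_id`, `probe_id`, `x_um`,
#'   `y_um`, `z_um` and optionally `replicate` (defaults to a single
#'   replicate).
#' @param probe Probe identifier to score.
#' @param tau Pairing distance threshold in micrometres (strict `<`).
#' @return Object of class `pairing_result`: list with `probe`, `tau`,
#'   `per_replicate` (data.frame `replicate`, `n_scored`, `n_paired`),
#'   `n_scored`, `n_paired`, `frequency` (percent, pooled over replicates),
#'   and `nuclei` (per-nucleus table with spot count, inter-spot distance for
#'   2-spot nuclei, and the paired call).
#' @examples
#' spots <- data.frame(
#'   nucleus_id = c(1, 1, 2, 2), probe_id = "kvdmr",
#'   x_um = c(0, 0.3, 0, 2), y_um = 0, z_um = 0
#' )
#' score_pairing(spots, "kvdmr")$frequency
#' @export
score_pairing <- function(spots, probe, tau = 0.5) {
  req <- c("nucleus_id", "probe_id", "x_um", "y_um", "z_um")
  if (!all(req %in% names(spots)))
    stop("spot table must have columns: ", paste(req, collapse = ", "))
  if (nrow(spots) == 0)
    stop("empty spot table")
  if (!probe %in% spots$probe_id)
    stop(sprintf("unknown probe_id '%s'", probe))
  if (tau <= 0)
    stop("pairing threshold tau must be positive")
  s <- spots[spots$probe_id == probe, , drop = FALSE]
  if (is.null(s$replicate)) s$replicate <- 1L
  idx <- split(seq_len(nrow(s)), s$nucleus_id)
  nuc <- data.frame(
    nucleus_id = names(idx),
    replicate = vapply(idx, function(i) as.character(s$replicate[i[1]]), ""),
    n_spots = lengths(idx),
    distance_um = NA_real_,
    paired = FALSE,
    stringsAsFactors = FALSE
  )
  two <- which(nuc$n_spots == 2L)
  for (k in two) {
    i <- idx[[k]]
    d <- sqrt((s$x_um[i[1]] - s$x_um[i[2]])^2 +
              (s$y_um[i[1]] - s$y_um[i[2]])^2 +
              (s$z_um[i[1]] - s$z_um[i[2]])^2)
    nuc$distance_um[k] <- d
    nuc$paired[k] <- d < tau
  }
  per <- do.call(rbind, lapply(split(nuc, nuc$replicate), function(g) {
    data.frame(replicate = g$replicate[1], n_scored = nrow(g),
               n_paired = sum(g$paired), stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  per$frequency <- 100 * per$n_paired / per$n_scored
  structure(
    list(
      probe = probe, tau = tau, per_replicate = per,
      n_scored = sum(per$n_scored), n_paired = sum(per$n_paired),
      frequency = 100 * sum(per$n_paired) / sum(per$n_scored),
      nuclei = nuc
    ),
    class = "pairing_result"
  )
}

#' @export
print.pairing_result <- function(x, ...) {
  cat(sprintf("pairing_result: probe %s, %d/%d nuclei paired (%.2f%%) at tau = %g um\n",
              x$probe, x$n_paired, x$n_scored, x$frequency, x$tau))
  invisible(x)
}

#' Radial distance of spots, as a fraction of the nuclear radius
#'
#' Distance from the spot to the nuclear centroid divided by the nuclear
#' radius. Values above 1 are possible when the nucleus is not a perfect
#' sphere and are returned unclipped.
#'
#' @param spots data.frame with `nucleus_id`, `x_um`, `y_um`, `z_um`.
#' @param nuclei data.frame with `nucleus_id`, `cx`, `cy`, `cz`, `radius_um`.
#' @return Numeric vector aligned with the rows of `spots`.
#' @export
radial_distance <- function(spots, nuclei) {
  stopifnot(all(nuclei$radius_um > 0))
  i <- match(spots$nucleus_id, nuclei$nucleus_id)
  if (anyNA(i))
    stop("spots reference nuclei missing from the nucleus table")
  sqrt((spots$x_um - nuclei$cx[i])^2 +
       (spots$y_um - nuclei$cy[i])^2 +
       (spots$z_um - nuclei$cz[i])^2) / nuclei$radius_um[i]
}

#' Normalized interallelic distance
#'
#' 3D Euclidean distance between two spots divided by the nuclear radius
#' (distance/radius), the scale on which interallelic distances are compared
#' across nuclei of different sizes.
#'
#' @param a,b data.frames (or single-row lists) with `x_um`, `y_um`, `z_um`;
#'   recycled to common length.
#' @param radius_um Nuclear radius (or radii) in micrometres.
#' @return Numeric vector of distances in units of nuclear radius.
#' @export
interallelic_distance <- function(a, b, radius_um) {
  stopifnot(all(radius_um > 0))
  sqrt((a$x_um - b$x_um)^2 + (a$y_um - b$y_um)^2 + (a$z_um - b$z_um)^2) / radius_um
}

#' Interallelic distances for all two-spot nuclei of a probe
#'
#' @param spots,nuclei Spot and nucleus tables (see [score_pairing()],
#'   [radial_distance()]).
#' @param probe Probe identifier.
#' @return data.frame with `nucleus_id` and `distance` (units of radius) for
#'   every nucleus carrying exactly two spots of the probe.
#' @export
interallelic_distances <- function(spots, nuclei, probe) {
  s <- spots[spots$probe_id == probe, , drop = FALSE]
  idx <- split(seq_len(nrow(s)), s$nucleus_id)
  idx <- idx[lengths(idx) == 2L]
  if (length(idx) == 0)
    return(data.frame(nucleus_id = character(0), distance = numeric(0)))
  r <- nuclei$radius_um[match(names(idx), nuclei$nucleus_id)]
  d <- vapply(idx, function(i) {
    sqrt((s$x_um[i[1]] - s$x_um[i[2]])^2 +
         (s$y_um[i[1]] - s$y_um[i[2]])^2 +
         (s$z_um[i[1]] - s$z_um[i[2]])^2)
  }, 0)
  data.frame(nucleus_id = names(idx), distance = unname(d) / r,
             stringsAsFactors = FALSE)
}

#' Fixed-bin histogram of normalized distances
#'
#' Default binning groups distances into four equal bins of width 0.7 radius
#' units centred at 0, 0.7, 1.4 and 2.1; each bin is the half-open interval
#' `[centre - width/2, centre + width/2)`. Values falling in no bin are
#' tallied as overflow, so bin counts plus overflow always equal the input
#' size.
#'
#' @param values Non-negative numeric vector of distances.
#' @param bin_width Bin width in the same units as `values`.
#' @param centers Bin centres.
#' @return data.frame with `center`, `lower`, `upper`, `count`; attribute
#'   `overflow` holds the count of values outside all bins.
#' @export
distance_histogram <- function(values, bin_width = 0.7,
                               centers = c(0, 0.7, 1.4, 2.1)) {
  if (any(values < 0))
    stop("distance_histogram expects non-negative values")
  lower <- centers - bin_width / 2
  upper <- centers + bin_width / 2
  counted <- rep(FALSE, length(values))
  count <- integer(length(centers))
  for (j in seq_along(centers)) {
    inbin <- !counted & values >= lower[j] & values < upper[j]
    count[j] <- sum(inbin)
    counted <- counted | inbin
  }
  out <- data.frame(center = centers, lower = lower, upper = upper, count = count)
  attr(out, "overflow") <- sum(!counted)
  out
}

#' Tukey box-whisker statistics
#'
#' Five-number summary with Tukey hinges (medians of the lower and upper
#' halves, the median included in both halves when n is odd), whiskers at the
#' most extreme data points within 1.5 IQR of the hinges, and everything
#' beyond flagged as outliers. Backed by [grDevices::boxplot.stats()], which
#' implements exactly this convention.
#'
#' @param values Non-empty numeric vector.
#' @return Object of class `box_stats`: list with `median`, `lower_hinge`,
#'   `upper_hinge`, `whisker_low`, `whisker_high`, `iqr`, `outliers`, `n`.
#' @export
tukey_box_stats <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0)
    stop("tukey_box_stats: empty input")
  bs <- grDevices::boxplot.stats(values, coef = 1.5, do.conf = FALSE)
  structure(
    list(
      median = bs$stats[3],
      lower_hinge = bs$stats[2],
      upper_hinge = bs$stats[4],
      whisker_low = bs$stats[1],
      whisker_high = bs$stats[5],
      iqr = bs$stats[4] - bs$stats[2],
      outliers = bs$out,
      n = bs$n
    ),
    class = "box_stats"
  )
}

#' @export
print.box_stats <- function(x, ...) {
  cat(sprintf(
    "box_stats (n = %d): whiskers [%.3g, %.3g], hinges [%.3g, %.3g], median %.3g, %d outlier(s)\n",
    x$n, x$whisker_low, x$whisker_high, x$lower_hinge, x$upper_hinge,
    x$median, length(x$outliers)
  ))
  invisible(x)
}

#' Pairing-frequency categories
#'
#' Partitions pairing frequencies (percent) into the three display
#' categories: high above 3.5%, medium from 2.5% to 3.5% (both boundaries
#' inclusive), low below 2.5%.
#'
#' @param frequency Numeric vector of frequencies in percent, in `[0, 100]`.
#' @return Factor with levels `low`, `medium`, `high`.
#' @export
classify_frequency <- function(frequency) {
  if (any(frequency < 0) || any(frequency > 100))
    stop("pairing frequencies must lie in [0, 100] percent")
  out <- ifelse(frequency > 3.5, "high", ifelse(frequency < 2.5, "low", "medium"))
  factor(out, levels = c("low", "medium", "high"))
}

#' Compare pairing or distance measurements between groups
#'
#' Two groups are compared by a two-sided unpaired pooled-variance t-test;
#' three or more groups by one-way ANOVA followed by all pairwise
#' pooled-variance t-tests with Bonferroni correction
#' (`p_adj = min(1, p_raw * n_comparisons)`). Two constant groups with equal
#' means return `t = 0, p = 1` by convention.
#'
#' @param groups Named list of two or more numeric vectors (each `n >= 2`).
#' @param method `"auto"` picks the test from the number of groups;
#'   `"t_test"` and `"anova_bonferroni"` force one.
#' @return For two groups, a list with `method`, `t`, `df`, `p`. For more, a
#'   list with `method`, `anova` (`F`, `df`, `p`) and `pairwise`
#'   (data.frame `group1`, `group2`, `t`, `p_raw`, `p_adj`).
#' @export
group_comparison <- function(groups, method = c("auto", "t_test", "anova_bonferroni")) {
  method <- match.arg(method)
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  if (any(vapply(groups, length, 0L) < 2))
    stop("each group needs at least 2 observations")
  if (method == "auto")
    method <- if (length(groups) == 2) "t_test" else "anova_bonferroni"
  pooled_t <- function(x, y) {
    nx <- length(x); ny <- length(y)
    sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
    df <- nx + ny - 2
    if (sp2 == 0) {
      if (mean(x) == mean(y)) return(list(t = 0, df = df, p = 1))
      return(list(t = sign(mean(x) - mean(y)) * Inf, df = df, p = 0))
    }
    t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
    list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
  }
  if (method == "t_test") {
    if (length(groups) != 2)
      stop("t_test requires exactly 2 groups")
    r <- pooled_t(groups[[1]], groups[[2]])
    return(list(method = "t_test", t = r$t, df = r$df, p = r$p))
  }
  value <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(names(groups), vapply(groups, length, 0L)),
                levels = names(groups))
  fit <- stats::aov(value ~ grp)
  an <- summary(fit)[[1]]
  combos <- utils::combn(names(groups), 2)
  n_comp <- ncol(combos)
  pw <- do.call(rbind, lapply(seq_len(n_comp), function(k) {
    g1 <- combos[1, k]; g2 <- combos[2, k]
    r <- pooled_t(groups[[g1]], groups[[g2]])
    data.frame(group1 = g1, group2 = g2, t = r$t, p_raw = r$p,
               p_adj = min(1, r$p * n_comp), stringsAsFactors = FALSE)
  }))
  list(
    method = "anova_bonferroni",
    anova = list(F = an$`F value`[1], df = an$Df, p = an$`Pr(>F)`[1]),
    pairwise = pw
  )
}

#' Gene density and expression count over a probe interval
#'
#' Gene density is the fraction of the probe interval covered by the union of
#' gene intervals; the expression count is the number of read positions
#' falling inside the probe. All intervals are 0-based, half-open.
#'
#' @param probe list or single-row data.frame with `chrom`, `start`, `end`.
#' @param genes data.frame of gene intervals with `chrom`, `start`, `end`.
#' @param reads data.frame of read positions with `chrom`, `pos`.
#' @return list with `gene_density` (fraction in `[0, 1]`) and
#'   `expression_count`.
#' @export
probe_covariates <- function(probe, genes, reads) {
  check_iv <- function(s, e, what) {
    if (any(s >= e)) stop(sprintf("malformed %s interval (start >= end)", what))
  }
  check_iv(probe$start, probe$end, "probe")
  g <- genes[genes$chrom == probe$chrom, , drop = FALSE]
  density <- 0
  if (nrow(g) > 0) {
    check_iv(g$start, g$end, "gene")
    # 0-based half-open -> 1-based closed for IRanges
    giv <- IRanges::reduce(IRanges::IRanges(g$start + 1, g$end))
    piv <- IRanges::IRanges(probe$start + 1, probe$end)
    ov <- IRanges::intersect(giv, piv)
    density <- sum(IRanges::width(ov)) / (probe$end - probe$start)
  }
  nreads <- sum(reads$chrom == probe$chrom &
                reads$pos >= probe$start & reads$pos < probe$end)
  list(gene_density = density, expression_count = nreads)
}

#' Pearson correlation with two-sided p-value
#'
#' Standard Pearson r with the p-value from the t transform, via
#' [stats::cor.test()]. Zero-variance input is rejected explicitly rather
#' than propagating NaN.
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @return list with `r`, `p`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for zero-variance input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
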