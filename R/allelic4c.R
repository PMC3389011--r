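#' In-silico restriction digestion of a genome
#'
#' Cuts every chromosome at `start + cut_offset` of each exact occurrence of
#' the recognition site and returns the resulting fragment map: 0-based,
#' half-open fragments tiling each chromosome without gaps or overlaps.
#' Zero-length fragments (cuts at a chromosome end) are dropped. The two
#' haplotypes of a hybrid genome are digested independently, since SNPs can
#' create or destroy recognition sites.
#'
#' @param genome Named character vector or [Biostrings::DNAStringSet] of
#'   chromosome sequences.
#' @param site Recognition sequence over A/C/G/T. The default AAGCTT with
#'   `cut_offset = 1` corresponds to HindIII (A^AGCTT).
#' @param cut_offset Cut position within the site, `0 <= cut_offset <=
#'   nchar(site)`.
#' @return data.frame with `chrom`, `start`, `end`, `fragment_id`.
#' @export
digest_genome <- function(genome, site = "AAGCTT", cut_offset = 1L) {
  if (!nzchar(site) || grepl("[^ACGT]", site))
    stop("recognition site must be a non-empty string over A/C/G/T")
  if (cut_offset < 0 || cut_offset > nchar(site))
    stop("cut_offset must lie within the recognition site")
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (is.null(names(genome)))
    stop("chromosome sequences must be named")
  out <- lapply(names(genome), function(chrom) {
    seq <- genome[[chrom]]
    len <- length(seq)
    m <- Biostrings::matchPattern(site, seq)
    cuts <- BiocGenerics::start(m) - 1L + as.integer(cut_offset)  # 0-based
    bounds <- sort(unique(c(0L, cuts, len)))
    s <- bounds[-length(bounds)]
    e <- bounds[-1]
    keep <- e > s
    data.frame(chrom = chrom, start = s[keep], end = e[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$fragment_id <- paste0(out$chrom, "_F", stats::ave(
    seq_len(nrow(out)), out$chrom, FUN = seq_along))
  rownames(out) <- NULL
  out
}

#' Classify fragments by allelic informativeness
#'
#' A fragment is *stringently informative* if at least one substitution SNP
#' lies within `read_length` bases of either fragment end, so a read
#' sequenced inward from a ligation junction covers a strain-distinguishing
#' base. A fragment whose only SNPs lie deeper than that is *weakly*
#' informative (the SNP exists but junction reads cannot see it); fragments
#' without SNPs are uninformative.
#'
#' @param fragments Fragment map from [digest_genome()].
#' @param snps data.frame with `chrom`, `pos` (0-based), `ref`, `alt`.
#' @param read_length Read length in bp.
#' @return data.frame: `fragment_id`, `chrom`, `start`, `end`, `n_snps`,
#'   `class` (factor stringent/weak/uninformative).
#' @export
classify_informative <- function(fragments, snps, read_length = 50) {
  stopifnot(read_length > 0)
  cls <- rep("uninformative", nrow(fragments))
  nsnp <- integer(nrow(fragments))
  for (chrom in unique(fragments$chrom)) {
    fi <- which(fragments$chrom == chrom)
    f <- fragments[fi, , drop = FALSE]
    sp <- snps$pos[snps$chrom == chrom]
    if (length(sp) == 0) next
    if (any(sp < min(f$start) | sp >= max(f$end)))
      stop("SNP position outside the fragment map: corrupt tiling?")
    j <- findInterval(sp, f$start)  # fragments tile, so j >= 1
    near <- sp < f$start[j] + read_length | sp >= f$end[j] - read_length
    nsnp[fi] <- tabulate(j, nbins = nrow(f))
    has_near <- unique(j[near])
    has_any <- unique(j)
    cls[fi[has_any]] <- "weak"
    cls[fi[has_near]] <- "stringent"
  }
  data.frame(
    fragment_id = fragments$fragment_id,
    chrom = fragments$chrom, start = fragments$start, end = fragments$end,
    n_snps = nsnp,
    class = factor(cls, levels = c("stringent", "weak", "uninformative")),
    stringsAsFactors = FALSE
  )
}

#' Call the allelic origin of aligned reads from SNP bases
#'
#' For each read, every SNP covered by its alignment interval is inspected:
#' if all covered SNP bases match one haplotype the read is assigned that
#' allele; conflicting matches (or a base matching neither haplotype) yield
#' `ambiguous`; reads covering no SNP are `uninformative`. Reads are assumed
#' aligned without indels, as holds for the substitution-only synthetic
#' setting.
#'
#' @param read_bases Character vector of read sequences (forward strand).
#' @param chrom,start Alignment chromosome and 0-based start per read.
#' @param snps SNP table (`chrom`, `pos` 0-based, `ref` = first-haplotype
#'   base, `alt` = second-haplotype base).
#' @param alleles Length-2 character: allele names for ref and alt matches.
#' @return Character vector per read: one of the two allele names,
#'   `"ambiguous"`, or `"uninformative"`.
#' @export
assign_allele <- function(read_bases, chrom, start, snps,
                          alleles = c("B6", "SD7")) {
  n <- length(read_bases)
  stopifnot(length(chrom) == n, length(start) == n, length(alleles) == 2)
  width <- nchar(read_bases)
  reads_gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, start + width))
  snps_gr <- GenomicRanges::GRanges(snps$chrom, IRanges::IRanges(snps$pos + 1, snps$pos + 1))
  hits <- GenomicRanges::findOverlaps(reads_gr, snps_gr)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  call <- rep("uninformative", n)
  if (length(q) > 0) {
    base <- substr(read_bases[q], snps$pos[s] - start[q] + 1,
                   snps$pos[s] - start[q] + 1)
    m_ref <- base == snps$ref[s]
    m_alt <- base == snps$alt[s]
    # per read: 1 = ref, 2 = alt, 3 = neither
    code <- ifelse(m_ref, 1L, ifelse(m_alt, 2L, 3L))
    agg_min <- tapply(code, q, min)
    agg_max <- tapply(code, q, max)
    rid <- as.integer(names(agg_min))
    verdict <- ifelse(agg_min == agg_max & agg_min == 1L, alleles[1],
               ifelse(agg_min == agg_max & agg_min == 2L, alleles[2],
                      "ambiguous"))
    call[rid] <- verdict
  }
  call
}

#' Map genomic positions to restriction fragments
#'
#' Binary search over the half-open fragment tiling; a position equal to a
#' fragment end belongs to the downstream fragment.
#'
#' @param chrom,pos Vectors of chromosome names and 0-based positions.
#' @param fragments Fragment map from [digest_genome()].
#' @return Character vector of fragment ids.
#' @export
map_prey_fragment <- function(chrom, pos, fragments) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n)
  pos <- rep_len(pos, n)
  out <- rep(NA_character_, n)
  for (ch in unique(chrom)) {
    f <- fragments[fragments$chrom == ch, , drop = FALSE]
    if (nrow(f) == 0)
      stop(sprintf("chromosome '%s' absent from the fragment map", ch))
    i <- which(chrom == ch)
    p <- pos[i]
    if (any(p < min(f$start) | p >= max(f$end)))
      stop(sprintf("position out of bounds on chromosome '%s'", ch))
    out[i] <- f$fragment_id[findInterval(p, f$start)]
  }
  out
}

#' Deduplicate 4C associations to unique positions
#'
#' Each position is counted only once: one hit is retained per unique
#' `(prey_chrom, prey_position, bait_allele, prey_allele)` key, so the
#' maternal- and paternal-bait profiles stay independent. Output is sorted by
#' genome coordinate and the operation is idempotent.
#'
#' @param hits data.frame with at least `prey_chrom`, `prey_position`,
#'   `bait_allele`, `prey_allele`.
#' @return The deduplicated, coordinate-sorted data.frame.
#' @export
dedupe_positions <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  o <- order(hits$prey_chrom, hits$prey_position)
  hits <- hits[o, , drop = FALSE]
  key <- paste(hits$prey_chrom, hits$prey_position,
               hits$bait_allele, hits$prey_allele, sep = "\r")
  out <- hits[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

window_tiles <- function(chrom, length, window) {
  starts <- seq(0, length - 1, by = window)
  data.frame(chrom = chrom, start = starts,
             end = pmin(starts + window, length),
             stringsAsFactors = FALSE)
}

#' Windowed profile of unique cis contact positions
#'
#' Counts deduplicated contact positions per half-open window tiled from
#' coordinate 0 (the display used for cis association profiles, 100 kb
#' windows by default).
#'
#' @param hits Deduplicated hits (`prey_chrom`, `prey_position`).
#' @param window Window size in bp.
#' @param chrom_lengths Optional named vector of chromosome lengths; when
#'   given, empty windows are included up to each chromosome end.
#' @return data.frame `chrom`, `start`, `end`, `count`.
#' @export
cis_window_profile <- function(hits, window = 100000, chrom_lengths = NULL) {
  stopifnot(window > 0)
  if (is.null(chrom_lengths)) {
    if (nrow(hits) == 0)
      return(data.frame(chrom = character(0), start = numeric(0),
                        end = numeric(0), count = integer(0)))
    chrom_lengths <- tapply(hits$prey_position, hits$prey_chrom, max) + 1
  }
  tiles <- do.call(rbind, lapply(names(chrom_lengths), function(ch)
    window_tiles(ch, chrom_lengths[[ch]], window)))
  tiles$count <- 0L
  if (nrow(hits) > 0) {
    key_hit <- paste(hits$prey_chrom, hits$prey_position %/% window)
    tab <- table(key_hit)
    key_tile <- paste(tiles$chrom, tiles$start %/% window)
    i <- match(names(tab), key_tile)
    if (anyNA(i)) stop("hit position beyond the supplied chromosome lengths")
    tiles$count[i] <- as.integer(tab)
  }
  tiles
}

#' Trans-allelic hit rate per window
#'
#' For each window (200 kb by default), the rate is the number of distinct
#' stringently informative fragments hit by at least one trans-allelic
#' association, divided by the number of stringently informative fragments in
#' the window (fragments are assigned to the window containing their start).
#' Windows without any stringent fragment carry a missing (`NA`) rate — no
#' allelic information exists there — which is distinct from a rate of zero.
#'
#' @param hits Trans-allelic hits with a `prey_fragment_id` column.
#' @param informative Classification table from [classify_informative()].
#' @param window Window size in bp.
#' @param chrom_lengths Named vector of chromosome lengths (defaults to the
#'   extent of the informative-fragment table).
#' @return data.frame `chrom`, `start`, `end`, `n_stringent`,
#'   `n_hit_fragments`, `rate`.
#' @export
trans_allelic_rate <- function(hits, informative, window = 200000,
                               chrom_lengths = NULL) {
  stopifnot(window > 0)
  stringent <- informative[informative$class == "stringent", , drop = FALSE]
  if (is.null(chrom_lengths))
    chrom_lengths <- tapply(informative$end, informative$chrom, max)
  tiles <- do.call(rbind, lapply(names(chrom_lengths), function(ch)
    window_tiles(ch, chrom_lengths[[ch]], window)))
  key_tile <- paste(tiles$chrom, tiles$start %/% window)
  tiles$n_stringent <- 0L
  if (nrow(stringent) > 0) {
    tab <- table(paste(stringent$chrom, stringent$start %/% window))
    i <- match(names(tab), key_tile)
    tiles$n_stringent[i[!is.na(i)]] <- as.integer(tab[!is.na(i)])
  }
  tiles$n_hit_fragments <- 0L
  hit_frags <- unique(hits$prey_fragment_id)
  hit_frags <- hit_frags[hit_frags %in% stringent$fragment_id]
  if (length(hit_frags) > 0) {
    hf <- stringent[match(hit_frags, stringent$fragment_id), , drop = FALSE]
    tab <- table(paste(hf$chrom, hf$start %/% window))
    i <- match(names(tab), key_tile)
    tiles$n_hit_fragments[i[!is.na(i)]] <- as.integer(tab[!is.na(i)])
  }
  tiles$rate <- ifelse(tiles$n_stringent > 0,
                       tiles$n_hit_fragments / tiles$n_stringent, NA_real_)
  tiles
}

#' Genome-wide trans contact summary with homologous-window flag
#'
#' Tiles the genome into windows (1.4 Mb by default, matching the size of
#' the region carrying allelic information), counts unique trans contact
#' positions of the bait per window, summarises the counts as Tukey
#' box-whisker statistics, and flags windows whose count exceeds the upper
#' Tukey fence (`upper hinge + 1.5 IQR`) as over-represented. The designated
#' homologous window — the window on the bait chromosome's homologue
#' containing the bait region — is reported separately with its count and
#' outlier status, so homologous trans-allelic contacts can be ranked against
#' heterologous trans contacts genome-wide.
#'
#' @param hits Deduplicated trans hits (`prey_chrom`, `prey_position`).
#' @param chrom_lengths Named vector of chromosome lengths to tile.
#' @param window Window size in bp.
#' @param homologous_window list or single-row data.frame with `chrom`,
#'   `start`, `end` delimiting the homologous region; if not aligned to the
#'   tiling, the tiling window containing its midpoint is used (with a
#'   message).
#' @return list with `windows` (data.frame `chrom`, `start`, `end`, `count`,
#'   `outlier`), `box` ([tukey_box_stats()] of the counts), `upper_fence`,
#'   and `homologous` (`chrom`, `start`, `end`, `count`, `outlier`).
#' @export
genomewide_trans_summary <- function(hits, chrom_lengths, window = 1400000,
                                     homologous_window) {
  stopifnot(window > 0)
  tiles <- cis_window_profile(hits, window = window,
                              chrom_lengths = chrom_lengths)
  box <- tukey_box_stats(tiles$count)
  fence <- box$upper_hinge + 1.5 * box$iqr
  tiles$outlier <- tiles$count > fence
  hw_start <- (homologous_window$start %/% window) * window
  mid <- (homologous_window$start + homologous_window$end) / 2
  if (homologous_window$start != hw_start ||
      homologous_window$end - homologous_window$start != window) {
    hw_start <- (mid %/% window) * window
    message(sprintf(
      "homologous window not aligned to the %g bp tiling; using containing window %s:%d-%d",
      window, homologous_window$chrom, hw_start, hw_start + window))
  }
  i <- which(tiles$chrom == homologous_window$chrom & tiles$start == hw_start)
  if (length(i) != 1)
    stop("homologous window outside the tiled genome")
  list(
    windows = tiles,
    box = box,
    upper_fence = fence,
    homologous = list(chrom = homologous_window$chrom, start = tiles$start[i],
                      end = tiles$end[i], count = tiles$count[i],
                      outlier = tiles$outlier[i])
  )
}
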