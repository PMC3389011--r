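# Readers and writers for the plain-text interchange formats used by the
# pipelines. Spot/nucleus/summary tables are TSV; genomes are FASTA
# (Biostrings); reads are FASTQ; SNPs are a minimal substitution-only
# VCFv4.2; genomic tracks are BED/bedGraph.

#' Write and read TSV tables
#'
#' Plain tab-separated tables with a header row, no quoting, no row names —
#' the interchange format for spot tables, nucleus tables, truth tables and
#' summary outputs.
#'
#' @param x data.frame to write.
#' @param path File path.
#' @return `read_tsv_table` returns a data.frame; `write_tsv_table` returns
#'   `path` invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  if (!file.exists(path))
    stop(sprintf("input table not found: %s", path))
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write a two-haplotype genome as FASTA files
#'
#' @param genome list with `b6` and `sd7` [Biostrings::DNAStringSet].
#' @param dir Output directory.
#' @return Character vector of the two file paths, invisibly.
#' @export
write_genome_fasta <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "haplotype_B6.fa")
  p2 <- file.path(dir, "haplotype_SD7.fa")
  Biostrings::writeXStringSet(genome$b6, p1)
  Biostrings::writeXStringSet(genome$sd7, p2)
  invisible(c(p1, p2))
}

#' Read a two-haplotype genome from FASTA files
#'
#' @param b6_path,sd7_path FASTA paths for the two haplotypes.
#' @return list with `b6` and `sd7` [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(b6_path, sd7_path) {
  for (p in c(b6_path, sd7_path))
    if (!file.exists(p)) stop(sprintf("haplotype FASTA not found: %s", p))
  list(b6 = Biostrings::readDNAStringSet(b6_path),
       sd7 = Biostrings::readDNAStringSet(sd7_path))
}

#' Minimal substitution-only VCF writer and reader
#'
#' Writes SNP tables as VCFv4.2 with CHROM/POS/ID/REF/ALT/QUAL/FILTER/INFO
#' columns and no genotypes (positions are converted between the package's
#' 0-based convention and VCF's 1-based one). The reader accepts any VCF
#' whose records are single-base substitutions and ignores additional
#' columns.
#'
#' @param snps data.frame `chrom`, `pos` (0-based), `ref`, `alt`.
#' @param path File path.
#' @return `read_snps_vcf` returns the SNP data.frame; `write_snps_vcf`
#'   returns `path` invisibly.
#' @export
write_snps_vcf <- function(snps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=homopair",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  ), con)
  if (nrow(snps) > 0)
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                       snps$chrom, snps$pos + 1L, snps$ref, snps$alt), con)
  invisible(path)
}

#' @rdname write_snps_vcf
#' @export
read_snps_vcf <- function(path) {
  if (!file.exists(path)) stop(sprintf("VCF not found: %s", path))
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0)
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0)))
  f <- strsplit(body, "\t", fixed = TRUE)
  chrom <- vapply(f, `[`, "", 1)
  pos <- as.integer(vapply(f, `[`, "", 2)) - 1L
  ref <- vapply(f, `[`, "", 4)
  alt <- vapply(f, `[`, "", 5)
  keep <- nchar(ref) == 1 & nchar(alt) == 1
  data.frame(chrom = chrom[keep], pos = pos[keep], ref = ref[keep],
             alt = alt[keep], stringsAsFactors = FALSE)
}

#' Write simulated reads as FASTQ
#'
#' Constant placeholder qualities ("I", Q40) are used: the generator has no
#' quality model.
#'
#' @param reads Named character vector of read sequences.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(unname(reads))
  names(x) <- names(reads)
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(strrep("I", nchar(reads)))
  )
  invisible(path)
}

#' Read FASTQ reads as a named character vector
#'
#' @param path FASTQ path.
#' @return Named character vector of read sequences.
#' @export
read_reads_fastq <- function(path) {
  if (!file.exists(path)) stop(sprintf("FASTQ not found: %s", path))
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(x)
  names(out) <- names(x)
  out
}

#' Write intervals as BED / counts as bedGraph
#'
#' Both formats are 0-based half-open, matching the package's internal
#' convention.
#'
#' @param x data.frame with `chrom`, `start`, `end` and, for bedGraph, a
#'   value column.
#' @param path Output path.
#' @param name_col,value_col Column holding the BED name / bedGraph value.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, name_col = NULL) {
  df <- data.frame(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
                   format(x$end, scientific = FALSE, trim = TRUE))
  if (!is.null(name_col)) df[[4]] <- x[[name_col]]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
write_bedgraph <- function(x, path, value_col = "count") {
  df <- data.frame(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
                   format(x$end, scientific = FALSE, trim = TRUE),
                   x[[value_col]])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene intervals from a GFF3 annotation
#'
#' Imports gene features via rtracklayer and returns 0-based half-open
#' intervals as used by [probe_covariates()].
#'
#' @param path GFF3 path.
#' @param feature Feature type to keep (default "gene").
#' @return data.frame `chrom`, `start`, `end`.
#' @export
read_gff3_genes <- function(path, feature = "gene") {
  if (!file.exists(path)) stop(sprintf("GFF3 not found: %s", path))
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GFF3 requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == feature]
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr), stringsAsFactors = FALSE)
}

#' Serialise a radial model as a YAML block
#'
#' @param model A [radial_model()].
#' @param path Optional file path; when `NULL` the YAML string is returned.
#' @return YAML string (invisibly, when written to file).
#' @export
radial_model_yaml <- function(model, path = NULL) {
  y <- yaml::as.yaml(list(radial_model = unclass(model)))
  if (!is.null(path)) {
    writeLines(y, path)
    return(invisible(y))
  }
  y
}
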