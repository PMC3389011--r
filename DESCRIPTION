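Package: homopair
Title: Allele-Specific 4C-Seq and 3D DNA-FISH Analysis of Homologous Pairing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies homologous chromosome pairing in interphase nuclei
    from two complementary assays. For linear 4C-Seq on a hybrid (SNP-bearing)
    genome it performs in-silico restriction digestion, classification of
    allelically informative fragments, SNP-based allele calling of bait-prey
    ligation products, unique-position deduplication, and windowed cis/trans
    contact summaries with Tukey outlier flagging of the homologous window.
    For 3D DNA FISH it scores pairing from spot coordinate tables with a
    distance criterion, computes radial and normalized interallelic distance
    statistics, and compares observed interallelic distances against a
    radially constrained null model that places signals in a unit sphere
    between sampled central and peripheric exclusion limits. A synthetic-data
    module generates haplotype genomes, 4C read sets with cis distance decay
    and a homologous trans peak, and nucleus/spot tables with a known pairing
    probability, so every estimator can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    grDevices,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
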