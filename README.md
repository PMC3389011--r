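# homopair

Quantifies **homologous chromosome pairing** — the transient spatial
proximity of the two parental alleles of a genomic region in interphase
nuclei — from the two assays that can detect it:

* **Allele-specific linear 4C-Seq** on a hybrid genome: in-silico
  restriction digestion of both haplotypes, classification of *stringently
  informative* fragments (a strain-distinguishing SNP readable from a
  ligation junction), SNP-based allele calling of bait–prey products,
  unique-position deduplication, and windowed summaries — unique cis
  positions per 100 kb window, trans-allelic hit rate per 200 kb window
  (distinct stringent fragments hit ÷ stringent fragments present), and a
  genome-wide 1.4 Mb trans comparison in which windows beyond the upper
  Tukey fence (upper hinge + 1.5·IQR) are flagged and the homologous window
  is reported separately.
* **3D DNA FISH** spot tables: a nucleus is *paired* iff it has exactly two
  spots of a probe strictly less than τ = 0.5 µm apart (the z-stack
  resolution) and no further signals; frequencies are aggregated over
  4 × 300-nucleus replicate panels and categorised (high > 3.5 %, medium
  2.5–3.5 %, low < 2.5 %). Radial distances (r/R, unclipped) and normalized
  interallelic distances (d/R) are summarised as Tukey box-whisker
  statistics and 0.7r-bin histograms.

The null model for interallelic distances places signals volume-uniformly in
a unit sphere between two radial *exclusion limits* c ~ N(μ_c, σ_c) and
p ~ N(μ_p, σ_p) (clipped to [0, 1], redrawn while c ≥ p), with the radial
coordinate r = (c³ + u·(p³ − c³))^{1/3}. Limits are fitted to observed
radial distributions by exhaustive grid search on the two-sample
Kolmogorov–Smirnov distance, and the fitted model yields the expected
interallelic distance distribution if allele positions are otherwise random.

A first-class **synthetic-data module** generates every input with known
ground truth — two-haplotype genomes with SNPs, 4C read sets with power-law
cis decay `(|d| + d0)^(−α)`, a homologous trans peak (weight β) and uniform
trans background (γ), and nucleus/spot tables with a known pairing
probability q — so every estimator is validated by parameter recovery. See
`vignettes/homologous-pairing-methods.Rmd` for the full model description.

## Worked example

Score synthetic foetal-liver-like nuclei generated at the built-in presets
(KvDMR-like probe, true pairing probability 4 %; myc-like control, 2 %):

```r
library(homopair)
sim <- simulate_nuclei(nuclei_config(seed = 1))   # 4 x 300 nuclei, 2 probes
score_pairing(sim$spots, "kvdmr_liver", tau = 0.5)
#> pairing_result: probe kvdmr_liver, 54/1200 nuclei paired (4.50%) at tau = 0.5 um
score_pairing(sim$spots, "myc_liver", tau = 0.5)
#> pairing_result: probe myc_liver, 21/1200 nuclei paired (1.75%) at tau = 0.5 um
```

The scorer recovers the generative truth (4 % vs 2 %) up to binomial noise
and ~0.1 pp of chance proximity. The full analyses live in `analysis/` as
numbered drivers that write their tables under `results/`:

```sh
Rscript analysis/01_fish_pairing.R     # pairing frequencies + categories + t-test
Rscript analysis/02_fish_distances.R   # radial/interallelic stats, null-model fit, ANOVA
Rscript analysis/03_fourc_pipeline.R   # allele-specific 4C end to end
Rscript analysis/04_covariates.R       # expression vs pairing-frequency correlation
```

`analysis/01` prints, for six samples per probe:

```
KvDMR pairing frequency: 4.12% (mean of 6 samples)
myc pairing frequency:   2.00% (mean of 6 samples)
ratio KvDMR/myc:         2.06
unpaired t-test:         t = 6.37, p = 8.2e-05
```

`analysis/03` runs the 4C pipeline on a 20-chromosome × 2 Mb hybrid genome
(one SNP per ~200 bp, congenic-like) with a 100,000-read library:

```
fragments: 9753 (3757 stringently informative)
reads: 100000 -> 2974 unique hits (1950 cis, 99 trans-allelic, 925 trans-chromosomal)
allele calling on SNP-covering reads: accuracy 1.000 (n = 29241)
homologous 1.4 Mb window chr1:0-1400000: 89 unique trans hits (upper fence 73.0) -> flagged as Tukey outlier
```

i.e. with homologous enrichment in the generative truth, the homologous
window is an upper Tukey outlier of the genome-wide trans count
distribution; with β = 0 it never is.

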