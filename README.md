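# aschip

Allele-specific chromatin state and expression skew analysis for F1 hybrid
cells.

## The problem

In an F1 hybrid cell line (here emulating a *Mus musculus* 129S1 x
*M. castaneus* cross, maternal allele "mus", paternal allele "cas"),
sequence variants let a fraction of ChIP-seq and RNA-seq fragments be
assigned to the parental haplotype they came from — roughly 37% of ChIP
fragments and 17% of RNA fragments. From those allele-assigned counts one
can ask, gene by gene: do the two alleles carry the same chromatin state?
Is one allele's expression skewed, and does its chromatin predict it?
`aschip` implements that pipeline end to end for users analysing
allele-specific ChIP/RNA count data, together with a seeded synthetic-data
generator that emulates the statistical structure of such data, so every
stage can be validated against known truth.

## The statistics at the core

* **Allelic skew test.** For a gene with allele-specific counts
  $(n_{mus}, n_{cas})$, the null is $n_{mus} \sim
  \mathrm{Bin}(n_{mus}+n_{cas},\,0.5)$; the two-sided p-value is the
  doubled smaller tail (observed value included, capped at 1). P-values
  are Benjamini–Hochberg adjusted within each assay, and a gene is called
  skewed when it has ≥ 15 allele-specific reads, a more than 2-fold
  difference between alleles, and FDR < 0.05. The reported skew is
  $\log_2(n_{mus}/n_{cas})$ (pseudocount 0.5 only when a zero count is
  present).
* **Chromatin states.** Promoter H3K4me3 x H3K27me3 input-normalized
  densities partition genes into *silent* (both depleted), *bivalent*
  (high K27me3, moderate K4me3) and *active* (high K4me3, low K27me3);
  boundaries are fitted by deterministic 1-D 2-means on the
  log-density distribution (or supplied manually). Per-allele states use
  *inferred allelic densities*: the composite density split in proportion
  to the observed allelic read ratio.
* **Expression prediction.** For each assay, kernel density estimates of
  enrichment are fitted over expressed (FPKM > 1) and non-expressed
  training genes; each allele scores $\sum_{assays}
  \log f_{expr}(x)/f_{nonexpr}(x)$ and the predicted expression skew is
  $BF_{mus} - BF_{cas}$. Evaluation includes Pearson R against observed
  RNA skew on a held-out validation half, ROC curves over sliding skew
  cutoffs 0–6 for single-mark and combined linear models, 2-fold
  cross-validated linear models, and an incremental variance
  decomposition (K4me3 → K36me3 → POL2S2 → K27me3).

## Worked example

```r
library(aschip)

cfg <- generator_config(n_genes = 2000, seed = 42)
ds  <- simulate_dataset(cfg)          # annotation, truth, counts, fpkm

calls <- call_skewed(ds$counts, "K4me3")
table(testable = calls$passed_min_reads, skewed = calls$is_skewed)
#>         skewed
#> testable FALSE TRUE
#>    FALSE   586    0
#>    TRUE   1156  258

head(calls[calls$is_skewed], 3)[, .(gene_id, n_mus, n_cas, log2_ratio, fdr, direction)]
#>    gene_id n_mus n_cas log2_ratio          fdr direction
#> 1:  g00001    26    83  -1.674600 2.224759e-07       cas
#> 2:  g00002   103    18   2.516576 9.866612e-15       mus
#> 3:  g00007     3    16  -2.415037 1.303546e-02       cas

ev <- run_evaluation(ds$counts, ds$fpkm, seed = 7)
ev$pearson_r            # 0.67  — BF-predicted vs observed RNA skew (validation half)
ev$pearson_r_expressed  # 0.69  — same, restricted to expressed genes (FPKM > 1)
round(ev$auc, 3)
#> combined    K4me3   K27me3   K36me3   POL2S2   POL2S5
#>    0.744    0.735    0.637    0.732    0.684    0.716
round(ev$variance$increments, 3)
#>  K4me3 K36me3 POL2S2 K27me3
#>  0.534  0.127  0.006  0.009     # increments sum to the full-model R^2 (0.68)
```

Of 2000 simulated genes, 1414 have enough allele-specific K4me3 reads to
be testable and 258 are called skewed; the first calls show the direction
and FDR of each. The Bayes-factor chromatin score correlates with observed
allelic expression skew at R = 0.67, the combined linear model's ROC AUC
(0.744) is at least as good as every single mark's within the evaluation
band, and K4me3 skew alone explains most of the explainable
expression-skew variance.

A command-line interface covers the same stages
(`simulate`, `count`, `call-skew`, `classify`, `census`, `predict`,
`evaluate`, `report`); see `inst/scripts/aschip` or
`Rscript -e 'aschip::aschip_cli("--help")'`. Every output directory gets a
`manifest.json` with content hashes of inputs and outputs.

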