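---
title: "Methods: allele-specific chromatin and expression skew analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-specific chromatin and expression skew analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(aschip)
```

# Scope and model

`aschip` analyses allele-specific ChIP-seq and RNA-seq of an F1 hybrid
cell line in which maternal (*mus*) and paternal (*cas*) haplotypes are
distinguishable by sequence variants. The pipeline has four stages —
fragment-to-allele assignment and region counting, binomial skew calling
with FDR control, chromatin-state classification, and Bayes-factor
prediction of allelic expression — plus a synthetic-data generator that
serves as the test bed for all of them. This vignette records the model
assumptions, the tunable parameters, and the design decisions made where
the method description was genuinely open.

# Fragment assignment and counting

A fragment is a paired-read interval (0-based half-open; ~400 bp) carrying
an alignment score against each of the two haplotype genomes. The
assignment rule is strict: *mus* if the mus-genome score is strictly
higher, *cas* if strictly higher the other way, *neutral* on an exact tie
— and, by our choice, also when only one score is present, since a single
score offers no basis for comparison. Deduplication keeps one fragment per
`(chrom, start, end, assay)` key and deliberately excludes the allele
label, so PCR duplicates cannot inflate one allele.

Promoters are `[TSS - 1000, TSS + 1000)`; gene bodies are the annotated
interval. A fragment contributes to every region it overlaps by at least
1 bp (half-open adjacency does not count), and a fragment spanning the
promoter/body junction counts in both — the attribution of partially
overlapping fragments is not uniquely determined by the method description,
and ≥ 1 bp to every overlapped region is our documented choice, checked
against a quadratic all-pairs oracle in the tests.

Input normalization divides ChIP counts by matched input counts over the
same region; since both share the region, per-kb factors cancel and the
density is a count ratio, flagged missing (never infinite) at zero input.
By default every track is normalized by the *composite* input density:
allelic input tracks carry only ~18% of input reads each and are too
sparse to be stable denominators (`input_track = "matched"` restores the
literal per-track division). *Inferred* allelic density splits the
composite density in proportion to observed allelic reads, with
`cas := composite - mus` so conservation is exact in floating point.

# Skew calling

The null model is symmetric mapping: each allele-specific read hits either
haplotype with probability 0.5. The two-sided p-value is the doubled
smaller tail of `Binomial(n_mus + n_cas, 0.5)` including the observed
value, capped at 1 — deterministic and exactly symmetric in the alleles,
unlike the minimum-likelihood rule of `binom.test`. At deep coverage an
extreme skew underflows this p-value to exactly 0 in double precision;
`bh_fdr` accepts such zeros. FDR is Benjamini–Hochberg, stratified per
assay, computed only across genes passing the read filter (genes below it
are reported *untestable*, not balanced).

A gene is skewed when all three hold:

| filter | default | note |
|---|---|---|
| total allele-specific reads | ≥ 15 | testability |
| fold difference | > 2 (strict) | any-vs-zero passes (observed fold infinite) |
| BH FDR | < 0.05 | per-assay stratification |

The reported skew is `log2(n_mus / n_cas)`; the 0.5 pseudocount enters
only when a zero count is present, keeping ratios of nonzero counts exact.
RNA replicates are summed before testing. The inbred-strain comparison
(for classifying hybrid skews as genetic vs sequence-independent) uses the
stricter FDR < 0.01 with the same 2-fold rule, as its own default.

# Chromatin states

Promoter K4me3 x K27me3 space has three dense regions: *silent* (both
marks depleted), *bivalent* (highest K27me3, moderate K4me3, depleted
elongation marks) and *active* (high K4me3/K36me3/POL2, low K27me3). No
numeric boundaries exist in the method description — they were drawn
visually — so `fit_thresholds` reconstructs them: exact, deterministic 1-D
2-means on `log2(1 + density)`, run twice for K4me3 (the second split
refining whichever side retains more within-cluster variance) and once
for K27me3. Reports must label these thresholds as fitted. Genes between
regions get an explicit *intermediate* label rather than a forced 3-way
call, and alleles with fewer than 5 allele-specific reads across
K4me3+K27me3 are *unclassifiable*. Allelic states are classified on
inferred allelic densities.

# Expression prediction

Training genes are split into expressed (composite FPKM > 1) and
non-expressed classes; for each assay a Gaussian-kernel density (Silverman
bandwidth) of `log2(1 + enrichment)` is fitted per class, with a density
floor of `1e-6` bounding each log likelihood ratio. The estimator choice
is ours — the method description names none. Three numerical guards
matter:

* both class densities of one assay share a common grid, and evaluation is
  clamped to the training range — otherwise, beyond support, both floored
  densities cancel to a likelihood ratio of 1 and extreme enrichment is
  scored as uninformative;
* each allele is scored at **twice** its inferred allelic density
  (`allelic_scale = 2`): references are trained on composite densities
  while one allele carries about half the composite signal, so unscaled
  alleles sit systematically in the left kernel tail where ratios invert;
* enrichment features follow canonical regions: promoter densities for
  K4me3/POL2S5/K27me3, gene-body densities for K36me3/POL2S2.

The per-allele score is the sum of log likelihood ratios over available
assays (missing assays skipped and counted), and the predicted expression
skew is `bf_mus - bf_cas` — the combination rule is not stated anywhere,
so the difference, which matches the RNA `log2(mus:cas)` sign convention
and is exactly antisymmetric, is our choice.

Evaluation: Pearson R of predicted vs observed RNA skew on a held-out
validation half (equal-sized seeded split); 2-fold cross-validated linear
models on per-mark skews, repeated 25 times because single splits are too
variable to test against (pseudo-inverse least squares, so collinear
predictors degrade gracefully); incremental variance decomposition in the
fixed order K4me3, K36me3, POL2S2, K27me3, whose increments telescope to
the full-model R² exactly; and ROC curves over cutoffs 0.0–6.0 on
|predicted skew|. The ROC is computed on *linear-regression* predictions
(single-mark and combined), which live on the log2-skew scale the 0–6
sweep was designed for; summed Bayes factors live on a larger scale that
the fixed sweep would truncate asymmetrically. Cross-validated correlation
has a small conditional bias within any one dataset (fold partitioning
anti-correlates train and test covariances), which is why the null
behaviour of `linear_cv_model` is tested across independent datasets.

The qPCR utility reports the fold difference exactly as the source formula
prints it, `2^(Ct_mus - Ct_cas)`; since a lower Ct means more transcript,
this is most likely inverted relative to expression, so `qpcr_report` also
emits the conventional `2^(Ct_cas - Ct_mus)` instead of silently "fixing"
the formula.

# The synthetic world

The generator is first-class, tested code. Its defaults are the stated
conditions of the emulated data, chosen once:

| parameter | default | why |
|---|---|---|
| `allelic_fraction_chip` / `_rna` | 0.37 / 0.17 | reported assignable-read fractions |
| `state_mixture` (silent/bivalent/active) | 0.40 / 0.15 / 0.45 | plausible MEF promoter mix; not a reported number |
| `p_same_type` | 0.90 | most genes share the gross state across alleles |
| `cross_type_weights` | 0.58 / 0.40 / 0.02 | bivalent–silent encoded as rare-not-impossible (2% of cross-type mass) |
| `within_type_skew_sd` | 0.30 log2 | continuous within-state allelic skew |
| `state_skew_scale` (bivalent) | 0.3 | poised promoters are allelically buffered: their skew distributions are much narrower than active ones; with uniform skew, the lower bivalent K4me3 coverage would make its *observed* skew wider, inverting the emulated pattern |
| `depth_per_assay` | 100 | puts typical genes near/above the 15-read testability threshold at 37% assignability |
| `dispersion` | 0.1 | negative-binomial composite counts; real ChIP counts are overdispersed (0 gives Poisson) |
| `expression_weights` | +0.55 K4me3, +0.45 K36me3, +0.35 POL2S2, +0.25 POL2S5, −0.45 K27me3 | log-linear expression model; active marks positive, K27me3 negative; calibrated so the full-marks predictor attains R ≈ 0.5–0.7 on defaults |
| `noise_sd` | 1.0 log2 | expression noise per allele, part of the same calibration |

Generation order: gross state pair (same-type with probability
`p_same_type`, else a weighted cross-type pair with random orientation);
log2 densities = state template + gene-level noise shared by the alleles +
independent per-allele noise + a latent *activity difference* that raises
active marks and lowers K27me3 on the more active allele (this single
latent variable is what makes same-gene K4me3/K36me3 skews correlate and
K4me3/K27me3 skews anticorrelate, as in the emulated data); allelic
expression is log-linear in `log2(1 + density)` with noise. Counts are
negative-binomial composites thinned binomially at the allelic fraction
and split by the true allelic proportion; RNA has two replicates; a
matched input assay has unit density. Fragment simulation expands count
rows into uniformly placed fixed-length intervals whose haplotype scores
encode the drawn allele.

What the generator does **not** emulate — hence what a green test does not
establish: mappability and SNP-density variation along the genome (every
gene is equally assignable), reference bias in alignment, fragment-level
positional structure (no peak shapes), imprinted clusters or any spatial
correlation between neighbouring genes, and tissue-specific expression.
Recovery and null-control results transfer to real data only insofar as
real counts behave like overdispersed thinned counts.

# Degenerate inputs and tie-breaks

Zero-count pairs are flagged, never turned into infinities; the two-sided
p at `n = 0` is undefined (`NA`); `fit_thresholds` refuses constant
densities and advises manual thresholds; ROC AUC is `NA` when the observed
classes are degenerate; Spearman correlations need ≥ 3 doubly-skewed
genes; hypergeometric overlap requires subsets of the universe. Exact ties
in alignment scores are neutral; a fold difference of exactly 2 fails the
strict filter.

# Known limitations

* The Bayes-factor likelihood ratio is not monotone in enrichment within
  the KDE tails; the clamping and scale alignment above mitigate but do
  not remove this (a parametric or isotonic reference would, at the cost
  of the flexibility the KDE provides).
* Threshold fitting assumes the K4me3 log-density is at least bimodal;
  cell types without a clear silent mode need manual thresholds.
* The inbred-strain concordance classification inherits whatever
  normalization differences exist between the hybrid and inbred expression
  measures; it bounds, rather than measures, the genetic contribution.
* `simulate_fragments` reproduces per-assay totals, not per-region counts,
  because promoters overlap gene bodies; counting correctness is
  established against an independent oracle instead.
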