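## Allelic skew statistics: exact two-sided binomial test of allelic read
## counts against p = 0.5, Benjamini-Hochberg FDR within each assay, and
## the skew-calling rule: >= 15 total allele-specific reads, more than
## 2-fold difference between alleles, FDR < 0.05.

#' Exact two-sided binomial allelic-skew test
#'
#' Under the null, allele-specific reads map to either haplotype with
#' probability 0.5.  The two-sided p-value is twice the smaller tail
#' probability of `Binomial(n_mus + n_cas, 0.5)` at the observed `n_mus`
#' (observed value included), capped at 1.  This doubled-tail rule is
#' deterministic and exactly symmetric in the two alleles (unlike the
#' minimum-likelihood two-sided rule of [stats::binom.test()]).
#'
#' @param n_mus,n_cas non-negative integer vectors of allelic read counts.
#' @return numeric vector of p-values in (0, 1]; `NA` where
#'   `n_mus + n_cas == 0` (undefined).
#' @export
binomial_skew_test <- function(n_mus, n_cas) {
  if (any(n_mus < 0 | n_cas < 0, na.rm = TRUE)) .stopf("negative counts")
  n <- n_mus + n_cas
  lower <- pbinom(n_mus, n, 0.5)                      # P(X <= n_mus)
  upper <- pbinom(n_mus - 1, n, 0.5, lower.tail = FALSE)  # P(X >= n_mus)
  p <- pmin(1, 2 * pmin(lower, upper))
  p[!is.na(n) & n == 0] <- NA_real_
  p
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment; `NA` p-values (untestable genes) are
#' excluded from the multiplicity count and returned as `NA`.  Exact zeros
#' are accepted: extreme skews at deep coverage legitimately underflow the
#' doubled-tail p-value to 0 in double precision.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    .stopf("p-values must be in (0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Log2 allelic skew
#'
#' `log2(n_mus / n_cas)`, the mus:cas log-ratio.  When either count is
#' zero, `pseudocount` is added to both alleles so the ratio is finite;
#' with two nonzero counts the raw ratio is returned so printed-style
#' ratios stay exact.  Antisymmetric under allele swap.
#'
#' @param n_mus,n_cas non-negative numeric vectors.
#' @param pseudocount value added to both counts when a zero is present.
#' @return numeric vector; `NA` where both counts are zero and
#'   `pseudocount` is 0.
#' @export
log2_skew <- function(n_mus, n_cas, pseudocount = 0.5) {
  if (any(n_mus < 0 | n_cas < 0, na.rm = TRUE)) .stopf("negative counts")
  haszero <- !is.na(n_mus) & !is.na(n_cas) & (n_mus == 0 | n_cas == 0)
  num <- ifelse(haszero, n_mus + pseudocount, n_mus)
  den <- ifelse(haszero, n_cas + pseudocount, n_cas)
  out <- log2(num / den)
  out[haszero & num == 0 & den == 0] <- NA_real_
  out
}

#' Call allelically skewed genes for one assay
#'
#' Applies the skew-calling rule to allelic counts of a single assay:
#' a gene is testable when it has at least `min_reads` total
#' allele-specific reads; among testable genes, it is skewed when the
#' between-allele fold difference strictly exceeds `fold` (an any-vs-zero
#' split counts as a pass: the observed fold is infinite) and the
#' within-assay Benjamini-Hochberg FDR of the exact binomial p-value is
#' below `fdr_max`.  RNA replicates are summed before testing; the reported
#' skew is the log-ratio of summed (equivalently averaged) allelic counts.
#'
#' @param counts count table with columns `assay, gene_id, n_mus, n_cas`
#'   (+ optional `region_type`, `replicate`).
#' @param assay assay to test (must be present in `counts`).
#' @param region region to use; defaults to the assay's canonical region
#'   when a `region_type` column is present.
#' @param min_reads minimum total allele-specific reads for testability.
#' @param fold fold-difference threshold (strict).
#' @param fdr_max FDR threshold (strict).
#' @param pseudocount passed to [log2_skew()].
#' @return `data.table` of class-style skew calls: `gene_id, assay, n_mus,
#'   n_cas, log2_ratio, p_value, fdr, passed_min_reads, passed_fold,
#'   passed_fdr, is_skewed, direction` with `direction` in
#'   `c("mus", "cas", "none")`.  Genes failing `min_reads` are reported
#'   untestable (`fdr = NA`, `is_skewed = FALSE`), not unskewed.
#' @export
call_skewed <- function(counts, assay, region = NULL, min_reads = 15L,
                        fold = 2.0, fdr_max = 0.05, pseudocount = 0.5) {
  if (min_reads < 1) .stopf("min_reads must be >= 1")
  if (fold < 1) .stopf("fold must be >= 1")
  if (fdr_max <= 0 || fdr_max > 1) .stopf("fdr_max must be in (0, 1]")
  cnt <- as.data.table(counts)
  the_assay <- assay
  if (!the_assay %in% cnt$assay) .stopf("unknown assay '%s'", the_assay)
  cnt <- cnt[assay == the_assay]
  if ("region_type" %in% names(cnt)) {
    if (is.null(region)) region <- canonical_region(the_assay)
    cnt <- cnt[region_type == region]
  }
  # sum across replicates (RNA); other assays have one replicate
  calls <- cnt[, .(n_mus = sum(n_mus), n_cas = sum(n_cas)),
               by = gene_id]
  calls[, `:=`(assay = the_assay,
               log2_ratio = log2_skew(n_mus, n_cas, pseudocount),
               total = n_mus + n_cas)]
  calls[, passed_min_reads := total >= min_reads]
  hi <- pmax(calls$n_mus, calls$n_cas)
  lo <- pmin(calls$n_mus, calls$n_cas)
  calls[, passed_fold := (lo == 0 & hi > 0) | (lo > 0 & hi / lo > fold)]
  calls[, p_value := ifelse(total > 0, binomial_skew_test(n_mus, n_cas),
                            NA_real_)]
  # FDR across genes passing the read filter only (the tested population)
  calls[, fdr := NA_real_]
  calls[passed_min_reads == TRUE, fdr := bh_fdr(p_value)]
  calls[, passed_fdr := !is.na(fdr) & fdr < fdr_max]
  calls[, is_skewed := passed_min_reads & passed_fold & passed_fdr]
  calls[, direction := ifelse(is_skewed & log2_ratio > 0, "mus",
                              ifelse(is_skewed & log2_ratio < 0, "cas",
                                     "none"))]
  setorder(calls, gene_id)
  calls[, .(gene_id, assay, n_mus, n_cas, log2_ratio, p_value, fdr,
            passed_min_reads, passed_fold, passed_fdr, is_skewed,
            direction)][]
}

#' Summaries of skewed-gene sets across assays
#'
#' Per assay: number of testable genes and number skewed; all pairwise and
#' triple intersections of skewed sets; fraction of testable genes skewed
#' in at least one assay.
#'
#' @param calls named list of skew-call tables (one per assay), as from
#'   [call_skewed()].
#' @return list with `per_assay` (data.table `assay, n_genes, n_testable,
#'   n_skewed`), `pairwise` (data.table `assay_a, assay_b, n_both`),
#'   `triples` (data.table with three assay columns and `n_all3`), and
#'   `union_fraction` (skewed-in-any / testable-in-any).
#' @export
skewed_set_summary <- function(calls) {
  stopifnot(is.list(calls), length(calls) >= 1L)
  nm <- names(calls)
  skew_sets <- lapply(calls, function(x) x$gene_id[x$is_skewed])
  test_sets <- lapply(calls, function(x) x$gene_id[x$passed_min_reads])
  per_assay <- rbindlist(lapply(nm, function(a)
    data.table(assay = a, n_genes = nrow(calls[[a]]),
               n_testable = length(test_sets[[a]]),
               n_skewed = length(skew_sets[[a]]))))
  pairwise <- if (length(nm) >= 2L) {
    cmb <- utils::combn(nm, 2L)
    rbindlist(lapply(seq_len(ncol(cmb)), function(i)
      data.table(assay_a = cmb[1L, i], assay_b = cmb[2L, i],
                 n_both = length(intersect(skew_sets[[cmb[1L, i]]],
                                           skew_sets[[cmb[2L, i]]])))))
  } else data.table(assay_a = character(), assay_b = character(),
                    n_both = integer())
  triples <- if (length(nm) >= 3L) {
    cmb <- utils::combn(nm, 3L)
    rbindlist(lapply(seq_len(ncol(cmb)), function(i)
      data.table(assay_a = cmb[1L, i], assay_b = cmb[2L, i],
                 assay_c = cmb[3L, i],
                 n_all3 = length(Reduce(intersect,
                                        skew_sets[cmb[, i]])))))
  } else data.table(assay_a = character(), assay_b = character(),
                    assay_c = character(), n_all3 = integer())
  testable_any <- unique(unlist(test_sets))
  skewed_any <- unique(unlist(skew_sets))
  list(per_assay = per_assay, pairwise = pairwise, triples = triples,
       union_fraction = if (length(testable_any))
         length(skewed_any) / length(testable_any) else NA_real_)
}

#' Hypergeometric overlap test of two gene sets
#'
#' Upper-tail probability of observing at least the given overlap between a
#' skewed-gene set and a reference set (e.g. known imprinted genes) drawn
#' from a common gene universe.
#'
#' @param skewed,reference character vectors of gene ids, both subsets of
#'   `universe`.
#' @param universe character vector of all eligible gene ids.
#' @return the exact hypergeometric p-value `P(overlap >= observed)`.
#' @export
hypergeometric_overlap <- function(skewed, reference, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) .stopf("empty universe")
  skewed <- unique(skewed)
  reference <- unique(reference)
  if (!all(skewed %in% universe) || !all(reference %in% universe))
    .stopf("skewed and reference must be subsets of the universe")
  k <- length(intersect(skewed, reference))
  phyper(k - 1L, length(reference), length(universe) - length(reference),
         length(skewed), lower.tail = FALSE)
}

#' Classify hybrid-vs-inbred skew concordance
#'
#' Compares allelic skew calls in the hybrid line with the expression skew
#' between the two inbred parental strains, for genes with adequate
#' expression, and classifies each gene: `genetic` (skewed in both with the
#' same direction — consistent with sequence-driven skew),
#' `sequence_independent` (hybrid-skewed, inbred-null),
#' `other_discordant` (inbred-skewed but hybrid-null, or skewed in both
#' with opposite directions), `concordant_null` (neither skewed).
#'
#' @param hybrid_calls skew-call table for hybrid RNA (from
#'   [call_skewed()]).
#' @param inbred_skews data.frame with columns `gene_id, log2_ratio,
#'   is_skewed` for the inbred strain comparison (typically called with
#'   `fold = 2, fdr_max = 0.01`).
#' @return `data.table` `gene_id, class`; genes present in only one input
#'   are excluded with a log note.
#' @export
classify_concordance <- function(hybrid_calls, inbred_skews) {
  h <- as.data.table(hybrid_calls)[, .(gene_id, h_skew = log2_ratio,
                                       h_is = is_skewed)]
  i <- as.data.table(inbred_skews)[, .(gene_id, i_skew = log2_ratio,
                                       i_is = is_skewed)]
  dropped <- length(setdiff(union(h$gene_id, i$gene_id),
                            intersect(h$gene_id, i$gene_id)))
  if (dropped > 0L)
    .logf("classify_concordance: %d genes present in only one input excluded",
          dropped)
  dt <- merge(h, i, by = "gene_id")
  dt[, class := ifelse(h_is & i_is & sign(h_skew) == sign(i_skew), "genetic",
               ifelse(h_is & !i_is, "sequence_independent",
               ifelse(!h_is & i_is, "other_discordant",
               ifelse(h_is & i_is, "other_discordant",
                      "concordant_null"))))]
  dt[, .(gene_id, class)][]
}
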