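## Bayes-factor prediction of allelic expression from allelic chromatin
## densities.  For each assay, reference distributions of enrichment
## (log2(1 + density), Gaussian KDE, Silverman bandwidth, density floor)
## are estimated on training genes split into expressed and non-expressed
## classes.  Each allele of each gene receives a summed log Bayes factor —
## the log likelihood ratio that its enrichment values were drawn from the
## expressed rather than the non-expressed reference — and the predicted
## allelic expression skew is the mus - cas difference of these scores.

#' Split genes into equal-sized training and validation sets
#'
#' @param genes character vector of gene ids (>= 2).
#' @param seed integer seed for the shuffle.
#' @return list with `train` and `validation`, disjoint, sizes differing by
#'   at most 1.
#' @export
split_train_validation <- function(genes, seed = 1L) {
  genes <- unique(genes)
  if (length(genes) < 2L) .stopf("need at least 2 genes to split")
  set.seed(as.integer(seed))
  idx <- sample.int(length(genes))
  half <- ceiling(length(genes) / 2)
  list(train = genes[idx[seq_len(half)]],
       validation = genes[idx[seq(half + 1L, length(genes))]])
}

# KDE on log2(1 + x) with evaluation by linear interpolation, clamped to
# the grid edges, floored to keep log ratios bounded.  `from`/`to` pin the
# grid so the expressed and non-expressed references of one assay share a
# common support (otherwise their edge behaviour under clamping would be
# incomparable for out-of-range enrichments).
.make_ref_density <- function(x, floor = 1e-6, n_grid = 512L,
                              from = NULL, to = NULL) {
  x <- log2(1 + x[is.finite(x)])
  if (length(x) < 2L) .stopf("too few values for a reference density")
  d <- if (is.null(from))
    density(x, bw = "nrd0", n = n_grid, cut = 3)
  else density(x, bw = "nrd0", n = n_grid, from = from, to = to)
  list(x = d$x, y = pmax(d$y, floor), floor = floor)
}

# Evaluation clamps the query to the training-data range: beyond the most
# extreme training enrichment the likelihood ratio is carried over from the
# boundary rather than letting both floored densities cancel to ratio 1
# (which would score extreme enrichment as uninformative).
.eval_ref_density <- function(ref, x) {
  lx <- log2(1 + x)
  if (!is.null(ref$lo)) lx <- pmin(pmax(lx, ref$lo), ref$hi)
  pmax(approx(ref$x, ref$y, xout = lx, rule = 2)$y, ref$floor)
}

#' Extract per-assay enrichment features from a density table
#'
#' One row per gene; for each assay, the composite density over the
#' assay's canonical region, plus the inferred allelic densities
#' (composite split by the observed allelic read ratio).
#'
#' @param densities density table from [normalize_density()].
#' @param assays assays to extract (default all ChIP assays present).
#' @return `data.table` with `gene_id` and columns `<assay>` (composite),
#'   `<assay>_mus`, `<assay>_cas`.
#' @export
enrichment_features <- function(densities, assays = NULL) {
  d <- as.data.table(densities)
  if (is.null(assays)) assays <- intersect(CHIP_ASSAYS, unique(d$assay))
  out <- NULL
  for (a in assays) {
    da <- d[assay == a & region_type == canonical_region(a)]
    inf <- inferred_allelic_density(da$density_composite, da$n_mus, da$n_cas)
    block <- data.table(gene_id = da$gene_id, comp = da$density_composite,
                        mus = inf$mus, cas = inf$cas)
    setnames(block, c("comp", "mus", "cas"),
             c(a, paste0(a, "_mus"), paste0(a, "_cas")))
    out <- if (is.null(out)) block else
      merge(out, block, by = "gene_id", all = TRUE)
  }
  out[]
}

#' Fit the Bayes-factor prediction model
#'
#' For each assay, estimates smoothed reference densities of enrichment
#' (on `log2(1 + density)`) over the expressed and non-expressed training
#' genes.  Expressed means composite FPKM above `expressed_threshold`.
#'
#' @param train_features feature table from [enrichment_features()]
#'   restricted to training genes (composite columns are used).
#' @param train_fpkm data.frame `gene_id, fpkm` for the training genes.
#' @param expressed_threshold FPKM threshold defining the expressed class.
#' @param assays assays to model (default: all ChIP assays present).
#' @param floor density floor bounding each log likelihood ratio.
#' @return object of class `bayes_factor_model`: per-assay expressed and
#'   non-expressed reference densities plus the training metadata.
#' @export
fit_bayes_factor_model <- function(train_features, train_fpkm,
                                   expressed_threshold = 1,
                                   assays = NULL, floor = 1e-6) {
  feats <- as.data.table(train_features)
  fpkm <- as.data.table(train_fpkm)
  if (is.null(assays)) assays <- intersect(CHIP_ASSAYS, names(feats))
  dt <- merge(feats, fpkm[, .(gene_id, fpkm)], by = "gene_id")
  expressed <- dt$fpkm > expressed_threshold
  if (!any(expressed))
    .stopf("no expressed training genes (fpkm > %g)", expressed_threshold)
  if (all(expressed))
    .stopf("no non-expressed training genes (fpkm <= %g)", expressed_threshold)
  refs <- list()
  for (a in assays) {
    x <- dt[[a]]
    lx <- log2(1 + x[is.finite(x)])
    bw <- max(stats::bw.nrd0(log2(1 + x[expressed & is.finite(x)])),
              stats::bw.nrd0(log2(1 + x[!expressed & is.finite(x)])))
    lo <- min(lx) - 3 * bw
    hi <- max(lx) + 3 * bw
    re <- .make_ref_density(x[expressed], floor, from = lo, to = hi)
    rn <- .make_ref_density(x[!expressed], floor, from = lo, to = hi)
    re$lo <- rn$lo <- min(lx)
    re$hi <- rn$hi <- max(lx)
    refs[[a]] <- list(expressed = re, nonexpressed = rn)
  }
  structure(list(refs = refs, assays = assays,
                 expressed_threshold = expressed_threshold,
                 n_train = nrow(dt), n_expressed = sum(expressed),
                 train_genes = dt$gene_id, floor = floor),
            class = "bayes_factor_model")
}

#' Summed log Bayes factor for one allele
#'
#' Sums, over the assays with a defined enrichment value, the natural-log
#' likelihood ratio of the expressed vs non-expressed reference densities
#' at the observed enrichment.  Missing assays are skipped (and counted in
#' the `n_assays` attribute); a row with no defined assay gives `NA`.
#'
#' @param model a `bayes_factor_model`.
#' @param features data.frame with one column per assay (densities for a
#'   single allele), rows are genes; or a single named numeric vector.
#' @return numeric vector of summed log Bayes factors with attribute
#'   `n_assays` (assays used per gene).
#' @export
allele_bayes_factor <- function(model, features) {
  if (!inherits(model, "bayes_factor_model")) .stopf("not a bayes_factor_model")
  if (is.numeric(features) && !is.null(names(features)))
    features <- as.data.table(as.list(features))
  features <- as.data.table(features)
  n <- nrow(features)
  bf <- numeric(n)
  used <- integer(n)
  for (a in model$assays) {
    if (!a %in% names(features)) next
    x <- features[[a]]
    ok <- !is.na(x)
    if (!any(ok)) next
    fe <- .eval_ref_density(model$refs[[a]]$expressed, x[ok])
    fn <- .eval_ref_density(model$refs[[a]]$nonexpressed, x[ok])
    bf[ok] <- bf[ok] + log(fe / fn)
    used[ok] <- used[ok] + 1L
  }
  bf[used == 0L] <- NA_real_
  attr(bf, "n_assays") <- used
  bf
}

#' Predict allelic expression skew from allelic chromatin densities
#'
#' Computes the summed log Bayes factor of each allele from its inferred
#' allelic densities and reports `predicted_skew = bf_mus - bf_cas`, whose
#' sign convention matches the RNA log2(mus:cas) skew.  Genes with one
#' allele entirely undefined are skipped with a log note.
#'
#' Because the reference distributions are estimated from composite
#' densities while an allele carries roughly half the composite signal,
#' each allelic density is scored at `allelic_scale` times its value
#' (default 2): the enrichment the composite would show if both alleles
#' behaved like this one.  Without this alignment every allele would sit
#' systematically left of the training distribution, in the kernel tails
#' where likelihood ratios are unstable.
#'
#' @param model a `bayes_factor_model`.
#' @param features feature table from [enrichment_features()] (allelic
#'   columns `<assay>_mus` / `<assay>_cas` are used).
#' @param allelic_scale factor mapping allelic densities onto the
#'   composite training scale.
#' @return `data.table`: `gene_id, bf_mus, bf_cas, predicted_skew`.
#' @export
predict_expression_skew <- function(model, features, allelic_scale = 2) {
  feats <- as.data.table(features)
  pick <- function(suffix) {
    cols <- paste0(model$assays, suffix)
    cols <- cols[cols %in% names(feats)]
    block <- feats[, cols, with = FALSE]
    setnames(block, sub(suffix, "", names(block), fixed = TRUE))
    for (cc in names(block)) block[[cc]] <- block[[cc]] * allelic_scale
    block
  }
  bf_mus <- allele_bayes_factor(model, pick("_mus"))
  bf_cas <- allele_bayes_factor(model, pick("_cas"))
  out <- data.table(gene_id = feats$gene_id, bf_mus = as.numeric(bf_mus),
                    bf_cas = as.numeric(bf_cas))
  skipped <- is.na(out$bf_mus) | is.na(out$bf_cas)
  if (any(skipped))
    .logf("predict_expression_skew: %d genes skipped (one allele undefined)",
          sum(skipped))
  out <- out[!skipped]
  out[, predicted_skew := bf_mus - bf_cas]
  out[]
}

# Moore-Penrose pseudo-inverse least squares: robust to rank deficiency
.pinv_fit <- function(X, y) {
  s <- svd(X)
  pos <- s$d > max(s$d) * 1e-10
  if (!all(pos))
    warning("rank-deficient predictors: pseudo-inverse fit", call. = FALSE)
  drop(s$v[, pos, drop = FALSE] %*%
         ((t(s$u[, pos, drop = FALSE]) %*% y) / s$d[pos]))
}

#' Cross-validated linear prediction of expression skew from mark skews
#'
#' Ordinary least squares with intercept (pseudo-inverse, so collinear or
#' duplicated predictors are harmless) fitted on one fold and evaluated by
#' Pearson correlation on the held-out fold, in a k-fold scheme repeated
#' with reshuffled folds.
#'
#' @param predictors data.frame/matrix of per-gene predictor columns
#'   (e.g. per-mark log2 skews).
#' @param response numeric vector of observed expression skews.
#' @param folds number of folds (default 2).
#' @param repeats number of reshuffled repetitions.
#' @param seed integer seed.
#' @return list: `mean_r` (mean held-out Pearson R), `per_fold_r` (vector,
#'   `repeats x folds` values), `n` (genes used).
#' @export
linear_cv_model <- function(predictors, response, folds = 2L, repeats = 25L,
                            seed = 1L) {
  X <- as.matrix(predictors)
  keep <- stats::complete.cases(X) & is.finite(response)
  X <- X[keep, , drop = FALSE]
  y <- response[keep]
  n <- length(y)
  if (n < 10L) .stopf("need >= 10 complete genes for cross-validation")
  X1 <- cbind(1, X)
  set.seed(as.integer(seed))
  rs <- numeric(0)
  for (r in seq_len(repeats)) {
    fold <- sample(rep_len(seq_len(folds), n))
    for (f in seq_len(folds)) {
      tr <- fold != f
      beta <- .pinv_fit(X1[tr, , drop = FALSE], y[tr])
      pred <- X1[!tr, , drop = FALSE] %*% beta
      rs <- c(rs, cor(pred, y[!tr]))
    }
  }
  list(mean_r = mean(rs), per_fold_r = rs, n = n)
}

# in-sample R^2 of an OLS fit with intercept
.r2 <- function(X, y) {
  X1 <- cbind(1, as.matrix(X))
  beta <- .pinv_fit(X1, y)
  res <- y - X1 %*% beta
  1 - sum(res^2) / sum((y - mean(y))^2)
}

#' Variance decomposition of expression skew across marks
#'
#' First row of the result: the proportion of expression-skew variance
#' explained by each mark's skew alone (single-predictor R-squared).
#' Second row: the increment in R-squared gained when each mark is added to
#' a multivariate model in the stated order; increments telescope, so they
#' sum to the full-model R-squared exactly.
#'
#' @param predictors data.frame of per-mark skew columns.
#' @param response observed expression skew vector.
#' @param order character vector giving the inclusion order (default:
#'   K4me3, K36me3, POL2S2, K27me3 restricted to available columns).
#' @return list: `individual_r2` (named), `increments` (named, same
#'   order), `full_r2`.
#' @export
variance_decomposition <- function(predictors, response,
                                   order = c("K4me3", "K36me3", "POL2S2",
                                             "K27me3")) {
  X <- as.data.table(predictors)
  order <- order[order %in% names(X)]
  if (length(order) == 0L) .stopf("no ordered predictors present")
  keep <- stats::complete.cases(X[, order, with = FALSE]) &
    is.finite(response)
  X <- X[keep]
  y <- response[keep]
  if (length(y) < 10L) .stopf("need >= 10 complete genes")
  individual <- vapply(order, function(a) .r2(X[[a]], y), 0)
  cum <- vapply(seq_along(order), function(k)
    .r2(X[, order[seq_len(k)], with = FALSE], y), 0)
  increments <- c(cum[1], diff(cum))
  names(increments) <- order
  list(individual_r2 = individual, increments = increments,
       full_r2 = cum[length(cum)])
}

#' ROC over sliding skew cutoffs
#'
#' Classifies genes as predicted-skewed when `|predicted skew| >= cutoff`
#' for each cutoff in the sweep, compares against the observed skew calls,
#' and reports TPR/FPR per cutoff plus the trapezoidal AUC (curve anchored
#' at (0,0) and (1,1)).
#'
#' @param predictions named list of numeric predicted-skew vectors (one per
#'   model), or a single numeric vector; all aligned with `observed`.
#' @param observed logical vector of observed skew calls.
#' @param cutoffs numeric sweep of cutoffs (default 0 to 6 by 0.1).
#' @return list: `roc` (data.table `model, cutoff, tpr, fpr`) and `auc`
#'   (named numeric; `NA` when observed classes are degenerate).
#' @export
roc_over_cutoffs <- function(predictions, observed,
                             cutoffs = seq(0, 6, by = 0.1)) {
  if (!is.list(predictions)) predictions <- list(model = predictions)
  observed <- as.logical(observed)
  n_pos <- sum(observed, na.rm = TRUE)
  n_neg <- sum(!observed, na.rm = TRUE)
  rocs <- list()
  aucs <- numeric(0)
  for (m in names(predictions)) {
    pred <- abs(predictions[[m]])
    ok <- !is.na(pred) & !is.na(observed)
    tpr <- vapply(cutoffs, function(cut)
      sum(pred[ok] >= cut & observed[ok]) / max(1L, sum(observed[ok])), 0)
    fpr <- vapply(cutoffs, function(cut)
      sum(pred[ok] >= cut & !observed[ok]) / max(1L, sum(!observed[ok])), 0)
    rocs[[m]] <- data.table(model = m, cutoff = cutoffs, tpr = tpr,
                            fpr = fpr)
    if (n_pos == 0L || n_neg == 0L) {
      aucs[m] <- NA_real_
      next
    }
    pts <- unique(data.table(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1)))
    setorder(pts, fpr, tpr)
    aucs[m] <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
  }
  if (n_pos == 0L || n_neg == 0L)
    .logf("roc_over_cutoffs: degenerate observed classes (pos=%d, neg=%d); AUC undefined",
          n_pos, n_neg)
  list(roc = rbindlist(rocs), auc = aucs)
}

#' Census of prediction/observation discordance
#'
#' Partitions genes with both a predicted and an observed skew status, and
#' at least one of the two skewed, into four classes: `concordant` (both
#' skewed, same direction), `anticorrelated` (both skewed, opposite
#' directions), `chromatin_only` (predicted skewed, expression balanced)
#' and `expression_only` (expression skewed, chromatin balanced).
#'
#' @param predictions prediction table from [predict_expression_skew()].
#' @param rna_calls RNA skew-call table from [call_skewed()].
#' @param pred_cutoff |predicted_skew| at or above which a gene counts as
#'   predicted skewed.
#' @return list: `classes` (data.table `gene_id, class`), `counts` (named
#'   tally over the four classes), `n_balanced` (genes evaluated but
#'   skewed in neither).
#' @export
discordance_census <- function(predictions, rna_calls, pred_cutoff = 1) {
  p <- as.data.table(predictions)[, .(gene_id, predicted_skew)]
  r <- as.data.table(rna_calls)[, .(gene_id, log2_ratio, is_skewed)]
  dt <- merge(p, r, by = "gene_id")
  dt[, pred_skewed := abs(predicted_skew) >= pred_cutoff]
  dt[, class := ifelse(pred_skewed & is_skewed &
                         sign(predicted_skew) == sign(log2_ratio),
                       "concordant",
                ifelse(pred_skewed & is_skewed, "anticorrelated",
                ifelse(pred_skewed & !is_skewed, "chromatin_only",
                ifelse(!pred_skewed & is_skewed, "expression_only",
                       "balanced"))))]
  classes <- dt[class != "balanced", .(gene_id, class)]
  counts <- table(factor(classes$class,
                         c("concordant", "anticorrelated", "chromatin_only",
                           "expression_only")))
  list(classes = classes[], counts = c(unclass(counts)),
       n_balanced = dt[, sum(class == "balanced")])
}

#' qPCR allelic fold difference
#'
#' Computes the allele-specific qRT-PCR fold difference exactly as the
#' source formula prints it: `2^(Ct_mus - Ct_cas)`.  Note that because a
#' lower Ct means more transcript, the conventional expression fold change
#' is `2^(Ct_cas - Ct_mus)`; [qpcr_report()] emits both.
#'
#' @param ct_mus,ct_cas finite Ct values.
#' @return `2^(ct_mus - ct_cas)`.
#' @export
qpcr_fold_difference <- function(ct_mus, ct_cas) {
  if (!all(is.finite(ct_mus) & is.finite(ct_cas)))
    .stopf("Ct values must be finite")
  2^(ct_mus - ct_cas)
}

#' qPCR fold-difference report with both sign conventions
#'
#' @param ct_table data.frame with columns `gene_id, ct_mus, ct_cas`.
#' @return `data.table` with `fold_difference` (`2^(Ct_mus - Ct_cas)`, as
#'   printed by the source formula) and `fold_expression`
#'   (`2^(Ct_cas - Ct_mus)`, the conventional delta-Ct expression ratio).
#' @export
qpcr_report <- function(ct_table) {
  dt <- as.data.table(ct_table)
  dt[, .(gene_id,
         fold_difference = qpcr_fold_difference(ct_mus, ct_cas),
         fold_expression = qpcr_fold_difference(ct_cas, ct_mus))][]
}
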