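## High-level orchestration: one call from count tables to the full
## prediction evaluation (Bayes-factor model, per-mark and combined ROC,
## cross-validated linear models, variance decomposition, discordance
## census).  The CLI subcommands and the acceptance checks both drive the
## pipeline through these functions.

#' Call allelic skew for several assays at once
#'
#' @param counts count table.
#' @param assays assays to test (default: every non-input assay present).
#' @param ... thresholds passed to [call_skewed()].
#' @return named list of skew-call tables.
#' @export
call_skewed_all <- function(counts, assays = NULL, ...) {
  cnt <- as.data.table(counts)
  if (is.null(assays)) assays <- setdiff(unique(cnt$assay), INPUT_ASSAY)
  setNames(lapply(assays, function(a) call_skewed(cnt, a, ...)), assays)
}

#' Evaluate expression-skew prediction on a dataset
#'
#' Runs the full evaluation protocol on an allelic count table with
#' matched input and RNA rows: input-normalized densities, RNA skew calls
#' (replicates summed), a seeded equal train/validation split, a
#' Bayes-factor model per the combined marks and per single mark, Pearson
#' correlation of predicted vs observed RNA skew on validation genes, ROC
#' over sliding cutoffs for the combined and single-mark predictors,
#' 2-fold cross-validated linear models of expression skew on per-mark
#' skews, the incremental variance decomposition, and the discordance
#' census.
#'
#' @param counts count table containing ChIP assays, `input` and `RNA`.
#' @param fpkm data.frame `gene_id, fpkm` (composite expression).
#' @param seed integer seed for the train/validation split and CV folds.
#' @param expressed_threshold FPKM cutoff for the expressed class.
#' @param cv_repeats repeats of the 2-fold cross-validation.
#' @param roc_cutoffs cutoff sweep for the ROC.
#' @param ... thresholds passed to the RNA [call_skewed()].
#' @return list: `split`, `model`, `predictions`, `pearson_r` (validation,
#'   RNA-testable genes), `pearson_r_expressed` (further restricted to
#'   fpkm > threshold), `roc`, `auc`, `linear_cv`, `variance`,
#'   `discordance`, `rna_calls`, `features`.
#' @export
run_evaluation <- function(counts, fpkm, seed = 1L, expressed_threshold = 1,
                           cv_repeats = 25L, roc_cutoffs = seq(0, 6, 0.1),
                           ...) {
  cnt <- as.data.table(counts)
  fpkm <- as.data.table(fpkm)
  densities <- normalize_density(cnt[!assay %in% c(INPUT_ASSAY, RNA_ASSAY)],
                                 cnt[assay == INPUT_ASSAY])
  features <- enrichment_features(densities)
  rna_calls <- call_skewed(cnt, RNA_ASSAY, ...)

  genes <- intersect(features$gene_id, fpkm$gene_id)
  split <- split_train_validation(genes, seed = seed)
  train_feats <- features[gene_id %in% split$train]
  val_feats <- features[gene_id %in% split$validation]

  model <- fit_bayes_factor_model(train_feats, fpkm,
                                  expressed_threshold = expressed_threshold)
  predictions <- predict_expression_skew(model, val_feats)

  obs <- merge(predictions,
               rna_calls[passed_min_reads == TRUE,
                         .(gene_id, observed_skew = log2_ratio,
                           rna_skewed = is_skewed)],
               by = "gene_id")
  pearson_r <- if (nrow(obs) >= 3L)
    cor(obs$predicted_skew, obs$observed_skew) else NA_real_
  obs_expr <- merge(obs, fpkm, by = "gene_id")[fpkm > expressed_threshold]
  pearson_r_expressed <- if (nrow(obs_expr) >= 3L)
    cor(obs_expr$predicted_skew, obs_expr$observed_skew) else NA_real_

  # linear models on per-mark allelic skews
  chip_calls <- call_skewed_all(cnt, assays = intersect(CHIP_ASSAYS,
                                                        unique(cnt$assay)))
  skew_wide <- Reduce(function(x, y) merge(x, y, by = "gene_id"),
                      lapply(names(chip_calls), function(a) {
                        k <- chip_calls[[a]][passed_min_reads == TRUE,
                                             .(gene_id, s = log2_ratio)]
                        setnames(k, "s", a)
                      }))
  lin <- merge(skew_wide,
               rna_calls[passed_min_reads == TRUE,
                         .(gene_id, observed_skew = log2_ratio,
                           rna_skewed = is_skewed)],
               by = "gene_id")
  marks <- intersect(names(chip_calls), names(lin))
  linear_cv <- linear_cv_model(lin[, marks, with = FALSE],
                               lin$observed_skew, folds = 2L,
                               repeats = cv_repeats, seed = seed)
  variance <- variance_decomposition(lin[, marks, with = FALSE],
                                     lin$observed_skew)

  # ROC over sliding cutoffs on linear-regression skew predictions
  # (single mark and combined), trained on the training half and swept on
  # the held-out half; predictions live on the log2-skew scale, matching
  # the 0-6 cutoff range
  lin_tr <- lin[gene_id %in% split$train]
  lin_va <- lin[gene_id %in% split$validation]
  fit_predict <- function(cols) {
    X <- cbind(1, as.matrix(lin_tr[, cols, with = FALSE]))
    beta <- .pinv_fit(X, lin_tr$observed_skew)
    drop(cbind(1, as.matrix(lin_va[, cols, with = FALSE])) %*% beta)
  }
  pred_list <- c(list(combined = fit_predict(marks)),
                 setNames(lapply(marks, fit_predict), marks))
  roc <- roc_over_cutoffs(pred_list, lin_va$rna_skewed,
                          cutoffs = roc_cutoffs)

  discordance <- discordance_census(predictions, rna_calls)

  list(split = split, model = model, predictions = predictions,
       pearson_r = pearson_r, pearson_r_expressed = pearson_r_expressed,
       roc = roc$roc, auc = roc$auc, linear_cv = linear_cv,
       variance = variance, discordance = discordance,
       rna_calls = rna_calls, features = features)
}
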