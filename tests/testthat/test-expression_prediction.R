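test_that("split_train_validation makes disjoint equal halves", {
  g100 <- sprintf("g%03d", 1:100)
  s <- split_train_validation(g100, seed = 3)
  expect_equal(length(s$train), 50L)
  expect_equal(length(s$validation), 50L)
  expect_length(intersect(s$train, s$validation), 0L)
  s101 <- split_train_validation(c(g100, "g101"), seed = 3)
  expect_lte(abs(length(s101$train) - length(s101$validation)), 1L)
  expect_identical(split_train_validation(g100, seed = 3), s)
  expect_error(split_train_validation("g1"), "2 genes")
})

# features where expressed genes have strictly higher K4me3
toy_training <- function(n = 200, seed = 9) {
  set.seed(seed)
  expressed <- rep(c(TRUE, FALSE), length.out = n)
  feats <- data.table::data.table(
    gene_id = sprintf("g%03d", 1:n),
    K4me3 = ifelse(expressed, 2^rnorm(n, 3, 0.4), 2^rnorm(n, -1, 0.4)),
    K27me3 = ifelse(expressed, 2^rnorm(n, -1, 0.4), 2^rnorm(n, 1, 0.4)))
  fpkm <- data.table::data.table(gene_id = feats$gene_id,
                                 fpkm = ifelse(expressed, 10, 0.1))
  list(features = feats, fpkm = fpkm, expressed = expressed)
}

test_that("fit_bayes_factor_model separates expressed reference densities", {
  toy <- toy_training()
  m <- fit_bayes_factor_model(toy$features, toy$fpkm)
  expect_s3_class(m, "bayes_factor_model")
  # expressed K4 reference dominates the non-expressed one at high density
  r <- m$refs$K4me3
  hi <- 3  # log2(1+d) of a clearly active promoter
  fe <- approx(r$expressed$x, r$expressed$y, hi, rule = 2)$y
  fn <- approx(r$nonexpressed$x, r$nonexpressed$y, hi, rule = 2)$y
  expect_gt(fe, fn)
  # expressed-class means differ in the right direction
  expect_gt(sum(r$expressed$x * r$expressed$y) / sum(r$expressed$y),
            sum(r$nonexpressed$x * r$nonexpressed$y) /
              sum(r$nonexpressed$y))
  # refit identical
  expect_identical(m, fit_bayes_factor_model(toy$features, toy$fpkm))
  # empty class errors name the class
  expect_error(fit_bayes_factor_model(toy$features, toy$fpkm,
                                      expressed_threshold = 100),
               "expressed")
})

test_that("allele_bayes_factor sums per-assay log likelihood ratios", {
  toy <- toy_training()
  m <- fit_bayes_factor_model(toy$features, toy$fpkm)
  # identical reference densities for every mark -> bayes factor 0
  m0 <- m
  for (a in m0$assays) m0$refs[[a]]$nonexpressed <- m0$refs[[a]]$expressed
  bf0 <- allele_bayes_factor(m0, c(K4me3 = 5, K27me3 = 1))
  expect_equal(as.numeric(bf0), 0)
  # active-typical densities score positive under the separated model
  bf_act <- allele_bayes_factor(m, c(K4me3 = 8, K27me3 = 0.3))
  expect_gt(as.numeric(bf_act), 0)
  # determinism
  expect_equal(as.numeric(allele_bayes_factor(m, c(K4me3 = 8, K27me3 = 0.3))),
               as.numeric(bf_act))
  # missing assays are skipped and counted
  bf1 <- allele_bayes_factor(m, data.frame(K4me3 = c(8, NA)))
  expect_equal(attr(bf1, "n_assays"), c(1L, 0L))
  expect_true(is.na(bf1[2]))
})

test_that("predict_expression_skew is antisymmetric in the alleles", {
  toy <- toy_training()
  m <- fit_bayes_factor_model(toy$features, toy$fpkm)
  set.seed(10)
  feats <- data.table::data.table(
    gene_id = sprintf("v%02d", 1:30),
    K4me3_mus = 2^rnorm(30, 1), K4me3_cas = 2^rnorm(30, 1),
    K27me3_mus = 2^rnorm(30, 0), K27me3_cas = 2^rnorm(30, 0))
  p <- predict_expression_skew(m, feats)
  expect_equal(p$predicted_skew, p$bf_mus - p$bf_cas)
  # symmetric alleles -> zero skew
  sym <- data.table::copy(feats)
  sym[, `:=`(K4me3_cas = K4me3_mus, K27me3_cas = K27me3_mus)]
  expect_equal(predict_expression_skew(m, sym)$predicted_skew,
               rep(0, 30))
  # allele swap -> negated skew
  sw <- data.table::data.table(gene_id = feats$gene_id,
                               K4me3_mus = feats$K4me3_cas,
                               K4me3_cas = feats$K4me3_mus,
                               K27me3_mus = feats$K27me3_cas,
                               K27me3_cas = feats$K27me3_mus)
  expect_equal(predict_expression_skew(m, sw)$predicted_skew,
               -p$predicted_skew)
})

test_that("linear_cv_model handles exact, null and collinear predictors", {
  set.seed(11)
  X <- data.frame(a = rnorm(60), b = rnorm(60))
  y <- 2 * X$a - X$b + 1
  fit <- linear_cv_model(X, y, repeats = 3, seed = 2)
  expect_equal(fit$mean_r, 1.0, tolerance = 1e-8)

  # independent response: over independent datasets the mean held-out R
  # is within 3 SE of 0 (within one dataset the fold R values share the
  # data, so the spread must be taken across datasets)
  null_r <- vapply(1:200, function(i) {
    set.seed(5000 + i)
    Xi <- data.frame(a = rnorm(60), b = rnorm(60))
    linear_cv_model(Xi, rnorm(60), repeats = 2, seed = i)$mean_r
  }, 0)
  se <- sd(null_r) / sqrt(length(null_r))
  # no spurious positive signal; held-out correlation under the null has a
  # small negative bias (fold partitioning anti-correlates the train and
  # test covariances within one finite sample), so the bound is one-sided
  # with a small allowance on the negative side
  expect_lt(mean(null_r), 3 * se)
  expect_gt(mean(null_r), -0.15)

  # duplicated predictor column: identical predictions via pseudo-inverse
  Xdup <- data.frame(a = X$a, a2 = X$a)
  f1 <- linear_cv_model(data.frame(a = X$a), y, repeats = 5, seed = 4)
  f2 <- suppressWarnings(linear_cv_model(Xdup, y, repeats = 5, seed = 4))
  expect_equal(f1$per_fold_r, f2$per_fold_r, tolerance = 1e-6)
  expect_error(linear_cv_model(X[1:5, ], y[1:5]), ">= 10")
})

test_that("variance_decomposition telescopes to the full model", {
  set.seed(12)
  n <- 400
  X <- data.frame(K4me3 = rnorm(n), K36me3 = rnorm(n), POL2S2 = rnorm(n),
                  K27me3 = rnorm(n))
  y <- 0.4 * X$K4me3 + 0.4 * X$K36me3 + 0.3 * X$POL2S2 - 0.3 * X$K27me3 +
    rnorm(n)
  vd <- variance_decomposition(X, y)
  expect_equal(sum(vd$increments), vd$full_r2, tolerance = 1e-9)
  # near-orthogonal predictors: increments close to individual R2
  expect_lt(max(abs(vd$increments - vd$individual_r2)), 0.03)
  # perfectly collinear second predictor: ~zero increment
  X2 <- data.frame(K4me3 = X$K4me3, K36me3 = X$K4me3)
  vd2 <- suppressWarnings(variance_decomposition(X2, y))
  expect_lt(abs(vd2$increments[["K36me3"]]), 1e-8)
})

test_that("roc_over_cutoffs reproduces known AUC regimes", {
  set.seed(13)
  obs <- rep(c(TRUE, FALSE), each = 50)
  perfect <- ifelse(obs, 6, 0)
  r1 <- roc_over_cutoffs(perfect, obs)
  expect_equal(unname(r1$auc), 1.0)
  # predictor independent of truth: AUC near 0.5
  obs2 <- sample(c(TRUE, FALSE), 2000, replace = TRUE)
  r2 <- roc_over_cutoffs(abs(rnorm(2000, 0, 2)), obs2)
  expect_gt(unname(r2$auc), 0.45)
  expect_lt(unname(r2$auc), 0.55)
  # degenerate observed classes: NA AUC
  r3 <- suppressMessages(roc_over_cutoffs(abs(rnorm(20)), rep(TRUE, 20)))
  expect_true(is.na(r3$auc))
  # multiple models keep their names
  r4 <- roc_over_cutoffs(list(x = perfect, y = abs(rnorm(100))), obs)
  expect_setequal(names(r4$auc), c("x", "y"))
  expect_setequal(unique(r4$roc$model), c("x", "y"))
})

test_that("qpcr_fold_difference follows the printed formula", {
  expect_equal(qpcr_fold_difference(20, 20), 1.0)
  expect_equal(qpcr_fold_difference(21, 20), 2.0)
  expect_equal(qpcr_fold_difference(17, 20), 0.125)
  expect_error(qpcr_fold_difference(Inf, 20), "finite")
  rep_ <- qpcr_report(data.frame(gene_id = c("a", "b"),
                                 ct_mus = c(21, 18), ct_cas = c(20, 20)))
  expect_equal(rep_$fold_difference, c(2, 0.25))
  expect_equal(rep_$fold_expression, c(0.5, 4))   # conventional delta-Ct
})

test_that("bf model text serialization round-trips predictions", {
  toy <- toy_training()
  m <- fit_bayes_factor_model(toy$features, toy$fpkm)
  path <- tempfile(fileext = ".txt")
  write_bf_model(m, path)
  m2 <- read_bf_model(path)
  x <- c(K4me3 = 4.2, K27me3 = 0.7)
  expect_equal(as.numeric(allele_bayes_factor(m2, x)),
               as.numeric(allele_bayes_factor(m, x)), tolerance = 1e-9)
})

test_that("validation R degrades monotonically with expression noise", {
  mean_r <- vapply(c(0.5, 1.5, 3.0), function(ns) {
    rs <- vapply(1:5, function(s) {
      cfg <- generator_config(n_genes = 700, seed = 100 + s, noise_sd = ns)
      ds <- simulate_dataset(cfg)
      ev <- suppressMessages(suppressWarnings(
        run_evaluation(ds$counts, ds$fpkm, seed = s, cv_repeats = 3)))
      ev$pearson_r
    }, 0)
    mean(rs)
  }, 0)
  expect_true(all(diff(mean_r) < 0))
})

test_that("uniform strong cas skew is predicted cas for expressed genes", {
  # emulates the inactivated maternal X: active marks depleted and K27me3
  # gained on the mus allele, paternal allele unchanged
  cfg <- generator_config(n_genes = 1000, seed = 51)
  ds <- simulate_dataset(cfg)
  truth <- data.table::copy(ds$truth)
  shift <- 2^3   # 8-fold
  for (mk in c("K4me3", "K36me3", "POL2S2", "POL2S5")) {
    truth[[paste0("d_", mk, "_mus")]] <-
      truth[[paste0("d_", mk, "_mus")]] / shift
  }
  truth$d_K27me3_mus <- truth$d_K27me3_mus * shift
  cnt <- simulate_counts(truth, cfg, ds$annotation, seed = 52)
  densities <- normalize_density(
    cnt[!cnt$assay %in% c("input", "RNA"), ],
    cnt[cnt$assay == "input", ])
  feats <- enrichment_features(densities)
  m <- fit_bayes_factor_model(enrichment_features(normalize_density(
    ds$counts[!ds$counts$assay %in% c("input", "RNA"), ],
    ds$counts[ds$counts$assay == "input", ])), ds$fpkm)
  preds <- suppressMessages(predict_expression_skew(m, feats))
  # expressed X-linked genes are those transcribed from the active (cas)
  # allele; genes silent on both alleles carry no chromatin signal to read
  expressed <- intersect(ds$fpkm$gene_id[ds$fpkm$fpkm > 1],
                         ds$truth$gene_id[ds$truth$state_cas == "active"])
  p <- preds[preds$gene_id %in% expressed, ]
  expect_gt(nrow(p), 200L)
  expect_gt(mean(p$predicted_skew < 0), 0.95)
})
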