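test_that("classify_state partitions the density plane", {
  thr <- state_thresholds(k4_low = 1, k4_high = 2.5, k27_high = 1.5)
  # natural-scale densities; classification is on log2(1 + d)
  lo <- 0.5      # log2(1.5) ~ 0.58, below k4_low
  mid <- 3       # log2(4) = 2, between bounds
  hi <- 10       # log2(11) ~ 3.46, above k4_high
  k27lo <- 0.5
  k27hi <- 6     # log2(7) ~ 2.8, above k27_high
  expect_equal(classify_state(lo, k27lo, thr), "silent")
  expect_equal(classify_state(mid, k27hi, thr), "bivalent")
  expect_equal(classify_state(hi, k27lo, thr), "active")
  expect_equal(classify_state(mid, k27lo, thr), "intermediate")
  expect_equal(classify_state(hi, k27hi, thr), "intermediate")
  expect_error(state_thresholds(2, 1, 1), "k4_low")
  expect_error(classify_state(-1, 0, thr), ">= 0")
  # partition: always exactly one label
  set.seed(7)
  lab <- classify_state(runif(500, 0, 20), runif(500, 0, 20), thr)
  expect_true(all(lab %in% c("silent", "bivalent", "active",
                             "intermediate")))
})

test_that("fit_thresholds recovers well-separated modes deterministically", {
  set.seed(8)
  # K4 tri-modal on log2(1+d): modes near 0.3, 2, 4 -> valleys between
  k4 <- 2^c(rnorm(200, 0.3, 0.15), rnorm(150, 2, 0.2),
            rnorm(200, 4, 0.2)) - 1
  k4 <- pmax(k4, 0)
  k27 <- 2^c(rnorm(350, 0.3, 0.15), rnorm(200, 3, 0.2)) - 1
  k27 <- pmax(k27, 0)
  thr <- fit_thresholds(k4, k27)
  expect_gt(thr$k4_low, 0.6); expect_lt(thr$k4_low, 1.8)
  expect_gt(thr$k4_high, 2.4); expect_lt(thr$k4_high, 3.8)
  expect_gt(thr$k27_high, 0.8); expect_lt(thr$k27_high, 2.8)
  expect_identical(thr, fit_thresholds(k4, k27))   # determinism
  expect_error(fit_thresholds(rep(1, 200), rep(1, 200)), "degenerate")
  expect_error(fit_thresholds(k4[1:50], k27[1:50]), "100")
})

make_profiles <- function(cfg) {
  ds <- simulate_dataset(cfg)
  densities <- normalize_density(
    ds$counts[!ds$counts$assay %in% c("input", "RNA"), ],
    ds$counts[ds$counts$assay == "input", ])
  list(ds = ds, densities = densities,
       profiles = classify_allelic_states(densities))
}

test_that("allelic state classification recovers generator truth", {
  x <- make_profiles(generator_config(n_genes = 1200, seed = 43))
  prof <- x$profiles
  expect_true(all(table(prof$gene_id) == 3L))   # composite + two alleles
  # manual thresholds bypass fitting (override contract)
  thr <- attr(prof, "thresholds")
  prof2 <- classify_allelic_states(x$densities, thresholds = thr)
  expect_equal(prof2$state, prof$state)
  # composite classification should agree with truth for most genes
  comp <- prof[prof$allele == "composite", ]
  truth_comp <- ifelse(x$ds$truth$state_mus == x$ds$truth$state_cas,
                       x$ds$truth$state_mus, NA)
  m <- match(comp$gene_id, x$ds$truth$gene_id)
  same <- !is.na(truth_comp[m]) & comp$state %in% c("silent", "bivalent",
                                                    "active")
  acc <- mean(comp$state[same] == truth_comp[m][same])
  expect_gt(acc, 0.8)
  # alleles with < 5 allelic reads over K4+K27 are unclassifiable
  k4 <- x$densities[x$densities$assay == "K4me3" &
                      x$densities$region_type == "promoter", ]
  k27 <- x$densities[x$densities$assay == "K27me3" &
                       x$densities$region_type == "promoter", ]
  ev <- k4$n_mus[match(comp$gene_id, k4$gene_id)] +
    k27$n_mus[match(comp$gene_id, k27$gene_id)]
  mus <- prof[prof$allele == "mus", ]
  expect_true(all(mus$state[ev < 5] == "unclassifiable"))
})

test_that("combination_census tallies pairs with conservation", {
  x <- make_profiles(generator_config(n_genes = 600, seed = 45,
                                      p_same_type = 1))
  cen <- combination_census(x$profiles)
  expect_equal(sum(cen$census), cen$n_classified)
  # p_same_type = 1: off-diagonal mass only from classification noise
  expect_gt(sum(diag(cen$census)) / cen$n_classified, 0.9)

  # direct wide-table census: forced diagonal and zero cells
  wide <- data.table::data.table(gene_id = sprintf("g%d", 1:9),
                                 state_mus = rep(c("silent", "bivalent",
                                                   "active"), 3))
  wide$state_cas <- wide$state_mus
  cen2 <- combination_census(wide)
  expect_equal(sum(diag(cen2$census)), 9L)
  expect_equal(cen2$rare_pair_count, 0L)
  # antisymmetry: swapping alleles transposes the census
  swapped <- data.table::copy(wide)
  swapped[2, `:=`(state_mus = "bivalent", state_cas = "silent")]
  cen_a <- combination_census(swapped)
  resw <- data.table::data.table(gene_id = swapped$gene_id,
                                 state_mus = swapped$state_cas,
                                 state_cas = swapped$state_mus)
  cen_b <- combination_census(resw)
  expect_equal(cen_a$census, t(cen_b$census))
  expect_equal(cen_a$rare_pair_count, 1L)
})

test_that("restrict_to limits the census to the given genes", {
  wide <- data.table::data.table(gene_id = c("a", "b", "c"),
                                 state_mus = c("active", "silent", "active"),
                                 state_cas = c("active", "silent", "silent"))
  cen <- combination_census(wide, restrict_to = c("a", "c"))
  expect_equal(cen$n_classified, 2L)
  expect_equal(cen$genes[["active|silent"]], "c")
})

test_that("skew_pair_analysis partitions genes and correlates both-skewed", {
  mk <- function(skew, skewed) data.table::data.table(
    gene_id = sprintf("g%02d", seq_along(skew)), assay = "x",
    n_mus = 30L, n_cas = 10L, log2_ratio = skew, p_value = 0.001,
    fdr = 0.001, passed_min_reads = TRUE, passed_fold = TRUE,
    passed_fdr = TRUE, is_skewed = skewed,
    direction = ifelse(skewed, "mus", "none"))
  s <- c(2, -1.5, 1.2, 3, -2, 0.1, 0.2, -0.1, 0.3, 0)
  skewed <- c(rep(TRUE, 5), rep(FALSE, 5))
  same <- skew_pair_analysis(mk(s, skewed), mk(s, skewed))
  expect_equal(same$spearman_rho, 1.0)
  expect_equal(same$n_both, 5L)
  neg <- skew_pair_analysis(mk(s, skewed), mk(-s, skewed))
  expect_equal(neg$spearman_rho, -1.0)
  # fewer than 3 doubly-skewed genes: undefined correlation
  few <- skew_pair_analysis(mk(s, c(TRUE, TRUE, rep(FALSE, 8))),
                            mk(s, c(TRUE, TRUE, rep(FALSE, 8))))
  expect_true(is.na(few$spearman_rho))
  expect_equal(few$n_both, 2L)
  # disjoint skew sets
  dis <- skew_pair_analysis(mk(s, c(rep(TRUE, 3), rep(FALSE, 7))),
                            mk(s, c(rep(FALSE, 3), rep(TRUE, 3),
                                    rep(FALSE, 4))))
  expect_equal(dis$n_both, 0L)
  expect_equal(dis$n_a_only, 3L)
  expect_equal(dis$n_b_only, 3L)
})

test_that("state-conditioned skew distributions behave as expected", {
  x <- make_profiles(generator_config(n_genes = 1500, seed = 47))
  calls <- list(K4me3 = call_skewed(x$ds$counts, "K4me3"),
                K27me3 = call_skewed(x$ds$counts, "K27me3"))
  dist <- state_conditioned_skew_distributions(x$profiles, calls)
  expect_true(all(c("state", "assay", "median", "q1", "q3") %in%
                    names(dist)))
  # no parental bias: medians near zero (tight in well-populated cells,
  # looser where few genes pass the read filter)
  big <- dist[dist$n >= 200, ]
  expect_gt(nrow(big), 2L)
  expect_true(all(abs(big$median) < 0.1))
  expect_true(all(abs(dist$median) < 0.3))
  # single-gene input: quartiles collapse onto the gene's skew
  st1 <- data.table::data.table(gene_id = "g03", state = "active")
  c1 <- list(K4me3 = call_skewed(ten_gene_counts()[3], "K4me3"))
  d1 <- state_conditioned_skew_distributions(st1, c1)
  expect_equal(d1$q1, d1$median)
  expect_equal(d1$q3, d1$median)
})
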