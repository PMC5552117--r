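## Chromatin-state classification from K4me3/K27me3 promoter densities.
##
## The K4me3 x K27me3 density plane of promoters shows three major
## regions: silent genes with concerted depletion of both marks, bivalent
## genes with the highest K27me3 and intermediate K4me3, and active genes
## with high K4me3 and low K27me3.  Numeric region boundaries are not a
## property of the data model; they are fitted from the observed density
## distribution (or supplied manually) and all classifications are relative
## to those fitted thresholds.

#' Construct state-classification thresholds
#'
#' Thresholds live on the `log2(1 + density)` scale of input-normalized
#' promoter densities.
#'
#' @param k4_low,k4_high lower/upper K4me3 boundaries (silent | bivalent |
#'   active).
#' @param k27_high K27me3 boundary above which a promoter is
#'   K27me3-occupied.
#' @return object of class `state_thresholds`.
#' @export
state_thresholds <- function(k4_low, k4_high, k27_high) {
  if (!all(is.finite(c(k4_low, k4_high, k27_high))))
    .stopf("thresholds must be finite")
  if (k4_low >= k4_high) .stopf("k4_low must be < k4_high")
  structure(list(k4_low = k4_low, k4_high = k4_high, k27_high = k27_high),
            class = "state_thresholds")
}

#' Classify chromatin state from K4me3 and K27me3 densities
#'
#' On the `log2(1 + density)` scale: `silent` when K4me3 is below `k4_low`
#' and K27me3 below `k27_high` (concerted depletion); `bivalent` when
#' K27me3 is at or above `k27_high` with K4me3 below `k4_high`; `active`
#' when K4me3 is at or above `k4_high` with K27me3 below `k27_high`;
#' everything else (including high-K4 high-K27 promoters and the band
#' between `k4_low` and `k4_high` at low K27me3) is `intermediate` rather
#' than force-fitted to a major state.
#'
#' @param k4_density,k27_density non-negative density vectors (natural
#'   scale; the log transform is applied internally).
#' @param thresholds a `state_thresholds` object.
#' @return character vector over `c("silent", "bivalent", "active",
#'   "intermediate")`; `NA` densities give `NA`.
#' @export
classify_state <- function(k4_density, k27_density, thresholds) {
  if (!inherits(thresholds, "state_thresholds"))
    .stopf("thresholds must be a state_thresholds object")
  if (any(k4_density < 0 | k27_density < 0, na.rm = TRUE))
    .stopf("densities must be >= 0")
  k4 <- log2(1 + k4_density)
  k27 <- log2(1 + k27_density)
  out <- rep(NA_character_, length(k4))
  ok <- !is.na(k4) & !is.na(k27)
  out[ok] <- "intermediate"
  out[ok & k4 < thresholds$k4_low & k27 < thresholds$k27_high] <- "silent"
  out[ok & k27 >= thresholds$k27_high & k4 < thresholds$k4_high] <- "bivalent"
  out[ok & k4 >= thresholds$k4_high & k27 < thresholds$k27_high] <- "active"
  out
}

# exact deterministic 1-D 2-means: exhaustive search over sorted splits
# minimizing within-cluster sum of squares; returns the midpoint between
# the two cluster edges
.split1d <- function(x) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 4L || stats::sd(x) < 1e-9)
    .stopf("degenerate density distribution: supply thresholds manually")
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  i <- seq_len(n - 1L)
  ss_lo <- cs2[i] - cs[i]^2 / i
  ss_hi <- (cs2[n] - cs2[i]) - (cs[n] - cs[i])^2 / (n - i)
  k <- which.min(ss_lo + ss_hi)
  (x[k] + x[k + 1L]) / 2
}

# two boundaries by recursive 2-means: split once, then re-split whichever
# side yields the larger further reduction in within-cluster sum of squares
.split1d_two <- function(x) {
  b1 <- .split1d(x)
  lo <- x[x <= b1]; hi <- x[x > b1]
  gain <- function(v) {
    if (length(v) < 4L || stats::sd(v) < 1e-9) return(list(g = -Inf))
    b <- .split1d(v)
    ss <- function(u) if (length(u)) sum((u - mean(u))^2) else 0
    list(g = ss(v) - ss(v[v <= b]) - ss(v[v > b]), b = b)
  }
  glo <- gain(lo); ghi <- gain(hi)
  if (!is.finite(glo$g) && !is.finite(ghi$g))
    .stopf("no secondary K4me3 mode: supply thresholds manually")
  b2 <- if (glo$g >= ghi$g) glo$b else ghi$b
  sort(c(b1, b2))
}

#' Fit state thresholds from observed densities
#'
#' Data-driven reconstruction of the region boundaries: the
#' `log2(1 + K4me3)` distribution is split by exact 1-D 2-means run twice
#' (the second split refining whichever side still carries the most
#' within-cluster variance), giving `k4_low` and `k4_high` at the valleys
#' between the depleted, moderate and high modes; `k27_high` splits the
#' `log2(1 + K27me3)` distribution once.  Deterministic given the input.
#' These boundaries are a reconstruction, not an observed quantity;
#' reports should label them as fitted.
#'
#' @param k4_density,k27_density non-negative promoter density vectors
#'   (>= 100 non-missing genes required).
#' @return a `state_thresholds` object.
#' @export
fit_thresholds <- function(k4_density, k27_density) {
  k4 <- log2(1 + k4_density[!is.na(k4_density)])
  k27 <- log2(1 + k27_density[!is.na(k27_density)])
  if (length(k4) < 100L || length(k27) < 100L)
    .stopf("need >= 100 genes with defined densities to fit thresholds")
  b <- .split1d_two(k4)
  k27_high <- .split1d(k27)
  state_thresholds(b[1], b[2], k27_high)
}

#' Classify composite and per-allele chromatin states
#'
#' Builds `AlleleStateProfile` rows for the composite track and for each
#' allele.  Allelic states are classified on inferred allelic densities
#' (composite promoter density split by the observed mus:cas read ratio,
#' see [inferred_allelic_density()]).  An allele with fewer than
#' `min_allelic_reads` allele-specific reads summed over K4me3 and K27me3
#' promoters is labelled `unclassifiable`.
#'
#' @param densities density table from [normalize_density()] (must contain
#'   promoter rows for K4me3 and K27me3, with counts).
#' @param thresholds a `state_thresholds` object, or `NULL` to fit from the
#'   composite densities via [fit_thresholds()].
#' @param min_allelic_reads minimum K4me3+K27me3 allelic evidence per
#'   allele.
#' @return `data.table`: `gene_id, allele` (`composite`, `mus`, `cas`),
#'   `k4, k27` (densities used), `state`; attribute `"thresholds"` carries
#'   the thresholds used.
#' @export
classify_allelic_states <- function(densities, thresholds = NULL,
                                    min_allelic_reads = 5L) {
  d <- as.data.table(densities)
  k4 <- d[assay == "K4me3" & region_type == "promoter"]
  k27 <- d[assay == "K27me3" & region_type == "promoter"]
  dt <- merge(k4[, .(gene_id, k4_comp = density_composite,
                     k4_mus_n = n_mus, k4_cas_n = n_cas)],
              k27[, .(gene_id, k27_comp = density_composite,
                      k27_mus_n = n_mus, k27_cas_n = n_cas)],
              by = "gene_id")
  if (is.null(thresholds))
    thresholds <- fit_thresholds(dt$k4_comp, dt$k27_comp)

  infer <- function(comp, nm, nc) {
    tot <- nm + nc
    p <- ifelse(tot > 0, nm / tot, NA_real_)
    list(mus = comp * p, cas = comp * (1 - p))
  }
  k4a <- infer(dt$k4_comp, dt$k4_mus_n, dt$k4_cas_n)
  k27a <- infer(dt$k27_comp, dt$k27_mus_n, dt$k27_cas_n)
  ev_mus <- dt$k4_mus_n + dt$k27_mus_n
  ev_cas <- dt$k4_cas_n + dt$k27_cas_n

  prof <- rbind(
    data.table(gene_id = dt$gene_id, allele = "composite",
               k4 = dt$k4_comp, k27 = dt$k27_comp,
               state = classify_state(dt$k4_comp, dt$k27_comp, thresholds)),
    data.table(gene_id = dt$gene_id, allele = "mus",
               k4 = k4a$mus, k27 = k27a$mus,
               state = ifelse(ev_mus < min_allelic_reads, "unclassifiable",
                              classify_state(k4a$mus, k27a$mus, thresholds))),
    data.table(gene_id = dt$gene_id, allele = "cas",
               k4 = k4a$cas, k27 = k27a$cas,
               state = ifelse(ev_cas < min_allelic_reads, "unclassifiable",
                              classify_state(k4a$cas, k27a$cas, thresholds))))
  setorder(prof, gene_id, allele)
  data.table::setattr(prof, "thresholds", thresholds)
  prof[]
}

#' Census of allelic state combinations
#'
#' Tallies the (mus state, cas state) pairs of all genes whose two alleles
#' both carry one of the three major states, and reports the gene ids per
#' cell.  The bivalent-silent combination is flagged as the "rare"
#' combination for reporting.
#'
#' @param profiles profile table from [classify_allelic_states()] (or any
#'   table with `gene_id, allele, state` rows for alleles `mus`/`cas`), or
#'   a wide table with `gene_id, state_mus, state_cas`.
#' @param restrict_to optional character vector of gene ids (e.g. skewed
#'   genes) to census.
#' @return list with `census` (3x3 integer matrix, rows = mus state,
#'   columns = cas state), `genes` (list of gene-id vectors per cell,
#'   named `"mus_state|cas_state"`), `n_classified`, `n_excluded`, and
#'   `rare_pair_count` (bivalent-silent in either orientation).
#' @export
combination_census <- function(profiles, restrict_to = NULL) {
  p <- as.data.table(profiles)
  if (all(c("state_mus", "state_cas") %in% names(p))) {
    wide <- p[, .(gene_id, state_mus, state_cas)]
  } else {
    m <- p[allele == "mus", .(gene_id, state_mus = state)]
    c_ <- p[allele == "cas", .(gene_id, state_cas = state)]
    wide <- merge(m, c_, by = "gene_id")
  }
  if (!is.null(restrict_to)) wide <- wide[gene_id %in% restrict_to]
  ok <- wide$state_mus %in% STATE_LEVELS & wide$state_cas %in% STATE_LEVELS
  n_excluded <- sum(!ok)
  wide <- wide[ok]
  census <- table(factor(wide$state_mus, STATE_LEVELS),
                  factor(wide$state_cas, STATE_LEVELS))
  census <- unclass(census)
  genes <- list()
  for (sm in STATE_LEVELS) for (sc in STATE_LEVELS)
    genes[[paste(sm, sc, sep = "|")]] <-
      wide[state_mus == sm & state_cas == sc, gene_id]
  list(census = census, genes = genes, n_classified = nrow(wide),
       n_excluded = n_excluded,
       rare_pair_count = census["bivalent", "silent"] +
         census["silent", "bivalent"])
}

#' Pairwise analysis of allelic skews of two marks
#'
#' Over the common gene universe of two skew-call tables, partitions genes
#' by which mark is skewed and computes the Spearman rank correlation of
#' the log2 skews among genes skewed in both marks.
#'
#' @param calls_a,calls_b skew-call tables from [call_skewed()].
#' @return list: `n_a_only`, `n_b_only`, `n_both`, `n_neither`,
#'   `spearman_rho` (NA when `n_both < 3`), and `both_genes`.
#' @export
skew_pair_analysis <- function(calls_a, calls_b) {
  a <- as.data.table(calls_a)[, .(gene_id, skew_a = log2_ratio,
                                  is_a = is_skewed)]
  b <- as.data.table(calls_b)[, .(gene_id, skew_b = log2_ratio,
                                  is_b = is_skewed)]
  dt <- merge(a, b, by = "gene_id")
  both <- dt[is_a & is_b]
  rho <- if (nrow(both) >= 3L)
    cor(both$skew_a, both$skew_b, method = "spearman") else NA_real_
  list(n_a_only = dt[, sum(is_a & !is_b)],
       n_b_only = dt[, sum(is_b & !is_a)],
       n_both = nrow(both),
       n_neither = dt[, sum(!is_a & !is_b)],
       spearman_rho = rho,
       both_genes = both$gene_id)
}

#' Skew distributions conditioned on chromatin state
#'
#' Boxplot statistics (median, quartiles, 1.5 x IQR whiskers, outliers) of
#' per-mark log2 allelic skew within each composite chromatin state.
#' Empty state classes are omitted with a log note.
#'
#' @param states data.frame `gene_id, state` (composite state per gene),
#'   e.g. the `allele == "composite"` rows of [classify_allelic_states()].
#' @param calls named list of skew-call tables (one per mark).
#' @return `data.table`: `state, assay, n, median, q1, q3, whisker_lo,
#'   whisker_hi, n_outliers`.
#' @export
state_conditioned_skew_distributions <- function(states, calls) {
  st <- as.data.table(states)
  if ("allele" %in% names(st)) st <- st[allele == "composite"]
  st <- st[, .(gene_id, state)]
  rows <- list()
  for (a in names(calls)) {
    dt <- merge(st, as.data.table(calls[[a]])[passed_min_reads == TRUE,
                                              .(gene_id, log2_ratio)],
                by = "gene_id")
    for (s in STATE_LEVELS) {
      x <- dt[state == s, log2_ratio]
      x <- x[is.finite(x)]
      if (length(x) == 0L) {
        .logf("state_conditioned_skew_distributions: no %s genes for %s",
              s, a)
        next
      }
      q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
      iqr <- q[3] - q[1]
      inl <- x[x >= q[1] - 1.5 * iqr & x <= q[3] + 1.5 * iqr]
      rows[[paste(a, s)]] <- data.table(
        state = s, assay = a, n = length(x), median = q[2],
        q1 = q[1], q3 = q[3],
        whisker_lo = min(inl), whisker_hi = max(inl),
        n_outliers = length(x) - length(inl))
    }
  }
  rbindlist(rows)[]
}
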