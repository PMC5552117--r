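## Seeded generator of gene annotations, allelic states, count tables and
## fragment intervals emulating the statistical structure of allele-specific
## ChIP/RNA-seq in an F1 hybrid MEF line: three gross chromatin states
## (silent / bivalent / active) with state-dependent mark densities,
## continuous within-state allelic skew, rare cross-type allelic
## combinations, allelically-assignable read fractions of ~0.37 (ChIP) and
## ~0.17 (RNA), and allelic expression log-linear in allelic mark densities.

#' Generator configuration
#'
#' Builds a validated configuration for the synthetic allele-specific
#' chromatin dataset generator.  Defaults encode the emulated data regime:
#' ChIP fragments are allele-assignable at fraction 0.37 and RNA fragments
#' at 0.17; most genes carry the same gross chromatin state on both alleles;
#' among cross-type genes the bivalent-silent combination is rare (2% of
#' cross-type mass); allelic expression is log-linear in allelic mark
#' densities with positive weights for active marks and a negative weight
#' for K27me3.
#'
#' @param n_genes number of genes to simulate.
#' @param state_mixture probabilities over `c(silent, bivalent, active)` for
#'   the gene's gross (composite) chromatin state.
#' @param p_same_type probability that both alleles share the gross state.
#' @param cross_type_weights probabilities over the unordered cross-type
#'   pairs `c(active_silent, active_bivalent, bivalent_silent)`; which
#'   allele receives which state is decided by a fair coin.
#' @param within_type_skew_sd standard deviation (log2) of the per-gene
#'   latent allelic activity difference; it shifts active-mark densities up
#'   and K27me3 density down on the more active allele.
#' @param state_skew_scale named multipliers damping the allelic activity
#'   difference and per-allele noise by gross state; the bivalent default
#'   (0.3) encodes the strong allelic buffering of poised promoters seen
#'   in the emulated data, whose bivalent-state skew distributions are
#'   much narrower than active-state ones.
#' @param allele_noise_sd standard deviation (log2) of independent
#'   per-allele, per-mark density noise.
#' @param template_sd standard deviation (log2) of per-gene mark-level
#'   noise shared by the two alleles.
#' @param depth_per_assay mean composite fragments per gene region per assay
#'   at unit density.
#' @param dispersion negative-binomial dispersion of composite counts
#'   (`size = 1/dispersion`); 0 gives Poisson counts.
#' @param allelic_fraction_chip fraction of ChIP/input fragments assignable
#'   to an allele.
#' @param allelic_fraction_rna same for RNA fragments.
#' @param expression_weights named signed coefficients mapping
#'   `log2(1 + density)` of each mark to log2 allelic expression.
#' @param expression_intercept intercept (log2) of the expression model.
#' @param noise_sd expression noise standard deviation (log2), per allele.
#' @param background_density input-normalized mark density outside the
#'   assay's canonical region.
#' @param rna_replicates number of RNA-seq replicates.
#' @param frag_len simulated fragment length in bp.
#' @param seed integer seed; all generator randomness derives from it.
#' @return an object of class `generator_config` (a named list).
#' @export
generator_config <- function(n_genes = 2000L,
                             state_mixture = c(silent = 0.40, bivalent = 0.15,
                                               active = 0.45),
                             p_same_type = 0.90,
                             cross_type_weights = c(active_silent = 0.58,
                                                    active_bivalent = 0.40,
                                                    bivalent_silent = 0.02),
                             within_type_skew_sd = 0.30,
                             state_skew_scale = c(silent = 1, bivalent = 0.3,
                                                  active = 1),
                             allele_noise_sd = 0.25,
                             template_sd = 0.50,
                             depth_per_assay = 100,
                             dispersion = 0.1,
                             allelic_fraction_chip = 0.37,
                             allelic_fraction_rna = 0.17,
                             expression_weights = c(K4me3 = 0.55, K27me3 = -0.45,
                                                    K36me3 = 0.45, POL2S2 = 0.35,
                                                    POL2S5 = 0.25),
                             expression_intercept = -1.5,
                             noise_sd = 1.0,
                             background_density = 0.25,
                             rna_replicates = 2L,
                             frag_len = 400L,
                             seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    state_mixture = state_mixture[STATE_LEVELS],
    p_same_type = p_same_type,
    cross_type_weights = cross_type_weights[c("active_silent",
                                              "active_bivalent",
                                              "bivalent_silent")],
    within_type_skew_sd = within_type_skew_sd,
    state_skew_scale = state_skew_scale[STATE_LEVELS],
    allele_noise_sd = allele_noise_sd,
    template_sd = template_sd,
    depth_per_assay = depth_per_assay,
    dispersion = dispersion,
    allelic_fraction_chip = allelic_fraction_chip,
    allelic_fraction_rna = allelic_fraction_rna,
    expression_weights = expression_weights[CHIP_ASSAYS],
    expression_intercept = expression_intercept,
    noise_sd = noise_sd,
    background_density = background_density,
    rna_replicates = as.integer(rna_replicates),
    frag_len = as.integer(frag_len),
    seed = as.integer(seed))
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

#' Validate a generator configuration
#'
#' @param config a `generator_config`.
#' @return the config, invisibly; errors on violation.
#' @export
validate_generator_config <- function(config) {
  if (!inherits(config, "generator_config"))
    .stopf("not a generator_config")
  if (is.na(config$n_genes) || config$n_genes < 1L)
    .stopf("n_genes must be >= 1")
  .check_simplex(config$state_mixture, "state_mixture")
  .check_simplex(config$cross_type_weights, "cross_type_weights")
  for (f in c("p_same_type", "allelic_fraction_chip", "allelic_fraction_rna"))
    if (config[[f]] < 0 || config[[f]] > 1)
      .stopf("%s must be in [0,1]", f)
  if (config$depth_per_assay <= 0) .stopf("depth_per_assay must be > 0")
  if (config$dispersion < 0) .stopf("dispersion must be >= 0")
  for (f in c("within_type_skew_sd", "allele_noise_sd", "template_sd",
              "noise_sd"))
    if (config[[f]] < 0) .stopf("%s must be >= 0", f)
  if (any(is.na(config$state_skew_scale)) || any(config$state_skew_scale < 0))
    .stopf("state_skew_scale must name non-negative values for all states")
  if (any(is.na(config$expression_weights)))
    .stopf("expression_weights must name all of: %s",
           paste(CHIP_ASSAYS, collapse = ", "))
  if (config$rna_replicates < 1L) .stopf("rna_replicates must be >= 1")
  invisible(config)
}

# log2-space state density templates: rows are gross states, columns marks.
# Geometry: active = high K4/K36/POL2, low K27; bivalent = moderate K4,
# high K27, depleted elongation marks; silent = concerted depletion.
.state_templates <- function() {
  rbind(
    silent   = c(K4me3 = -2.0, K27me3 = -1.5, K36me3 = -2.5,
                 POL2S2 = -2.5, POL2S5 = -2.5),
    bivalent = c(K4me3 =  1.0, K27me3 =  3.0, K36me3 = -2.0,
                 POL2S2 = -2.0, POL2S5 = -2.0),
    active   = c(K4me3 =  3.0, K27me3 = -1.0, K36me3 =  2.5,
                 POL2S2 =  2.5, POL2S5 =  2.5))
}

# sign with which the latent allelic activity difference hits each mark:
# the more active allele gains active marks and loses K27me3
.mark_sign <- c(K4me3 = 1, K27me3 = -1, K36me3 = 1, POL2S2 = 1, POL2S5 = 1)

#' Generate a synthetic gene annotation
#'
#' Places `n_genes` non-overlapping gene bodies on a small set of named
#' chromosomes, with random strand; the TSS sits at the 5' end of the body
#' on the annotated strand.  Coordinates are 0-based half-open.
#'
#' @param n_genes number of genes (>= 1).
#' @param seed integer seed.
#' @param chromosomes chromosome names to distribute genes over.
#' @return `data.table` with columns `gene_id, chrom, start, end, strand,
#'   tss`.
#' @export
generate_annotation <- function(n_genes, seed = 1L,
                                chromosomes = paste0("chr", 1:5)) {
  if (is.na(n_genes) || n_genes < 1) .stopf("n_genes must be >= 1")
  n_genes <- as.integer(n_genes)
  set.seed(as.integer(seed))
  chrom <- sort(sample(chromosomes, n_genes, replace = TRUE))
  len <- sample(2000:20000, n_genes, replace = TRUE)
  gap <- sample(3000:10000, n_genes, replace = TRUE)
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  dt <- data.table(gene_id = sprintf("g%05d", seq_len(n_genes)),
                   chrom = chrom, len = len, gap = gap, strand = strand)
  # sequential placement per chromosome guarantees non-overlap
  dt[, start := 2000L + cumsum(gap) + cumsum(c(0L, head(len, -1L))), by = chrom]
  dt[, end := start + len]
  dt[, tss := ifelse(strand == "+", start, end - 1L)]
  dt[, c("len", "gap") := NULL]
  dt[]
}

#' Promoter and gene-body regions for an annotation
#'
#' Promoter is `[TSS - width, TSS + width)` (default TSS +/- 1 kb, clipped
#' at zero); body is the annotated gene interval.
#'
#' @param annotation annotation `data.table` from [generate_annotation()] or
#'   [read_annotation()].
#' @param promoter_halfwidth half-width of the promoter window in bp.
#' @return `data.table` with columns `gene_id, chrom, strand, region_type,
#'   start, end`.
#' @export
make_region_set <- function(annotation, promoter_halfwidth = 1000L) {
  a <- as.data.table(annotation)
  prom <- a[, .(gene_id, chrom, strand, region_type = "promoter",
                start = pmax(0L, as.integer(tss - promoter_halfwidth)),
                end = as.integer(tss + promoter_halfwidth))]
  body <- a[, .(gene_id, chrom, strand, region_type = "body",
                start = as.integer(start), end = as.integer(end))]
  out <- rbind(prom, body)
  if (any(out$end <= out$start)) .stopf("zero-length region in region set")
  setorder(out, gene_id, region_type)
  out[]
}

#' Draw per-gene allelic chromatin states and true densities
#'
#' For each gene, draws the gross chromatin state of each allele (same-type
#' with probability `p_same_type`, otherwise a cross-type pair weighted by
#' `cross_type_weights`), then generates per-allele input-normalized mark
#' densities: a state template plus gene-level noise shared by the alleles,
#' an independent per-allele noise term, and a latent allelic activity
#' difference that raises active marks and lowers K27me3 on the more active
#' allele.  Allelic expression is log-linear in `log2(1 + density)` with the
#' configured weights plus noise.
#'
#' @param config a `generator_config`.
#' @return `data.table` truth table: `gene_id`, `state_mus`, `state_cas`,
#'   per-mark densities `d_<mark>_<allele>`, expression `expr_mus/expr_cas`,
#'   `true_expression_proportion` (mus fraction, strictly in (0,1)) and true
#'   log2 skews `skew_<assay>` for every mark and RNA.
#' @export
draw_allelic_states <- function(config) {
  validate_generator_config(config)
  n <- config$n_genes
  set.seed(config$seed)
  tmpl <- .state_templates()

  same <- runif(n) < config$p_same_type
  comp_state <- sample(STATE_LEVELS, n, replace = TRUE,
                       prob = config$state_mixture)
  pair_names <- list(active_silent = c("active", "silent"),
                     active_bivalent = c("active", "bivalent"),
                     bivalent_silent = c("bivalent", "silent"))
  pair <- sample(names(pair_names), n, replace = TRUE,
                 prob = config$cross_type_weights)
  flip <- runif(n) < 0.5

  state_mus <- comp_state
  state_cas <- comp_state
  cross <- !same
  p1 <- vapply(pair_names[pair[cross]], `[`, "", 1L)
  p2 <- vapply(pair_names[pair[cross]], `[`, "", 2L)
  state_mus[cross] <- ifelse(flip[cross], p2, p1)
  state_cas[cross] <- ifelse(flip[cross], p1, p2)

  nm <- length(CHIP_ASSAYS)
  z_gene <- matrix(rnorm(n * nm), n, nm, dimnames = list(NULL, CHIP_ASSAYS))
  z_mus <- matrix(rnorm(n * nm), n, nm, dimnames = list(NULL, CHIP_ASSAYS))
  z_cas <- matrix(rnorm(n * nm), n, nm, dimnames = list(NULL, CHIP_ASSAYS))
  z_skew <- rnorm(n)
  z_expr <- matrix(rnorm(n * 2L), n, 2L)

  a <- config$within_type_skew_sd * z_skew   # latent activity difference
  # poised (bivalent) alleles are allelically buffered: both the activity
  # difference and the per-allele noise are damped by the state's scale
  sc_mus <- config$state_skew_scale[state_mus]
  sc_cas <- config$state_skew_scale[state_cas]
  ld_mus <- tmpl[state_mus, , drop = FALSE] +
    config$template_sd * z_gene +
    sc_mus * config$allele_noise_sd * z_mus +
    outer(sc_mus * a / 2, .mark_sign[CHIP_ASSAYS])
  ld_cas <- tmpl[state_cas, , drop = FALSE] +
    config$template_sd * z_gene +
    sc_cas * config$allele_noise_sd * z_cas -
    outer(sc_cas * a / 2, .mark_sign[CHIP_ASSAYS])
  d_mus <- 2^ld_mus
  d_cas <- 2^ld_cas

  w <- config$expression_weights
  le_mus <- config$expression_intercept +
    log2(1 + d_mus) %*% w + config$noise_sd * z_expr[, 1L]
  le_cas <- config$expression_intercept +
    log2(1 + d_cas) %*% w + config$noise_sd * z_expr[, 2L]
  expr_mus <- as.numeric(2^le_mus)
  expr_cas <- as.numeric(2^le_cas)

  cols <- list(gene_id = sprintf("g%05d", seq_len(n)),
               state_mus = state_mus, state_cas = state_cas)
  for (m in CHIP_ASSAYS) {
    cols[[paste0("d_", m, "_mus")]] <- d_mus[, m]
    cols[[paste0("d_", m, "_cas")]] <- d_cas[, m]
    cols[[paste0("skew_", m)]] <- ld_mus[, m] - ld_cas[, m]
  }
  cols$expr_mus <- expr_mus
  cols$expr_cas <- expr_cas
  cols$true_expression_proportion <- expr_mus / (expr_mus + expr_cas)
  cols$skew_RNA <- as.numeric(le_mus - le_cas)
  out <- as.data.table(cols)
  out[]
}

# negative-binomial (or Poisson when dispersion == 0) composite counts
.rcomposite <- function(n, mu, dispersion) {
  if (dispersion <= 0) return(stats::rpois(n, mu))
  rnbinom(n, size = 1 / dispersion, mu = mu)
}

#' Simulate allelic count tables from a truth table
#'
#' Composite fragment counts per gene x region x assay are drawn from a
#' negative binomial with mean `depth_per_assay x mean allelic density`;
#' allelic counts arise by binomial thinning at the assay's allelic fraction
#' and are split mus/cas according to the true allelic density (expression)
#' proportion.  ChIP marks carry their template density on the canonical
#' region and `background_density` elsewhere; a matched `input` assay has
#' unit density everywhere; RNA is simulated in `rna_replicates` replicates
#' over the gene body.
#'
#' @param truth truth table from [draw_allelic_states()].
#' @param config the same `generator_config`.
#' @param annotation optional annotation supplying `chrom` (else `NA`).
#' @param seed seed for the count noise; defaults to `config$seed + 1`.
#' @return `data.table` with columns `assay, gene_id, chrom, region_type,
#'   replicate, n_composite, n_mus, n_cas`.
#' @export
simulate_counts <- function(truth, config, annotation = NULL,
                            seed = config$seed + 1L) {
  validate_generator_config(config)
  truth <- as.data.table(truth)
  if (nrow(truth) != config$n_genes)
    .stopf("truth has %d genes but config says %d", nrow(truth),
           config$n_genes)
  set.seed(as.integer(seed))
  n <- nrow(truth)
  chrom <- rep(NA_character_, n)
  if (!is.null(annotation)) {
    ann <- as.data.table(annotation)
    chrom <- ann$chrom[match(truth$gene_id, ann$gene_id)]
  }
  depth <- config$depth_per_assay
  bg <- config$background_density

  one_block <- function(assay, region, rep_i, dm, dc, frac) {
    mu <- depth * (dm + dc) / 2
    n_comp <- .rcomposite(n, mu, config$dispersion)
    n_alle <- rbinom(n, n_comp, frac)
    p_mus <- ifelse(dm + dc > 0, dm / (dm + dc), 0.5)
    n_mus <- rbinom(n, n_alle, p_mus)
    data.table(assay = assay, gene_id = truth$gene_id, chrom = chrom,
               region_type = region, replicate = rep_i,
               n_composite = n_comp, n_mus = n_mus, n_cas = n_alle - n_mus)
  }

  blocks <- list()
  for (m in CHIP_ASSAYS) {
    dm <- truth[[paste0("d_", m, "_mus")]]
    dc <- truth[[paste0("d_", m, "_cas")]]
    can <- canonical_region(m)
    for (r in c("promoter", "body")) {
      if (r == can) {
        blocks[[paste(m, r)]] <- one_block(m, r, 1L, dm, dc,
                                           config$allelic_fraction_chip)
      } else {
        blocks[[paste(m, r)]] <- one_block(m, r, 1L, rep(bg, n), rep(bg, n),
                                           config$allelic_fraction_chip)
      }
    }
  }
  for (r in c("promoter", "body")) {
    blocks[[paste(INPUT_ASSAY, r)]] <-
      one_block(INPUT_ASSAY, r, 1L, rep(1, n), rep(1, n),
                config$allelic_fraction_chip)
  }
  for (k in seq_len(config$rna_replicates)) {
    blocks[[paste(RNA_ASSAY, k)]] <-
      one_block(RNA_ASSAY, "body", k, truth$expr_mus, truth$expr_cas,
                config$allelic_fraction_rna)
  }
  rbindlist(blocks)[]
}

#' Simulate fragment intervals consistent with a count table
#'
#' Expands each ChIP/input count-table row into `n_composite` fragment
#' records of length `frag_len` with uniformly placed starts inside the
#' region, carrying per-haplotype alignment scores that encode the drawn
#' allele: mus fragments score higher against the mus genome, cas fragments
#' against the cas genome, neutral fragments tie.  RNA rows are skipped.
#'
#' @param counts count table from [simulate_counts()].
#' @param annotation annotation `data.table` (for region coordinates).
#' @param config a `generator_config` (fragment length).
#' @param seed seed; defaults to `config$seed + 2`.
#' @return `data.table` with columns `chrom, start, end, assay, score_mus,
#'   score_cas`.
#' @export
simulate_fragments <- function(counts, annotation, config,
                               seed = config$seed + 2L) {
  counts <- as.data.table(counts)[assay != RNA_ASSAY]
  regions <- make_region_set(annotation)
  dt <- merge(counts, regions, by = c("gene_id", "chrom", "region_type"))
  set.seed(as.integer(seed))
  tot <- dt$n_composite
  if (sum(tot) == 0L)
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), assay = character(),
                      score_mus = numeric(), score_cas = numeric()))
  idx <- rep(seq_len(nrow(dt)), tot)
  lo <- dt$start[idx]
  hi <- pmax(dt$start, dt$end - config$frag_len)[idx]
  start <- lo + floor(runif(length(idx)) * (hi - lo + 1L))
  # allele of each fragment within its row: first n_mus mus, then n_cas cas
  within <- sequence(tot)
  allele <- ifelse(within <= dt$n_mus[idx], "mus",
                   ifelse(within <= (dt$n_mus + dt$n_cas)[idx], "cas",
                          "neutral"))
  data.table(chrom = dt$chrom[idx],
             start = as.integer(start),
             end = as.integer(start + config$frag_len),
             assay = dt$assay[idx],
             score_mus = ifelse(allele == "mus", 60,
                                ifelse(allele == "cas", 50, 37)),
             score_cas = ifelse(allele == "cas", 60,
                                ifelse(allele == "mus", 50, 37)))[]
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper running [generate_annotation()],
#' [draw_allelic_states()] and [simulate_counts()], and deriving a composite
#' FPKM-like expression estimate (mean composite RNA count scaled so unit
#' value matches unit summed allelic expression).
#'
#' @param config a `generator_config`.
#' @param fragments if `TRUE`, also simulate fragment intervals (expensive
#'   at high depth; intended for small runs).
#' @return list with elements `config`, `annotation`, `truth`, `counts`,
#'   `fpkm` (data.table `gene_id, fpkm`) and optionally `fragments`.
#' @export
simulate_dataset <- function(config = generator_config(), fragments = FALSE) {
  validate_generator_config(config)
  annotation <- generate_annotation(config$n_genes, seed = config$seed)
  truth <- draw_allelic_states(config)
  counts <- simulate_counts(truth, config, annotation)
  rna <- counts[assay == RNA_ASSAY,
                .(fpkm = mean(n_composite) / (config$depth_per_assay / 2)),
                by = gene_id]
  out <- list(config = config, annotation = annotation, truth = truth,
              counts = counts, fpkm = rna[])
  if (isTRUE(fragments))
    out$fragments <- simulate_fragments(counts, annotation, config)
  out
}
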