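# shared fixture builders (everything generated in code; no files)

# a small, fast generator configuration
small_config <- function(n_genes = 400L, seed = 1L, ...) {
  generator_config(n_genes = n_genes, seed = seed, ...)
}

# a configuration whose truth has zero allelic skew everywhere
null_skew_config <- function(n_genes, seed) {
  generator_config(n_genes = n_genes, seed = seed,
                   p_same_type = 1, within_type_skew_sd = 0,
                   allele_noise_sd = 0, noise_sd = 0)
}

# hand-built 10-gene single-assay count table exercising every
# skew-calling class: untestable, fold-fail, FDR-fail, skewed
ten_gene_counts <- function() {
  data.table::data.table(
    assay = "K4me3",
    gene_id = sprintf("g%02d", 1:10),
    chrom = "chr1",
    region_type = "promoter",
    replicate = 1L,
    n_mus = c(10L, 20L, 30L,  5L, 60L, 45L, 18L, 16L,  0L, 8L),
    n_cas = c( 2L, 15L,  5L, 30L, 25L, 40L,  9L,  7L, 20L, 8L))[
      , n_composite := as.integer((n_mus + n_cas) * 2)][]
}

# expected class per fixture gene (derived from the calling rule)
ten_gene_classes <- c(g01 = "untestable", g02 = "fold_fail",
                      g03 = "skewed", g04 = "skewed", g05 = "skewed",
                      g06 = "fold_fail", g07 = "fold_fail",
                      g08 = "fdr_fail", g09 = "skewed", g10 = "fold_fail")
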