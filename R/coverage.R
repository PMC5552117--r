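## Allelic fragment assignment and region counting.
##
## Fragments are paired-read intervals (0-based half-open) carrying the
## alignment score of the read pair against each of the two reconstructed
## haplotype genomes.  A fragment with a strictly higher score against one
## haplotype is assigned to that allele; ties and single-scored fragments
## are neutral.  Counting is overlap >= 1 bp against promoter (TSS +/- 1 kb)
## and gene-body regions; a fragment overlapping both contributes to both.

#' Assign fragments to alleles from per-haplotype alignment scores
#'
#' `"mus"` when the mus-genome score is strictly higher, `"cas"` when the
#' cas-genome score is strictly higher, `"neutral"` on an exact tie or when
#' only one score is present (no basis for comparison).  A fragment with
#' both scores missing is unaligned and must be rejected upstream.
#'
#' @param score_mus,score_cas numeric vectors of alignment scores; `NA`
#'   marks a missing score.
#' @return character vector over `c("mus", "cas", "neutral")`.
#' @export
assign_allele <- function(score_mus, score_cas) {
  if (length(score_mus) != length(score_cas))
    .stopf("score vectors must have equal length")
  if (any(is.na(score_mus) & is.na(score_cas)))
    .stopf("fragment with both haplotype scores missing: unaligned records must be removed upstream")
  out <- rep("neutral", length(score_mus))
  both <- !is.na(score_mus) & !is.na(score_cas)
  out[both & score_mus > score_cas] <- "mus"
  out[both & score_cas > score_mus] <- "cas"
  out
}

#' Remove duplicate fragments
#'
#' Keeps at most one fragment per `(chrom, start, end, assay)` key,
#' mirroring standard ChIP-seq PCR-duplicate removal.  The allele label is
#' deliberately not part of the key: dedup runs before (or regardless of)
#' allelic assignment so duplicates cannot inflate one allele.  The result
#' is order-independent (sorted by key).
#'
#' @param fragments `data.table`/data.frame with columns `chrom, start,
#'   end, assay` (+ any others, retained from the first occurrence in key
#'   order).
#' @return deduplicated `data.table`.
#' @export
deduplicate <- function(fragments) {
  f <- as.data.table(fragments)
  if (nrow(f) == 0L) return(f)
  if (any(f$start >= f$end)) .stopf("fragment with start >= end")
  setorder(f, chrom, start, end, assay)
  unique(f, by = c("chrom", "start", "end", "assay"))[]
}

#' Count fragments over promoter and gene-body regions
#'
#' A fragment contributes to every region its interval overlaps by at least
#' 1 bp (half-open adjacency does not count); a fragment spanning both the
#' promoter and the body of a gene is counted in both.  Composite counts
#' include all fragments; `n_mus`/`n_cas`/`n_neutral` partition them by
#' allele label.  Fragments on chromosomes absent from the region set are
#' ignored with a warning.
#'
#' @param fragments fragment `data.table` with `chrom, start, end, assay`
#'   and either an `allele` column or `score_mus`/`score_cas` columns (in
#'   which case [assign_allele()] is applied).
#' @param regions region set from [make_region_set()].
#' @return `data.table` count table: `assay, gene_id, chrom, region_type,
#'   replicate, n_composite, n_mus, n_cas, n_neutral`, one row per gene x
#'   region x assay present in `regions` (zero rows included).
#' @export
count_fragments <- function(fragments, regions) {
  f <- as.data.table(fragments)
  r <- as.data.table(regions)
  if (!"allele" %in% names(f)) {
    if (!all(c("score_mus", "score_cas") %in% names(f)))
      .stopf("fragments need an 'allele' column or score_mus/score_cas")
    f[, allele := assign_allele(score_mus, score_cas)]
  }
  bad <- setdiff(unique(f$chrom), unique(r$chrom))
  if (length(bad)) {
    warning(sprintf("ignoring %d fragments on chromosomes absent from regions: %s",
                    sum(f$chrom %in% bad), paste(bad, collapse = ",")),
            call. = FALSE)
    f <- f[!chrom %in% bad]
  }
  grid <- r[, .(gene_id, chrom, region_type)]
  grid <- grid[, .(assay = unique(f$assay)), by = names(grid)]
  if (nrow(f) == 0L || nrow(grid) == 0L) {
    out <- grid[, .(assay, gene_id, chrom, region_type, replicate = 1L,
                    n_composite = 0L, n_mus = 0L, n_cas = 0L,
                    n_neutral = 0L)]
    return(out[])
  }
  # GRanges are 1-based closed; shift half-open starts by +1
  gf <- GRanges(f$chrom, IRanges(f$start + 1L, f$end))
  gr <- GRanges(r$chrom, IRanges(r$start + 1L, r$end))
  ov <- findOverlaps(gf, gr, minoverlap = 1L)
  hits <- data.table(fi = queryHits(ov), ri = subjectHits(ov))
  hits[, `:=`(assay = f$assay[fi], allele = f$allele[fi],
              gene_id = r$gene_id[ri], chrom = r$chrom[ri],
              region_type = r$region_type[ri])]
  tab <- hits[, .(n_composite = .N,
                  n_mus = sum(allele == "mus"),
                  n_cas = sum(allele == "cas")),
              by = .(assay, gene_id, chrom, region_type)]
  out <- merge(grid, tab, by = c("assay", "gene_id", "chrom", "region_type"),
               all.x = TRUE)
  for (col in c("n_composite", "n_mus", "n_cas"))
    out[is.na(get(col)), (col) := 0L]
  out[, `:=`(replicate = 1L, n_neutral = n_composite - n_mus - n_cas)]
  setorder(out, assay, gene_id, region_type)
  out[, .(assay, gene_id, chrom, region_type, replicate,
          n_composite, n_mus, n_cas, n_neutral)][]
}

#' Input-normalized densities
#'
#' Per gene x region and track (composite, mus, cas), the ratio of the ChIP
#' fragment density to the matched input density over the same region.
#' Because numerator and denominator share the region, the per-kb length
#' factor cancels and the density reduces to a count ratio.  Where the
#' matching input count is zero the density is `NA` (flagged missing, never
#' infinite).
#'
#' @param counts count table (ChIP assays) as from [simulate_counts()] or
#'   [count_fragments()].
#' @param input_counts count table rows for the matched input assay.
#' @param input_track which input track to normalize against:
#'   `"composite"` (default; allelic input tracks are typically too sparse)
#'   or `"matched"` to divide each track by the same-named input track.
#' @return `data.table`: `assay, gene_id, chrom, region_type,
#'   density_composite, density_mus, density_cas`.
#' @export
normalize_density <- function(counts, input_counts,
                              input_track = c("composite", "matched")) {
  input_track <- match.arg(input_track)
  cnt <- as.data.table(counts)[assay != INPUT_ASSAY]
  inp <- as.data.table(input_counts)
  if ("assay" %in% names(inp) && INPUT_ASSAY %in% inp$assay)
    inp <- inp[assay == INPUT_ASSAY]
  inp <- inp[, .(gene_id, region_type, i_composite = n_composite,
                 i_mus = n_mus, i_cas = n_cas)]
  dt <- merge(cnt, inp, by = c("gene_id", "region_type"))
  if (nrow(dt) < nrow(cnt))
    .stopf("input table lacks %d gene x region keys present in counts",
           nrow(cnt) - nrow(dt))
  safe_ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  if (input_track == "composite") {
    dt[, `:=`(density_composite = safe_ratio(n_composite, i_composite),
              density_mus = safe_ratio(n_mus, i_composite),
              density_cas = safe_ratio(n_cas, i_composite))]
  } else {
    dt[, `:=`(density_composite = safe_ratio(n_composite, i_composite),
              density_mus = safe_ratio(n_mus, i_mus),
              density_cas = safe_ratio(n_cas, i_cas))]
  }
  setorder(dt, assay, gene_id, region_type)
  dt[, .(assay, gene_id, chrom, region_type, n_composite, n_mus, n_cas,
         density_composite, density_mus, density_cas)][]
}

#' Inferred allelic density
#'
#' Partitions a composite density between the alleles in proportion to the
#' observed mus:cas allelic read counts, so the allelic densities sum to
#' the composite exactly.  Undefined (`NA`) when no allelic reads exist.
#'
#' @param composite_density numeric vector of composite densities.
#' @param n_mus,n_cas allelic read counts (same length).
#' @return `data.table` with columns `mus`, `cas`.
#' @export
inferred_allelic_density <- function(composite_density, n_mus, n_cas) {
  if (any(n_mus < 0 | n_cas < 0, na.rm = TRUE)) .stopf("negative counts")
  tot <- n_mus + n_cas
  p <- ifelse(!is.na(tot) & tot > 0, n_mus / tot, NA_real_)
  mus <- composite_density * p
  # complement, not composite * (1 - p): keeps the sum exact in floating point
  data.table(mus = mus, cas = composite_density - mus)
}

#' Per-chromosome allelic balance diagnostic
#'
#' Sums allelic counts over all genes and regions per chromosome (and
#' assay) and reports the log2 mus:cas ratio — a screen for large-scale
#' chromosomal aberrations (aneuploidy, large deletions/amplifications),
#' which would unbalance a whole chromosome.
#'
#' @param counts a count table.
#' @param pseudocount added to both alleles in the log ratio when either
#'   count is zero.
#' @param by_assay if `TRUE`, stratify by assay as well.
#' @return `data.table`: `(assay,) chrom, n_mus, n_cas, log2_ratio`.
#' @export
chromosome_balance <- function(counts, pseudocount = 0.5, by_assay = FALSE) {
  cnt <- as.data.table(counts)
  if (nrow(cnt) == 0L)
    return(data.table(chrom = character(), n_mus = integer(),
                      n_cas = integer(), log2_ratio = numeric()))
  keys <- if (by_assay) c("assay", "chrom") else "chrom"
  out <- cnt[, .(n_mus = sum(n_mus), n_cas = sum(n_cas)), by = keys]
  out[, log2_ratio := log2_skew(n_mus, n_cas, pseudocount)]
  setorder(out, chrom)
  out[]
}
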