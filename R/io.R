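## Readers and writers for the pipeline's plain-text interchange formats:
## tab-separated tables with a mandatory header and '#' comment lines,
## strictly 0-based half-open BED, a flat "key: value" run-configuration
## format, and a JSON run manifest with content hashes.

.read_tsv <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  fread(path, sep = "\t", header = TRUE, na.strings = c("NA", ""))
}

.write_tsv <- function(dt, path) {
  fwrite(as.data.table(dt), path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read an allelic count table
#'
#' Tab-separated with header; `#`-prefixed lines are comments.  Required
#' columns: `gene_id, region_type, n_composite, n_mus, n_cas`; `assay`,
#' `chrom` and `replicate` are filled with defaults when absent.  Counts
#' must be non-negative integers with `n_mus + n_cas <= n_composite`;
#' violations are reported with their line number.
#'
#' @param path TSV path.
#' @return count `data.table`.
#' @export
read_count_table <- function(path) {
  dt <- .read_tsv(path)
  need <- c("gene_id", "region_type", "n_composite", "n_mus", "n_cas")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    .stopf("%s: missing required columns: %s", path,
           paste(miss, collapse = ", "))
  if (!"assay" %in% names(dt)) dt[, assay := NA_character_]
  if (!"chrom" %in% names(dt)) dt[, chrom := NA_character_]
  if (!"replicate" %in% names(dt)) dt[, replicate := 1L]
  if (nrow(dt)) {
    for (col in c("n_composite", "n_mus", "n_cas")) {
      v <- dt[[col]]
      bad <- which(is.na(v) | v < 0 | v != floor(v))
      if (length(bad))
        .stopf("%s line %d: column %s must be a non-negative integer",
               path, bad[1] + 1L, col)
    }
    bad <- which(dt$n_mus + dt$n_cas > dt$n_composite)
    if (length(bad))
      .stopf("%s line %d: n_mus + n_cas exceeds n_composite",
             path, bad[1] + 1L)
  }
  dt[]
}

#' Write an allelic count table
#'
#' @param table count table.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_count_table <- function(table, path) {
  dt <- as.data.table(table)
  if (nrow(dt) && any(dt$n_mus + dt$n_cas > dt$n_composite))
    .stopf("refusing to write table violating n_mus + n_cas <= n_composite")
  .write_tsv(dt, path)
}

#' Read a gene annotation table
#'
#' TSV with columns `gene_id, chrom, start, end, strand, tss` (0-based
#' half-open body; `tss` is a 0-based position).  A `tss_1based` column is
#' accepted instead of `tss` and converted.
#'
#' @param path TSV path.
#' @return annotation `data.table`.
#' @export
read_annotation <- function(path) {
  dt <- .read_tsv(path)
  if ("tss_1based" %in% names(dt) && !"tss" %in% names(dt))
    dt[, tss := as.integer(tss_1based) - 1L]
  need <- c("gene_id", "chrom", "start", "end", "strand", "tss")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    .stopf("%s: missing required columns: %s", path,
           paste(miss, collapse = ", "))
  if (nrow(dt) && any(dt$end <= dt$start))
    .stopf("%s: gene with end <= start", path)
  dt[]
}

#' @rdname read_annotation
#' @param annotation annotation table.
#' @export
write_annotation <- function(annotation, path) .write_tsv(annotation, path)

#' Write fragments as extended BED
#'
#' Columns: chrom, start, end, name (assay label), score (0), strand (.),
#' then `score_mus` and `score_cas` in columns 7-8.  Coordinates are
#' 0-based half-open, BED-native.
#'
#' @param fragments fragment table with `chrom, start, end, assay,
#'   score_mus, score_cas`.
#' @param path output BED path.
#' @return the path, invisibly.
#' @export
write_fragment_bed <- function(fragments, path) {
  f <- as.data.table(fragments)
  bed <- f[, .(chrom, start, end, name = assay, score = 0L, strand = ".",
               score_mus, score_cas)]
  fwrite(bed, path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a fragment BED
#'
#' Accepts the extended 8-column form written by [write_fragment_bed()]
#' (per-haplotype scores in columns 7-8, assay in column 4) or a
#' pre-assigned 4+ column BED whose column 4 holds an allele label in
#' `mus/cas/neutral` (assay then supplied via `assay`).
#'
#' @param path BED path.
#' @param assay assay label for pre-assigned BEDs lacking one.
#' @return fragment `data.table` with either score columns or an `allele`
#'   column.
#' @export
read_fragment_bed <- function(path, assay = NULL) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  dt <- fread(path, sep = "\t", header = FALSE)
  if (ncol(dt) < 4L)
    .stopf("%s: BED needs >= 4 columns (chrom, start, end, name)", path)
  if (nrow(dt) && any(dt[[3]] <= dt[[2]]))
    .stopf("%s line %d: end <= start",
           path, which(dt[[3]] <= dt[[2]])[1])
  out <- data.table(chrom = as.character(dt[[1]]),
                    start = as.integer(dt[[2]]),
                    end = as.integer(dt[[3]]))
  if (ncol(dt) >= 8L && is.numeric(dt[[7]]) && is.numeric(dt[[8]])) {
    out[, `:=`(assay = as.character(dt[[4]]),
               score_mus = as.numeric(dt[[7]]),
               score_cas = as.numeric(dt[[8]]))]
  } else if (all(dt[[4]] %in% c("mus", "cas", "neutral"))) {
    out[, `:=`(allele = as.character(dt[[4]]),
               assay = if (is.null(assay)) "unknown" else assay)]
  } else {
    .stopf("%s: column 4 is neither an assay with scores in cols 7-8 nor an allele label", path)
  }
  out[]
}

#' Serialize / parse a flat run configuration
#'
#' "key: value" lines; vectors are comma-joined with element names as
#' `name=value` pairs.  Parsing restores numeric scalars and named numeric
#' vectors, so a write/read round trip is the identity on such configs.
#'
#' @param config named list of scalars and named numeric vectors.
#' @param path output path.
#' @return the path ([write_run_config()]) or the restored list
#'   ([read_run_config()]).
#' @export
write_run_config <- function(config, path) {
  fmt_num <- function(v) format(v, digits = 17, trim = TRUE,
                                scientific = FALSE)
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    val <- if (is.numeric(v) && !is.null(names(v)))
      paste(sprintf("%s=%s", names(v), fmt_num(v)), collapse = ",")
    else paste(if (is.numeric(v)) fmt_num(v) else as.character(v),
               collapse = ",")
    sprintf("%s: %s", k, val)
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  out <- list()
  for (ln in lines) {
    sep <- regexpr(": ", ln, fixed = TRUE)
    if (sep < 0) .stopf("%s: malformed config line: %s", path, ln)
    k <- substr(ln, 1L, sep - 1L)
    val <- substr(ln, sep + 2L, nchar(ln))
    parts <- strsplit(val, ",", fixed = TRUE)[[1]]
    if (all(grepl("=", parts, fixed = TRUE))) {
      kv <- strsplit(parts, "=", fixed = TRUE)
      v <- as.numeric(vapply(kv, `[`, "", 2L))
      names(v) <- vapply(kv, `[`, "", 1L)
      out[[k]] <- v
    } else {
      num <- suppressWarnings(as.numeric(parts))
      out[[k]] <- if (!anyNA(num)) num else parts
    }
  }
  out
}

#' Append a stage entry to a run manifest
#'
#' The manifest (`manifest.json` in the output directory) records, per
#' pipeline stage: the stage name, package version, the configuration
#' used, and MD5 content hashes of the stage's input and output files.
#' Re-running a stage appends a new entry.
#'
#' @param dir output directory.
#' @param stage stage name.
#' @param inputs,outputs character vectors of file paths to hash.
#' @param config list of stage parameters to record.
#' @return the manifest path, invisibly.
#' @export
write_manifest <- function(dir, stage, inputs = character(),
                           outputs = character(), config = list()) {
  path <- file.path(dir, "manifest.json")
  hash <- function(files) {
    files <- files[file.exists(files)]
    as.list(setNames(unname(tools::md5sum(files)), basename(files)))
  }
  entry <- list(stage = stage,
                package = "aschip",
                version = as.character(utils::packageVersion("aschip")),
                config = config,
                inputs = hash(inputs),
                outputs = hash(outputs))
  manifest <- if (file.exists(path))
    jsonlite::fromJSON(path, simplifyVector = FALSE) else list()
  manifest[[length(manifest) + 1L]] <- entry
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a run manifest
#'
#' @param dir directory containing `manifest.json`.
#' @return list of stage entries.
#' @export
read_manifest <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path)) .stopf("no manifest.json in %s", dir)
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}
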