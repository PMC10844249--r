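# Reading, validating, and writing the tabular formats: DE summary tables,
# ortholog maps, GMT gene-set collections, and flat result reports.
# Conventions: TAB delimiter, "." decimal point, mandatory header, UTF-8, LF.

#' Construct a differential-expression summary table
#'
#' A `diff_table` holds one dataset's per-feature differential summary on one
#' molecular layer: log2 fold change, raw P, and (usually) adjusted P.
#' Feature ids are case-sensitive and must be unique; records with non-finite
#' log2 fold change are rejected here (readers drop them with a logged count
#' before calling this constructor).
#'
#' @param feature_id character vector of unique feature identifiers.
#' @param log2fc numeric log2 fold changes, all finite.
#' @param p_raw raw P-values in \[0, 1\] (NA allowed).
#' @param p_adj adjusted P-values in \[0, 1\], or `NULL` when
#'   `unadjusted = TRUE`.
#' @param dataset_label label naming the dataset (used in reports).
#' @param layer `"mrna"` or `"protein"`.
#' @param unadjusted set `TRUE` to allow a missing `p_adj` column; downstream
#'   operations that need adjusted P then fail loudly instead of propagating
#'   `NA`.
#' @return An object of class `diff_table`: a data.frame with columns
#'   `feature_id`, `log2fc`, `p_raw`, `p_adj` and attributes `dataset_label`,
#'   `layer`, `unadjusted`.
#' @export
diff_table <- function(feature_id, log2fc, p_raw, p_adj = NULL,
                       dataset_label = "dataset", layer = c("mrna", "protein"),
                       unadjusted = is.null(p_adj)) {
  layer <- match.arg(layer)
  feature_id <- as.character(feature_id)
  n <- length(feature_id)
  if (length(log2fc) != n || length(p_raw) != n)
    validation_error("feature_id, log2fc and p_raw must have equal length")
  if (anyDuplicated(feature_id)) {
    dups <- unique(feature_id[duplicated(feature_id)])
    validation_error(sprintf(
      "duplicated feature_id (%d): %s", length(dups),
      paste(head(dups, 10L), collapse = ", ")))
  }
  if (any(!is.finite(log2fc)))
    validation_error("log2fc must be finite for every record")
  chk_p <- function(p, nm) {
    if (any(p < 0 | p > 1, na.rm = TRUE))
      validation_error(sprintf("%s values outside [0, 1]", nm))
    as.numeric(p)
  }
  p_raw <- chk_p(p_raw, "p_raw")
  if (is.null(p_adj)) {
    if (!unadjusted)
      config_error("p_adj missing but table not flagged 'unadjusted'")
    p_adj <- rep(NA_real_, n)
  } else {
    if (length(p_adj) != n) validation_error("p_adj length mismatch")
    p_adj <- chk_p(p_adj, "p_adj")
  }
  out <- data.frame(feature_id = feature_id, log2fc = as.numeric(log2fc),
                    p_raw = p_raw, p_adj = p_adj, stringsAsFactors = FALSE)
  structure(out, class = c("diff_table", "data.frame"),
            dataset_label = dataset_label, layer = layer,
            unadjusted = isTRUE(unadjusted))
}

#' @export
print.diff_table <- function(x, ...) {
  cat(sprintf("diff_table '%s' (%s layer): %d features%s\n",
              attr(x, "dataset_label"), attr(x, "layer"), nrow(x),
              if (attr(x, "unadjusted")) ", unadjusted" else ""))
  print.data.frame(head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Read a differential-expression table from delimited text
#'
#' Expects TAB-delimited text with a header.  Column names are remappable via
#' `column_spec`; rows whose log2 fold change is missing or non-finite are
#' dropped with a logged count.
#'
#' @param path path to a TSV file.
#' @param column_spec named list mapping the canonical names `feature_id`,
#'   `log2fc`, `p_raw`, `p_adj` to the file's column names.
#' @param dataset_label,layer,unadjusted passed to [diff_table()]; when
#'   `unadjusted = TRUE` the `p_adj` entry of `column_spec` is ignored.
#' @return A validated [diff_table()].
#' @export
read_diff_table <- function(path,
                            column_spec = list(feature_id = "feature_id",
                                               log2fc = "log2fc",
                                               p_raw = "p_raw",
                                               p_adj = "p_adj"),
                            dataset_label = basename(path),
                            layer = c("mrna", "protein"),
                            unadjusted = FALSE) {
  layer <- match.arg(layer)
  if (!file.exists(path)) io_error(sprintf("file not found: %s", path))
  raw <- read.delim(path, header = TRUE, sep = "\t", dec = ".",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c("NA", ""))
  need <- c("feature_id", "log2fc", "p_raw", if (!unadjusted) "p_adj")
  for (canon in need) {
    col <- column_spec[[canon]] %||% canon
    if (!col %in% names(raw))
      config_error(sprintf("required column '%s' (for %s) absent from %s",
                           col, canon, path))
  }
  get <- function(canon) raw[[column_spec[[canon]] %||% canon]]
  lfc <- suppressWarnings(as.numeric(get("log2fc")))
  keep <- is.finite(lfc)
  n_drop <- sum(!keep)
  os_log("read %d rows from %s; dropped %d with missing/non-finite log2fc; kept %d",
         nrow(raw), path, n_drop, sum(keep))
  if (!any(keep))
    validation_error(sprintf("no usable records in %s after filtering", path))
  diff_table(
    feature_id = get("feature_id")[keep],
    log2fc = lfc[keep],
    p_raw = suppressWarnings(as.numeric(get("p_raw")))[keep],
    p_adj = if (unadjusted) NULL else
      suppressWarnings(as.numeric(get("p_adj")))[keep],
    dataset_label = dataset_label, layer = layer, unadjusted = unadjusted)
}

#' Write a diff_table to TSV
#' @param x a [diff_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_diff_table <- function(x, path) {
  stopifnot(inherits(x, "diff_table"))
  write_tsv_deterministic(as.data.frame(x), path)
}

#' Construct an ortholog map
#'
#' Source-to-target feature-id pairs (e.g. mouse to human).  Duplicate
#' (source, target) pairs are invalid; one-to-many relations are permitted
#' here and resolved at pairing time (see [pair_by_orthology()]).
#'
#' @param source_id,target_id character vectors of equal length.
#' @return An object of class `ortholog_map` (a two-column data.frame).
#' @export
ortholog_map <- function(source_id, target_id) {
  source_id <- as.character(source_id); target_id <- as.character(target_id)
  if (length(source_id) != length(target_id))
    validation_error("source_id and target_id must have equal length")
  key <- paste(source_id, target_id, sep = "\r")
  if (anyDuplicated(key))
    validation_error("duplicated (source_id, target_id) pairs in ortholog map")
  structure(data.frame(source_id = source_id, target_id = target_id,
                       stringsAsFactors = FALSE),
            class = c("ortholog_map", "data.frame"))
}

#' Read an ortholog map from a two-column TSV
#'
#' Header must be `source_id<TAB>target_id`.
#'
#' @param path path to the TSV.
#' @return An [ortholog_map()].
#' @export
read_ortholog_map <- function(path) {
  if (!file.exists(path)) io_error(sprintf("file not found: %s", path))
  raw <- read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("source_id", "target_id"))
    if (!col %in% names(raw))
      config_error(sprintf("ortholog map %s lacks column '%s'", path, col))
  ortholog_map(raw$source_id, raw$target_id)
}

#' Write an ortholog map to TSV
#' @param x an [ortholog_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ortholog_map <- function(x, path) {
  stopifnot(inherits(x, "ortholog_map"))
  write_tsv_deterministic(as.data.frame(x), path)
}

#' Construct a gene-set collection
#'
#' @param sets named list; each element is a character vector of member
#'   feature ids (non-empty, de-duplicated on construction).
#' @param descriptions optional character vector parallel to `sets`.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (length(sets) == 0L) validation_error("gene-set collection is empty")
  if (is.null(names(sets)) || anyDuplicated(names(sets)) ||
      any(!nzchar(names(sets))))
    validation_error("set term_ids must be unique non-empty names")
  sets <- lapply(sets, function(m) unique(as.character(m)))
  if (any(lengths(sets) == 0L))
    validation_error("every gene set must have at least one member")
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  if (length(descriptions) != length(sets))
    validation_error("descriptions length mismatch")
  structure(list(sets = sets,
                 descriptions = setNames(as.character(descriptions),
                                         names(sets))),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d terms, member counts %d-%d\n",
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read gene sets from a GMT file
#'
#' GMT dialect: one term per line, `term_id<TAB>description<TAB>member...`.
#' Lines with fewer than three fields are rejected with the offending line
#' number.
#'
#' @param path path to a GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) io_error(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    parse_error(sprintf("malformed GMT line %d in %s (need term, description, >=1 member)",
                        bad[1L], path))
  gene_set_collection(
    sets = setNames(lapply(fields, function(f) f[-(1:2)]),
                    vapply(fields, `[[`, "", 1L)),
    descriptions = vapply(fields, `[[`, "", 2L))
}

#' Write gene sets to a GMT file
#' @param x a [gene_set_collection()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(x, path) {
  stopifnot(inherits(x, "gene_set_collection"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  con <- file(path, open = "wb"); on.exit(close(con))
  lines <- vapply(names(x$sets), function(tid)
    paste(c(tid, x$descriptions[[tid]], x$sets[[tid]]), collapse = "\t"), "")
  writeLines(unname(lines), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Write a flat result report to TSV
#'
#' Rows are sorted by the primary key column(s) and doubles rendered with
#' full (round-trip) precision, so re-running a pipeline with identical
#' inputs yields byte-identical files.
#'
#' @param result a data.frame (or object coercible to one).
#' @param path output path.
#' @param key column name(s) to sort by; defaults to the first column.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, key = NULL) {
  df <- as.data.frame(result, stringsAsFactors = FALSE)
  if (nrow(df)) {
    key <- key %||% names(df)[1L]
    df <- df[do.call(order, df[key]), , drop = FALSE]
    rownames(df) <- NULL
  }
  write_tsv_deterministic(df, path)
}
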