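# Aligning two diff_tables into paired fold-change vectors, either through an
# ortholog map (cross-species) or by shared feature ids (mRNA vs protein of
# the same study).

#' Construct a paired_changes object
#'
#' Aligned fold-change vectors for two tables; each row is one matched
#' feature pair with both tables' log2FC and adjusted P.
#'
#' @param id_x,id_y character ids in the two tables (pairs must be unique).
#' @param x,y finite numeric log2 fold changes.
#' @param p_adj_x,p_adj_y adjusted P-values (NA allowed).
#' @param pair_labels length-2 character: the two dataset labels.
#' @return An object of class `paired_changes` (a data.frame, rows ordered
#'   lexicographically by `(id_x, id_y)`).
#' @export
paired_changes <- function(id_x, id_y, x, y, p_adj_x = NA_real_,
                           p_adj_y = NA_real_,
                           pair_labels = c("x", "y")) {
  n <- length(id_x)
  if (n < 1L) validation_error("paired_changes needs at least one row")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    validation_error("all paired log2FC values must be finite")
  df <- data.frame(id_x = as.character(id_x), id_y = as.character(id_y),
                   x = as.numeric(x), y = as.numeric(y),
                   p_adj_x = rep_len(as.numeric(p_adj_x), n),
                   p_adj_y = rep_len(as.numeric(p_adj_y), n),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(paste(df$id_x, df$id_y, sep = "\r")))
    validation_error("duplicated (id_x, id_y) pairs")
  df <- df[order(df$id_x, df$id_y, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("paired_changes", "data.frame"),
            pair_labels = as.character(pair_labels))
}

#' @export
print.paired_changes <- function(x, ...) {
  lab <- attr(x, "pair_labels")
  cat(sprintf("paired_changes %s vs %s: n = %d\n", lab[1L], lab[2L], nrow(x)))
  print.data.frame(head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

# Drop every map pair whose source or target id occurs more than once.
resolve_one_to_one <- function(map) {
  keep <- !(map$source_id %in% map$source_id[duplicated(map$source_id)]) &
          !(map$target_id %in% map$target_id[duplicated(map$target_id)])
  map[keep, , drop = FALSE]
}

#' Pair two tables through an ortholog map
#'
#' Joins `table_x` (ids on the map's source side) to `table_y` (target side).
#' Under the default `one_to_one_only` policy any source or target id that
#' appears in more than one map pair is discarded before joining, because
#' ambiguous homology would duplicate fold-change values and inflate the
#' apparent sample size of downstream correlations.  `first_match` instead
#' keeps, for each source id, the first map row (file order) whose target is
#' unique among the kept rows.
#'
#' @param table_x,table_y [diff_table()] objects.
#' @param map an [ortholog_map()] with `table_x` ids as `source_id`.
#' @param policy `"one_to_one_only"` (default) or `"first_match"`.
#' @return A [paired_changes()] with `x` from `table_x`, `y` from `table_y`.
#' @export
pair_by_orthology <- function(table_x, table_y, map,
                              policy = c("one_to_one_only", "first_match")) {
  policy <- match.arg(policy)
  stopifnot(inherits(table_x, "diff_table"), inherits(table_y, "diff_table"),
            inherits(map, "ortholog_map"))
  if (nrow(map) == 0L) validation_error("ortholog map is empty")
  n_map <- nrow(map)
  res <- if (policy == "one_to_one_only") resolve_one_to_one(map) else {
    m <- map[!duplicated(map$source_id), , drop = FALSE]
    m[!duplicated(m$target_id), , drop = FALSE]
  }
  n_ambig <- n_map - nrow(res)
  ix <- match(res$source_id, table_x$feature_id)
  iy <- match(res$target_id, table_y$feature_id)
  ok <- !is.na(ix) & !is.na(iy)
  os_log("ortholog pairing: %d map pairs, %d dropped as ambiguous (%s), %d matched in both tables",
         n_map, n_ambig, policy, sum(ok))
  if (!any(ok)) validation_error("no ortholog pairs matched")
  ix <- ix[ok]; iy <- iy[ok]
  paired_changes(table_x$feature_id[ix], table_y$feature_id[iy],
                 table_x$log2fc[ix], table_y$log2fc[iy],
                 table_x$p_adj[ix], table_y$p_adj[iy],
                 pair_labels = c(attr(table_x, "dataset_label"),
                                 attr(table_y, "dataset_label")))
}

#' Pair two tables sharing an id namespace
#'
#' Inner join on `feature_id`; used for same-study mRNA vs protein tables.
#'
#' @param table_x,table_y [diff_table()] objects with comparable ids.
#' @return A [paired_changes()] sorted by feature id.
#' @export
pair_by_identity <- function(table_x, table_y) {
  stopifnot(inherits(table_x, "diff_table"), inherits(table_y, "diff_table"))
  shared <- intersect(table_x$feature_id, table_y$feature_id)
  os_log("identity pairing: %d and %d features, %d shared",
         nrow(table_x), nrow(table_y), length(shared))
  if (length(shared) == 0L)
    validation_error("no shared feature ids between tables")
  ix <- match(shared, table_x$feature_id)
  iy <- match(shared, table_y$feature_id)
  paired_changes(shared, shared,
                 table_x$log2fc[ix], table_y$log2fc[iy],
                 table_x$p_adj[ix], table_y$p_adj[iy],
                 pair_labels = c(attr(table_x, "dataset_label"),
                                 attr(table_y, "dataset_label")))
}
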