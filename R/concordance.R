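# Global, DEG-overlap, and gene-set-restricted Pearson concordance between
# paired fold-change vectors, with Fisher r-to-z comparison of correlations.

#' Pearson correlation of paired fold changes
#'
#' Two-sided P from the t statistic `r * sqrt((n - 2) / (1 - r^2))` on
#' `n - 2` degrees of freedom.
#'
#' @param pairs a [paired_changes()] with `n >= 4` and non-degenerate
#'   variance in both vectors.
#' @param subset_label label recorded in the result (default `"global"`).
#' @return A `correlation_result`: list with `r`, `n`, `p`, `subset_label`.
#' @export
pearson_cor <- function(pairs, subset_label = "global") {
  stopifnot(inherits(pairs, "paired_changes"))
  n <- nrow(pairs)
  if (n < 4L) validation_error(sprintf("need n >= 4 pairs, got %d", n))
  x <- pairs$x; y <- pairs$y
  if (var(x) <= 0 || var(y) <= 0)
    degenerate_error("zero variance in a fold-change vector")
  r <- cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tt), df = n - 2)
  }
  structure(list(r = r, n = n, p = p, subset_label = subset_label),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("correlation [%s]: r = %.4f, n = %d, p = %.3g\n",
              x$subset_label, x$r, x$n, x$p))
  invisible(x)
}

#' Compare two Pearson correlations (Fisher r-to-z)
#'
#' Variance-stabilizes both coefficients with `atanh` and tests their
#' difference as for two independent samples:
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, two-sided
#' normal P.  When both correlations involve the same reference dataset the
#' independence assumption is violated; a warning is logged but the test is
#' still the one reported (it is the field's standard procedure).
#'
#' @param c1,c2 `correlation_result` objects (or lists with `r`, `n`, and
#'   optionally `subset_label`).
#' @param shared_reference logical; set `TRUE` to log the non-independence
#'   caveat.
#' @return A `correlation_comparison`: list with `label_1`, `label_2`, `r1`,
#'   `r2`, `n1`, `n2`, `z`, `p`.
#' @export
compare_correlations <- function(c1, c2, shared_reference = FALSE) {
  r1 <- c1$r; r2 <- c2$r; n1 <- c1$n; n2 <- c2$n
  for (nm in c("r1", "r2")) {
    r <- get(nm)
    stopifnot_scalar_number(r, nm, lower = -1, upper = 1)
    if (abs(r) >= 1)
      validation_error(sprintf("|%s| = 1: atanh diverges", nm))
  }
  if (n1 <= 3 || n2 <= 3)
    validation_error("both sample sizes must exceed 3")
  if (isTRUE(shared_reference))
    os_log("note: correlations share a reference dataset; r-to-z assumes independence")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p <- 2 * pnorm(-abs(z))
  structure(list(label_1 = c1$subset_label %||% "c1",
                 label_2 = c2$subset_label %||% "c2",
                 r1 = r1, r2 = r2, n1 = n1, n2 = n2, z = z, p = p),
            class = "correlation_comparison")
}

#' @export
print.correlation_comparison <- function(x, ...) {
  cat(sprintf("r-to-z: %s (r=%.3f, n=%d) vs %s (r=%.3f, n=%d): z = %.3f, p = %.3g\n",
              x$label_1, x$r1, x$n1, x$label_2, x$r2, x$n2, x$z, x$p))
  invisible(x)
}

#' Classify differentially expressed features
#'
#' Strict thresholds, matching the usual DE convention: up-regulated means
#' `log2fc > lfc_cut` and `p_adj < p_cut`; down-regulated means
#' `log2fc < -lfc_cut` and `p_adj < p_cut`.  A feature sitting exactly on a
#' cut belongs to neither set.
#'
#' @param table a [diff_table()] carrying adjusted P-values.
#' @param lfc_cut absolute log2 fold-change threshold (default 1).
#' @param p_cut adjusted-P threshold (default 0.05).
#' @return A `deg_sets` object: list with character vectors `up` and `down`
#'   and the `thresholds` used.
#' @export
classify_deg <- function(table, lfc_cut = 1, p_cut = 0.05) {
  stopifnot(inherits(table, "diff_table"))
  if (attr(table, "unadjusted") || all(is.na(table$p_adj)))
    config_error("classify_deg requires adjusted P-values (table is unadjusted)")
  sig <- !is.na(table$p_adj) & table$p_adj < p_cut
  structure(list(up = table$feature_id[sig & table$log2fc > lfc_cut],
                 down = table$feature_id[sig & table$log2fc < -lfc_cut],
                 thresholds = c(lfc_cut = lfc_cut, p_cut = p_cut)),
            class = "deg_sets")
}

#' @export
print.deg_sets <- function(x, ...) {
  cat(sprintf("deg_sets: %d up, %d down (|log2FC| > %g, p_adj < %g)\n",
              length(x$up), length(x$down),
              x$thresholds[["lfc_cut"]], x$thresholds[["p_cut"]]))
  invisible(x)
}

#' Venn-style overlap of DEG sets across two datasets
#'
#' Maps dataset A's ids through the (one-to-one-resolved) ortholog map into
#' B's namespace, then counts exclusive and shared members per direction.
#'
#' @param sets_a,sets_b `deg_sets` from [classify_deg()].
#' @param map an [ortholog_map()] (A ids as source, B ids as target), or
#'   `NULL` when the two datasets already share a namespace.
#' @return data.frame with one row per direction (`up`, `down`) and counts
#'   `a_only`, `shared`, `b_only`.
#' @export
deg_overlap <- function(sets_a, sets_b, map = NULL) {
  stopifnot(inherits(sets_a, "deg_sets"), inherits(sets_b, "deg_sets"))
  translate <- function(ids) {
    if (is.null(map)) return(ids)
    m <- resolve_one_to_one(map)
    m$target_id[match(ids, m$source_id)][!is.na(match(ids, m$source_id))]
  }
  one <- function(a, b) {
    a2 <- translate(a)
    shared <- intersect(a2, b)
    c(a_only = length(setdiff(a2, b)), shared = length(shared),
      b_only = length(setdiff(b, a2)))
  }
  up <- one(sets_a$up, sets_b$up)
  down <- one(sets_a$down, sets_b$down)
  data.frame(direction = c("up", "down"),
             a_only = c(up[["a_only"]], down[["a_only"]]),
             shared = c(up[["shared"]], down[["shared"]]),
             b_only = c(up[["b_only"]], down[["b_only"]]),
             stringsAsFactors = FALSE)
}

#' Correlation restricted to a feature subset
#'
#' Recomputes the Pearson correlation using only rows whose id (on the chosen
#' side) belongs to `member_set` -- e.g. only genes annotated to enriched
#' protease-activity GO terms.  With `member_set` covering every row the
#' result is bit-identical to [pearson_cor()] on the full object.
#'
#' @param pairs a [paired_changes()].
#' @param member_set character vector of feature ids.
#' @param side which id column to match: `"x_ids"` or `"y_ids"`.
#' @param subset_label label recorded in the result.
#' @return A `correlation_result`.
#' @export
subset_correlation <- function(pairs, member_set, side = c("x_ids", "y_ids"),
                               subset_label = "subset") {
  side <- match.arg(side)
  stopifnot(inherits(pairs, "paired_changes"))
  ids <- if (side == "x_ids") pairs$id_x else pairs$id_y
  keep <- ids %in% member_set
  if (sum(keep) < 4L)
    validation_error(sprintf(
      "subset '%s' leaves %d rows; need >= 4", subset_label, sum(keep)))
  sub <- pairs[keep, , drop = FALSE]
  class(sub) <- class(pairs)
  attr(sub, "pair_labels") <- attr(pairs, "pair_labels")
  pearson_cor(sub, subset_label = subset_label)
}

#' Concordance of several datasets against one reference
#'
#' Pairs each candidate table with the reference (through `map` when the
#' namespaces differ), computes the global Pearson correlation (and one per
#' gene set if `subsets` is given), and compares every pair of global
#' correlations by Fisher r-to-z.  All comparisons share the reference
#' dataset, so the independence assumption of the r-to-z test is knowingly
#' violated; raw P is reported together with a Bonferroni column, with no
#' claim that either fixes the dependence.
#'
#' @param tables list of [diff_table()] objects (candidate datasets; ids on
#'   the map's source side).
#' @param reference a [diff_table()] (ids on the map's target side).
#' @param map an [ortholog_map()], or `NULL` for a shared namespace.
#' @param subsets optional [gene_set_collection()]; each term restricts the
#'   correlation via [subset_correlation()] (matching reference-side ids).
#' @param deg_only if `TRUE`, restrict each pairing to the union of DEGs of
#'   the two tables (thresholds `lfc_cut`, `padj_cut`) before correlating.
#' @param lfc_cut,padj_cut DEG thresholds used when `deg_only = TRUE`.
#' @return List with `correlations` (data.frame: label, subset, r, n, p) and
#'   `comparisons` (data.frame: label_1, label_2, r1, n1, r2, n2, z, p,
#'   p_bonferroni) and `results` (the underlying `correlation_result`s).
#' @export
concordance_matrix <- function(tables, reference, map = NULL, subsets = NULL,
                               deg_only = FALSE, lfc_cut = 1,
                               padj_cut = 0.05) {
  if (!is.list(tables) || length(tables) < 2L)
    validation_error("need at least two candidate tables")
  stopifnot(inherits(reference, "diff_table"))
  labels <- vapply(tables, function(t) attr(t, "dataset_label"), "")
  global <- list(); rows <- list()
  for (i in seq_along(tables)) {
    tab <- tables[[i]]
    pairs <- if (is.null(map)) pair_by_identity(tab, reference)
             else pair_by_orthology(tab, reference, map)
    if (isTRUE(deg_only)) {
      da <- classify_deg(tab, lfc_cut, padj_cut)
      db <- classify_deg(reference, lfc_cut, padj_cut)
      keep <- pairs$id_x %in% c(da$up, da$down) |
              pairs$id_y %in% c(db$up, db$down)
      if (sum(keep) < 4L)
        validation_error(sprintf("DEG-only restriction leaves %d pairs for %s",
                                 sum(keep), labels[i]))
      pairs <- structure(pairs[keep, , drop = FALSE],
                         class = class(pairs),
                         pair_labels = attr(pairs, "pair_labels"))
    }
    cr <- pearson_cor(pairs, subset_label = labels[i])
    global[[labels[i]]] <- cr
    rows[[length(rows) + 1L]] <- data.frame(
      label = labels[i], subset = "global", r = cr$r, n = cr$n, p = cr$p,
      stringsAsFactors = FALSE)
    if (!is.null(subsets)) {
      for (tid in names(subsets$sets)) {
        sc <- tryCatch(
          subset_correlation(pairs, subsets$sets[[tid]], side = "y_ids",
                             subset_label = tid),
          orthoscreen_validation_error = function(e) NULL)
        if (!is.null(sc))
          rows[[length(rows) + 1L]] <- data.frame(
            label = labels[i], subset = tid, r = sc$r, n = sc$n, p = sc$p,
            stringsAsFactors = FALSE)
      }
    }
  }
  cmp <- list()
  idx <- utils::combn(length(global), 2L)
  for (j in seq_len(ncol(idx))) {
    a <- global[[idx[1L, j]]]; b <- global[[idx[2L, j]]]
    cc <- compare_correlations(a, b, shared_reference = TRUE)
    cmp[[j]] <- data.frame(label_1 = cc$label_1, label_2 = cc$label_2,
                           r1 = cc$r1, n1 = cc$n1, r2 = cc$r2, n2 = cc$n2,
                           z = cc$z, p = cc$p, stringsAsFactors = FALSE)
  }
  comparisons <- do.call(rbind, cmp)
  comparisons$p_bonferroni <- pmin(1, comparisons$p * nrow(comparisons))
  list(correlations = do.call(rbind, rows), comparisons = comparisons,
       results = global)
}
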