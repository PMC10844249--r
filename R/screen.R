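# The four-stage transcriptome-proteome discordance screen.  Proteins whose
# fold change falls well below (or above) the level predicted from their
# transcript's fold change -- consistently across datasets, within enriched
# functional categories, and backed by significant differential expression --
# are nominated as candidate proteolysis targets.

#' Ordinary least squares fit of protein on mRNA fold change
#'
#' The regression direction is fixed: protein log2FC (`y`) on mRNA log2FC
#' (`x`), with intercept, because the protein level is the quantity being
#' "predicted" from the transcript.  `residual_sd` is `sqrt(RSS / (n - 2))`.
#'
#' @param pairs a [paired_changes()] with mRNA in `x`, protein in `y`,
#'   `n >= 4`.
#' @return A `regression_fit`: list with `slope`, `intercept`, `residual_sd`,
#'   `n`.
#' @export
fit_fc_regression <- function(pairs) {
  stopifnot(inherits(pairs, "paired_changes"))
  n <- nrow(pairs)
  if (n < 4L) validation_error(sprintf("need n >= 4 pairs, got %d", n))
  x <- pairs$x; y <- pairs$y
  sxx <- sum((x - mean(x))^2)
  if (sxx <= 0) degenerate_error("mRNA fold changes have zero variance")
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  rss <- sum((y - intercept - slope * x)^2)
  structure(list(slope = slope, intercept = intercept,
                 residual_sd = sqrt(rss / (n - 2)), n = n),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("fit: y = %.4f + %.4f x, residual sd = %.4f, n = %d\n",
              x$intercept, x$slope, x$residual_sd, x$n))
  invisible(x)
}

#' Standardized residuals of the fold-change regression
#'
#' The discordance statistic: each pair's raw residual (observed minus
#' predicted protein log2FC) divided by the fit's global residual standard
#' deviation.  Pairs below -1 have less protein than their transcript
#' predicts.  (Leverage-corrected, internally studentized residuals are
#' available via `studentized = TRUE`; the default matches a single global
#' +/-1 threshold on the regression plot.)
#'
#' @param pairs the [paired_changes()] the fit was computed from.
#' @param fit the corresponding `regression_fit`.
#' @param studentized divide by `residual_sd * sqrt(1 - h_i)` (leverage
#'   `h_i`) instead of the constant `residual_sd`.
#' @return Named numeric vector of standardized residuals, keyed by `id_x`.
#' @export
standardized_residuals <- function(pairs, fit, studentized = FALSE) {
  stopifnot(inherits(pairs, "paired_changes"), inherits(fit, "regression_fit"))
  if (nrow(pairs) != fit$n)
    validation_error("fit was not produced from these pairs (n mismatch)")
  if (fit$residual_sd <= 0)
    degenerate_error("residual sd is zero (collinear data); screening undefined")
  resid <- pairs$y - (fit$intercept + fit$slope * pairs$x)
  denom <- if (isTRUE(studentized)) {
    x <- pairs$x
    h <- 1 / fit$n + (x - mean(x))^2 / sum((x - mean(x))^2)
    fit$residual_sd * sqrt(1 - h)
  } else fit$residual_sd
  setNames(resid / denom, pairs$id_x)
}

#' Stage 1: select consistently discordant pairs across two datasets
#'
#' Keeps pairs whose standardized residual exceeds `cut` in both datasets
#' (direction `"up"`) or falls below `-cut` in both (direction `"down"`).
#' Mixed-sign pairs are excluded: the later per-direction enrichment step
#' treats up- and down-shifted proteins as separate biological groups, so a
#' pair must be discordant the same way in both datasets to be meaningful.
#'
#' @param res_a,res_b named standardized-residual vectors sharing a key
#'   space (see [standardized_residuals()]).
#' @param cut residual threshold (default 1).
#' @return data.frame with columns `key` and `direction` (`"up"`/`"down"`),
#'   sorted by key.
#' @export
stage1_select <- function(res_a, res_b, cut = 1) {
  keys <- intersect(names(res_a), names(res_b))
  if (length(keys) == 0L)
    validation_error("no shared keys between residual vectors")
  a <- res_a[keys]; b <- res_b[keys]
  up <- a > cut & b > cut
  down <- a < -cut & b < -cut
  out <- data.frame(key = c(keys[up], keys[down]),
                    direction = c(rep("up", sum(up)), rep("down", sum(down))),
                    stringsAsFactors = FALSE)
  out <- out[order(out$key, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stage 2: intersect candidate sets across dataset comparisons
#'
#' @param ... two or more character vectors (or stage-1 data.frames, whose
#'   `key` column is used) of candidate keys.
#' @return Character vector of keys present in every input, sorted.
#' @export
stage2_intersect <- function(...) {
  sets <- lapply(list(...), function(s) if (is.data.frame(s)) s$key else s)
  out <- sort(Reduce(intersect, sets))
  if (length(out) == 0L) os_log("stage 2: candidate intersection is empty")
  out
}

#' Stage 3: retain candidates belonging to enriched gene sets
#'
#' Over-representation is run separately on the up-shifted and down-shifted
#' candidate sets, against each provided gene-set collection (e.g. one for
#' biological process, one for cellular component).  A candidate survives iff
#' it belongs to at least one significantly enriched term from its own
#' direction's analysis, in any collection.
#'
#' @param up_candidates,down_candidates character vectors of candidate keys.
#' @param background character vector: the screening universe (all pairs
#'   tested).
#' @param sets a [gene_set_collection()] or a list of them (categories).
#' @param alpha Bonferroni-adjusted significance threshold (default 0.05).
#' @param mode over-representation statistic, see [overrep_p()].
#' @return List with `retained` (sorted character vector) and `enrichment`
#'   (data.frame of all tests, with `direction` and `category` columns).
#' @export
stage3_go_filter <- function(up_candidates, down_candidates, background,
                             sets, alpha = 0.05, mode = "ease") {
  if (inherits(sets, "gene_set_collection")) sets <- list(gene_sets = sets)
  if (!length(sets)) validation_error("stage 3 needs at least one gene-set collection")
  if (is.null(names(sets))) names(sets) <- paste0("category", seq_along(sets))
  retained <- character(); tabs <- list()
  for (direction in c("up", "down")) {
    cand <- if (direction == "up") up_candidates else down_candidates
    for (cat_name in names(sets)) {
      res <- enrich(cand, background, sets[[cat_name]], mode = mode,
                    alpha = alpha)
      if (nrow(res)) {
        res$direction <- direction; res$category <- cat_name
        tabs[[length(tabs) + 1L]] <- res
        sig_terms <- res$term_id[res$significant]
        for (tid in sig_terms)
          retained <- c(retained,
                        cand[cand %in% sets[[cat_name]]$sets[[tid]]])
      }
    }
  }
  list(retained = sort(unique(retained)),
       enrichment = if (length(tabs)) do.call(rbind, tabs) else
         data.frame())
}

#' Stage 4: final filter on differential-expression statistics
#'
#' Confirms that a candidate's shift is anchored in significant differential
#' expression.  Defaults mirror the usual DEG criteria: transcript adjusted
#' P below 0.05 and absolute transcript log2FC above 1 (strict
#' inequalities); the protein adjusted-P criterion is off by default.
#'
#' @param candidates data.frame with columns `key`, `mrna_lfc`,
#'   `mrna_p_adj`, and `prot_p_adj` (the last only needed when the protein
#'   criterion is enabled).
#' @param mrna_padj_max transcript adjusted-P threshold (strict `<`).
#' @param mrna_lfc_min_abs minimum absolute transcript log2FC (strict `>`).
#' @param prot_padj_max protein adjusted-P threshold, or `NULL` to disable.
#' @return The subset of `candidates` meeting every enabled criterion.
#' @export
stage4_final_filter <- function(candidates, mrna_padj_max = 0.05,
                                mrna_lfc_min_abs = 1, prot_padj_max = NULL) {
  need <- c("key", "mrna_lfc", "mrna_p_adj",
            if (!is.null(prot_padj_max)) "prot_p_adj")
  missing_cols <- setdiff(need, names(candidates))
  if (length(missing_cols))
    config_error(sprintf("stage 4 criteria reference absent statistics: %s",
                         paste(missing_cols, collapse = ", ")))
  keep <- !is.na(candidates$mrna_p_adj) &
    candidates$mrna_p_adj < mrna_padj_max &
    abs(candidates$mrna_lfc) > mrna_lfc_min_abs
  if (!is.null(prot_padj_max))
    keep <- keep & !is.na(candidates$prot_p_adj) &
      candidates$prot_p_adj < prot_padj_max
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full four-stage substrate screen
#'
#' For each (mRNA, protein) dataset pair the mRNA and protein tables are
#' joined on feature id, the protein-on-mRNA regression is fitted, and
#' standardized residuals are computed.  The first pair is the anchor
#' dataset; every other pair is compared against it:
#' \enumerate{
#'   \item pairs discordant beyond `residual_cut` in the same direction in
#'     the anchor and in the other dataset are selected;
#'   \item candidates are intersected across all comparisons;
#'   \item the surviving up- and down-shifted sets are tested for gene-set
#'     over-representation (per direction, per category) and only members of
#'     significantly enriched terms are retained;
#'   \item retained candidates must show significant differential expression
#'     of the anchor transcript (and optionally protein).
#' }
#' Keys live in the anchor dataset's id namespace; `maps` translates each
#' other dataset's ids into it.
#'
#' @param dataset_pairs named list; each element a list with components
#'   `mrna` and `protein`, both [diff_table()]s sharing an id namespace.
#'   The first element is the anchor dataset.
#' @param maps `NULL` (all datasets share the anchor's namespace), a single
#'   [ortholog_map()] applied to every non-anchor dataset, or a named list
#'   with one entry (map or `NULL`) per non-anchor dataset.  Maps are
#'   oriented anchor id -> other-dataset id and resolved one-to-one.
#' @param sets gene sets for stage 3: a [gene_set_collection()] or named
#'   list of collections.
#' @param residual_cut stage-1 threshold in residual-SD units (default 1).
#' @param alpha,mode stage-3 enrichment settings (see [stage3_go_filter()]).
#' @param mrna_padj_max,mrna_lfc_min_abs,prot_padj_max stage-4 criteria
#'   (see [stage4_final_filter()]).
#' @param studentized use leverage-corrected residuals (default `FALSE`).
#' @return A `screen_result`: list with
#' \describe{
#'   \item{rows}{data.frame over all anchor pairs: ids, fold changes,
#'     expected protein log2FC, standardized residual, monotone
#'     `pass_stage1..4` flags, and `direction`.}
#'   \item{fits}{named list of `regression_fit` per dataset.}
#'   \item{enrichment}{the stage-3 enrichment table.}
#'   \item{final}{character vector of final candidate keys.}
#'   \item{config_echo}{all thresholds used.}
#' }
#' @export
run_screen <- function(dataset_pairs, maps = NULL, sets,
                       residual_cut = 1, alpha = 0.05, mode = "ease",
                       mrna_padj_max = 0.05, mrna_lfc_min_abs = 1,
                       prot_padj_max = NULL, studentized = FALSE) {
  if (!is.list(dataset_pairs) || length(dataset_pairs) < 2L)
    validation_error("run_screen needs at least two (mRNA, protein) dataset pairs")
  if (is.null(names(dataset_pairs)))
    names(dataset_pairs) <- paste0("dataset", seq_along(dataset_pairs))
  ds_names <- names(dataset_pairs)
  others <- ds_names[-1L]
  if (inherits(maps, "ortholog_map"))
    maps <- setNames(rep(list(maps), length(others)), others)

  paired <- list(); fits <- list(); resid <- list()
  for (nm in ds_names) {
    dp <- dataset_pairs[[nm]]
    pr <- tryCatch(pair_by_identity(dp$mrna, dp$protein),
                   error = function(e) validation_error(
                     sprintf("pairing dataset '%s': %s", nm, conditionMessage(e))))
    ft <- fit_fc_regression(pr)
    paired[[nm]] <- pr; fits[[nm]] <- ft
    resid[[nm]] <- standardized_residuals(pr, ft, studentized = studentized)
    os_log("dataset %s: %d mRNA-protein pairs, slope %.3f, residual sd %.3f",
           nm, ft$n, ft$slope, ft$residual_sd)
  }

  anchor <- ds_names[1L]
  # Translate each non-anchor residual vector into the anchor id namespace.
  resid_in_anchor <- list()
  for (nm in others) {
    mp <- if (is.list(maps) && !inherits(maps, "ortholog_map"))
      maps[[nm]] else maps
    rv <- resid[[nm]]
    if (!is.null(mp)) {
      m <- resolve_one_to_one(mp)
      i <- match(names(rv), m$target_id)
      rv <- setNames(rv[!is.na(i)], m$source_id[i[!is.na(i)]])
    }
    resid_in_anchor[[nm]] <- rv
  }

  stage1 <- lapply(resid_in_anchor, function(rv)
    stage1_select(resid[[anchor]], rv, cut = residual_cut))
  s1_union <- unique(do.call(rbind, stage1))
  s1_keys <- sort(unique(s1_union$key))
  s2_keys <- do.call(stage2_intersect, stage1)
  os_log("stage 1: %d candidates (union), stage 2: %d shared",
         length(s1_keys), length(s2_keys))

  dir_of <- setNames(ifelse(resid[[anchor]] > 0, "up", "down"),
                     names(resid[[anchor]]))
  up2 <- s2_keys[dir_of[s2_keys] == "up"]
  down2 <- s2_keys[dir_of[s2_keys] == "down"]
  background <- names(resid[[anchor]])
  s3 <- stage3_go_filter(up2, down2, background, sets, alpha = alpha,
                         mode = mode)
  s3_keys <- s3$retained
  os_log("stage 3: %d retained in enriched terms", length(s3_keys))

  ap <- paired[[anchor]]
  mrna_padj <- setNames(ap$p_adj_x, ap$id_x)
  prot_padj <- setNames(ap$p_adj_y, ap$id_x)
  cand4 <- data.frame(key = s3_keys,
                      mrna_lfc = setNames(ap$x, ap$id_x)[s3_keys],
                      mrna_p_adj = mrna_padj[s3_keys],
                      prot_p_adj = prot_padj[s3_keys],
                      stringsAsFactors = FALSE)
  s4 <- stage4_final_filter(cand4, mrna_padj_max = mrna_padj_max,
                            mrna_lfc_min_abs = mrna_lfc_min_abs,
                            prot_padj_max = prot_padj_max)
  s4_keys <- sort(s4$key)
  os_log("stage 4: %d final candidates", length(s4_keys))

  fit_a <- fits[[anchor]]
  rows <- data.frame(
    id_x = ap$id_x, id_y = ap$id_y,
    mrna_lfc = ap$x, prot_lfc = ap$y,
    expected_prot_lfc = fit_a$intercept + fit_a$slope * ap$x,
    std_residual = unname(resid[[anchor]][ap$id_x]),
    pass_stage1 = ap$id_x %in% s1_keys,
    pass_stage2 = ap$id_x %in% s2_keys,
    pass_stage3 = ap$id_x %in% s3_keys,
    pass_stage4 = ap$id_x %in% s4_keys,
    direction = unname(dir_of[ap$id_x]),
    stringsAsFactors = FALSE)

  structure(list(rows = rows, fits = fits, enrichment = s3$enrichment,
                 final = s4_keys,
                 config_echo = list(residual_cut = residual_cut,
                                    alpha = alpha, mode = mode,
                                    mrna_padj_max = mrna_padj_max,
                                    mrna_lfc_min_abs = mrna_lfc_min_abs,
                                    prot_padj_max = prot_padj_max,
                                    studentized = studentized,
                                    anchor = anchor)),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf(
    "screen_result (anchor %s): %d pairs | stage1 %d, stage2 %d, stage3 %d, final %d\n",
    x$config_echo$anchor, nrow(x$rows), sum(x$rows$pass_stage1),
    sum(x$rows$pass_stage2), sum(x$rows$pass_stage3), sum(x$rows$pass_stage4)))
  if (length(x$final)) cat("final candidates:", paste(x$final, collapse = ", "), "\n")
  invisible(x)
}
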