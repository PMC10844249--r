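# Summary-statistic simulator with planted ground truth.  Emulates (i) paired
# cross-species DE tables sharing a latent disease program, (ii) matched
# proteome tables linearly related to the transcriptome with a subset of
# "substrate" proteins shifted below the regression prediction, and (iii)
# gene-set annotations containing a term that covers the planted substrates.

#' Simulation configuration
#'
#' Defaults describe the regime the package is validated in: a
#' transcriptome-scale experiment (5,000 genes) in which 30% of genes carry
#' a latent log2FC drawn from Normal(0, tau^2), each dataset observes it
#' with measurement noise `sigma_dataset`, protein fold change follows the
#' transcript linearly with substantial biological noise, and a small set of
#' strongly differential genes has its protein shifted down by
#' `delta_shift` residual SDs (the proteolysis signature).
#'
#' @param n_genes number of genes in the universe.
#' @param pi_de fraction of genes carrying a non-zero latent effect.
#' @param tau_effect SD of the latent log2FC among DE genes (log2 units).
#' @param sigma_dataset per-dataset observation noise SD; scalar or vector
#'   recycled over datasets.
#' @param mrna_prot_slope slope of the protein-on-mRNA fold-change relation.
#' @param mrna_prot_noise_sd SD of protein-level noise around that line.
#' @param n_substrates number of planted substrate genes.
#' @param delta_shift downward protein shift of substrates, in units of
#'   `mrna_prot_noise_sd` (0 disables the shift).
#' @param substrate_min_effect substrates are drawn only from DE genes with
#'   `|latent effect| >` this value: the screen targets robustly
#'   dysregulated transcripts, so planting substrates on near-null genes
#'   would not represent its intended use.
#' @param n_terms number of random gene sets (>= 1).
#' @param term_size_range integer length-2: min/max random-set size.
#' @param seed integer seed; all simulator randomness derives from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 5000, pi_de = 0.3, tau_effect = 2,
                       sigma_dataset = 0.5, mrna_prot_slope = 0.5,
                       mrna_prot_noise_sd = 1, n_substrates = 25,
                       delta_shift = 3, substrate_min_effect = 2,
                       n_terms = 50, term_size_range = c(10L, 50L),
                       seed = 0L) {
  stopifnot_scalar_number(n_genes, "n_genes", lower = 10)
  stopifnot_scalar_number(pi_de, "pi_de", lower = 0, upper = 1,
                          strict_lower = TRUE)
  stopifnot_scalar_number(tau_effect, "tau_effect", lower = 0,
                          strict_lower = TRUE)
  if (any(!is.finite(sigma_dataset)) || any(sigma_dataset <= 0))
    validation_error("sigma_dataset values must be > 0")
  stopifnot_scalar_number(mrna_prot_noise_sd, "mrna_prot_noise_sd",
                          lower = 0, strict_lower = TRUE)
  stopifnot_scalar_number(n_substrates, "n_substrates", lower = 0,
                          upper = n_genes)
  stopifnot_scalar_number(delta_shift, "delta_shift", lower = 0)
  stopifnot_scalar_number(n_terms, "n_terms", lower = 0)
  if (length(term_size_range) != 2L || term_size_range[1] > term_size_range[2] ||
      term_size_range[1] < 1 || term_size_range[2] > n_genes)
    validation_error("term_size_range infeasible for the gene universe")
  structure(list(n_genes = as.integer(n_genes), pi_de = pi_de,
                 tau_effect = tau_effect, sigma_dataset = sigma_dataset,
                 mrna_prot_slope = mrna_prot_slope,
                 mrna_prot_noise_sd = mrna_prot_noise_sd,
                 n_substrates = as.integer(n_substrates),
                 delta_shift = delta_shift,
                 substrate_min_effect = substrate_min_effect,
                 n_terms = as.integer(n_terms),
                 term_size_range = as.integer(term_size_range),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Deterministic sub-seed: keeps independent draws reproducible regardless of
# the order in which simulator functions are called.  Stays below 2^31.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label))) %% 99991L
  (abs(as.integer(seed)) %% 20000L) * 100000L + h
}

#' Simulate paired cross-dataset DE tables
#'
#' Gene `g` carries a latent log2FC `theta_g` (zero with probability
#' `1 - pi_de`, else Normal(0, tau^2)); dataset `d` observes
#' `theta_g + Normal(0, sigma_d^2)`.  Raw P comes from the two-sided normal
#' test of `x / sigma_d` (the observation SE is known by construction) and
#' adjusted P from Benjamini-Hochberg, emulating what DE pipelines report.
#' "Mouse"-style source ids and "human"-style target ids are linked by the
#' emitted ortholog map.
#'
#' @param cfg a [sim_config()].
#' @param n_datasets number of tables to generate (>= 1).
#' @param id_side character vector (recycled) choosing each table's id
#'   namespace: `"source"` (mouse-like, lowercase) or `"target"`
#'   (human-like, uppercase).  Default: all tables source except the last,
#'   which acts as the human-side reference.
#' @return List with `tables` (list of [diff_table()]s, layer `"mrna"`),
#'   `map` (the [ortholog_map()]), and `truth` (list: `de_genes`,
#'   `substrate_genes` both as source/target id vectors, `latent_effects`
#'   named by source id, `seed_used`).
#' @export
simulate_paired_transcriptomes <- function(cfg, n_datasets = 2L,
                                           id_side = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (n_datasets < 1L) validation_error("n_datasets must be >= 1")
  id_side <- id_side %||%
    c(rep("source", max(1L, n_datasets - 1L)),
      if (n_datasets > 1L) "target")
  id_side <- rep_len(match.arg(id_side, c("source", "target"),
                               several.ok = TRUE), n_datasets)
  n <- cfg$n_genes
  src_ids <- sprintf("g%05d", seq_len(n))
  tgt_ids <- toupper(src_ids)
  map <- ortholog_map(src_ids, tgt_ids)

  set.seed(derive_seed(cfg$seed, "latent"))
  is_de <- runif(n) < cfg$pi_de
  theta <- ifelse(is_de, rnorm(n, 0, cfg$tau_effect), 0)

  eligible <- which(is_de & abs(theta) > cfg$substrate_min_effect)
  if (cfg$n_substrates > length(eligible))
    validation_error(sprintf(
      "only %d genes eligible as substrates (need %d); increase n_genes/pi_de/tau_effect",
      length(eligible), cfg$n_substrates))
  substrate_idx <- sort(eligible[sample.int(length(eligible),
                                            cfg$n_substrates)])

  sigmas <- rep_len(cfg$sigma_dataset, n_datasets)
  tables <- vector("list", n_datasets)
  for (d in seq_len(n_datasets)) {
    set.seed(derive_seed(cfg$seed, paste0("transcriptome", d)))
    x <- theta + rnorm(n, 0, sigmas[d])
    p_raw <- 2 * pnorm(-abs(x / sigmas[d]))
    ids <- if (id_side[d] == "source") src_ids else tgt_ids
    tables[[d]] <- diff_table(
      feature_id = ids, log2fc = x, p_raw = p_raw,
      p_adj = p.adjust(p_raw, method = "BH"),
      dataset_label = sprintf("sim_%s_d%d", id_side[d], d), layer = "mrna")
  }
  truth <- list(de_genes = src_ids[is_de],
                de_genes_target = tgt_ids[is_de],
                substrate_genes = src_ids[substrate_idx],
                substrate_genes_target = tgt_ids[substrate_idx],
                latent_effects = setNames(theta, src_ids),
                seed_used = cfg$seed)
  list(tables = tables, map = map, truth = truth)
}

#' Simulate a matched proteome table
#'
#' Protein log2FC follows `slope * x + Normal(0, noise_sd^2)`; planted
#' substrates are additionally shifted by `-delta_shift * noise_sd`,
#' i.e. their protein falls below the line by `delta_shift` residual SDs.
#' P-values are generated as for transcripts (normal test of
#' `y / noise_sd`, BH adjustment).
#'
#' @param transcriptome a [diff_table()] from
#'   [simulate_paired_transcriptomes()].
#' @param cfg the same [sim_config()].
#' @param truth the matching truth list (identifies substrate genes).
#' @return A protein-layer [diff_table()] over the same feature ids.
#' @export
simulate_proteome <- function(transcriptome, cfg, truth) {
  stopifnot(inherits(transcriptome, "diff_table"), inherits(cfg, "sim_config"))
  ids <- transcriptome$feature_id
  known <- c(names(truth$latent_effects), toupper(names(truth$latent_effects)))
  if (!all(ids %in% known))
    validation_error("transcriptome contains gene ids unknown to the simulation truth")
  label <- attr(transcriptome, "dataset_label")
  set.seed(derive_seed(cfg$seed, paste0("proteome_", label)))
  sd_p <- cfg$mrna_prot_noise_sd
  y <- cfg$mrna_prot_slope * transcriptome$log2fc + rnorm(length(ids), 0, sd_p)
  is_sub <- ids %in% truth$substrate_genes |
            ids %in% truth$substrate_genes_target
  y[is_sub] <- y[is_sub] - cfg$delta_shift * sd_p
  p_raw <- 2 * pnorm(-abs(y / sd_p))
  diff_table(feature_id = ids, log2fc = y, p_raw = p_raw,
             p_adj = p.adjust(p_raw, method = "BH"),
             dataset_label = paste0(label, "_prot"), layer = "protein")
}

#' Simulate a gene-set collection with one planted term
#'
#' `n_terms` random sets with sizes uniform in `term_size_range`, plus one
#' designated term (`term_id` `"T0000"`) containing every planted substrate
#' and random filler genes up to a size drawn from the same range.  Term ids
#' and memberships are deterministic given the config seed.
#'
#' @param cfg a [sim_config()] with `n_terms >= 1`.
#' @param truth truth list from [simulate_paired_transcriptomes()].
#' @param id_side namespace of set members: `"source"` (default) or
#'   `"target"`.
#' @return A [gene_set_collection()]; the planted term id is stored in
#'   `attr(, "planted_term")`.
#' @export
simulate_gene_sets <- function(cfg, truth, id_side = c("source", "target")) {
  stopifnot(inherits(cfg, "sim_config"))
  id_side <- match.arg(id_side)
  if (cfg$n_terms < 1L)
    validation_error("n_terms must be >= 1 (the screen needs annotations)")
  universe <- names(truth$latent_effects)
  subs <- truth$substrate_genes
  if (id_side == "target") {
    universe <- toupper(universe); subs <- toupper(subs)
  }
  set.seed(derive_seed(cfg$seed, paste0("genesets_", id_side)))
  lo <- cfg$term_size_range[1]; hi <- cfg$term_size_range[2]
  draw_size <- function(k) lo + sample.int(hi - lo + 1L, k, replace = TRUE) - 1L
  sizes <- draw_size(cfg$n_terms)
  sets <- lapply(sizes, function(s) sample(universe, s))
  names(sets) <- sprintf("T%04d", seq_len(cfg$n_terms))
  planted_size <- max(length(subs), draw_size(1L))
  fillers <- sample(setdiff(universe, subs), planted_size - length(subs))
  planted <- list(T0000 = c(subs, fillers))
  coll <- gene_set_collection(
    c(planted, sets),
    descriptions = c("planted substrate term",
                     rep("random set", cfg$n_terms)))
  attr(coll, "planted_term") <- "T0000"
  coll
}
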