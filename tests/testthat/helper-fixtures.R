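# Shared fixtures: tiny in-code tables and TSV writers used across tests.

toy_table <- function(ids = c("a", "b", "c", "d", "e"),
                      lfc = c(2.0, -1.5, 0.2, 1.2, -0.1),
                      p_adj = c(0.001, 0.02, 0.9, 0.04, 0.7),
                      label = "toy", layer = "mrna") {
  diff_table(ids, lfc, p_raw = p_adj / 2, p_adj = p_adj,
             dataset_label = label, layer = layer)
}

write_tmp_tsv <- function(df, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, paste0("tbl-", as.integer(stats::runif(1, 1, 1e8)), ".tsv"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Independent combinatorial oracle for the upper hypergeometric tail:
# P(X >= k) via explicit binomial-coefficient summation.
tail_sum_oracle <- function(k, K, n, N) {
  if (k <= 0) return(1)
  i <- k:min(K, n)
  if (length(i) == 0 || k > min(K, n)) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# A small simulated screen world reused by several tests.
small_screen_world <- function(seed = 7, n_genes = 1200, delta_shift = 3,
                               n_substrates = 10) {
  cfg <- sim_config(n_genes = n_genes, n_substrates = n_substrates,
                    delta_shift = delta_shift, n_terms = 20, seed = seed)
  sim <- simulate_paired_transcriptomes(cfg, 2)
  list(cfg = cfg, sim = sim,
       prot = lapply(sim$tables, simulate_proteome, cfg = cfg,
                     truth = sim$truth),
       sets = simulate_gene_sets(cfg, sim$truth))
}

run_sim_screen <- function(world, ...) {
  run_screen(list(anchor = list(mrna = world$sim$tables[[1]],
                                protein = world$prot[[1]]),
                  other = list(mrna = world$sim$tables[[2]],
                               protein = world$prot[[2]])),
             maps = world$sim$map, sets = world$sets, ...)
}
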