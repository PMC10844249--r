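# Pearson concordance, Fisher r-to-z, DEG classification and overlap.

make_pairs <- function(x, y, ids = sprintf("g%03d", seq_along(x))) {
  paired_changes(ids, toupper(ids), x, y)
}

test_that("pearson_cor matches the textbook formula and handles degenerate input", {
  expect_equal(pearson_cor(make_pairs(1:4, 1:4))$r, 1)
  expect_equal(pearson_cor(make_pairs(1:4, -(1:4)))$r, -1)

  set.seed(21)
  x <- rnorm(20); y <- 0.4 * x + rnorm(20)
  cr <- pearson_cor(make_pairs(x, y))
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(cr$r, r_direct, tolerance = 1e-12)
  tt <- r_direct * sqrt(18 / (1 - r_direct^2))
  expect_equal(cr$p, 2 * pt(-abs(tt), 18), tolerance = 1e-12)

  expect_error(pearson_cor(make_pairs(1:3, 1:3)),
               class = "orthoscreen_validation_error")
  expect_error(pearson_cor(make_pairs(rep(1, 5), rnorm(5))),
               class = "orthoscreen_degenerate_error")
})

test_that("pearson_cor is affine-invariant and flips sign under reflection", {
  set.seed(33)
  for (i in 1:20) {
    x <- rnorm(30); y <- rnorm(30)
    r0 <- pearson_cor(make_pairs(x, y))$r
    a <- runif(1, 0.1, 5); b <- rnorm(1)
    expect_equal(pearson_cor(make_pairs(a * x + b, y))$r, r0,
                 tolerance = 1e-12)
    expect_equal(pearson_cor(make_pairs(-a * x + b, y))$r, -r0,
                 tolerance = 1e-12)
  }
})

test_that("compare_correlations follows the r-to-z closed form", {
  c1 <- list(r = 0.8, n = 103, subset_label = "a")
  c2 <- list(r = 0.5, n = 103, subset_label = "b")
  cc <- compare_correlations(c1, c2)
  expect_equal(cc$z, (atanh(0.8) - atanh(0.5)) / sqrt(2 / 100),
               tolerance = 1e-12)
  expect_equal(cc$z, 3.884, tolerance = 1e-3)

  # equal correlations: exactly z = 0, p = 1
  eq <- compare_correlations(list(r = 0.5, n = 100), list(r = 0.5, n = 100))
  expect_identical(eq$z, 0)
  expect_identical(eq$p, 1)

  # antisymmetry
  sw <- compare_correlations(c2, c1)
  expect_equal(sw$z, -cc$z)
  expect_equal(sw$p, cc$p)

  expect_error(compare_correlations(list(r = 1, n = 10), c2),
               class = "orthoscreen_validation_error")
  expect_error(compare_correlations(list(r = 0.5, n = 3), c2),
               class = "orthoscreen_validation_error")
})

test_that("classify_deg uses strict thresholds; overlap matches set algebra", {
  tab <- diff_table(c("g1", "g2", "g3", "g4", "g5", "g6"),
                    c(1.0, 1.5, -2.0, -0.9, 3.0, -1.2),
                    p_raw = rep(0.01, 6),
                    p_adj = c(0.01, 0.20, 0.01, 0.01, 0.04, 0.05))
  d <- classify_deg(tab, lfc_cut = 1, p_cut = 0.05)
  # g1: lfc exactly 1 -> excluded; g2: p_adj 0.2 -> excluded;
  # g6: p_adj exactly 0.05 -> excluded
  expect_equal(d$up, "g5")
  expect_equal(d$down, "g3")

  set.seed(44)
  ids_a <- sprintf("m%02d", 1:30); ids_b <- sprintf("H%02d", 1:40)
  sa <- structure(list(up = sample(ids_a, 12), down = sample(ids_a, 8),
                       thresholds = c(lfc_cut = 1, p_cut = 0.05)),
                  class = "deg_sets")
  sb <- structure(list(up = sample(ids_b, 15), down = sample(ids_b, 9),
                       thresholds = c(lfc_cut = 1, p_cut = 0.05)),
                  class = "deg_sets")
  map <- ortholog_map(ids_a[1:25], ids_b[1:25])
  ov <- deg_overlap(sa, sb, map)
  # oracle: explicit set algebra in B's namespace
  tr <- function(ids) map$target_id[match(intersect(ids, map$source_id),
                                          map$source_id)]
  expect_equal(ov$shared[ov$direction == "up"],
               length(intersect(tr(sa$up), sb$up)))
  expect_equal(ov$a_only[ov$direction == "down"],
               length(setdiff(tr(sa$down), sb$down)))
  expect_equal(ov$b_only[ov$direction == "down"],
               length(setdiff(sb$down, tr(sa$down))))

  ov_id <- deg_overlap(sa, sa, map = NULL)
  expect_true(all(ov_id$a_only == 0) && all(ov_id$b_only == 0))
})

test_that("subset_correlation restricts correctly and is bit-identical on the full set", {
  set.seed(55)
  x <- rnorm(12); y <- rnorm(12)
  pr <- make_pairs(x, y)
  full <- subset_correlation(pr, pr$id_x, side = "x_ids",
                             subset_label = "global")
  expect_identical(full$r, pearson_cor(pr)$r)
  expect_identical(full$p, pearson_cor(pr)$p)

  members <- pr$id_x[c(2, 5, 7, 11)]
  sub <- subset_correlation(pr, members, side = "x_ids")
  keep <- pr$id_x %in% members
  r_hand <- cor(pr$x[keep], pr$y[keep])
  expect_equal(sub$r, r_hand, tolerance = 1e-12)
  expect_equal(sub$n, 4L)

  expect_error(subset_correlation(pr, c("nope1", "nope2")),
               class = "orthoscreen_validation_error")
})

test_that("concordance_matrix recovers planted correlation ordering", {
  # reference-noise inversion: choose sigma_d so the latent-program model
  # yields the requested correlation with the reference table
  v <- 1; s_ref2 <- 0.05
  rho <- c(0.7, 0.5, 0.2)
  sig_d <- sqrt(v^2 / (rho^2 * (v + s_ref2)) - v)
  cfg <- sim_config(n_genes = 2000, pi_de = 1, tau_effect = 1,
                    sigma_dataset = c(sig_d, sqrt(s_ref2)),
                    n_substrates = 5, substrate_min_effect = 1.5, seed = 12)
  sim <- simulate_paired_transcriptomes(
    cfg, 4, id_side = c("source", "source", "source", "target"))
  # distinct labels per candidate table
  for (i in 1:3) attr(sim$tables[[i]], "dataset_label") <- paste0("cand", i)
  cm <- suppressMessages(concordance_matrix(sim$tables[1:3], sim$tables[[4]],
                                            map = sim$map))
  r <- cm$correlations$r[match(paste0("cand", 1:3), cm$correlations$label)]
  expect_true(all(diff(r) < 0))          # 0.7 > 0.5 > 0.2 recovered
  expect_equal(r, rho, tolerance = 0.08)
  cmp <- cm$comparisons
  p13 <- cmp$p[cmp$label_1 == "cand1" & cmp$label_2 == "cand3"]
  expect_lt(p13, 0.01)

  # identical tables compared to each other give z = 0
  t_dup <- sim$tables[[1]]
  attr(t_dup, "dataset_label") <- "cand1_dup"
  cm2 <- suppressMessages(concordance_matrix(list(sim$tables[[1]], t_dup),
                                             sim$tables[[4]], map = sim$map))
  z12 <- cm2$comparisons$z[1]
  expect_equal(z12, 0)

  expect_error(concordance_matrix(list(sim$tables[[1]]), sim$tables[[4]]),
               class = "orthoscreen_validation_error")
})
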