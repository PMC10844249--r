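# The four-stage transcriptome-proteome discordance screen.

make_pairs <- function(x, y, ids = sprintf("g%03d", seq_along(x))) {
  paired_changes(ids, ids, x, y)
}

test_that("fit_fc_regression solves the normal equations", {
  # exact line: zero residual sd
  x <- 0:4; f <- fit_fc_regression(make_pairs(x, 2 * x + 1))
  expect_equal(f$slope, 2); expect_equal(f$intercept, 1)
  expect_equal(f$residual_sd, 0)

  # hand-solved 4-point toy: slope 0.6, intercept 0.1
  f2 <- fit_fc_regression(make_pairs(c(0, 1, 2, 3), c(0, 1, 1, 2)))
  expect_equal(f2$slope, 0.6, tolerance = 1e-12)
  expect_equal(f2$intercept, 0.1, tolerance = 1e-12)
  rss <- sum((c(0, 1, 1, 2) - 0.1 - 0.6 * c(0, 1, 2, 3))^2)
  expect_equal(f2$residual_sd, sqrt(rss / 2), tolerance = 1e-12)

  # agreement with lm() as an independent solver on random data
  set.seed(13)
  x <- rnorm(40); y <- 0.5 * x + rnorm(40)
  f3 <- fit_fc_regression(make_pairs(x, y))
  lmf <- lm(y ~ x)
  expect_equal(f3$slope, unname(coef(lmf)[2]), tolerance = 1e-12)
  expect_equal(f3$intercept, unname(coef(lmf)[1]), tolerance = 1e-12)
  expect_equal(f3$residual_sd, summary(lmf)$sigma, tolerance = 1e-12)

  expect_error(fit_fc_regression(make_pairs(rep(1, 5), rnorm(5))),
               class = "orthoscreen_degenerate_error")
})

test_that("standardized residuals satisfy OLS identities and match direct recomputation", {
  set.seed(14)
  x <- rnorm(60); y <- 0.7 * x + rnorm(60)
  pr <- make_pairs(x, y)
  fit <- fit_fc_regression(pr)
  sr <- standardized_residuals(pr, fit)
  raw <- pr$y - fit$intercept - fit$slope * pr$x
  expect_equal(sum(raw), 0, tolerance = 1e-9)
  expect_equal(sum(sr^2), length(x) - 2, tolerance = 1e-9)
  expect_equal(unname(sr), raw / fit$residual_sd, tolerance = 1e-12)
  expect_named(sr)

  # studentized variant matches rstandard() on the same model
  sr_t <- standardized_residuals(pr, fit, studentized = TRUE)
  lmf <- lm(pr$y ~ pr$x)
  expect_equal(unname(sr_t), unname(rstandard(lmf)), tolerance = 1e-9)

  collinear <- make_pairs(1:5, 2 * (1:5))
  expect_error(standardized_residuals(collinear, fit_fc_regression(collinear)),
               class = "orthoscreen_degenerate_error")
})

test_that("stage 1 keeps same-direction exceedances only; null rate matches binomial oracle", {
  res_a <- c(g1 = -1.5, g2 = -1.5, g3 = 2.0, g4 = 0.5, g5 = 1.2)
  res_b <- c(g1 = -2.0, g2 = +1.5, g3 = 1.1, g4 = 2.0, g5 = -1.2)
  s1 <- stage1_select(res_a, res_b, cut = 1)
  expect_equal(s1$key, c("g1", "g3"))
  expect_equal(s1$direction, c("down", "up"))   # g2 mixed sign excluded

  expect_error(stage1_select(c(a = 1), c(b = 1)),
               class = "orthoscreen_validation_error")

  # 200 independent standard-normal pairs: expected down count 200 * pnorm(-1)^2
  set.seed(15)
  counts <- replicate(40, {
    ra <- setNames(rnorm(200), sprintf("g%03d", 1:200))
    rb <- setNames(rnorm(200), sprintf("g%03d", 1:200))
    s <- stage1_select(ra, rb)
    sum(s$direction == "down")
  })
  p0 <- pnorm(-1)^2
  ci <- qbinom(c(0.005, 0.995), 200, p0)
  expect_gt(mean(counts >= ci[1] & counts <= ci[2]), 0.9)
  expect_equal(mean(counts), 200 * p0, tolerance = 0.35)
})

test_that("stages 2-4 follow their set-algebra and threshold definitions", {
  set.seed(16)
  a <- sample(letters, 12); b <- sample(letters, 15)
  expect_equal(stage2_intersect(a, b), sort(intersect(a, b)))
  expect_equal(stage2_intersect(a, a), sort(a))
  expect_length(suppressMessages(stage2_intersect(c("q1"), c("q2"))), 0L)

  bg <- sprintf("g%02d", 1:50)
  coll <- gene_set_collection(list(down_term = bg[1:10], junk = bg[30:40]))
  down <- bg[c(1, 2, 3, 4, 25)]   # 4 of 5 in the significant term
  up <- bg[45:47]
  s3 <- stage3_go_filter(up, down, bg, coll, alpha = 0.05, mode = "fisher")
  expect_equal(s3$retained, bg[1:4])
  expect_true(all(c("direction", "category") %in% names(s3$enrichment)))
  # a term significant only for the down analysis must not rescue up candidates
  expect_false(any(up %in% s3$retained))

  cand <- data.frame(key = sprintf("c%02d", 1:10),
                     mrna_lfc = c(2, -2, 0.5, 1.2, -1.2, 3, 1.01, -4, 2, 1),
                     mrna_p_adj = c(.01, .2, .01, .04, .001, .06, .01, .02, NA, .01),
                     stringsAsFactors = FALSE)
  kept <- stage4_final_filter(cand)
  # hand evaluation: need p_adj < 0.05 & |lfc| > 1
  expect_equal(kept$key, c("c01", "c04", "c05", "c07", "c08"))
  expect_error(stage4_final_filter(cand, prot_padj_max = 0.05),
               class = "orthoscreen_config_error")
})

test_that("run_screen recovers planted substrates and keeps the funnel monotone", {
  world <- small_screen_world(seed = 101)
  res <- suppressMessages(run_sim_screen(world))
  rows <- res$rows
  expect_true(all(rows$pass_stage1 | !rows$pass_stage2))
  expect_true(all(rows$pass_stage2 | !rows$pass_stage3))
  expect_true(all(rows$pass_stage3 | !rows$pass_stage4))
  counts <- c(sum(rows$pass_stage1), sum(rows$pass_stage2),
              sum(rows$pass_stage3), sum(rows$pass_stage4))
  expect_true(all(diff(counts) <= 0))

  subs <- world$sim$truth$substrate_genes
  recall <- length(intersect(res$final, subs)) / length(subs)
  precision <- length(intersect(res$final, subs)) / max(1, length(res$final))
  expect_gte(recall, 0.8)
  expect_gte(precision, 0.5)
  expect_identical(res$config_echo$residual_cut, 1)

  # determinism: identical inputs give identical results
  res2 <- suppressMessages(run_sim_screen(world))
  expect_identical(res$rows, res2$rows)
  expect_identical(res$final, res2$final)

  expect_error(run_screen(list(a = 1), sets = world$sets),
               class = "orthoscreen_validation_error")
})

test_that("run_screen under the null yields few final candidates", {
  world <- small_screen_world(seed = 202, delta_shift = 0)
  res <- suppressMessages(run_sim_screen(world))
  # without the planted shift the enriched-term filter has nothing coherent
  # to retain; the final set stays a tiny fraction of the universe
  expect_lte(length(res$final), 0.01 * world$cfg$n_genes)
})
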