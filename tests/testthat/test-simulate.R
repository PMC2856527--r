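test_that("simulation is deterministic and respects degenerate dispersion", {
  cfg <- panel_sim_config(n_panelists = 5, seed = 31)
  a <- simulate_panel(cfg)
  b <- simulate_panel(cfg)
  expect_identical(a, b)
  ra <- simulate_retest(a$weights, cfg)
  rb <- simulate_retest(b$weights, cfg)
  expect_identical(ra, rb)

  flat <- panel_sim_config(n_panelists = 4, weight_means = 4,
                           score_means = 2, panelist_sd = 0, seed = 1)
  p <- simulate_panel(flat)
  for (w in p$weights) expect_true(all(w$weights == 4))
  for (s in p$scores) expect_true(all(s$scores == 2))
})

test_that("simulated panels have the elicitation-grid shape", {
  f <- evidem_framework(not_applicable = "Q1")
  cfg <- panel_sim_config(n_panelists = 8, framework = f, seed = 3)
  p <- simulate_panel(cfg)
  expect_length(p$weights, 8)
  expect_length(p$scores, 8)
  expect_length(p$weights[[1]]$weights, 15)
  expect_length(p$scores[[1]]$scores, 14)
  expect_false("Q1" %in% names(p$scores[[1]]$scores))
})

test_that("generated values always lie within scale bounds", {
  set.seed(77)
  for (i in 1:8) {
    cfg <- panel_sim_config(
      n_panelists = sample(2:10, 1),
      weight_means = runif(1, 1, 5),
      score_means = runif(1, 0, 3),
      panelist_sd = runif(1, 0, 3),
      retest_probs = local({
        p <- runif(3)
        p / sum(p)
      }),
      seed = sample.int(1e6, 1)
    )
    p <- simulate_panel(cfg)
    for (w in p$weights) {
      expect_true(all(w$weights >= 1 & w$weights <= 5))
    }
    r <- simulate_retest(p$scores, cfg)
    for (s in r) expect_true(all(s$scores >= 0 & s$scores <= 3))
  }
})

test_that("degenerate retest probabilities behave as specified", {
  f <- evidem_framework()
  cfg0 <- panel_sim_config(n_panelists = 6, framework = f,
                           retest_probs = c(1, 0, 0), seed = 8)
  p <- simulate_panel(cfg0)
  r <- simulate_retest(p$weights, cfg0)
  pw <- pair_testretest(p$weights, r, f)
  expect_equal(agreement_proportions(pw),
               c(diff0 = 1, diff1 = 0, diff2plus = 0))
  expect_equal(as.numeric(icc_twoway_mixed(pw)), 1)

  # all-2-point shifts on interior cells (weight 3 on 1-5 never clamps)
  cfg2 <- panel_sim_config(n_panelists = 6, framework = f, weight_means = 3,
                           panelist_sd = 0, retest_probs = c(0, 0, 1),
                           seed = 8)
  p2 <- simulate_panel(cfg2)
  r2 <- simulate_retest(p2$weights, cfg2)
  pw2 <- pair_testretest(p2$weights, r2, f)
  expect_equal(agreement_proportions(pw2)[["diff2plus"]], 1)
})

test_that("realized shift frequencies are reported and recovered downstream", {
  f <- evidem_framework()
  cfg <- panel_sim_config(n_panelists = 40, framework = f, weight_means = 3,
                          panelist_sd = 0.8,
                          retest_probs = c(0.65, 0.29, 0.06), seed = 99)
  p <- simulate_panel(cfg)
  r <- simulate_retest(p$weights, cfg)
  n_cells <- 40 * 15
  nominal <- attr(r, "nominal_shift_freq")
  realized <- attr(r, "realized_shift_freq")
  se <- sqrt(0.65 * 0.35 / n_cells)
  expect_lt(abs(nominal[["diff0"]] - 0.65), 3 * se)
  # downstream agreement proportions equal the realized frequencies exactly
  pw <- pair_testretest(p$weights, r, f)
  expect_equal(agreement_proportions(pw), realized)
  # clamping can only turn shifts into smaller ones
  expect_gte(realized[["diff0"]], nominal[["diff0"]])
})

test_that("the full pipeline runs end to end", {
  st <- simulate_study(panel_sim_config(n_panelists = 9, seed = 17))
  expect_length(st$estimates_test, 9)
  expect_equal(st$reliability$weights$n_pairs, 15 * length(st$retained))
  expect_lte(st$reliability$estimates$icc_3_1, 1)
  expect_equal(
    st$reliability$scores$prop_diff0 + st$reliability$scores$prop_diff1 +
      st$reliability$scores$prop_diff2plus, 1)
})

test_that("the panelist-bias option shifts each panelist's cells by a constant", {
  f <- evidem_framework()
  biased <- panel_sim_config(n_panelists = 30, framework = f,
                             weight_means = 3, panelist_sd = 0,
                             retest_probs = c(1, 0, 0),
                             panelist_bias_sd = 0.8, seed = 4)
  p <- simulate_panel(biased)
  r <- simulate_retest(p$weights, biased)
  shifts <- vapply(seq_along(r), function(i) {
    d <- unique(r[[i]]$weights - p$weights[[i]]$weights)
    expect_length(d, 1)  # constant within panelist (interior cells)
    d
  }, numeric(1))
  expect_gt(length(unique(shifts)), 1)  # but varying across panelists
})
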