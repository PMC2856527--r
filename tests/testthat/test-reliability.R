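test_that("pairing expands panelist-by-component cells and drops unpaired units", {
  f <- evidem_framework(not_applicable = "Q1")
  cfg <- panel_sim_config(n_panelists = 8, framework = f, seed = 11)
  test <- simulate_panel(cfg)
  rw <- simulate_retest(test$weights, cfg)
  rs <- simulate_retest(test$scores, cfg, seed = 13)

  pw <- pair_testretest(test$weights, rw, f)
  expect_equal(length(pw$unit_ids), 120)  # 8 panelists x 15 weighted
  ps <- pair_testretest(test$scores, rs, f)
  expect_equal(length(ps$unit_ids), 112)  # 8 panelists x 14 scoreable

  est_t <- Map(function(w, s) value_estimate(w, s, f), test$weights,
               test$scores)
  est_r <- Map(function(w, s) value_estimate(w, s, f), rw, rs)
  pe <- pair_testretest(unname(est_t), unname(est_r), f)
  expect_equal(length(pe$unit_ids), 8)
  expect_null(pe$scale)

  # pairwise deletion: drop one panelist's retest entirely
  pw2 <- pair_testretest(test$weights, rw[-1], f)
  expect_equal(length(pw2$unit_ids), 105)
  expect_length(attr(pw2, "dropped_units"), 15)
  expect_error(pair_testretest(test$weights[1], rw[-1], f), "no complete")
})

test_that("both ICC forms match the aov-based oracle on a fixed 6-unit fixture", {
  test <- c(4, 2, 5, 3, 1, 4)
  retest <- c(5, 2, 4, 3, 2, 4)
  p <- paired_series(paste0("u", 1:6), test, retest, scale = c(1, 5))
  o <- oracle_iccs(test, retest)
  expect_equal(as.numeric(icc_oneway(p)), o$icc_1_1, tolerance = 1e-10)
  expect_equal(as.numeric(icc_twoway_mixed(p)), o$icc_3_1, tolerance = 1e-10)
})

test_that("ICC forms respond to systematic shift as their models imply", {
  base <- c(1.2, 0.7, 2.5, 1.9, 0.4, 2.2, 1.1, 1.6)
  same <- paired_series(paste0("u", 1:8), base, base)
  expect_equal(as.numeric(icc_oneway(same)), 1)
  expect_equal(as.numeric(icc_twoway_mixed(same)), 1)

  shifted <- paired_series(paste0("u", 1:8), base, base + 0.6)
  expect_equal(as.numeric(icc_twoway_mixed(shifted)), 1, tolerance = 1e-12)
  expect_lt(as.numeric(icc_oneway(shifted)), 1)

  # undefined when there is no variance at all
  flat <- paired_series(paste0("u", 1:4), rep(2, 4), rep(2, 4))
  expect_true(is.nan(icc_oneway(flat)))
  expect_true(attr(icc_oneway(flat), "undefined"))
  expect_true(is.nan(icc_twoway_mixed(flat)))
})

test_that("ICCs are invariant under common affine rescaling", {
  set.seed(5)
  for (i in 1:10) {
    p <- random_paired_series(sample(4:20, 1))
    a <- runif(1, 0.5, 3)
    b <- runif(1, -2, 2)
    q <- paired_series(p$unit_ids, a * p$test + b, a * p$retest + b)
    expect_equal(as.numeric(icc_oneway(q)), as.numeric(icc_oneway(p)),
                 tolerance = 1e-9)
    expect_equal(as.numeric(icc_twoway_mixed(q)),
                 as.numeric(icc_twoway_mixed(p)), tolerance = 1e-9)
  }
})

test_that("negative ICC estimates are reported, not truncated", {
  # within-unit disagreement exceeding between-unit spread drives the
  # estimator negative
  p <- paired_series(paste0("u", 1:4), c(1, 2, 1, 2), c(2, 1, 2, 1),
                     scale = c(1, 5))
  expect_lt(as.numeric(icc_oneway(p)), 0)
})

test_that("agreement proportions partition the pairs", {
  p <- paired_series(c("u1", "u2", "u3"), c(4, 4, 2), c(4, 5, 4),
                     scale = c(1, 5))
  expect_equal(agreement_proportions(p),
               c(diff0 = 1 / 3, diff1 = 1 / 3, diff2plus = 1 / 3))

  same <- paired_series(c("u1", "u2"), c(2, 3), c(2, 3), scale = c(0, 3))
  expect_equal(agreement_proportions(same),
               c(diff0 = 1, diff1 = 0, diff2plus = 0))

  set.seed(9)
  for (i in 1:10) {
    q <- random_paired_series(sample(5:40, 1), scale = c(1, 5))
    props <- agreement_proportions(q)
    expect_equal(sum(props), 1)
    perm <- sample(seq_along(q$unit_ids))
    qp <- paired_series(q$unit_ids[perm], q$test[perm], q$retest[perm],
                        scale = q$scale)
    expect_equal(agreement_proportions(qp), props)
  }

  cont <- paired_series(c("u1", "u2"), c(1.5, 2), c(1, 2), scale = c(0, 3))
  expect_error(agreement_proportions(cont), "integer")
  noscale <- paired_series(c("u1", "u2"), c(1, 2), c(1, 2))
  expect_error(agreement_proportions(noscale), "ordinal")
})

test_that("independent 1-5 pairs agree exactly 20% of the time in expectation", {
  # exact enumeration over the 25 equiprobable pairs gives P(diff 0) = 5/25
  grid <- expand.grid(t = 1:5, r = 1:5)
  expect_equal(mean(grid$t == grid$r), 0.2)
  set.seed(42)
  props <- agreement_proportions(paired_series(
    paste0("u", 1:2000), sample(1:5, 2000, TRUE), sample(1:5, 2000, TRUE),
    scale = c(1, 5)))
  se <- sqrt(0.2 * 0.8 / 2000)
  expect_lt(abs(props[["diff0"]] - 0.2), 3 * se)
})

test_that("the systematic-error rule flags large relative differences", {
  rep1 <- flag_outliers(c(p1 = 2.0), c(p1 = 1.15))
  expect_equal(rep1$relative_difference, 0.85 / 1.575, tolerance = 1e-12)
  expect_true(rep1$flagged)

  rep2 <- flag_outliers(c(a = 1.2, b = 1.0), c(a = 1.2, b = 1.4))
  expect_equal(rep2$relative_difference, c(0, 1 / 3), tolerance = 1e-12)
  expect_false(any(rep2$flagged))

  # equal pairs are never flagged, including the all-zero pair
  rep3 <- flag_outliers(c(0, 2), c(0, 2))
  expect_false(any(rep3$flagged))

  # zero mean with unequal values: undefined ratio, flagged with reason
  rep4 <- flag_outliers(c(x = 0.5), c(x = -0.5))
  expect_true(rep4$flagged)
  expect_match(rep4$reason, "undefined")

  expect_error(flag_outliers(1:3, 1:2), "aligned")
})

test_that("reliability results assemble into the standard agreement table", {
  f <- evidem_framework(not_applicable = "Q1")
  cfg <- panel_sim_config(n_panelists = 8, framework = f, seed = 21)
  test <- simulate_panel(cfg)
  rw <- simulate_retest(test$weights, cfg)
  rs <- simulate_retest(test$scores, cfg, seed = 23)
  rel_w <- reliability_result(pair_testretest(test$weights, rw, f))
  rel_s <- reliability_result(pair_testretest(test$scores, rs, f))
  expect_equal(rel_w$n_pairs, 120)
  expect_equal(rel_s$n_pairs, 112)
  expect_equal(rel_w$prop_diff0 + rel_w$prop_diff1 + rel_w$prop_diff2plus, 1)
  tab <- reliability_table(weights = rel_w, scores = rel_s)
  expect_equal(names(tab), c("statistic", "weights", "scores"))
  expect_equal(tab$weights[tab$statistic == "n_pairs"], 120)
  expect_equal(nrow(tab), 8)
})
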