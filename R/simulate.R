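#' Configure a synthetic panel simulation
#'
#' The simulator emulates a small appraisal panel: each panelist's weight or
#' score for a component is a Gaussian draw centred on that component's
#' population tendency with between-panelist spread `panelist_sd`, rounded
#' to the integer scale and clamped at its bounds. A retest occasion
#' perturbs each cell independently by 0, 1 or 2 points (direction uniform,
#' clamped), reproducing the mostly-identical / some-1-point / rare-2-point
#' pattern of real test-retest elicitation.
#'
#' Defaults emulate the study conditions the framework was exercised under:
#' a 9-panelist panel on the default framework, weight tendencies near 4 on
#' the 1--5 scale, score tendencies near 1.3 on the 0--3 scale,
#' between-panelist SD 0.9, and retest shift probabilities
#' (0.55, 0.35, 0.10).
#'
#' @param n_panelists number of panelists (default 9).
#' @param framework an `evidem_framework` (default [evidem_framework()]).
#' @param weight_means named vector of per-component weight tendencies, or a
#'   single number recycled; default 4.
#' @param score_means likewise for scores (over scoreable components);
#'   default 1.3.
#' @param panelist_sd between-panelist SD of the latent draw, default 0.9.
#' @param retest_probs probabilities of a 0-, 1- and 2-point retest shift;
#'   must sum to 1. Default `c(0.55, 0.35, 0.10)`.
#' @param panelist_bias_sd SD of an optional per-panelist constant retest
#'   shift (before rounding), default 0 (cell-level independence). A
#'   positive value induces the systematic per-unit shifts that separate
#'   ICC(1,1) from ICC(3,1).
#' @param seed integer RNG seed.
#' @return An object of class `panel_sim_config`.
#' @export
panel_sim_config <- function(n_panelists = 9,
                             framework = evidem_framework(),
                             weight_means = 4,
                             score_means = 1.3,
                             panelist_sd = 0.9,
                             retest_probs = c(0.55, 0.35, 0.10),
                             panelist_bias_sd = 0,
                             seed = 1L) {
  stopifnot(inherits(framework, "evidem_framework"))
  if (n_panelists < 1) stop_invalid("n_panelists must be >= 1")
  if (panelist_sd < 0 || panelist_bias_sd < 0) {
    stop_invalid("dispersion parameters must be non-negative")
  }
  if (length(retest_probs) != 3 || any(retest_probs < 0) ||
      abs(sum(retest_probs) - 1) > 1e-9) {
    stop_invalid("retest_probs must be 3 non-negative probabilities summing to 1")
  }
  expand <- function(means, ids, scale, what) {
    if (is.null(names(means))) {
      if (length(means) == 1) means <- stats::setNames(rep(means, length(ids)), ids)
      else if (length(means) == length(ids)) names(means) <- ids
      else stop_invalid(what, " means must be named, scalar, or match the component count")
    }
    missing_ids <- setdiff(ids, names(means))
    if (length(missing_ids) > 0) {
      stop_invalid("missing ", what, " mean(s) for ",
                   paste(missing_ids, collapse = ", "))
    }
    m <- means[ids]
    if (any(m < scale[1] | m > scale[2])) {
      stop_invalid(what, " means must lie within the ", scale[1], "-",
                   scale[2], " scale")
    }
    m
  }
  structure(
    list(
      n_panelists = as.integer(n_panelists),
      framework = framework,
      weight_means = expand(weight_means, weightable_ids(framework),
                            framework$weight_scale, "weight"),
      score_means = expand(score_means, scoreable_ids(framework),
                           framework$score_scale, "score"),
      panelist_sd = panelist_sd,
      retest_probs = retest_probs,
      panelist_bias_sd = panelist_bias_sd,
      seed = as.integer(seed)
    ),
    class = "panel_sim_config"
  )
}

discretize <- function(x, scale) pmin(pmax(round(x), scale[1]), scale[2])

#' Simulate a panel's test-occasion weights and scores
#'
#' @param config a [panel_sim_config()].
#' @return List with elements `weights` (list of [weight_set()]s) and
#'   `scores` (list of [score_set()]s), occasion `"test"`. Deterministic
#'   given the config (including its seed).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "panel_sim_config"))
  f <- config$framework
  with_seed(config$seed, {
    ids <- sprintf("p%02d", seq_len(config$n_panelists))
    weights <- lapply(ids, function(pid) {
      draw <- stats::rnorm(length(config$weight_means),
                           mean = config$weight_means,
                           sd = config$panelist_sd)
      weight_set(pid, "test",
                 stats::setNames(discretize(draw, f$weight_scale),
                                 names(config$weight_means)), f)
    })
    scores <- lapply(ids, function(pid) {
      draw <- stats::rnorm(length(config$score_means),
                           mean = config$score_means,
                           sd = config$panelist_sd)
      score_set(pid, "test",
                stats::setNames(discretize(draw, f$score_scale),
                                names(config$score_means)), f)
    })
    list(weights = weights, scores = scores)
  })
}

# Shift one panelist's cells by the configured 0/1/2-point process; returns
# the perturbed integer vector plus the nominal (pre-clamp) magnitudes.
perturb_cells <- function(values, probs, scale, bias = 0) {
  magnitude <- sample(0:2, length(values), replace = TRUE, prob = probs)
  sign <- sample(c(-1, 1), length(values), replace = TRUE)
  shifted <- values + magnitude * sign + round(bias)
  list(values = pmin(pmax(shifted, scale[1]), scale[2]),
       nominal = magnitude)
}

#' Simulate the retest occasion from test data
#'
#' Each cell is independently shifted by 0, 1 or 2 points with the
#' configured probabilities (direction uniform), then clamped to the scale;
#' with `panelist_bias_sd > 0` a per-panelist constant shift is added first,
#' inducing the systematic error that lowers ICC(1,1) but not ICC(3,1).
#' Because clamping absorbs shifts at the scale edges, realized shift
#' frequencies differ from the nominal probabilities; both are reported.
#'
#' @param sets list of [weight_set()]s or [score_set()]s (occasion
#'   `"test"`).
#' @param config the [panel_sim_config()] (supplies probabilities, bias and
#'   framework).
#' @param seed RNG seed for the perturbation (defaults to `config$seed + 1`
#'   so test and retest draws are distinct but jointly reproducible).
#' @return List of sets with occasion `"retest"`, with attributes
#'   `nominal_shift_freq` (frequencies of the drawn 0/1/2 magnitudes) and
#'   `realized_shift_freq` (frequencies of |retest - test| after clamping).
#' @export
simulate_retest <- function(sets, config, seed = config$seed + 1L) {
  stopifnot(inherits(config, "panel_sim_config"))
  f <- config$framework
  kind <- class(sets[[1]])[1]
  field <- switch(kind, weight_set = "weights", score_set = "scores",
                  stop_invalid("sets must be weight or score sets"))
  scale <- switch(kind, weight_set = f$weight_scale,
                  score_set = f$score_scale)
  with_seed(seed, {
    nominal <- integer()
    realized <- integer()
    out <- lapply(sets, function(s) {
      bias <- if (config$panelist_bias_sd > 0) {
        stats::rnorm(1, 0, config$panelist_bias_sd)
      } else 0
      p <- perturb_cells(s[[field]], config$retest_probs, scale, bias)
      nominal <<- c(nominal, p$nominal)
      realized <<- c(realized, abs(p$values - s[[field]]))
      args <- list(s$panelist_id, "retest",
                   stats::setNames(p$values, names(s[[field]])), f)
      do.call(kind, args)
    })
    freq <- function(d) {
      n <- length(d)
      c(diff0 = sum(d == 0) / n, diff1 = sum(d == 1) / n,
        diff2plus = sum(d >= 2) / n)
    }
    attr(out, "nominal_shift_freq") <- freq(nominal)
    attr(out, "realized_shift_freq") <- freq(realized)
    out
  })
}

#' Run the full simulate-estimate-reliability pipeline
#'
#' Convenience wrapper used by tests and the command-line interface:
#' simulates both occasions, computes per-panelist value estimates, applies
#' the outlier rule to the estimate pairs, and returns the three reliability
#' results over retained panelists.
#'
#' @param config a [panel_sim_config()].
#' @param outlier_threshold relative-difference bound for
#'   [flag_outliers()]; `NULL` disables exclusion.
#' @return List with the simulated sets, estimates per occasion, the
#'   `outliers` report, and `reliability` (list of
#'   [reliability_result()]s for weights, scores, estimates over retained
#'   panelists).
#' @export
simulate_study <- function(config, outlier_threshold = 0.5) {
  f <- config$framework
  test <- simulate_panel(config)
  retest_w <- simulate_retest(test$weights, config)
  retest_s <- simulate_retest(test$scores, config, seed = config$seed + 2L)
  est <- function(ws, ss) {
    Map(function(w, s) value_estimate(w, s, f), ws, ss)
  }
  est_test <- est(test$weights, test$scores)
  est_retest <- est(retest_w, retest_s)
  outliers <- flag_outliers(est_test, est_retest,
                            threshold = outlier_threshold %||% Inf)
  keep <- setdiff(vapply(est_test, `[[`, character(1), "panelist_id"),
                  attr(outliers, "flagged_units"))
  keep_sets <- function(sets) {
    Filter(function(s) s$panelist_id %in% keep, sets)
  }
  rel <- list(
    weights = reliability_result(
      pair_testretest(keep_sets(test$weights), keep_sets(retest_w), f)),
    scores = reliability_result(
      pair_testretest(keep_sets(test$scores), keep_sets(retest_s), f)),
    estimates = reliability_result(
      pair_testretest(keep_sets(est_test), keep_sets(est_retest), f))
  )
  list(
    test = test,
    retest = list(weights = retest_w, scores = retest_s),
    estimates_test = est_test,
    estimates_retest = est_retest,
    outliers = outliers,
    retained = keep,
    reliability = rel
  )
}
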