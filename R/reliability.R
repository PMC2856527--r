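#' Paired test-retest series
#'
#' A paired series holds one row per rated unit with its value on each
#' occasion. For weights and scores a unit is one panelist-by-component cell,
#' pooled across panelists (occasions act as the two "raters" of each cell);
#' for value estimates a unit is one panelist.
#'
#' @param unit_ids character labels, one per unit.
#' @param test,retest numeric vectors of the two occasions' values.
#' @param scale optional `c(min, max)` integer range; present for ordinal
#'   series (weights, scores) and required by [agreement_proportions()].
#' @return An object of class `paired_series`.
#' @export
paired_series <- function(unit_ids, test, retest, scale = NULL) {
  n <- length(unit_ids)
  if (length(test) != n || length(retest) != n) {
    stop_invalid("unit_ids, test and retest must have equal length")
  }
  if (n < 2) stop_invalid("a paired series needs at least 2 units")
  if (anyNA(test) || anyNA(retest)) {
    stop_invalid("paired series cannot contain missing values; drop unpaired units first")
  }
  if (!is.null(scale)) {
    vals <- c(test, retest)
    if (any(vals < scale[1] | vals > scale[2])) {
      stop_invalid("values outside the declared ", scale[1], "-", scale[2],
                   " scale")
    }
  }
  structure(
    list(unit_ids = as.character(unit_ids), test = as.numeric(test),
         retest = as.numeric(retest), scale = scale),
    class = "paired_series"
  )
}

#' Pair elicitation data across test and retest occasions
#'
#' Joins two collections of the same kind (weight sets, score sets or value
#' estimates) on panelist id. Weight/score sets are expanded to
#' panelist-by-component cells; units present on only one occasion (or with a
#' score on only one occasion) are dropped pairwise and reported in the
#' `dropped_units` attribute. With a full panel of 8 on the default
#' framework this yields 120 weight pairs, 112 score pairs when one
#' component is unscoreable, and 8 estimate pairs.
#'
#' @param test,retest lists of [weight_set()]s, [score_set()]s or
#'   [value_estimate()]s (both of the same kind).
#' @param f the framework (supplies the ordinal scale for weights/scores).
#' @return A [paired_series()]; attribute `dropped_units` lists the unit ids
#'   excluded by pairwise deletion.
#' @export
pair_testretest <- function(test, retest, f = NULL) {
  if (length(test) == 0 || length(retest) == 0) {
    stop_invalid("empty occasion")
  }
  kind <- class(test[[1]])[1]
  stopifnot(all(vapply(test, inherits, TRUE, kind)),
            all(vapply(retest, inherits, TRUE, kind)))

  cells <- function(sets, field) {
    ids <- vapply(sets, `[[`, character(1), "panelist_id")
    out <- lapply(seq_along(sets), function(i) {
      v <- sets[[i]][[field]]
      stats::setNames(v, paste(ids[i], names(v), sep = ":"))
    })
    unlist(out)
  }

  if (kind == "value_estimate") {
    t_vals <- stats::setNames(vapply(test, `[[`, numeric(1), "value"),
                              vapply(test, `[[`, character(1), "panelist_id"))
    r_vals <- stats::setNames(vapply(retest, `[[`, numeric(1), "value"),
                              vapply(retest, `[[`, character(1), "panelist_id"))
    scale <- NULL
  } else if (kind == "weight_set") {
    t_vals <- cells(test, "weights")
    r_vals <- cells(retest, "weights")
    scale <- if (!is.null(f)) f$weight_scale else NULL
  } else if (kind == "score_set") {
    t_vals <- cells(test, "scores")
    r_vals <- cells(retest, "scores")
    scale <- if (!is.null(f)) f$score_scale else NULL
  } else {
    stop_invalid("unsupported element class: ", kind)
  }

  common <- intersect(names(t_vals), names(r_vals))
  dropped <- setdiff(union(names(t_vals), names(r_vals)), common)
  if (length(common) == 0) stop_invalid("no complete test-retest pairs")
  p <- paired_series(common, t_vals[common], r_vals[common], scale = scale)
  attr(p, "dropped_units") <- dropped
  p
}

# Sums-of-squares decomposition for n units x 2 occasions, computed from the
# definitions (no model fit): between-unit, between-occasion and residual
# mean squares.
anova_decomposition <- function(p) {
  x <- cbind(p$test, p$retest)
  n <- nrow(x)
  k <- ncol(x)
  grand <- mean(x)
  row_means <- rowMeans(x)
  col_means <- colMeans(x)
  ss_between <- k * sum((row_means - grand)^2)
  ss_within <- sum((x - row_means)^2)
  ss_occasion <- n * sum((col_means - grand)^2)
  ss_error <- ss_within - ss_occasion
  list(
    n = n, k = k,
    bms = ss_between / (n - 1),
    wms = ss_within / (n * (k - 1)),
    jms = ss_occasion / (k - 1),
    ems = ss_error / ((n - 1) * (k - 1))
  )
}

#' Intraclass correlation ICC(1,1): one-way random model
#'
#' The Shrout-Fleiss single-rating ICC from a one-way ANOVA with units as
#' groups: \eqn{(BMS - WMS) / (BMS + (k-1) WMS)} with \eqn{k = 2} occasions.
#' It treats test and retest as interchangeable, so a systematic shift
#' between occasions lowers it; compare with [icc_twoway_mixed()]. Negative
#' estimates are reported as computed, not truncated.
#'
#' @param p a [paired_series()].
#' @return The ICC estimate; `NaN` with attribute `undefined = TRUE` when
#'   all values are identical (no variance to apportion).
#' @references Shrout, P.E. and Fleiss, J.L. (1979) Intraclass correlations:
#'   uses in assessing rater reliability. Psychological Bulletin 86, 420-428.
#' @export
icc_oneway <- function(p) {
  stopifnot(inherits(p, "paired_series"))
  a <- anova_decomposition(p)
  denom <- a$bms + (a$k - 1) * a$wms
  if (denom == 0) {
    return(structure(NaN, undefined = TRUE))
  }
  structure((a$bms - a$wms) / denom, undefined = FALSE)
}

#' Intraclass correlation ICC(3,1): two-way mixed, consistency
#'
#' The Shrout-Fleiss single-rating consistency ICC from a two-way mixed
#' ANOVA with the occasion (test/retest) effect fixed:
#' \eqn{(BMS - EMS) / (BMS + (k-1) EMS)}, where EMS is the residual mean
#' square after removing the occasion effect. A constant shift between
#' occasions leaves it unchanged.
#'
#' @inheritParams icc_oneway
#' @inherit icc_oneway return references
#' @export
icc_twoway_mixed <- function(p) {
  stopifnot(inherits(p, "paired_series"))
  a <- anova_decomposition(p)
  denom <- a$bms + (a$k - 1) * a$ems
  if (denom == 0) {
    return(structure(NaN, undefined = TRUE))
  }
  structure((a$bms - a$ems) / denom, undefined = FALSE)
}

#' Agreement proportions on an ordinal series
#'
#' Fractions of test-retest pairs whose values are identical, differ by
#' exactly 1 point, or differ by 2 or more points. The three buckets
#' partition all pairs, so the proportions sum to 1.
#'
#' @param p a [paired_series()] with `scale` present and integer values.
#' @return Named numeric vector `c(diff0, diff1, diff2plus)`.
#' @export
agreement_proportions <- function(p) {
  stopifnot(inherits(p, "paired_series"))
  if (is.null(p$scale)) {
    stop_invalid("agreement proportions need an ordinal series (scale present)")
  }
  if (any(p$test != round(p$test)) || any(p$retest != round(p$retest))) {
    stop_invalid("agreement proportions need integer values")
  }
  d <- abs(p$test - p$retest)
  n <- length(d)
  c(diff0 = sum(d == 0) / n,
    diff1 = sum(d == 1) / n,
    diff2plus = sum(d >= 2) / n)
}

#' Flag panelists with systematic test-retest error
#'
#' A panelist whose two value estimates differ by more than the threshold as
#' a fraction of their mean, \eqn{|t - r| / ((t + r)/2) > } `threshold`,
#' shows systematic error and is excluded from downstream summaries and
#' reliability runs. The default threshold of 0.5 flags the pair
#' (2.0, 1.15), whose relative difference is 0.54.
#'
#' @param test,retest numeric vectors of per-panelist value estimates (or
#'   lists of [value_estimate()]s), aligned; names (or panelist ids) label
#'   the units.
#' @param threshold relative-difference bound, default 0.5.
#' @return An object of class `outlier_report`: data.frame with columns
#'   `unit`, `test`, `retest`, `relative_difference`, `flagged`, `reason`,
#'   plus attributes `threshold` and `flagged_units`.
#' @export
flag_outliers <- function(test, retest, threshold = 0.5) {
  if (is.list(test)) {
    nm <- vapply(test, `[[`, character(1), "panelist_id")
    test <- stats::setNames(vapply(test, `[[`, numeric(1), "value"), nm)
  }
  if (is.list(retest)) {
    nm <- vapply(retest, `[[`, character(1), "panelist_id")
    retest <- stats::setNames(vapply(retest, `[[`, numeric(1), "value"), nm)
  }
  if (length(test) != length(retest)) {
    stop_invalid("test and retest estimates must be aligned")
  }
  if (!is.null(names(test)) && !is.null(names(retest))) {
    retest <- retest[names(test)]
  }
  units <- names(test) %||% as.character(seq_along(test))
  if (threshold <= 0) stop_invalid("threshold must be positive")
  denom <- (test + retest) / 2
  rel <- abs(test - retest) / denom
  reason <- rep("", length(test))
  undef <- denom == 0 & test != retest
  rel[undef] <- Inf
  reason[undef] <- "relative difference undefined (mean of pair is 0)"
  rel[denom == 0 & test == retest] <- 0
  flagged <- rel > threshold
  reason[flagged & !undef] <- sprintf(
    "relative difference %.3f exceeds threshold %.2f", rel[flagged & !undef],
    threshold)
  out <- data.frame(
    unit = units, test = as.numeric(test), retest = as.numeric(retest),
    relative_difference = as.numeric(rel), flagged = flagged,
    reason = reason, stringsAsFactors = FALSE, row.names = NULL
  )
  structure(out, class = c("outlier_report", "data.frame"),
            threshold = threshold, flagged_units = units[flagged])
}

#' Full test-retest reliability result for one series
#'
#' Computes pair counts, occasion means, both ICC forms and (for ordinal
#' series) the agreement proportions for a paired series.
#'
#' @param p a [paired_series()].
#' @return An object of class `reliability_result`.
#' @export
reliability_result <- function(p) {
  stopifnot(inherits(p, "paired_series"))
  icc1 <- icc_oneway(p)
  icc3 <- icc_twoway_mixed(p)
  props <- if (!is.null(p$scale)) agreement_proportions(p) else
    c(diff0 = NA_real_, diff1 = NA_real_, diff2plus = NA_real_)
  structure(
    list(
      n_pairs = length(p$unit_ids),
      mean_test = mean(p$test),
      mean_retest = mean(p$retest),
      icc_3_1 = as.numeric(icc3),
      icc_1_1 = as.numeric(icc1),
      prop_diff0 = props[["diff0"]],
      prop_diff1 = props[["diff1"]],
      prop_diff2plus = props[["diff2plus"]],
      undefined = c(icc_1_1 = isTRUE(attr(icc1, "undefined")),
                    icc_3_1 = isTRUE(attr(icc3, "undefined")),
                    proportions = is.null(p$scale)),
      dropped_units = attr(p, "dropped_units") %||% character()
    ),
    class = "reliability_result"
  )
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("Test-retest reliability over %d pairs\n", x$n_pairs))
  cat(sprintf("  mean test %.3f | mean retest %.3f\n", x$mean_test,
              x$mean_retest))
  cat(sprintf("  ICC(3,1) %.3f | ICC(1,1) %.3f\n", x$icc_3_1, x$icc_1_1))
  if (!is.na(x$prop_diff0)) {
    cat(sprintf("  agreement: %.1f%% identical, %.1f%% 1 point, %.1f%% >=2 points\n",
                100 * x$prop_diff0, 100 * x$prop_diff1,
                100 * x$prop_diff2plus))
  }
  invisible(x)
}

#' Assemble the test-retest agreement table
#'
#' Stacks the reliability results for weights, scores and value estimates
#' into the standard panel-report layout: one row per statistic, one column
#' per series.
#'
#' @param weights,scores,estimates [reliability_result()]s (any may be
#'   `NULL` to omit the column).
#' @return data.frame with a `statistic` column and one column per supplied
#'   series.
#' @export
reliability_table <- function(weights = NULL, scores = NULL,
                              estimates = NULL) {
  cols <- Filter(Negate(is.null),
                 list(weights = weights, scores = scores,
                      estimates = estimates))
  if (length(cols) == 0) stop_invalid("no reliability results supplied")
  stat_rows <- function(r) {
    c(n_pairs = r$n_pairs,
      mean_test = round(r$mean_test, 3),
      mean_retest = round(r$mean_retest, 3),
      icc_3_1 = round(r$icc_3_1, 3),
      icc_1_1 = round(r$icc_1_1, 3),
      pct_diff0 = if (is.na(r$prop_diff0)) NA else
        round(100 * r$prop_diff0, 1),
      pct_diff1 = if (is.na(r$prop_diff1)) NA else
        round(100 * r$prop_diff1, 1),
      pct_diff2plus = if (is.na(r$prop_diff2plus)) NA else
        round(100 * r$prop_diff2plus, 1))
  }
  mat <- vapply(cols, stat_rows, numeric(8))
  out <- data.frame(statistic = rownames(mat), mat, stringsAsFactors = FALSE,
                    row.names = NULL)
  names(out) <- c("statistic", names(cols))
  out
}
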