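#' Elicited weights for one panelist on one occasion
#'
#' Weights express the relative importance a panelist attaches to each
#' decision component, elicited independently of any intervention and from a
#' societal perspective on an integer scale (default 1--5, 5 = most
#' important).
#'
#' @param panelist_id opaque panelist label.
#' @param occasion `"test"` or `"retest"`.
#' @param weights named integer vector, one entry per weightable component.
#' @param f framework the weights are validated against.
#' @return An object of class `weight_set`.
#' @export
weight_set <- function(panelist_id, occasion, weights, f) {
  occasion <- match.arg(occasion, c("test", "retest"))
  ids <- weightable_ids(f)
  missing_ids <- setdiff(ids, names(weights))
  if (length(missing_ids) > 0) {
    stop_invalid("panelist '", panelist_id, "': missing weight(s) for ",
                 paste(missing_ids, collapse = ", "))
  }
  extra <- setdiff(names(weights), ids)
  if (length(extra) > 0) {
    stop_invalid("panelist '", panelist_id, "': weight(s) for unknown or ",
                 "unweightable component(s) ", paste(extra, collapse = ", "))
  }
  w <- weights[ids]
  bad <- names(w)[is.na(w) | w < f$weight_scale[1] | w > f$weight_scale[2] |
                    w != round(w)]
  if (length(bad) > 0) {
    stop_invalid("panelist '", panelist_id, "': weight out of ",
                 f$weight_scale[1], "-", f$weight_scale[2], " scale for ",
                 paste(bad, collapse = ", "))
  }
  structure(
    list(panelist_id = as.character(panelist_id), occasion = occasion,
         weights = stats::setNames(as.numeric(w), names(w))),
    class = "weight_set"
  )
}

#' Elicited scores for one panelist on one occasion
#'
#' Scores rate the intervention under appraisal against each component's
#' anchors on an integer scale (default 0--3; 0 = brings no value).
#' Not-applicable components carry no score. A panelist can flag a low score
#' as driven by data limitations rather than by demonstrated poor
#' performance.
#'
#' @inheritParams weight_set
#' @param scores named integer vector over scoreable components; components
#'   the panelist left unscored may be `NA` or absent.
#' @param data_limitation optional character vector of component ids whose
#'   score reflects data limitations.
#' @return An object of class `score_set`.
#' @export
score_set <- function(panelist_id, occasion, scores, f,
                      data_limitation = character()) {
  occasion <- match.arg(occasion, c("test", "retest"))
  ids <- scoreable_ids(f)
  extra <- setdiff(names(scores), ids)
  if (length(extra) > 0) {
    stop_invalid("panelist '", panelist_id, "': score(s) for unscoreable or ",
                 "unknown component(s) ", paste(extra, collapse = ", "))
  }
  s <- scores[!is.na(scores)]
  bad <- names(s)[s < f$score_scale[1] | s > f$score_scale[2] | s != round(s)]
  if (length(bad) > 0) {
    stop_invalid("panelist '", panelist_id, "': score out of ",
                 f$score_scale[1], "-", f$score_scale[2], " scale for ",
                 paste(bad, collapse = ", "))
  }
  structure(
    list(panelist_id = as.character(panelist_id), occasion = occasion,
         scores = stats::setNames(as.numeric(s), names(s)),
         data_limitation = intersect(as.character(data_limitation), ids)),
    class = "score_set"
  )
}

#' Normalize a panelist's weights over an inclusion set
#'
#' The linear additive model uses normalized weights
#' \eqn{\tilde w_i = w_i / \sum_{j \in included} w_j}, so a panelist's value
#' estimate stays on the scoring scale regardless of how many components are
#' included and of any common rescaling of the raw weights.
#'
#' @param w a [weight_set()].
#' @param included component ids forming the normalization set (defaults to
#'   all weighted components).
#' @return Named numeric vector of fractions summing to 1 over `included`.
#' @export
normalize_weights <- function(w, included = names(w$weights)) {
  stopifnot(inherits(w, "weight_set"))
  included <- as.character(included)
  if (length(included) == 0) stop_invalid("empty inclusion set")
  unknown <- setdiff(included, names(w$weights))
  if (length(unknown) > 0) {
    stop_invalid("included component(s) without weights: ",
                 paste(unknown, collapse = ", "))
  }
  raw <- w$weights[included]
  total <- sum(raw)
  if (total <= 0) stop_invalid("weights sum to zero over the inclusion set")
  raw / total
}

#' Per-panelist MCDA value estimate
#'
#' Applies the linear additive model \eqn{V = \sum_i \tilde w_i s_i} over the
#' components the panelist scored, with weights renormalized over that same
#' inclusion set. `V` lives on the scoring scale (0--3 by default): an
#' intervention scoring the maximum everywhere attains the scale maximum for
#' any weight profile.
#'
#' @param w a [weight_set()] and @param s a [score_set()] for the same
#'   panelist and occasion.
#' @param f the framework.
#' @return An object of class `value_estimate` with elements `panelist_id`,
#'   `occasion`, `included`, `normalized_weights`, `scores`, `value` and
#'   `percent_of_max`.
#' @examples
#' f <- evidem_framework()
#' w <- weight_set("p1", "test", setNames(rep(3, 15), f$components$id), f)
#' s <- score_set("p1", "test", setNames(rep(2, 15), f$components$id), f)
#' value_estimate(w, s, f)$value  # 2
#' @export
value_estimate <- function(w, s, f) {
  stopifnot(inherits(w, "weight_set"), inherits(s, "score_set"),
            inherits(f, "evidem_framework"))
  if (w$panelist_id != s$panelist_id || w$occasion != s$occasion) {
    stop_invalid("weight set (", w$panelist_id, "/", w$occasion,
                 ") and score set (", s$panelist_id, "/", s$occasion,
                 ") do not match")
  }
  included <- intersect(names(w$weights), names(s$scores))
  if (length(included) == 0) {
    stop_invalid("panelist '", w$panelist_id, "': no scored components")
  }
  nw <- normalize_weights(w, included)
  sc <- s$scores[included]
  v <- sum(nw * sc)
  structure(
    list(
      panelist_id = w$panelist_id,
      occasion = w$occasion,
      included = included,
      normalized_weights = nw,
      scores = sc,
      value = v,
      percent_of_max = percent_of_max(v, f)
    ),
    class = "value_estimate"
  )
}

#' Express a value estimate as percent of the scale maximum
#'
#' Converts a value on the scoring scale to an integer percent of the scale
#' maximum, rounding half away from zero (1.23 on a 0--3 scale is 41%).
#'
#' @param value value on the scoring scale.
#' @param f the framework supplying the scale maximum.
#' @return Integer percent.
#' @export
percent_of_max <- function(value, f) {
  lo <- f$score_scale[1]
  hi <- f$score_scale[2]
  if (any(value < lo - 1e-9) || any(value > hi + 1e-9)) {
    stop_invalid("value outside the ", lo, "-", hi, " scoring scale")
  }
  as.integer(round_half_away(100 * value / hi))
}

#' Decompose a value estimate into component contributions
#'
#' Each scored component contributes \eqn{100 \tilde w_i s_i / V} percent of
#' the estimate. When `V = 0` every contribution is zero and the result
#' carries a `degenerate` attribute flag instead of dividing by zero.
#'
#' @param v a [value_estimate()].
#' @return Named numeric vector of percents summing to 100 (when `V > 0`),
#'   with attribute `degenerate` set to `TRUE` when `V = 0`.
#' @export
component_contributions <- function(v) {
  stopifnot(inherits(v, "value_estimate"))
  parts <- v$normalized_weights * v$scores
  if (v$value > 0) {
    out <- 100 * parts / v$value
    attr(out, "degenerate") <- FALSE
  } else {
    out <- stats::setNames(numeric(length(parts)), names(parts))
    attr(out, "degenerate") <- TRUE
    warning("value estimate is 0; contributions undefined, reported as 0",
            call. = FALSE)
  }
  out
}

#' Aggregate component contributions by cluster
#'
#' @param v a [value_estimate()].
#' @param f the framework defining cluster membership.
#' @return Named numeric vector (one entry per cluster, in framework order)
#'   of percents; sums to 100 when the estimate is positive.
#' @export
cluster_contributions <- function(v, f) {
  cc <- suppressWarnings(component_contributions(v))
  cluster_of <- stats::setNames(f$components$cluster_id, f$components$id)
  out <- stats::setNames(numeric(nrow(f$clusters)), f$clusters$id)
  by_cl <- tapply(cc, cluster_of[names(cc)], sum)
  out[names(by_cl)] <- by_cl
  attr(out, "degenerate") <- attr(cc, "degenerate")
  out
}

#' @export
print.value_estimate <- function(x, ...) {
  cat(sprintf("MCDA value estimate: %.3f (%d%% of maximum) [%s, %s, %d components]\n",
              x$value, x$percent_of_max, x$panelist_id, x$occasion,
              length(x$included)))
  invisible(x)
}

#' Summarize a panel's value estimates
#'
#' Panel-level value is the mean of individual estimates (with sample SD,
#' minimum and maximum), not the estimate of mean inputs; the framework is a
#' value-clarification instrument, so between-panelist spread is part of the
#' result. Per-component weight means/SDs and mean contribution
#' decompositions are reported alongside.
#'
#' @param estimates list of [value_estimate()]s, one per panelist, all from
#'   the same occasion.
#' @param weights optional list of the matching [weight_set()]s, for the
#'   per-component weight statistics.
#' @param f optional framework; enables percent and cluster summaries.
#' @return An object of class `panel_summary`.
#' @export
panel_summary <- function(estimates, weights = NULL, f = NULL) {
  if (length(estimates) == 0) stop_invalid("no value estimates supplied")
  stopifnot(all(vapply(estimates, inherits, TRUE, "value_estimate")))
  vals <- vapply(estimates, `[[`, numeric(1), "value")
  n <- length(vals)
  single <- n < 2
  out <- list(
    n_panelists = n,
    occasion = unique(vapply(estimates, `[[`, character(1), "occasion")),
    value_mean = mean(vals),
    value_sd = if (single) 0 else stats::sd(vals),
    value_min = min(vals),
    value_max = max(vals),
    sd_undefined = single
  )
  if (!is.null(f)) {
    out$percent_mean <- percent_of_max(out$value_mean, f)
    out$percent_min <- percent_of_max(out$value_min, f)
    out$percent_max <- percent_of_max(out$value_max, f)
    contribs <- lapply(estimates, function(v) {
      suppressWarnings(component_contributions(v))
    })
    all_ids <- unique(unlist(lapply(contribs, names)))
    cmat <- vapply(contribs, function(x) {
      y <- stats::setNames(numeric(length(all_ids)), all_ids)
      y[names(x)] <- x
      y
    }, numeric(length(all_ids)))
    cmat <- matrix(cmat, nrow = length(all_ids),
                   dimnames = list(all_ids, NULL))
    out$mean_contributions <- rowMeans(cmat)
    cluster_of <- stats::setNames(f$components$cluster_id, f$components$id)
    out$mean_cluster_contributions <- stats::setNames(
      as.numeric(tapply(out$mean_contributions,
                        cluster_of[names(out$mean_contributions)], sum)[f$clusters$id]),
      f$clusters$id
    )
  }
  if (!is.null(weights)) {
    stopifnot(all(vapply(weights, inherits, TRUE, "weight_set")))
    wmat <- vapply(weights, `[[`, weights[[1]]$weights, "weights")
    wmat <- matrix(wmat, nrow = length(weights[[1]]$weights),
                   dimnames = list(names(weights[[1]]$weights), NULL))
    out$weight_stats <- data.frame(
      component_id = rownames(wmat),
      mean = rowMeans(wmat),
      sd = if (ncol(wmat) < 2) 0 else apply(wmat, 1, stats::sd),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  structure(out, class = "panel_summary")
}

#' @export
print.panel_summary <- function(x, ...) {
  cat(sprintf("Panel of %d: mean value %.2f (SD %.2f), range %.2f-%.2f\n",
              x$n_panelists, x$value_mean, x$value_sd, x$value_min,
              x$value_max))
  if (!is.null(x$percent_mean)) {
    cat(sprintf("  %d%% of maximum (range %d%%-%d%%)\n", x$percent_mean,
                x$percent_min, x$percent_max))
  }
  if (!is.null(x$mean_cluster_contributions)) {
    cat("  mean cluster contributions:",
        paste(sprintf("%s %.0f%%", names(x$mean_cluster_contributions),
                      x$mean_cluster_contributions), collapse = ", "), "\n")
  }
  invisible(x)
}
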