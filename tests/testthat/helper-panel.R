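# Shared fixture builders and the independent ICC oracle.

# A minimal 3-component framework for hand-checkable arithmetic.
mini_framework <- function() {
  framework(
    clusters = data.frame(id = "C", label = "Cluster",
                          stringsAsFactors = FALSE),
    components = data.frame(
      id = c("a", "b", "c"), cluster_id = "C",
      label = c("A", "B", "C"),
      low_anchor = "low", high_anchor = "high",
      weightable = TRUE, scoreable = TRUE, stringsAsFactors = FALSE
    )
  )
}

full_weights <- function(f, value = 3) {
  stats::setNames(rep(value, nrow(f$components)), f$components$id)
}

full_scores <- function(f, value = 2) {
  ids <- f$components$id[f$components$scoreable]
  stats::setNames(rep(value, length(ids)), ids)
}

# Independent ICC oracle: mean squares taken from stats::aov() model fits
# (one-way for ICC(1,1); occasion + unit two-way for ICC(3,1)), a different
# route than the package's explicit sums-of-squares arithmetic.
oracle_iccs <- function(test, retest) {
  n <- length(test)
  d <- data.frame(
    y = c(test, retest),
    unit = factor(rep(seq_len(n), 2)),
    occasion = factor(rep(1:2, each = n))
  )
  one <- summary(stats::aov(y ~ unit, data = d))[[1]]
  bms <- one["unit", "Mean Sq"]
  wms <- one["Residuals", "Mean Sq"]
  two <- summary(stats::aov(y ~ occasion + unit, data = d))[[1]]
  ems <- two["Residuals", "Mean Sq"]
  list(icc_1_1 = (bms - wms) / (bms + wms),
       icc_3_1 = (bms - ems) / (bms + ems))
}

random_paired_series <- function(n, scale = NULL) {
  if (is.null(scale)) {
    test <- rnorm(n)
    retest <- test + rnorm(n, sd = 0.5)
  } else {
    test <- sample(scale[1]:scale[2], n, replace = TRUE)
    retest <- test + sample(-1:1, n, replace = TRUE)
    retest <- pmin(pmax(retest, scale[1]), scale[2])
  }
  paired_series(paste0("u", seq_len(n)), test, retest, scale = scale)
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "evidemr", mustWork = TRUE)
}
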