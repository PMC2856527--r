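#' Define a decision framework
#'
#' A framework bundles the decision clusters, the quantifiable ("intrinsic")
#' value components with their scale anchors, the qualitative ("extrinsic")
#' components, and the elicitation scales. The shipped default
#' ([evidem_framework()]) carries 15 intrinsic components in four clusters
#' (quality of evidence, disease impact, intervention, economics) weighted on
#' 1--5 and scored on 0--3, plus six extrinsic components.
#'
#' @param clusters data.frame with columns `id`, `label`.
#' @param components data.frame of intrinsic components with columns `id`,
#'   `cluster_id`, `label`, `low_anchor`, `high_anchor`, `weightable`,
#'   `scoreable`.
#' @param extrinsic data.frame of extrinsic components with columns `id`,
#'   `label`, `definition`, `group` (`"ethical_framework"` or
#'   `"other_components"`). May have zero rows.
#' @param weight_scale,score_scale length-2 integer vectors `c(min, max)`.
#'   Weight scales start at 1 or above; score scales start at 0.
#' @return An object of class `evidem_framework`.
#' @seealso [validate_framework()], [evidem_framework()],
#'   [mark_not_applicable()]
#' @export
framework <- function(clusters, components, extrinsic = NULL,
                      weight_scale = c(1L, 5L), score_scale = c(0L, 3L)) {
  if (is.null(extrinsic)) {
    extrinsic <- data.frame(
      id = character(), label = character(), definition = character(),
      group = character(), stringsAsFactors = FALSE
    )
  }
  f <- structure(
    list(
      clusters = as.data.frame(clusters, stringsAsFactors = FALSE),
      components = as.data.frame(components, stringsAsFactors = FALSE),
      extrinsic = as.data.frame(extrinsic, stringsAsFactors = FALSE),
      weight_scale = as.integer(weight_scale),
      score_scale = as.integer(score_scale)
    ),
    class = "evidem_framework"
  )
  viol <- validate_framework(f)
  if (length(viol) > 0) {
    stop_invalid("invalid framework: ", paste(viol, collapse = "; "))
  }
  f
}

#' Validate a framework definition
#'
#' Checks the structural invariants (unique ids, resolvable cluster
#' references, non-empty anchors on scoreable components, legal scale bounds)
#' and returns the violations rather than throwing, so callers can report all
#' problems at once.
#'
#' @param f an `evidem_framework` (or a bare list with the same slots).
#' @return Character vector of violation messages; empty when `f` is valid.
#' @export
validate_framework <- function(f) {
  v <- character()
  cl <- f$clusters
  cp <- f$components
  ex <- f$extrinsic
  if (anyDuplicated(cl$id)) {
    v <- c(v, paste0("duplicate cluster id(s): ",
                     paste(unique(cl$id[duplicated(cl$id)]), collapse = ", ")))
  }
  if (anyDuplicated(cp$id)) {
    v <- c(v, paste0("duplicate component id(s): ",
                     paste(unique(cp$id[duplicated(cp$id)]), collapse = ", ")))
  }
  bad_ref <- setdiff(unique(cp$cluster_id), cl$id)
  for (x in bad_ref) {
    v <- c(v, paste0("component cluster reference '", x,
                     "' does not match any cluster"))
  }
  empty_cl <- setdiff(cl$id, cp$cluster_id)
  for (x in empty_cl) {
    v <- c(v, paste0("cluster '", x, "' has no components"))
  }
  if (nrow(cp) > 0) {
    sc <- cp[isTRUE_vec(cp$scoreable), , drop = FALSE]
    bad_anchor <- sc$id[!nzchar(sc$low_anchor) | !nzchar(sc$high_anchor)]
    for (x in bad_anchor) {
      v <- c(v, paste0("scoreable component '", x, "' has an empty anchor"))
    }
  }
  if (nrow(ex) > 0 && anyDuplicated(ex$id)) {
    v <- c(v, paste0("duplicate extrinsic id(s): ",
                     paste(unique(ex$id[duplicated(ex$id)]), collapse = ", ")))
  }
  both <- intersect(cp$id, ex$id)
  for (x in both) {
    v <- c(v, paste0("id '", x, "' is both intrinsic and extrinsic"))
  }
  ws <- f$weight_scale
  ss <- f$score_scale
  if (length(ws) != 2 || ws[1] < 1 || ws[2] <= ws[1]) {
    v <- c(v, "weight_scale must be c(min, max) with min >= 1 and max > min")
  }
  if (length(ss) != 2 || ss[1] != 0 || ss[2] <= ss[1]) {
    v <- c(v, "score_scale must be c(0, max) with max > 0")
  }
  v
}

isTRUE_vec <- function(x) !is.na(x) & x

#' The default EVIDEM value framework
#'
#' Returns the built-in framework: 15 intrinsic components with their scale
#' anchors, grouped as Q1--Q3 (quality of evidence), D1--D2 (disease impact),
#' I1--I7 (intervention) and E1--E3 (economics), weighted on a 1--5 scale and
#' scored on 0--3; plus the six extrinsic components of the Extrinsic Value
#' Tool (utility, efficiency and fairness forming an ethical framework;
#' system capacity/appropriate use, stakeholder pressures and
#' political/historical context as healthcare-system components).
#'
#' All components are scoreable in the shipped framework. Case-level
#' not-applicable components (e.g. a criterion a particular appraisal cannot
#' score) are expressed per evaluation with [mark_not_applicable()], which
#' keeps the component weightable but drops it from scoring.
#'
#' @param not_applicable character vector of component ids to mark
#'   not-scoreable for a specific case, convenience for
#'   `mark_not_applicable(evidem_framework(), ids)`.
#' @return An `evidem_framework`.
#' @examples
#' f <- evidem_framework()
#' nrow(f$components)            # 15
#' table(f$components$cluster_id)
#' @export
evidem_framework <- function(not_applicable = NULL) {
  clusters <- data.frame(
    id = c("Q", "D", "I", "E"),
    label = c("Quality of evidence", "Disease impact", "Intervention",
              "Economics"),
    stringsAsFactors = FALSE
  )
  components <- data.frame(
    id = c("Q1", "Q2", "Q3", "D1", "D2",
           "I1", "I2", "I3", "I4", "I5", "I6", "I7",
           "E1", "E2", "E3"),
    cluster_id = c("Q", "Q", "Q", "D", "D",
                   "I", "I", "I", "I", "I", "I", "I",
                   "E", "E", "E"),
    label = c(
      "Adherence to requirements of decisionmaking body",
      "Completeness and consistency of reporting evidence",
      "Relevance and validity of evidence",
      "Disease severity",
      "Size of population",
      "Clinical guidelines",
      "Comparative interventions limitations",
      "Improvement of efficacy/effectiveness",
      "Improvement of safety & tolerability",
      "Improvement of patient reported outcomes",
      "Public health interest",
      "Type of medical service",
      "Budget impact on health plan",
      "Cost-effectiveness of intervention",
      "Impact on other spending"
    ),
    low_anchor = c(
      "Low adherence",
      "Many gaps/inconsistent",
      "Low relevance/validity",
      "Not severe",
      "Very rare disease",
      "No recommendation",
      "No or very minor limitations",
      "Lower than comparators",
      "Lower than comparators",
      "Worse patient reported outcomes than comparators",
      "No risk reduction",
      "Minor service",
      "Substantial additional expenditures",
      "Not cost-effective",
      "Substantial additional spending"
    ),
    high_anchor = c(
      "High adherence",
      "Complete and consistent",
      "High relevance/validity",
      "Very severe",
      "Common disease",
      "Strong recommendation",
      "Major limitations",
      "Major improvement",
      "Major improvement",
      "Major improvement",
      "Major risk reduction",
      "Major service (e.g. cure)",
      "Substantial savings",
      "Highly cost-effective",
      "Substantial savings"
    ),
    weightable = TRUE,
    scoreable = TRUE,
    stringsAsFactors = FALSE
  )
  extrinsic <- data.frame(
    id = c("utility", "efficiency", "fairness",
           "system_capacity", "stakeholder_pressures", "political_context"),
    label = c(
      "Goals of healthcare - utility",
      "Opportunity costs - efficiency",
      "Population priority & access - fairness",
      "System capacity and appropriate use of intervention",
      "Stakeholder pressures",
      "Political/historical context"
    ),
    definition = c(
      "Alignment with the goal of healthcare to maintain normal functioning; the principle of producing the greatest benefit for the greatest number.",
      "Opportunity costs: resources or interventions forgone if this intervention is used; maximizing health impact for a given level of resources, at patient and society level.",
      "Population priorities and access: treating like cases alike, different cases differently, and priority to the worst-off.",
      "Capacity of the healthcare system to implement the intervention and ensure appropriate use: infrastructure, skills, legislation, risks of inappropriate use.",
      "Pressures and interests of stakeholder groups surrounding the intervention and how they may affect decisionmakers' values.",
      "Political priorities and historical context, including habits, traditions and precedence."
    ),
    group = c("ethical_framework", "ethical_framework", "ethical_framework",
              "other_components", "other_components", "other_components"),
    stringsAsFactors = FALSE
  )
  f <- framework(clusters, components, extrinsic,
                 weight_scale = c(1L, 5L), score_scale = c(0L, 3L))
  if (!is.null(not_applicable)) f <- mark_not_applicable(f, not_applicable)
  f
}

#' Mark components not applicable for a case evaluation
#'
#' Returns a copy of the framework with the given components flagged
#' `scoreable = FALSE`. Their elicited weights remain usable (e.g. for
#' reliability analysis) but they are excluded from value estimation and from
#' the weight-normalization denominator.
#'
#' @param f an `evidem_framework`.
#' @param ids component ids to mark not applicable.
#' @return The modified framework.
#' @export
mark_not_applicable <- function(f, ids) {
  stopifnot(inherits(f, "evidem_framework"))
  unknown <- setdiff(ids, f$components$id)
  if (length(unknown) > 0) {
    stop_invalid("unknown component id(s): ", paste(unknown, collapse = ", "))
  }
  f$components$scoreable[f$components$id %in% ids] <- FALSE
  f
}

# Components usable in each role.
weightable_ids <- function(f) f$components$id[isTRUE_vec(f$components$weightable)]
scoreable_ids <- function(f) f$components$id[isTRUE_vec(f$components$scoreable)]

#' @export
print.evidem_framework <- function(x, ...) {
  cat("Decision framework:", nrow(x$components), "intrinsic components in",
      nrow(x$clusters), "clusters;", nrow(x$extrinsic),
      "extrinsic components\n")
  cat("  weight scale", x$weight_scale[1], "to", x$weight_scale[2],
      "| score scale", x$score_scale[1], "to", x$score_scale[2], "\n")
  for (i in seq_len(nrow(x$clusters))) {
    cid <- x$clusters$id[i]
    members <- x$components$id[x$components$cluster_id == cid]
    cat(sprintf("  %s (%s): %s\n", cid, x$clusters$label[i],
                paste(members, collapse = ", ")))
  }
  na_ids <- x$components$id[!isTRUE_vec(x$components$scoreable)]
  if (length(na_ids) > 0) {
    cat("  not applicable (unscored):", paste(na_ids, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read or write a framework as JSON
#'
#' The JSON schema has top-level keys `clusters`, `components`, `extrinsic`,
#' `weight_scale`, `score_scale`, each mirroring the corresponding framework
#' slot. A bundled fixture encoding the default framework ships at
#' `system.file("extdata", "evidem_framework.json", package = "evidemr")`.
#'
#' @param path file path.
#' @param f an `evidem_framework`.
#' @return `read_framework_json()` returns an `evidem_framework`;
#'   `write_framework_json()` returns `path` invisibly.
#' @export
read_framework_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  framework(
    clusters = x$clusters,
    components = x$components,
    extrinsic = x$extrinsic,
    weight_scale = x$weight_scale,
    score_scale = x$score_scale
  )
}

#' @rdname read_framework_json
#' @export
write_framework_json <- function(f, path) {
  stopifnot(inherits(f, "evidem_framework"))
  jsonlite::write_json(
    list(
      clusters = f$clusters,
      components = f$components,
      extrinsic = f$extrinsic,
      weight_scale = f$weight_scale,
      score_scale = f$score_scale
    ),
    path,
    dataframe = "rows", auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(path)
}
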