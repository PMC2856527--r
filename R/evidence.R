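#' Evidence summary for one decision component
#'
#' The HTA layer attaches, to each component of the framework, a synthesized
#' account of the evidence panelists use when scoring.
#'
#' @param component_id a framework component id (intrinsic or extrinsic).
#' @param synthesized_text the synthesized evidence text.
#' @param source_refs character vector of citation labels.
#' @return An object of class `evidence_summary`.
#' @export
evidence_summary <- function(component_id, synthesized_text,
                             source_refs = character()) {
  structure(
    list(component_id = as.character(component_id),
         synthesized_text = as.character(synthesized_text),
         source_refs = as.character(source_refs)),
    class = "evidence_summary"
  )
}

quality_types <- c("clinical", "patient_reported_outcomes", "epidemiological",
                   "economic", "budget_impact")
quality_criteria <- c("completeness_consistency", "relevance_validity")
quality_stages <- c("first_reviewer", "second_reviewer", "expert_validated")

#' Quality Matrix assessment of one evidence cell
#'
#' Evidence quality is scored per evidence type (clinical, patient-reported
#' outcomes, epidemiological, economic, budget impact) on two criteria
#' (completeness/consistency of reporting; relevance/validity), moving
#' through a three-stage review: first reviewer, second reviewer, expert
#' validation. The stage field models that consensus process; selection
#' always prefers the most advanced stage.
#'
#' @param evidence_type one of `r paste(quality_types, collapse = ", ")`.
#' @param criterion `"completeness_consistency"` or `"relevance_validity"`.
#' @param score integer on the scoring scale (0--3 by default).
#' @param rationale free text justifying the score.
#' @param stage `"first_reviewer"`, `"second_reviewer"` or
#'   `"expert_validated"`.
#' @param f framework supplying the score scale (default 0--3).
#' @return An object of class `quality_assessment`.
#' @export
quality_assessment <- function(evidence_type, criterion, score, rationale = "",
                               stage = "first_reviewer", f = NULL) {
  evidence_type <- match.arg(evidence_type, quality_types)
  criterion <- match.arg(criterion, quality_criteria)
  stage <- match.arg(stage, quality_stages)
  scale <- if (!is.null(f)) f$score_scale else c(0L, 3L)
  if (is.na(score) || score < scale[1] || score > scale[2] ||
      score != round(score)) {
    stop_invalid("quality score must be an integer on the ", scale[1], "-",
                 scale[2], " scale")
  }
  structure(
    list(evidence_type = evidence_type, criterion = criterion,
         score = as.integer(score), rationale = as.character(rationale),
         stage = stage),
    class = "quality_assessment"
  )
}

#' Summarize Quality Matrix assessments by review stage
#'
#' For each (evidence type, criterion) cell, the assessment from the most
#' advanced review stage wins; two assessments at the same winning stage for
#' one cell are a conflict. Cells with no assessment are reported absent
#' (`NA` score).
#'
#' @param assessments list of [quality_assessment()]s.
#' @return data.frame with one row per (evidence_type, criterion) cell:
#'   `score`, `rationale`, `stage` (all `NA` for absent cells).
#' @export
quality_summary <- function(assessments) {
  stopifnot(all(vapply(assessments, inherits, TRUE, "quality_assessment")))
  grid <- expand.grid(evidence_type = quality_types,
                      criterion = quality_criteria,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cell <- Filter(function(a) {
      a$evidence_type == grid$evidence_type[i] &&
        a$criterion == grid$criterion[i]
    }, assessments)
    if (length(cell) == 0) {
      return(data.frame(evidence_type = grid$evidence_type[i],
                        criterion = grid$criterion[i],
                        score = NA_integer_, rationale = NA_character_,
                        stage = NA_character_, stringsAsFactors = FALSE))
    }
    ranks <- match(vapply(cell, `[[`, character(1), "stage"), quality_stages)
    top <- which(ranks == max(ranks))
    if (length(top) > 1) {
      stop_conflict("conflicting '", quality_stages[max(ranks)],
                    "' assessments for cell (", grid$evidence_type[i], ", ",
                    grid$criterion[i], ")")
    }
    a <- cell[[top]]
    data.frame(evidence_type = a$evidence_type, criterion = a$criterion,
               score = a$score, rationale = a$rationale, stage = a$stage,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Annual budget impact of covering a population
#'
#' The budget-impact arithmetic behind a framework's economics rows: annual
#' per-patient drug cost times the number of covered patients, exact.
#'
#' @param cost_per_patient_per_year non-negative currency amount.
#' @param n_patients non-negative patient count.
#' @return Exact product, in the same currency unit.
#' @examples
#' annual_budget_impact(28525, 396)                   # 11295900
#' format_budget_impact(annual_budget_impact(28525, 396))  # "$11.3 million"
#' @export
annual_budget_impact <- function(cost_per_patient_per_year, n_patients) {
  if (cost_per_patient_per_year < 0 || n_patients < 0) {
    stop_invalid("economic inputs must be non-negative")
  }
  cost_per_patient_per_year * n_patients
}

#' @rdname annual_budget_impact
#' @param amount currency amount to render.
#' @export
format_budget_impact <- function(amount) {
  if (amount >= 1e6) {
    paste0("$", format(signif(amount / 1e6, 3), trim = TRUE), " million")
  } else {
    paste0("$", format(amount, big.mark = ",", scientific = FALSE,
                       trim = TRUE))
  }
}

#' Attach evidence summaries (and quality assessments) to a framework
#'
#' Builds the case bundle the report renderer consumes: the framework joined
#' with per-component evidence texts and the Quality Matrix summary.
#'
#' @param f an `evidem_framework`.
#' @param summaries list of [evidence_summary()]s.
#' @param quality optional list of [quality_assessment()]s.
#' @param overview optional named list of free-text overview fields (disease,
#'   intervention, setting, ...).
#' @return An object of class `evidence_bundle`.
#' @export
attach_evidence <- function(f, summaries = list(), quality = NULL,
                            overview = NULL) {
  stopifnot(inherits(f, "evidem_framework"))
  known <- c(f$components$id, f$extrinsic$id)
  ids <- vapply(summaries, `[[`, character(1), "component_id")
  unknown <- setdiff(ids, known)
  if (length(unknown) > 0) {
    stop_invalid("evidence for unknown component id(s): ",
                 paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(ids)) {
    stop_conflict("multiple evidence summaries for component(s): ",
                  paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  structure(
    list(
      framework = f,
      summaries = stats::setNames(summaries, ids),
      quality = if (is.null(quality)) NULL else quality_summary(quality),
      overview = overview
    ),
    class = "evidence_bundle"
  )
}

#' @export
print.evidence_bundle <- function(x, ...) {
  cat("Evidence bundle:", length(x$summaries), "component summaries",
      if (!is.null(x$quality)) {
        paste0("; Quality Matrix over ", sum(!is.na(x$quality$score)),
               " assessed cells")
      } else "", "\n", sep = "")
  invisible(x)
}

#' Read or write an evidence bundle as JSON
#'
#' Schema: `overview` (named strings), `summaries` (rows of `component_id`,
#' `synthesized_text`, `source_refs`), `quality` (rows of `evidence_type`,
#' `criterion`, `score`, `rationale`, `stage`). The bundled
#' growth-hormone-for-Turner-syndrome fixture lives at
#' `system.file("extdata", "turner_gh_evidence.json", package = "evidemr")`
#' and pairs with `evidem_framework(not_applicable = "Q1")`.
#'
#' @param path JSON file path.
#' @param f framework the summaries attach to.
#' @return An `evidence_bundle`.
#' @export
read_evidence_json <- function(path, f) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  summaries <- lapply(seq_len(nrow(x$summaries)), function(i) {
    evidence_summary(x$summaries$component_id[i],
                     x$summaries$synthesized_text[i],
                     unlist(x$summaries$source_refs[i]))
  })
  quality <- NULL
  if (!is.null(x$quality) && NROW(x$quality) > 0) {
    quality <- lapply(seq_len(nrow(x$quality)), function(i) {
      quality_assessment(x$quality$evidence_type[i], x$quality$criterion[i],
                         x$quality$score[i], x$quality$rationale[i],
                         x$quality$stage[i], f = f)
    })
  }
  attach_evidence(f, summaries, quality, overview = as.list(x$overview))
}

#' The bundled illustrative case: growth hormone for Turner syndrome
#'
#' Loads the shipped evidence bundle for the illustrative appraisal of
#' growth hormone in Turner syndrome (Canadian setting), attached to the
#' default framework with Q1 marked not applicable for this case. The
#' evidence texts condense the published appraisal materials; the Quality
#' Matrix scores in the bundle are illustrative reconstructions consistent
#' with the recorded critical analysis (the original cell scores were not
#' published) and exercise the data model rather than the historical
#' record.
#'
#' @return An `evidence_bundle`.
#' @export
turner_gh_case <- function() {
  path <- system.file("extdata", "turner_gh_evidence.json",
                      package = "evidemr")
  read_evidence_json(path, evidem_framework(not_applicable = "Q1"))
}

#' Render an evidence bundle (with optional results) to markdown
#'
#' Emits the framework-shaped report: an overview block, intrinsic
#' components grouped by cluster with their anchors and evidence, the
#' Quality Matrix summary, the extrinsic components, and, when supplied,
#' the panel results (summary, reliability table, extrinsic tally).
#'
#' @param bundle an [attach_evidence()] bundle.
#' @param summary optional [panel_summary()].
#' @param reliability optional [reliability_table()] data.frame.
#' @param tally optional [extrinsic_tally()].
#' @return Character vector of markdown lines.
#' @export
render_report <- function(bundle, summary = NULL, reliability = NULL,
                          tally = NULL) {
  stopifnot(inherits(bundle, "evidence_bundle"))
  f <- bundle$framework
  out <- c("# Decision framework report", "")
  if (!is.null(bundle$overview)) {
    out <- c(out, "## Overview", "",
             vapply(names(bundle$overview), function(k) {
               paste0("- **", k, "**: ", bundle$overview[[k]])
             }, character(1)), "")
  }
  out <- c(out, "## Intrinsic value components", "")
  for (i in seq_len(nrow(f$clusters))) {
    cid <- f$clusters$id[i]
    out <- c(out, paste0("### ", f$clusters$label[i], " (", cid, ")"), "")
    members <- f$components[f$components$cluster_id == cid, , drop = FALSE]
    for (j in seq_len(nrow(members))) {
      m <- members[j, ]
      hdr <- paste0("**", m$id, " ", m$label, "**")
      if (!isTRUE_vec(m$scoreable)) {
        hdr <- paste0(hdr, " *(not applicable for this case)*")
      }
      out <- c(out, hdr, "",
               paste0("- anchors: 0 = ", m$low_anchor, "; ",
                      f$score_scale[2], " = ", m$high_anchor))
      sm <- bundle$summaries[[m$id]]
      if (!is.null(sm)) {
        out <- c(out, paste0("- evidence: ", sm$synthesized_text))
        if (length(sm$source_refs) > 0) {
          out <- c(out, paste0("- sources: ",
                               paste(sm$source_refs, collapse = "; ")))
        }
      }
      out <- c(out, "")
    }
  }
  if (!is.null(bundle$quality)) {
    q <- bundle$quality[!is.na(bundle$quality$score), , drop = FALSE]
    out <- c(out, "## Quality Matrix summary", "",
             "| Evidence type | Criterion | Score | Stage |",
             "|---|---|---|---|",
             sprintf("| %s | %s | %d | %s |", q$evidence_type, q$criterion,
                     q$score, q$stage), "")
  }
  if (nrow(f$extrinsic) > 0) {
    out <- c(out, "## Extrinsic value components", "")
    for (i in seq_len(nrow(f$extrinsic))) {
      e <- f$extrinsic[i, ]
      out <- c(out, paste0("**", e$label, "** (", e$group, ")"), "",
               paste0("- ", e$definition))
      sm <- bundle$summaries[[e$id]]
      if (!is.null(sm)) out <- c(out, paste0("- evidence: ",
                                             sm$synthesized_text))
      out <- c(out, "")
    }
  }
  if (!is.null(summary)) {
    out <- c(out, "## Panel value estimate", "",
             sprintf("- mean value %.2f (%d%% of maximum), SD %.2f, range %.2f-%.2f over %d panelists",
                     summary$value_mean,
                     summary$percent_mean %||% NA_integer_,
                     summary$value_sd, summary$value_min, summary$value_max,
                     summary$n_panelists))
    if (!is.null(summary$mean_cluster_contributions)) {
      out <- c(out, paste0("- mean cluster contributions: ",
                           paste(sprintf("%s %.0f%%",
                                         names(summary$mean_cluster_contributions),
                                         summary$mean_cluster_contributions),
                                 collapse = ", ")))
    }
    out <- c(out, "")
  }
  if (!is.null(reliability)) {
    hdr <- paste0("| ", paste(names(reliability), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(reliability)), collapse = "|"),
                  "|")
    body <- apply(reliability, 1, function(r) {
      paste0("| ", paste(r, collapse = " | "), " |")
    })
    out <- c(out, "## Test-retest agreement", "", hdr, sep, body, "")
  }
  if (!is.null(tally)) {
    out <- c(out, "## Extrinsic considerations", "",
             "| Component | Respondents | Would not consider | Positive | Negative | Mixed | None |",
             "|---|---|---|---|---|---|---|",
             sprintf("| %s | %d | %s | %d | %d | %d | %d |",
                     tally$component_id, tally$n_respondents,
                     ifelse(is.na(tally$pct_not_considering), "-",
                            paste0(tally$pct_not_considering, "%")),
                     tally$n_positive, tally$n_negative, tally$n_mixed,
                     tally$n_none), "")
  }
  out
}
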