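#' One panelist's judgment on one extrinsic component
#'
#' Extrinsic components (ethics and healthcare-system context) are not
#' quantified into the MCDA estimate; each panelist records whether the
#' component should be considered at all and, if so, whether it would impact
#' the intervention's value positively or negatively, with free-text
#' reasoning.
#'
#' @param panelist_id panelist label.
#' @param component_id an extrinsic component id.
#' @param considered `"yes"`, `"no"` or `"abstain"`.
#' @param impact `"positive"`, `"negative"`, `"mixed"`, `"none"` or
#'   `"not_applicable"`; must be `"not_applicable"` unless
#'   `considered = "yes"`.
#' @param comment free text.
#' @return An object of class `extrinsic_record`.
#' @export
extrinsic_record <- function(panelist_id, component_id, considered,
                             impact = "not_applicable", comment = "") {
  considered <- match.arg(considered, c("yes", "no", "abstain"))
  impact <- match.arg(impact,
                      c("positive", "negative", "mixed", "none",
                        "not_applicable"))
  if (considered != "yes" && impact != "not_applicable") {
    stop_invalid("panelist '", panelist_id, "', component '", component_id,
                 "': impact '", impact, "' given but considered='",
                 considered, "'")
  }
  structure(
    list(panelist_id = as.character(panelist_id),
         component_id = as.character(component_id),
         considered = considered, impact = impact,
         comment = as.character(comment)),
    class = "extrinsic_record"
  )
}

#' Validate an extrinsic record against a framework
#'
#' Checks that the record's component id is one of the framework's extrinsic
#' components. With `survey_mode = TRUE`, intrinsic ids are also accepted,
#' supporting a should-this-be-considered survey across the whole framework.
#'
#' @param r an [extrinsic_record()].
#' @param f the framework.
#' @param survey_mode also accept intrinsic component ids.
#' @return The record, invisibly, when valid; errors otherwise.
#' @export
record_consideration <- function(r, f, survey_mode = FALSE) {
  stopifnot(inherits(r, "extrinsic_record"), inherits(f, "evidem_framework"))
  allowed <- f$extrinsic$id
  if (survey_mode) allowed <- c(allowed, f$components$id)
  if (!r$component_id %in% allowed) {
    if (r$component_id %in% f$components$id) {
      stop_invalid("component '", r$component_id,
                   "' is intrinsic, not extrinsic (use survey_mode = TRUE ",
                   "to tally consideration of intrinsic components)")
    }
    stop_invalid("unknown extrinsic component '", r$component_id, "'")
  }
  invisible(r)
}

#' Tally extrinsic consideration records
#'
#' Per component: how many panelists responded, what fraction would not
#' consider the component (abstentions excluded from that fraction's
#' denominator), the impact-direction counts among those who would, and the
#' collated comments. Denominators are per-component respondent counts, not
#' the panel size, since not every panelist answers every item.
#'
#' @param records list of [extrinsic_record()]s; at most one per
#'   (panelist, component).
#' @param f optional framework; when given, records are validated first and
#'   components with no responses are reported too.
#' @param survey_mode passed to [record_consideration()].
#' @return An object of class `extrinsic_tally`: data.frame with one row per
#'   component (`n_respondents`, `n_yes`, `n_no`, `n_abstain`,
#'   `pct_not_considering` as integer percent or `NA`, impact counts,
#'   `comments`).
#' @examples
#' recs <- c(
#'   lapply(1:6, function(i)
#'     extrinsic_record(paste0("p", i), "stakeholder_pressures", "yes",
#'                      "negative")),
#'   lapply(7:9, function(i)
#'     extrinsic_record(paste0("p", i), "stakeholder_pressures", "no"))
#' )
#' extrinsic_tally(recs)$pct_not_considering  # 33
#' @export
extrinsic_tally <- function(records, f = NULL, survey_mode = FALSE) {
  stopifnot(all(vapply(records, inherits, TRUE, "extrinsic_record")))
  if (!is.null(f)) {
    lapply(records, record_consideration, f = f, survey_mode = survey_mode)
  }
  keys <- vapply(records, function(r) {
    paste(r$panelist_id, r$component_id, sep = "\r")
  }, character(1))
  if (anyDuplicated(keys)) {
    dup <- strsplit(keys[duplicated(keys)][1], "\r")[[1]]
    stop_conflict("duplicate record for panelist '", dup[1],
                  "', component '", dup[2], "'")
  }
  comp_ids <- unique(vapply(records, `[[`, character(1), "component_id"))
  if (!is.null(f)) {
    universe <- f$extrinsic$id
    if (survey_mode) universe <- c(universe, f$components$id)
    comp_ids <- union(intersect(universe, comp_ids), comp_ids)
    comp_ids <- c(comp_ids, setdiff(f$extrinsic$id, comp_ids))
  }
  rows <- lapply(comp_ids, function(cid) {
    rs <- Filter(function(r) r$component_id == cid, records)
    considered <- vapply(rs, `[[`, character(1), "considered")
    impact <- vapply(rs, `[[`, character(1), "impact")
    n_yes <- sum(considered == "yes")
    n_no <- sum(considered == "no")
    n_abstain <- sum(considered == "abstain")
    denom <- n_yes + n_no
    comments <- vapply(rs, `[[`, character(1), "comment")
    data.frame(
      component_id = cid,
      n_respondents = length(rs),
      n_yes = n_yes, n_no = n_no, n_abstain = n_abstain,
      pct_not_considering = if (denom > 0) {
        as.integer(round_half_away(100 * n_no / denom))
      } else NA_integer_,
      n_positive = sum(impact == "positive"),
      n_negative = sum(impact == "negative"),
      n_mixed = sum(impact == "mixed"),
      n_none = sum(impact == "none"),
      comments = paste(comments[nzchar(comments)], collapse = " | "),
      stringsAsFactors = FALSE
    )
  })
  structure(do.call(rbind, rows),
            class = c("extrinsic_tally", "data.frame"))
}

#' Read or write extrinsic records as a delimited table
#'
#' Columns: `panelist_id`, `component_id`, `considered`, `impact`,
#' `comment`; UTF-8, comma-separated, header row.
#'
#' @param path file path.
#' @param records list of [extrinsic_record()]s.
#' @return `read_extrinsic_table()` returns a list of records;
#'   `write_extrinsic_table()` returns `path` invisibly.
#' @export
read_extrinsic_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  need <- c("panelist_id", "component_id", "considered", "impact", "comment")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols) > 0) {
    stop_invalid("extrinsic table missing column(s): ",
                 paste(missing_cols, collapse = ", "))
  }
  lapply(seq_len(nrow(d)), function(i) {
    extrinsic_record(d$panelist_id[i], d$component_id[i], d$considered[i],
                     d$impact[i], d$comment[i])
  })
}

#' @rdname read_extrinsic_table
#' @export
write_extrinsic_table <- function(records, path) {
  d <- do.call(rbind, lapply(records, function(r) {
    data.frame(panelist_id = r$panelist_id, component_id = r$component_id,
               considered = r$considered, impact = r$impact,
               comment = r$comment, stringsAsFactors = FALSE)
  }))
  utils::write.csv(d, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
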