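#' Read panel weight/score tables
#'
#' The canonical dialect is a UTF-8 comma-separated table with a header row:
#' required columns `panelist_id` and `occasion` (`test`/`retest`), then one
#' column per component id. Scores for not-applicable or unscored components
#' are the literal `NA`. Every violation (unknown id, out-of-scale value,
#' missing column, bad token) is collected with its row/column coordinates;
#' in strict mode any violation aborts.
#'
#' @param weights_path,scores_path CSV paths (either may be `NULL` to skip).
#' @param f the framework to validate against.
#' @param occasion restrict to one occasion, or `"both"` (default).
#' @param strict abort on any violation instead of dropping offending rows.
#' @return List with `weights` and `scores` (each a list of sets keyed by
#'   `panelist:occasion`), and `violations` (data.frame with columns `file`,
#'   `row`, `column`, `message`).
#' @export
read_panel_tables <- function(weights_path = NULL, scores_path = NULL, f,
                              occasion = "both", strict = FALSE) {
  stopifnot(inherits(f, "evidem_framework"))
  occasion <- match.arg(occasion, c("both", "test", "retest"))
  violations <- data.frame(file = character(), row = integer(),
                           column = character(), message = character(),
                           stringsAsFactors = FALSE)
  note <- function(file, row, column, message) {
    violations <<- rbind(violations, data.frame(
      file = file, row = row, column = column, message = message,
      stringsAsFactors = FALSE))
  }

  parse_one <- function(path, kind) {
    ids <- if (kind == "weight") weightable_ids(f) else scoreable_ids(f)
    scale <- if (kind == "weight") f$weight_scale else f$score_scale
    d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    fname <- basename(path)
    for (col in c("panelist_id", "occasion")) {
      if (!col %in% names(d)) {
        stop_invalid(fname, ": malformed header, missing column '", col, "'")
      }
    }
    missing_ids <- setdiff(ids, names(d))
    for (m in missing_ids) note(fname, NA_integer_, m,
                                "missing component column")
    unknown <- setdiff(names(d), c("panelist_id", "occasion", ids))
    for (u in unknown) note(fname, NA_integer_, u,
                            "unknown component column (ignored)")
    have <- intersect(ids, names(d))
    sets <- list()
    for (i in seq_len(nrow(d))) {
      occ <- d$occasion[i]
      if (!occ %in% c("test", "retest")) {
        note(fname, i, "occasion", paste0("invalid occasion '", occ, "'"))
        next
      }
      if (occasion != "both" && occ != occasion) next
      vals <- suppressWarnings(as.numeric(unlist(d[i, have])))
      names(vals) <- have
      row_ok <- TRUE
      for (cid in have) {
        raw <- d[[cid]][i]
        v <- vals[[cid]]
        if (is.na(v)) {
          if (!is.na(raw) && !identical(toupper(trimws(as.character(raw))), "NA") &&
              nzchar(trimws(as.character(raw)))) {
            note(fname, i, cid, paste0("unparseable value '", raw, "'"))
            row_ok <- FALSE
          } else if (kind == "weight") {
            note(fname, i, cid, "missing weight (weights admit no NA)")
            row_ok <- FALSE
          }
          # a missing score is legal: counted later as a dropped unit
        } else if (v < scale[1] || v > scale[2] || v != round(v)) {
          note(fname, i, cid,
               paste0("value ", raw, " outside the integer ", scale[1], "-",
                      scale[2], " scale"))
          row_ok <- FALSE
        }
      }
      if (length(missing_ids) > 0 && kind == "weight") row_ok <- FALSE
      if (!row_ok) next
      key <- paste(d$panelist_id[i], occ, sep = ":")
      sets[[key]] <- if (kind == "weight") {
        weight_set(d$panelist_id[i], occ, vals, f)
      } else {
        score_set(d$panelist_id[i], occ, vals, f)
      }
    }
    sets
  }

  weights <- if (!is.null(weights_path)) parse_one(weights_path, "weight")
             else list()
  scores <- if (!is.null(scores_path)) parse_one(scores_path, "score")
            else list()
  if (strict && nrow(violations) > 0) {
    stop_invalid("panel table validation failed: ",
                 paste(sprintf("%s row %s col %s: %s", violations$file,
                               violations$row, violations$column,
                               violations$message), collapse = "; "))
  }
  list(weights = weights, scores = scores, violations = violations)
}

sets_to_frame <- function(sets, ids) {
  rows <- lapply(sets, function(s) {
    field <- if (inherits(s, "weight_set")) s$weights else s$scores
    vals <- stats::setNames(rep(NA_real_, length(ids)), ids)
    vals[names(field)] <- field
    cbind(data.frame(panelist_id = s$panelist_id, occasion = s$occasion,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(vals), check.names = FALSE))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Write panel weight/score tables
#'
#' Writes sets in the canonical dialect read by [read_panel_tables()]; a
#' write-then-read round trip is the identity on the typed data.
#'
#' @param sets list of [weight_set()]s or [score_set()]s.
#' @param path output CSV path.
#' @param f the framework (fixes the column order).
#' @return `path`, invisibly.
#' @export
write_panel_table <- function(sets, path, f) {
  stopifnot(length(sets) > 0)
  ids <- if (inherits(sets[[1]], "weight_set")) weightable_ids(f)
         else scoreable_ids(f)
  d <- sets_to_frame(sets, ids)
  utils::write.csv(d, path, row.names = FALSE, na = "NA",
                   fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

# Split a keyed set list by occasion, preserving panelist order.
split_occasions <- function(sets) {
  occ <- vapply(sets, `[[`, character(1), "occasion")
  list(test = unname(sets[occ == "test"]),
       retest = unname(sets[occ == "retest"]))
}

#' Serialize value estimates or a panel summary to JSON
#'
#' @param x a [value_estimate()], a list of them, or a [panel_summary()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(x, path) {
  strip <- function(v) {
    if (inherits(v, "value_estimate")) {
      list(panelist_id = v$panelist_id, occasion = v$occasion,
           value = v$value, percent_of_max = v$percent_of_max,
           normalized_weights = as.list(v$normalized_weights),
           scores = as.list(v$scores),
           contributions = as.list(suppressWarnings(component_contributions(v))))
    } else if (inherits(v, "panel_summary")) {
      unclass(v)
    } else if (is.list(v)) {
      lapply(v, strip)
    } else {
      v
    }
  }
  jsonlite::write_json(strip(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
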