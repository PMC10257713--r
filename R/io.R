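## Cohort serialization: one directory of UTF-8 CSVs with fixed headers.

cohort_schemas <- function() {
  list(
    subjects = c("subject_id", "group", "age", "gender", "scip_z",
                 "rgpts_b", "pdi21", "panss_p6", "panss_p1"),
    prl_trials = c("subject_id", "trial", "block", "choice", "outcome",
                   "points", "best_deck", "reversal", "transition"),
    horizon_trials = c("subject_id", "game", "horizon", "info", "trial",
                       "side", "forced", "reward", "gen_mean_left",
                       "gen_mean_right"),
    bade = c("subject_id", "scenario", "explanation", "stage", "rating"),
    questionnaires = c("subject_id", "instrument", "item", "score"),
    ground_truth = c("subject_id", "group"))
}

#' Write / read a cohort directory
#'
#' `write_cohort()` serializes a [generate_cohort()] result as tidy CSVs
#' (`subjects.csv`, `prl_trials.csv`, `horizon_trials.csv`, `bade.csv`,
#' `questionnaires.csv`, `ground_truth.csv`). `read_cohort()` loads and
#' validates such a directory: missing required columns, duplicated
#' subject ids, and malformed rows are reported with their location.
#' Unknown extra columns are preserved and passed through.
#'
#' @param cohort A `vb_cohort`.
#' @param dir Directory path (created if needed).
#' @return `write_cohort()`: `dir`, invisibly. `read_cohort()`: a
#'   `vb_cohort` list.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "vb_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(cohort_schemas())) {
    tb <- cohort[[nm]]
    if (is.null(tb)) next
    utils::write.csv(tb, file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  check_that(dir.exists(dir), paste0("Cohort directory not found: ", dir))
  schemas <- cohort_schemas()
  out <- list()
  for (nm in names(schemas)) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(path)) {
      if (nm %in% c("subjects", "questionnaires", "bade")) {
        abort(paste0("Required cohort file missing: ", nm, ".csv"))
      }
      out[[nm]] <- NULL
      next
    }
    tb <- tryCatch(
      as_tibble(utils::read.csv(path, fileEncoding = "UTF-8")),
      error = function(e) abort(paste0("Failed to parse ", nm, ".csv: ",
                                       conditionMessage(e))))
    missing <- setdiff(schemas[[nm]], names(tb))
    if (length(missing)) {
      abort(paste0(nm, ".csv is missing column(s): ",
                   paste(missing, collapse = ", ")))
    }
    bad <- which(is.na(tb$subject_id) | tb$subject_id == "")
    if (length(bad)) {
      abort(paste0(nm, ".csv has invalid subject_id at row(s): ",
                   paste(head(bad, 5), collapse = ", ")))
    }
    out[[nm]] <- tb
  }
  dups <- out$subjects$subject_id[duplicated(out$subjects$subject_id)]
  if (length(dups)) {
    abort(paste0("Duplicated subject id(s) in subjects.csv: ",
                 paste(unique(dups), collapse = ", ")))
  }
  if (!is.null(out$prl_trials)) {
    nonnum <- which(!is.numeric(out$prl_trials$choice))
    if (length(nonnum) || anyNA(out$prl_trials$choice)) {
      abort(paste0("prl_trials.csv has malformed choice at row(s): ",
                   paste(head(which(is.na(out$prl_trials$choice)), 5),
                         collapse = ", ")))
    }
  }
  structure(out, class = "vb_cohort")
}
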