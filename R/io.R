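# CSV interchange. One tabular format for studies (UTF-8, header row, "NR"
# sentinel for unreported counts): one row per study, or per center stratum
# for a multilab study reported by center.

STUDIES_REQUIRED <- c("study_id", "design", "comparison_id", "direction",
                      "mean_treat", "disp_treat", "n_treat",
                      "mean_control", "disp_control", "n_control",
                      "dispersion_kind")

#' Validate a studies data frame
#'
#' Checks the schema used throughout the package; row-level problems are
#' aggregated and reported together.
#'
#' @param studies Data frame to validate.
#' @return The input, invisibly, on success.
#' @export
validate_studies <- function(studies) {
  if (!is.data.frame(studies) || nrow(studies) == 0L) stop("studies table is empty")
  missing_cols <- setdiff(STUDIES_REQUIRED, names(studies))
  if (length(missing_cols)) stop("missing required column(s): ", toString(missing_cols))
  problems <- character()
  note <- function(rows, what) {
    if (length(rows)) problems <<- c(problems, paste0(what, " (row ", toString(rows), ")"))
  }
  num_cols <- c("mean_treat", "disp_treat", "n_treat",
                "mean_control", "disp_control", "n_control")
  for (cl in num_cols) {
    note(which(!is.finite(suppressWarnings(as.numeric(studies[[cl]])))),
         paste("non-numeric", cl))
  }
  note(which(!studies$design %in% c("multilab", "single")), "unknown design")
  note(which(!studies$direction %in% c("higher_is_better", "lower_is_better")),
       "unknown direction")
  note(which(!toupper(studies$dispersion_kind) %in% c("SD", "SE")),
       "unknown dispersion_kind")
  note(which(studies$n_treat < 1 | studies$n_control < 1), "nonpositive n")
  note(which(studies$disp_treat < 0 | studies$disp_control < 0), "negative dispersion")
  # duplicate ids are fine only as center strata of one multilab study
  dup <- unique(studies$study_id[duplicated(studies$study_id)])
  for (id in dup) {
    rows <- which(studies$study_id == id)
    if (any(studies$design[rows] != "multilab")) {
      note(rows, paste0("duplicate study_id '", id, "' outside multilab strata"))
    }
  }
  for (cid in unique(studies$comparison_id)) {
    rows <- studies[studies$comparison_id == cid, ]
    n_multi <- length(unique(rows$study_id[rows$design == "multilab"]))
    if (n_multi != 1L) {
      problems <- c(problems, paste0("comparison '", cid, "' has ", n_multi,
                                     " multilab studies (need exactly 1)"))
    }
    n_single <- length(unique(rows$study_id[rows$design == "single"]))
    if (n_single > 10L) {
      problems <- c(problems, paste0("comparison '", cid, "' has ", n_single,
                                     " single-lab studies (max 10)"))
    }
  }
  if (length(problems)) {
    stop("invalid studies table:\n  ", paste(problems, collapse = "\n  "))
  }
  invisible(studies)
}

#' Read a studies table from CSV
#'
#' @param path CSV with the columns of `STUDIES_REQUIRED` plus any of:
#'   `center`, `outcome_label`, `species`, `sex`, `year`, `total_animals`, the
#'   five quality-flag columns.
#' @return Validated data frame.
#' @export
read_studies <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  studies <- utils::read.csv(path, stringsAsFactors = FALSE)
  n_se <- sum(toupper(studies$dispersion_kind) == "SE", na.rm = TRUE)
  if (n_se > 0) message(n_se, " arm pair(s) report SE; SDs reconstructed as SE*sqrt(n)")
  validate_studies(studies)
  studies
}

#' Write a studies table to CSV
#'
#' @param studies Validated studies data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_studies <- function(studies, path) {
  validate_studies(studies)
  utils::write.csv(studies, path, row.names = FALSE)
  invisible(path)
}

#' Read a study-characteristics table from CSV
#'
#' One row per species cohort: `study_id`, `species`, `n` (count or "NR"),
#' and optionally `sex`, `year`, `centers_experimental`,
#' `centers_nonexperimental`, `dual_role_centers`.
#'
#' @param path CSV path.
#' @return Data frame (sample sizes kept as read; "NR" handled downstream).
#' @export
read_characteristics <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(n = "character"))
  need <- c("study_id", "species", "n")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) stop("missing required column(s): ", toString(missing_cols))
  x
}

#' Path to the bundled multilab characteristics table
#'
#' The characteristics of the sixteen published preclinical multilaboratory
#' studies that motivate this package (one row per species cohort; the
#' unreported sample size is "NR"; the dual-role coordinating center of one
#' stroke study is flagged so it is counted once).
#'
#' @return File path within the installed package.
#' @export
multilab_characteristics_path <- function() {
  system.file("extdata", "multilab_characteristics.csv",
              package = "multilabmeta", mustWork = TRUE)
}
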