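# Descriptive synthesis of study characteristics: sample sizes, species mix,
# sex, and the number of centers per multilaboratory study. One row per
# species cohort (a study running several species contributes one sample-size
# entry per cohort); "NR" marks an unreported count and is excluded from the
# median, range, and total.

RODENT_SPECIES <- c("mouse", "rat")

parse_nr <- function(x) {
  if (is.numeric(x)) return(x)
  x <- trimws(as.character(x))
  x[toupper(x) %in% c("NR", "NA", "")] <- NA
  bad <- !is.na(x) & is.na(suppressWarnings(as.numeric(x)))
  if (any(bad)) stop("non-numeric sample size(s) in row(s): ", toString(which(bad)))
  as.numeric(x)
}

#' Summarize sample sizes, species, and sex across cohorts
#'
#' @param cohorts Data frame with one row per species cohort: `species`,
#'   `n` (integer count or the string `"NR"`), and optionally `sex` and
#'   `study_id`.
#' @return A `characteristics_summary`: median and range of cohort sample
#'   sizes, total animals, percent of animals that are lab rodents (mouse or
#'   rat; exact value plus the integer used for display), species tallies, and
#'   sex tallies both per cohort and per study (when `study_id` is present).
#' @export
summarize_characteristics <- function(cohorts) {
  stopifnot(is.data.frame(cohorts), all(c("species", "n") %in% names(cohorts)))
  n <- parse_nr(cohorts$n)
  if (any(n < 0, na.rm = TRUE)) {
    stop("negative sample size(s) in row(s): ", toString(which(!is.na(n) & n < 0)))
  }
  usable <- !is.na(n)
  if (!any(usable)) stop("no usable sample sizes: all entries are NR")
  if (any(!usable)) {
    message("excluding ", sum(!usable), " NR sample-size row(s): ",
            toString(which(!usable)))
  }
  total <- sum(n[usable])
  species <- tolower(trimws(cohorts$species))
  rodent_total <- sum(n[usable & species %in% RODENT_SPECIES])
  pct_rodent <- 100 * rodent_total / total
  out <- list(
    median_n = stats::median(n[usable]),
    n_range = range(n[usable]),
    total_animals = total,
    pct_rodent = pct_rodent,
    pct_rodent_display = round(pct_rodent),
    n_cohorts = nrow(cohorts),
    n_excluded_nr = sum(!usable),
    species_counts = table(species)
  )
  if ("sex" %in% names(cohorts)) {
    out$sex_counts_cohort <- table(cohorts$sex)
    if ("study_id" %in% names(cohorts)) {
      per_study <- cohorts[!duplicated(cohorts$study_id), ]
      out$sex_counts_study <- table(per_study$sex)
    }
  }
  structure(out, class = "characteristics_summary")
}

#' @export
print.characteristics_summary <- function(x, ...) {
  cat(sprintf("Sample size: median %g (range %g-%g), total %g animals; %.0f%% lab rodents\n",
              x$median_n, x$n_range[1], x$n_range[2], x$total_animals, x$pct_rodent))
  invisible(x)
}

#' Summarize center counts across multilaboratory studies
#'
#' Total centers per study = experimental + non-experimental, with a center
#' holding both roles (e.g. an experimental site that also coordinates)
#' counted once via the `dual_role_centers` column.
#'
#' @param studies Data frame with one row per study (rows duplicated per
#'   cohort are collapsed on `study_id` if present): `centers_experimental`,
#'   `centers_nonexperimental`, and optionally `dual_role_centers`
#'   (default 0).
#' @return List with `median_total`, `range_total`, `median_experimental`,
#'   `range_experimental`, and the per-study `totals`.
#' @export
summarize_centers <- function(studies) {
  stopifnot(is.data.frame(studies))
  if ("study_id" %in% names(studies)) {
    studies <- studies[!duplicated(studies$study_id), , drop = FALSE]
  }
  if (!"centers_experimental" %in% names(studies)) {
    stop("missing centers_experimental column")
  }
  ce <- parse_nr(studies$centers_experimental)
  if (anyNA(ce)) {
    offenders <- if ("study_id" %in% names(studies)) {
      studies$study_id[is.na(ce)]
    } else which(is.na(ce))
    stop("missing experimental center count for study(ies): ", toString(offenders))
  }
  cn <- if ("centers_nonexperimental" %in% names(studies)) {
    parse_nr(studies$centers_nonexperimental)
  } else rep(0, nrow(studies))
  cn[is.na(cn)] <- 0
  dual <- if ("dual_role_centers" %in% names(studies)) {
    parse_nr(studies$dual_role_centers)
  } else rep(0, nrow(studies))
  dual[is.na(dual)] <- 0
  totals <- ce + cn - dual
  list(
    median_total = stats::median(totals), range_total = range(totals),
    median_experimental = stats::median(ce), range_experimental = range(ce),
    totals = totals
  )
}
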