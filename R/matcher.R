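# Similarity-based selection of single-lab studies for a comparison: rank
# candidates by a transparent weighted sum of per-feature similarities to the
# reference multilab study and keep the top k, breaking ties at the selection
# boundary with a seeded random draw so the selection is auditable and
# reproducible.

#' Configuration for similarity matching
#'
#' Binary features (species, sex) score 1 on a match; proximity features
#' (intervention timing, dose, measurement time, publication year) score
#' 1/(1 + |delta|) on their stated unit. A missing feature on either side
#' contributes 0.
#'
#' @param w_species,w_sex,w_timing,w_dose,w_measure_time,w_year Nonnegative
#'   feature weights (all default 1).
#' @param k Number of studies to select (default 10).
#' @param seed Integer seed for tie-breaking.
#' @return An object of class `similarity_config`.
#' @export
similarity_config <- function(w_species = 1, w_sex = 1, w_timing = 1,
                              w_dose = 1, w_measure_time = 1, w_year = 1,
                              k = 10, seed = 1L) {
  w <- c(species = w_species, sex = w_sex, timing = w_timing,
         dose = w_dose, measure_time = w_measure_time, year = w_year)
  if (any(w < 0)) stop("feature weights must be nonnegative")
  if (k < 1) stop("k must be at least 1")
  structure(list(weights = w, k = as.integer(k), seed = as.integer(seed)),
            class = "similarity_config")
}

feature_similarity <- function(candidate, reference) {
  bin <- function(a, b) {
    if (is.null(a) || is.null(b) || is.na(a) || is.na(b)) return(0)
    as.numeric(tolower(trimws(a)) == tolower(trimws(b)))
  }
  prox <- function(a, b) {
    if (is.null(a) || is.null(b) || is.na(a) || is.na(b)) return(0)
    1 / (1 + abs(as.numeric(a) - as.numeric(b)))
  }
  g <- function(x, f) if (f %in% names(x)) x[[f]] else NULL
  c(species = bin(g(candidate, "species"), g(reference, "species")),
    sex = bin(g(candidate, "sex"), g(reference, "sex")),
    timing = prox(g(candidate, "intervention_time"), g(reference, "intervention_time")),
    dose = prox(g(candidate, "dose"), g(reference, "dose")),
    measure_time = prox(g(candidate, "measurement_time"), g(reference, "measurement_time")),
    year = prox(g(candidate, "year"), g(reference, "year")))
}

#' Similarity of a candidate single-lab study to a reference multilab study
#'
#' @param candidate,reference Lists or one-row data frames with any of the
#'   fields `species`, `sex`, `intervention_time`, `dose`, `measurement_time`,
#'   `year`. Missing fields contribute 0.
#' @param cfg A [similarity_config()].
#' @return List with the total `score` and the per-feature `contributions`.
#' @export
similarity_score <- function(candidate, reference, cfg = similarity_config()) {
  stopifnot(inherits(cfg, "similarity_config"))
  sims <- feature_similarity(as.list(candidate), as.list(reference))
  contributions <- cfg$weights * sims
  list(score = sum(contributions), contributions = contributions)
}

#' Select the k candidates most similar to a reference study
#'
#' Candidates are sorted by descending similarity score. When a tie straddles
#' the k-th position, the tied candidates are chosen by a seeded uniform draw;
#' everything strictly above the tie band is always kept. With at most k
#' candidates, all are returned.
#'
#' @param candidates Data frame of candidate studies (one per row), with the
#'   feature columns of [similarity_score()] and any identifying columns.
#' @param reference The reference multilab study (list or one-row data frame).
#' @param cfg A [similarity_config()]; `cfg$seed` drives the tie-break draw.
#' @return The selected rows of `candidates`, ordered by descending score,
#'   with columns `similarity` and `tie_broken` appended.
#' @export
select_top_k <- function(candidates, reference, cfg = similarity_config()) {
  stopifnot(inherits(cfg, "similarity_config"))
  if (!is.data.frame(candidates) || nrow(candidates) == 0L) {
    stop("no candidate studies supplied")
  }
  scores <- vapply(seq_len(nrow(candidates)), function(i) {
    similarity_score(candidates[i, , drop = FALSE], reference, cfg)$score
  }, numeric(1))
  out <- candidates
  out$similarity <- scores
  out$tie_broken <- FALSE
  if (nrow(out) <= cfg$k) {
    return(out[order(-out$similarity), , drop = FALSE])
  }
  cutoff <- sort(scores, decreasing = TRUE)[cfg$k]
  above <- which(scores > cutoff)
  tied <- which(scores == cutoff)
  need <- cfg$k - length(above)
  if (need < length(tied)) {
    drawn <- withr::with_seed(cfg$seed, sample(tied, need))
    out$tie_broken[drawn] <- TRUE
    keep <- c(above, drawn)
  } else {
    keep <- c(above, tied)
  }
  sel <- out[keep, , drop = FALSE]
  sel[order(-sel$similarity), , drop = FALSE]
}
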