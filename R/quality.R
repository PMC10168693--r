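# Methodological-quality scoring: five binary bias-reducing practices
# (randomization, low-risk randomization method, blinding of personnel,
# blinding of the outcome assessor, complete outcome data), summed to a 0-5
# score and compared between designs with a Mann-Whitney U test.

#' Column names of the five quality-practice flags
#' @export
quality_flag_cols <- c("randomized", "rand_method_lowrob", "blind_personnel",
                       "blind_assessor", "complete_data")

#' Total quality score from the five practice flags
#'
#' @param flags A named numeric/integer vector or list with the five entries
#'   of [quality_flag_cols], or a data frame with those columns (one score per
#'   row). Each flag must be 0 or 1.
#' @return Integer score(s) in 0-5.
#' @export
#' @examples
#' total_score(c(randomized = 1, rand_method_lowrob = 0, blind_personnel = 1,
#'               blind_assessor = 1, complete_data = 0))
total_score <- function(flags) {
  if (is.data.frame(flags)) {
    missing_cols <- setdiff(quality_flag_cols, names(flags))
    if (length(missing_cols)) stop("missing quality flag(s): ", toString(missing_cols))
    m <- as.matrix(flags[quality_flag_cols])
  } else {
    flags <- unlist(flags)
    missing_cols <- setdiff(quality_flag_cols, names(flags))
    if (length(missing_cols)) stop("missing quality flag(s): ", toString(missing_cols))
    m <- matrix(flags[quality_flag_cols], nrow = 1)
  }
  if (anyNA(m) || !all(m %in% c(0, 1))) stop("quality flags must be 0 or 1")
  as.integer(rowSums(m))
}

#' Mann-Whitney U test between two groups
#'
#' U for group `a` is computed from midranks (ties allowed); the p-value comes
#' from the exact rank distribution when `n_a * n_b <= 400` and there are no
#' ties, and otherwise from the tie-corrected normal approximation with
#' continuity correction.
#'
#' @param a,b Numeric vectors (both nonempty).
#' @param exact Override the exact/approximate switch (logical), or `NULL` for
#'   the default rule.
#' @return List with `u` (for group `a`), `p_value`, `n_a`, `n_b`, `exact`.
#' @export
#' @examples
#' mann_whitney(c(3, 4, 5), c(1, 2)) # complete separation: U = 6, p = 0.2
mann_whitney <- function(a, b, exact = NULL) {
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be nonempty")
  r <- rank(c(a, b))
  u <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0
  if (is.null(exact)) exact <- length(a) * length(b) <= 400 && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  list(u = unname(u), p_value = wt$p.value,
       n_a = length(a), n_b = length(b), exact = exact && !ties)
}

#' Proportion of scores at or above a threshold
#'
#' @param scores Integer scores in 0-5.
#' @param threshold Cutoff (default 3).
#' @return Fraction in `[0, 1]`.
#' @export
proportion_at_least <- function(scores, threshold = 3) {
  if (length(scores) == 0L) stop("no scores")
  if (any(scores < 0 | scores > 5)) stop("scores must lie in 0-5")
  mean(scores >= threshold)
}

#' Compare quality scores between multilab and single-lab studies
#'
#' Scores every study on the five practices, summarizes each design as
#' median (range), tests the score distributions with a Mann-Whitney U test,
#' and tabulates the per-practice adherence percentages (descriptive only; the
#' individual practices are not tested).
#'
#' @param studies A studies data frame with `design` and the five flag columns.
#' @return An object of class `quality_comparison`.
#' @export
compare_quality <- function(studies) {
  stopifnot("design" %in% names(studies))
  scores <- total_score(studies)
  multi <- scores[studies$design == "multilab"]
  single <- scores[studies$design == "single"]
  if (length(multi) == 0L || length(single) == 0L) {
    stop("need at least one study of each design")
  }
  mw <- mann_whitney(multi, single)
  practice_pct <- function(design) {
    100 * colMeans(as.matrix(studies[studies$design == design, quality_flag_cols]))
  }
  structure(
    list(scores_multi = multi, scores_single = single,
         median_multi = stats::median(multi), range_multi = range(multi),
         median_single = stats::median(single), range_single = range(single),
         u_statistic = mw$u, p_value = mw$p_value,
         prop_ge3_multi = proportion_at_least(multi),
         prop_ge3_single = proportion_at_least(single),
         practice_pct = data.frame(
           practice = quality_flag_cols,
           multilab = unname(practice_pct("multilab")),
           single = unname(practice_pct("single"))
         )),
    class = "quality_comparison"
  )
}

#' @export
print.quality_comparison <- function(x, ...) {
  cat(sprintf("Quality scores: multilab median %g (range %g-%g, n = %d) vs single %g (range %g-%g, n = %d)\n",
              x$median_multi, x$range_multi[1], x$range_multi[2], length(x$scores_multi),
              x$median_single, x$range_single[1], x$range_single[2], length(x$scores_single)))
  cat(sprintf("  Mann-Whitney U = %g, two-sided p = %.3g\n", x$u_statistic, x$p_value))
  cat(sprintf("  scores >= 3: %.0f%% multilab vs %.0f%% single\n",
              100 * x$prop_ge3_multi, 100 * x$prop_ge3_single))
  invisible(x)
}
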