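# The design contrasts: per-comparison DSMD (difference in standardized mean
# differences, single-lab pool minus multilab estimate; > 0 means larger
# effects in single-lab studies) and ESR (ratio of the pooled single-lab
# effect to the multilab effect; 1 means no difference), plus their corpus
# level summaries.

#' Per-study standardized effects from a studies table
#'
#' Computes one oriented (benefit-positive) effect estimate per study. A
#' multilaboratory study reported as per-center strata (several rows sharing
#' `study_id`, distinguished by `center`) is reduced to a single estimate by
#' random-effects pooling of the per-center SMDs; a study reported as one
#' aggregate pair of arms is used directly.
#'
#' @param studies A studies data frame (see [read_studies()] for the schema).
#' @param metric `"g"` (default) or `"d"`.
#' @return A data frame with one row per study: `study_id`, `design`,
#'   `comparison_id`, `point`, `variance`, `se`, `ci_low`, `ci_high`,
#'   `n_strata`.
#' @export
study_effects <- function(studies, metric = c("g", "d")) {
  metric <- match.arg(metric)
  validate_studies(studies)
  ids <- unique(studies$study_id)
  rows <- lapply(ids, function(id) {
    s <- studies[studies$study_id == id, , drop = FALSE]
    ests <- lapply(seq_len(nrow(s)), function(i) {
      e <- smd(
        arm_summary(s$mean_treat[i], s$disp_treat[i], s$n_treat[i], s$dispersion_kind[i]),
        arm_summary(s$mean_control[i], s$disp_control[i], s$n_control[i], s$dispersion_kind[i]),
        metric = metric
      )
      orient(e, s$direction[i])
    })
    if (length(ests) > 1L) {
      p <- random_pool(ests)
      point <- p$point; variance <- p$se^2
    } else {
      point <- ests[[1]]$point; variance <- ests[[1]]$variance
    }
    data.frame(
      study_id = id, design = s$design[1], comparison_id = s$comparison_id[1],
      point = point, variance = variance, se = sqrt(variance),
      ci_low = point - 1.96 * sqrt(variance),
      ci_high = point + 1.96 * sqrt(variance),
      n_strata = nrow(s), stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Difference in standardized mean differences for one comparison
#'
#' DSMD = pooled single-lab effect minus the multilab effect, both on the
#' benefit-positive scale. The two designs are treated as independent, so
#' se^2 = se_single^2 + se_multi^2; the CI is the 95% z interval.
#'
#' @param d_single,d_multi `pooled_estimate` objects for the single-lab pool
#'   and the multilab study.
#' @param comparison_id Identifier carried through to reports.
#' @return An object of class `dsmd_result`.
#' @export
dsmd <- function(d_single, d_multi, comparison_id = NA_character_) {
  if (is.null(d_single) || is.null(d_multi)) {
    stop("comparison ", comparison_id, ": both a single-lab pool and a multilab estimate are required")
  }
  stopifnot(inherits(d_single, "pooled_estimate"), inherits(d_multi, "pooled_estimate"))
  est <- d_single$point - d_multi$point
  se <- sqrt(d_single$se^2 + d_multi$se^2)
  structure(
    list(comparison_id = comparison_id, dsmd = est, se = se,
         ci_low = est - 1.96 * se, ci_high = est + 1.96 * se,
         d_single = d_single, d_multi = d_multi),
    class = "dsmd_result"
  )
}

#' Effect size ratio for one comparison
#'
#' ESR = pooled single-lab effect / multilab effect. Ratios with a multilab
#' effect within `tol` of zero are flagged degenerate and excluded from the
#' median.
#'
#' @inheritParams dsmd
#' @param tol Denominator tolerance on the SMD scale.
#' @return An object of class `esr_result`.
#' @export
esr <- function(d_single, d_multi, comparison_id = NA_character_, tol = 1e-8) {
  stopifnot(inherits(d_single, "pooled_estimate"), inherits(d_multi, "pooled_estimate"))
  degenerate <- abs(d_multi$point) < tol
  if (degenerate) {
    warning("comparison ", comparison_id,
            ": multilab effect within tolerance of zero; ESR flagged degenerate")
  }
  structure(
    list(comparison_id = comparison_id,
         esr = if (degenerate) NA_real_ else d_single$point / d_multi$point,
         es_single = d_single$point, es_multi = d_multi$point,
         degenerate = degenerate),
    class = "esr_result"
  )
}

#' Pool per-comparison DSMDs across a corpus
#'
#' Random-effects (default) or fixed-effect inverse-variance pool of the
#' per-comparison DSMDs using their variances; `weights = "equal"` pools with
#' unit weights instead (simple mean with variance = mean variance / k).
#'
#' @param results List of `dsmd_result` objects.
#' @param method `"random"` (default) or `"fixed"`.
#' @param weights `"inverse_variance"` (default) or `"equal"`.
#' @return A `pooled_estimate` (two-sided z p-value in `p_value`).
#' @export
pool_dsmd <- function(results, method = c("random", "fixed"),
                      weights = c("inverse_variance", "equal")) {
  method <- match.arg(method)
  weights <- match.arg(weights)
  if (length(results) == 0L) stop("no DSMD results to pool")
  yi <- vapply(results, `[[`, numeric(1), "dsmd")
  vi <- vapply(results, `[[`, numeric(1), "se")^2
  if (weights == "equal") {
    k <- length(yi)
    return(new_pooled_estimate(mean(yi), sqrt(mean(vi) / k),
                               tau2 = 0, q = NA_real_, k = k, model = method))
  }
  if (method == "random") random_pool(yi, vi) else fixed_pool(yi, vi)
}

#' Median and range of non-degenerate ESRs
#'
#' @param results List of `esr_result` objects.
#' @return List with `median`, `range` (min, max) and `n_used`.
#' @export
median_esr <- function(results) {
  vals <- vapply(results, `[[`, numeric(1), "esr")
  deg <- vapply(results, `[[`, logical(1), "degenerate")
  if (any(deg)) message(sum(deg), " degenerate ESR(s) excluded from the median")
  vals <- vals[!deg]
  if (length(vals) == 0L) stop("no non-degenerate ESRs")
  list(median = stats::median(vals), range = range(vals), n_used = length(vals))
}

#' Count comparisons with larger single-lab effects
#'
#' Strictly positive DSMDs; exact zeros are reported separately as ties.
#'
#' @param results List of `dsmd_result` objects.
#' @return List with `n_positive`, `n_ties`, `n_total`.
#' @export
direction_count <- function(results) {
  if (length(results) == 0L) stop("no DSMD results")
  d <- vapply(results, `[[`, numeric(1), "dsmd")
  list(n_positive = sum(d > 0), n_ties = sum(d == 0), n_total = length(d))
}

#' Count comparisons whose design CIs are disjoint
#'
#' A comparison counts when the multilab 95% CI and the pooled single-lab 95%
#' CI do not intersect, i.e. the multilab interval falls entirely outside the
#' single-lab interval.
#'
#' @param results List of `dsmd_result` objects.
#' @return Integer count.
#' @export
ci_nonoverlap_count <- function(results) {
  sum(vapply(results, function(r) {
    r$d_multi$ci_high < r$d_single$ci_low || r$d_multi$ci_low > r$d_single$ci_high
  }, logical(1)))
}

#' Full design contrast over a studies table
#'
#' Runs the whole comparison: per-study SMDs, per-comparison pooling of the
#' single-lab studies (random effects, DerSimonian-Laird), the multilab
#' estimate, per-comparison DSMD and ESR, and the corpus summaries (pooled
#' DSMD, median ESR, direction and CI-nonoverlap counts).
#'
#' @inheritParams study_effects
#' @param pool_method,pool_weights Passed to [pool_dsmd()].
#' @param esr_tol Passed to [esr()].
#' @return A `contrast_report`: list with `pooled_dsmd`, `median_esr`,
#'   `n_single_larger`, `n_esr_gt_1`, `n_ci_nonoverlap`, `n_comparisons`,
#'   `dsmd_results`, `esr_results`, `effects`, `per_comparison` (data frame).
#' @export
design_contrast <- function(studies, metric = c("g", "d"),
                            pool_method = c("random", "fixed"),
                            pool_weights = c("inverse_variance", "equal"),
                            esr_tol = 1e-8) {
  metric <- match.arg(metric)
  effects <- study_effects(studies, metric = metric)
  cids <- unique(effects$comparison_id)
  dsmd_results <- vector("list", length(cids))
  esr_results <- vector("list", length(cids))
  for (i in seq_along(cids)) {
    e <- effects[effects$comparison_id == cids[i], , drop = FALSE]
    singles <- e[e$design == "single", , drop = FALSE]
    multi <- e[e$design == "multilab", , drop = FALSE]
    if (nrow(multi) != 1L || nrow(singles) < 1L) {
      stop("comparison ", cids[i],
           ": needs exactly one multilab study and at least one single-lab study")
    }
    d_single <- random_pool(singles)
    d_multi <- random_pool(multi)
    dsmd_results[[i]] <- dsmd(d_single, d_multi, cids[i])
    esr_results[[i]] <- suppressWarnings(esr(d_single, d_multi, cids[i], tol = esr_tol))
  }
  esr_vals <- vapply(esr_results, `[[`, numeric(1), "esr")
  per_comparison <- data.frame(
    comparison_id = cids,
    dsmd = vapply(dsmd_results, `[[`, numeric(1), "dsmd"),
    dsmd_se = vapply(dsmd_results, `[[`, numeric(1), "se"),
    dsmd_ci_low = vapply(dsmd_results, `[[`, numeric(1), "ci_low"),
    dsmd_ci_high = vapply(dsmd_results, `[[`, numeric(1), "ci_high"),
    es_single = vapply(dsmd_results, function(r) r$d_single$point, numeric(1)),
    es_multi = vapply(dsmd_results, function(r) r$d_multi$point, numeric(1)),
    esr = esr_vals,
    stringsAsFactors = FALSE
  )
  structure(
    list(
      pooled_dsmd = pool_dsmd(dsmd_results, method = pool_method, weights = pool_weights),
      median_esr = suppressMessages(median_esr(esr_results)),
      n_single_larger = direction_count(dsmd_results)$n_positive,
      n_esr_gt_1 = sum(esr_vals > 1, na.rm = TRUE),
      n_ci_nonoverlap = ci_nonoverlap_count(dsmd_results),
      n_comparisons = length(cids),
      dsmd_results = dsmd_results, esr_results = esr_results,
      effects = effects, per_comparison = per_comparison,
      metric = metric
    ),
    class = "contrast_report"
  )
}

#' @export
print.contrast_report <- function(x, ...) {
  p <- x$pooled_dsmd
  cat(sprintf("Design contrast over %d comparisons (metric: %s)\n",
              x$n_comparisons, x$metric))
  cat(sprintf("  pooled DSMD: %.2f [95%% CI %.2f, %.2f], z p = %.3g\n",
              p$point, p$ci_low, p$ci_high, p$p_value))
  cat(sprintf("  median ESR: %.2f (range %.2f-%.2f)\n",
              x$median_esr$median, x$median_esr$range[1], x$median_esr$range[2]))
  cat(sprintf("  single-lab effect larger in %d/%d; ESR > 1 in %d/%d; disjoint CIs in %d/%d\n",
              x$n_single_larger, x$n_comparisons, x$n_esr_gt_1, x$n_comparisons,
              x$n_ci_nonoverlap, x$n_comparisons))
  invisible(x)
}
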