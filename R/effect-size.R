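#' Pooled standard deviation of two arms
#'
#' Denominator of the standardized mean difference: the square root of the
#' degrees-of-freedom weighted average of the two arm variances.
#'
#' @param sd_t,sd_c Arm standard deviations (>= 0).
#' @param n_t,n_c Arm sample sizes (each >= 2).
#' @return Nonnegative scalar.
#' @export
#' @examples
#' pooled_sd(2, 3, 1, 5) # sqrt((2*4 + 4*1)/6)
pooled_sd <- function(sd_t, n_t, sd_c, n_c) {
  if (any(c(sd_t, sd_c) < 0)) stop("standard deviations must be nonnegative")
  if (n_t < 2 || n_c < 2) stop("degrees of freedom exhausted: each arm needs n >= 2")
  sqrt(((n_t - 1) * sd_t^2 + (n_c - 1) * sd_c^2) / (n_t + n_c - 2))
}

#' Small-sample correction factor for Hedges' g
#'
#' Approximate correction J = 1 - 3/(4*df - 1), with df = n_t + n_c - 2.
#'
#' @param df Degrees of freedom (>= 1).
#' @return Scalar in (0, 1).
#' @export
hedges_j <- function(df) {
  if (any(df < 1)) stop("need df >= 1 for the small-sample correction")
  1 - 3 / (4 * df - 1)
}

#' Convert a reported dispersion to a standard deviation
#'
#' Extraction sheets report either the SD or the SE of an arm mean; the SE is
#' converted back with SE * sqrt(n).
#'
#' @param dispersion Reported value (>= 0).
#' @param kind `"SD"` or `"SE"`.
#' @param n Arm sample size.
#' @return Standard deviation on the native scale.
#' @export
dispersion_to_sd <- function(dispersion, kind, n) {
  kind <- match.arg(toupper(kind), c("SD", "SE"))
  if (any(dispersion < 0, na.rm = TRUE)) stop("dispersion must be nonnegative")
  if (kind == "SE") dispersion * sqrt(n) else dispersion
}

#' Construct an arm summary
#'
#' One experimental arm's summary statistics as extracted from a report.
#'
#' @param mean Arm mean on the native outcome scale.
#' @param dispersion Nonnegative dispersion value.
#' @param n Positive integer animal count.
#' @param dispersion_kind `"SD"` (default) or `"SE"`.
#' @return An object of class `arm_summary`.
#' @export
arm_summary <- function(mean, dispersion, n, dispersion_kind = "SD") {
  dispersion_kind <- match.arg(toupper(dispersion_kind), c("SD", "SE"))
  if (!is.finite(mean)) stop("arm mean must be finite")
  if (!is.finite(dispersion) || dispersion < 0) stop("dispersion must be nonnegative")
  if (!is.finite(n) || n < 1 || n != round(n)) stop("n must be a positive integer")
  structure(
    list(mean = mean, dispersion = dispersion, n = as.integer(n),
         dispersion_kind = dispersion_kind,
         sd = dispersion_to_sd(dispersion, dispersion_kind, n)),
    class = "arm_summary"
  )
}

new_effect_estimate <- function(point, variance, metric, n_treat, n_control,
                                degenerate = FALSE) {
  se <- sqrt(variance)
  structure(
    list(point = point, variance = variance, se = se,
         ci_low = point - 1.96 * se, ci_high = point + 1.96 * se,
         metric = metric, n_treat = n_treat, n_control = n_control,
         degenerate = degenerate),
    class = "effect_estimate"
  )
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("%s = %.4f (SE %.4f), 95%% CI [%.4f, %.4f], n = %d/%d\n",
              x$metric, x$point, x$se, x$ci_low, x$ci_high,
              x$n_treat, x$n_control))
  invisible(x)
}

#' Standardized mean difference between two arms
#'
#' Computes Cohen's d or, by default, Hedges' g (d scaled by the small-sample
#' correction J), with the large-sample variance
#' var(d) = (n_t + n_c)/(n_t * n_c) + d^2 / (2 (n_t + n_c)) and a 95% normal
#' confidence interval. Dispersions reported as SEs are converted to SDs
#' before pooling.
#'
#' @param treat,control `arm_summary` objects.
#' @param metric `"g"` (default, small-sample corrected) or `"d"`.
#' @return An `effect_estimate`.
#' @export
#' @examples
#' smd(arm_summary(1, 1, 100), arm_summary(0, 1, 100), metric = "g")
smd <- function(treat, control, metric = c("g", "d")) {
  metric <- match.arg(metric)
  stopifnot(inherits(treat, "arm_summary"), inherits(control, "arm_summary"))
  n_t <- treat$n
  n_c <- control$n
  s_pool <- pooled_sd(treat$sd, n_t, control$sd, n_c)
  if (s_pool == 0) {
    if (treat$mean != control$mean) {
      stop("undefined SMD: pooled SD is zero with unequal means")
    }
    return(new_effect_estimate(0, NA_real_, metric, n_t, n_c, degenerate = TRUE))
  }
  d <- (treat$mean - control$mean) / s_pool
  v <- (n_t + n_c) / (n_t * n_c) + d^2 / (2 * (n_t + n_c))
  if (metric == "g") {
    j <- hedges_j(n_t + n_c - 2)
    d <- j * d
    v <- j^2 * v
  }
  new_effect_estimate(d, v, metric, n_t, n_c)
}

#' Orient an effect estimate so that positive favours treatment
#'
#' Outcomes where lower values are better (e.g. infarct volume) yield negative
#' raw SMDs for beneficial treatments; flipping the sign puts every outcome on
#' a common benefit-positive scale. Variance is unchanged and the CI bounds
#' swap.
#'
#' @param e An `effect_estimate`.
#' @param direction `"higher_is_better"` or `"lower_is_better"`.
#' @return An `effect_estimate` on the benefit-positive scale.
#' @export
orient <- function(e, direction = c("higher_is_better", "lower_is_better")) {
  direction <- match.arg(direction)
  stopifnot(inherits(e, "effect_estimate"))
  if (direction == "lower_is_better") {
    lo <- -e$ci_high
    hi <- -e$ci_low
    e$point <- -e$point
    e$ci_low <- lo
    e$ci_high <- hi
  }
  e
}
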