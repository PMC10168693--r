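# Inverse-variance pooling with DerSimonian-Laird heterogeneity. Inputs are
# vectors of estimates and their variances (or objects coercible to them);
# outputs carry tau2, Cochran's Q and a 95% z interval.

as_yi_vi <- function(yi, vi = NULL) {
  if (is.null(vi)) {
    if (is.data.frame(yi)) {
      vi <- yi$variance
      yi <- yi$point
    } else if (is.list(yi) && all(vapply(yi, inherits, logical(1), "effect_estimate"))) {
      vi <- vapply(yi, `[[`, numeric(1), "variance")
      yi <- vapply(yi, `[[`, numeric(1), "point")
    } else {
      stop("supply variances, a data frame with point/variance, or a list of effect estimates")
    }
  }
  if (length(yi) == 0L) stop("no estimates to pool")
  if (length(yi) != length(vi)) stop("estimates and variances differ in length")
  if (any(!is.finite(yi)) || any(!is.finite(vi)) || any(vi <= 0)) {
    stop("all estimates must be finite with positive variance")
  }
  list(yi = yi, vi = vi)
}

new_pooled_estimate <- function(point, se, tau2, q, k, model) {
  structure(
    list(point = point, se = se,
         ci_low = point - 1.96 * se, ci_high = point + 1.96 * se,
         tau2 = tau2, q = q, df = k - 1L, k = k, model = model,
         p_value = 2 * stats::pnorm(-abs(point / se))),
    class = "pooled_estimate"
  )
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("%s-effects pool (k = %d): %.4f (SE %.4f), 95%% CI [%.4f, %.4f]\n",
              x$model, x$k, x$point, x$se, x$ci_low, x$ci_high))
  cat(sprintf("  tau2 = %.4f, Q = %.4f (df %d), z p = %.4g\n",
              x$tau2, x$q, x$df, x$p_value))
  invisible(x)
}

#' Fixed-effect inverse-variance pooling
#'
#' Weights each estimate by the reciprocal of its variance.
#'
#' @param yi Estimates: a numeric vector, a data frame with `point` and
#'   `variance` columns, or a list of `effect_estimate` objects.
#' @param vi Variances (when `yi` is a numeric vector).
#' @return A `pooled_estimate` with `model = "fixed"`.
#' @export
fixed_pool <- function(yi, vi = NULL) {
  x <- as_yi_vi(yi, vi)
  w <- 1 / x$vi
  q <- sum(w * (x$yi - sum(w * x$yi) / sum(w))^2)
  new_pooled_estimate(sum(w * x$yi) / sum(w), sqrt(1 / sum(w)),
                      tau2 = 0, q = q, k = length(x$yi), model = "fixed")
}

#' DerSimonian-Laird between-study variance
#'
#' Method-of-moments estimator from Cochran's Q, truncated at zero:
#' tau2 = max(0, (Q - (k-1)) / C) with C = sum(w) - sum(w^2)/sum(w).
#' A single study carries no heterogeneity information; tau2 is 0.
#'
#' @inheritParams fixed_pool
#' @return Nonnegative scalar.
#' @export
dl_tau2 <- function(yi, vi = NULL) {
  x <- as_yi_vi(yi, vi)
  k <- length(x$yi)
  if (k < 2) {
    message("tau2 requires k >= 2; returning 0 for a single estimate")
    return(0)
  }
  w <- 1 / x$vi
  xbar <- sum(w * x$yi) / sum(w)
  q <- sum(w * (x$yi - xbar)^2)
  cc <- sum(w) - sum(w^2) / sum(w)
  max(0, (q - (k - 1)) / cc)
}

#' Random-effects inverse-variance pooling (DerSimonian-Laird)
#'
#' Adds the DL tau2 to each within-study variance before inverse-variance
#' weighting; the 95% CI is the plain z interval. With a single estimate the
#' pool is that estimate (tau2 = 0), which is how a lone multilaboratory study
#' enters a design contrast.
#'
#' @inheritParams fixed_pool
#' @return A `pooled_estimate` with `model = "random"`.
#' @export
random_pool <- function(yi, vi = NULL) {
  x <- as_yi_vi(yi, vi)
  k <- length(x$yi)
  if (k == 1) {
    return(new_pooled_estimate(x$yi, sqrt(x$vi), tau2 = 0, q = 0,
                               k = 1L, model = "random"))
  }
  tau2 <- suppressMessages(dl_tau2(x$yi, x$vi))
  fe <- fixed_pool(x$yi, x$vi)
  w <- 1 / (x$vi + tau2)
  new_pooled_estimate(sum(w * x$yi) / sum(w), sqrt(1 / sum(w)),
                      tau2 = tau2, q = fe$q, k = k, model = "random")
}
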