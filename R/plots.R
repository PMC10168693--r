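# Forest plots. Plots are artifacts for inspection; the numeric tables are
# the contract.

#' Forest plot of per-comparison DSMDs with the pooled estimate
#'
#' One row per comparison plus the pooled diamond row; the dashed line marks
#' DSMD = 0 (no design difference).
#'
#' @param report A `contrast_report` from [design_contrast()].
#' @return A ggplot object.
#' @export
plot_dsmd_forest <- function(report) {
  stopifnot(inherits(report, "contrast_report"))
  pc <- report$per_comparison
  pooled <- report$pooled_dsmd
  df <- rbind(
    data.frame(label = pc$comparison_id, est = pc$dsmd,
               lo = pc$dsmd_ci_low, hi = pc$dsmd_ci_high, pooled = FALSE),
    data.frame(label = "Pooled", est = pooled$point,
               lo = pooled$ci_low, hi = pooled$ci_high, pooled = TRUE)
  )
  df$label <- factor(df$label, levels = rev(df$label))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$est, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$pooled, size = .data$pooled)) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 15, `TRUE` = 18), guide = "none") +
    ggplot2::scale_size_manual(values = c(`FALSE` = 2, `TRUE` = 4), guide = "none") +
    ggplot2::labs(x = "DSMD (single-lab pool minus multilab)", y = NULL,
                  title = "Difference in standardized mean differences") +
    ggplot2::theme_minimal()
}

#' Per-comparison forest panels: single-lab studies, their pool, the multilab study
#'
#' @param report A `contrast_report` from [design_contrast()].
#' @return A ggplot object faceted by comparison.
#' @export
plot_comparison_forest <- function(report) {
  stopifnot(inherits(report, "contrast_report"))
  eff <- report$effects
  rows <- lapply(report$dsmd_results, function(r) {
    e <- eff[eff$comparison_id == r$comparison_id, ]
    singles <- e[e$design == "single", ]
    data.frame(
      comparison = r$comparison_id,
      label = c(singles$study_id, "Single-lab pool", "Multilab"),
      est = c(singles$point, r$d_single$point, r$d_multi$point),
      lo = c(singles$ci_low, r$d_single$ci_low, r$d_multi$ci_low),
      hi = c(singles$ci_high, r$d_single$ci_high, r$d_multi$ci_high),
      kind = c(rep("single", nrow(singles)), "pool", "multilab")
    )
  })
  df <- do.call(rbind, rows)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$est,
                                   y = stats::reorder(.data$label, .data$est),
                                   colour = .data$kind)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.2) +
    ggplot2::geom_point(size = 1.8) +
    ggplot2::facet_wrap(~comparison, scales = "free_y") +
    ggplot2::labs(x = "Standardized mean difference (benefit-positive)",
                  y = NULL, colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}
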