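# ggplot2 autoplot methods for the package's result objects.

#' Plot a ROC summary
#'
#' ROC curve with the Youden operating point marked; set `type = "pr"`
#' for the precision-recall curve with its prevalence baseline.
#'
#' @param object A `mash_roc`.
#' @param type `"roc"` or `"pr"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mash_roc <- function(object, type = c("roc", "pr"), ...) {
  type <- match.arg(type)
  cv <- object$curve
  if (type == "roc") {
    op <- cv[which.min(abs(cv$threshold - object$youden$cutoff)), ]
    ggplot2::ggplot(cv, ggplot2::aes(x = 1 - .data$specificity,
                                     y = .data$sensitivity)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                           colour = "grey60") +
      ggplot2::geom_path() +
      ggplot2::geom_point(data = op, colour = "red", size = 2) +
      ggplot2::labs(
        x = "1 - specificity", y = "Sensitivity",
        title = sprintf("ROC curve (AUC = %.3f)", object$roc_auc),
        subtitle = sprintf("Youden cutoff %.3f: sens %.1f%%, spec %.1f%%",
                           object$youden$cutoff,
                           100 * object$youden$sensitivity,
                           100 * object$youden$specificity)) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(cv, ggplot2::aes(x = .data$recall,
                                     y = .data$precision)) +
      ggplot2::geom_hline(yintercept = object$prevalence, linetype = 2,
                          colour = "grey60") +
      ggplot2::geom_path() +
      ggplot2::labs(x = "Recall", y = "Precision",
                    title = sprintf("Precision-recall curve (AUC = %.3f)",
                                    object$pr_auc)) +
      ggplot2::theme_minimal()
  }
}

#' Plot per-behavior correction distributions
#'
#' Boxplots of the per-day correction minutes (harmonized minus
#' pre-harmonization) per behavior, over corrected days.
#'
#' @param object A `mash_corrections`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mash_corrections <- function(object, ...) {
  dd <- object$days |>
    filter(.data$corrected) |>
    select(SB = "corr_sb_min", LLPA = "corr_llpa_min",
           HLPA = "corr_hlpa_min", MVPA = "corr_mvpa_min") |>
    pivot_longer(dplyr::everything(), names_to = "behavior",
                 values_to = "correction_min") |>
    mutate(behavior = factor(.data$behavior,
                             levels = c("SB", "LLPA", "HLPA", "MVPA")))
  ggplot2::ggplot(dd, ggplot2::aes(x = .data$behavior,
                                   y = .data$correction_min)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_boxplot(outlier.alpha = 0.2) +
    ggplot2::labs(x = NULL, y = "Correction (min, harmonized - raw)",
                  title = "Waking-behavior corrections on corrected days") +
    ggplot2::theme_minimal()
}

#' Plot the fitted wake-length / removal-gap sample
#'
#' Scatter of the fitted (wake length, gap) pairs with 2-D density
#' contours, clipped to the bounded support.
#'
#' @param object A `mash_gapdist`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mash_gapdist <- function(object, ...) {
  ggplot2::ggplot(object$samples,
                  ggplot2::aes(x = .data$length, y = .data$gap)) +
    ggplot2::geom_point(alpha = 0.3) +
    ggplot2::geom_density_2d(colour = "steelblue") +
    ggplot2::labs(x = "Wake interval length (min, bounded)",
                  y = "Hip removal gap before onset (min)",
                  title = sprintf("Removal-gap distribution (n = %d)",
                                  object$n)) +
    ggplot2::theme_minimal()
}

#' Plot wake-interval sizes pre and post harmonization
#'
#' Overlaid density of the pre-harmonization waking wear estimate and the
#' harmonized wake-interval length, the distributional shift the
#' harmonization is designed to produce.
#'
#' @param harmony A `mash_harmony`.
#' @return A ggplot object.
#' @export
plot_interval_sizes <- function(harmony) {
  cc <- harmony$compositions
  dd <- bind_rows(
    tibble(size = cc$pre_sb_min + cc$pre_llpa_min + cc$pre_hlpa_min +
             cc$pre_mvpa_min, which = "Pre-harmonization waking wear"),
    tibble(size = cc$sb_min + cc$llpa_min + cc$hlpa_min + cc$mvpa_min,
           which = "Harmonized waking behavior")
  )
  ggplot2::ggplot(dd, ggplot2::aes(x = .data$size, colour = .data$which)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "Waking behavior minutes per day", colour = NULL,
                  title = "Waking time before and after harmonization") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}
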