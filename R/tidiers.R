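# broom-style tidy()/glance() methods for the package's result objects.

#' Tidy a ROC summary into its threshold curve
#'
#' @param x A `mash_roc`.
#' @param ... Unused.
#' @return The threshold-level curve tibble.
#' @export
tidy.mash_roc <- function(x, ...) x$curve

#' @rdname tidy.mash_roc
#' @return For `glance()`: a one-row tibble of the scalar summaries.
#' @export
glance.mash_roc <- function(x, ...) {
  tibble(roc_auc = x$roc_auc, pr_auc = x$pr_auc,
         prevalence = x$prevalence, youden_cutoff = x$youden$cutoff,
         sensitivity = x$youden$sensitivity,
         specificity = x$youden$specificity, n = x$n)
}

#' Tidy a trained wake-interval CNN bundle
#'
#' @param x A `mash_cnn`.
#' @param ... Unused.
#' @return `tidy()`: the per-epoch training history; `glance()`: a
#'   one-row summary with the cutoff contract.
#' @export
tidy.mash_cnn <- function(x, ...) x$history

#' @rdname tidy.mash_cnn
#' @export
glance.mash_cnn <- function(x, ...) {
  tibble(variant = x$variant, window_len = x$window_len,
         n_channels = length(x$channels),
         cutoff = x$cutoff, cutoff_j = x$cutoff_j,
         sensitivity = x$cutoff_sensitivity,
         specificity = x$cutoff_specificity,
         epochs_trained = nrow(x$history))
}

#' Tidy harmonization results
#'
#' @param x A `mash_harmony`.
#' @param ... Unused.
#' @return `tidy()`: the day-level composition tibble; `glance()`: a
#'   one-row summary of routing and correction rates.
#' @export
tidy.mash_harmony <- function(x, ...) x$compositions

#' @rdname tidy.mash_harmony
#' @export
glance.mash_harmony <- function(x, ...) {
  cc <- x$compositions
  tibble(
    n_days = nrow(x$ledger),
    n_kept = nrow(cc),
    n_scored = sum(cc$tier == "SCORED"),
    n_cnn = sum(cc$tier == "CNN"),
    pct_corrected = 100 * mean(cc$corrected),
    mean_interval_size_h = mean(cc$interval_size_h)
  )
}

#' Tidy a correction summary
#'
#' @param x A `mash_corrections`.
#' @param ... Unused.
#' @return `tidy()`: the per-behavior median/IQR table; `glance()`: a
#'   one-row overview.
#' @export
tidy.mash_corrections <- function(x, ...) x$summary

#' @rdname tidy.mash_corrections
#' @export
glance.mash_corrections <- function(x, ...) {
  tibble(n_days = x$n_days, n_corrected = x$n_corrected,
         pct_corrected = 100 * x$n_corrected / x$n_days)
}

#' Tidy a fitted removal-gap distribution
#'
#' @param x A `mash_gapdist`.
#' @param ... Unused.
#' @return `tidy()`: the fitted (length, gap) sample; `glance()`: a
#'   one-row summary of bounds, bandwidths and the gap mean.
#' @export
tidy.mash_gapdist <- function(x, ...) x$samples

#' @rdname tidy.mash_gapdist
#' @export
glance.mash_gapdist <- function(x, ...) {
  tibble(n = x$n, gap_mean = mean(x$samples$gap),
         gap_bw = x$bw[["gap"]], length_bw = x$bw[["length"]],
         gap_lower = x$bounds$gap[1L], gap_upper = x$bounds$gap[2L])
}
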