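# Model and pipeline evaluation: ROC / precision-recall curves with
# trapezoidal AUCs, Youden operating point, pre/post correction summaries
# and paired t-tests.

#' ROC and precision-recall summary for epoch probabilities
#'
#' Computes the full ROC and PR curves over the distinct observed scores,
#' trapezoidal areas under both (ties share concordance credit, so the
#' ROC area equals the pairwise concordance probability), the PR baseline
#' (positive prevalence), and the Youden-J operating point.
#'
#' @param prob Numeric scores/probabilities.
#' @param labels Binary labels (0/1 or logical).
#' @return A `mash_roc` object with elements `curve` (tibble of
#'   `threshold`, `sensitivity`, `specificity`, `precision`, `recall`),
#'   `roc_auc`, `pr_auc`, `prevalence`, `youden`, `n`.
#' @export
roc_pr <- function(prob, labels) {
  y <- as.integer(labels)
  stopifnot(length(prob) == length(y))
  if (length(unique(y)) < 2L) {
    abort("both classes must be present", class = "mash_value_error")
  }
  ord <- order(prob, decreasing = TRUE)
  p <- prob[ord]; yy <- y[ord]
  P <- sum(yy); N <- length(yy) - P
  last <- which(!duplicated(p, fromLast = TRUE))
  tp <- cumsum(yy)[last]
  fp <- cumsum(1L - yy)[last]
  curve <- tibble(
    threshold = p[last],
    sensitivity = tp / P,
    specificity = 1 - fp / N,
    precision = ifelse(tp + fp > 0, tp / (tp + fp), 1),
    recall = tp / P
  )
  tpr <- c(0, curve$sensitivity, 1)
  fpr <- c(0, 1 - curve$specificity, 1)
  roc_auc <- sum(diff(fpr) * (head(tpr, -1L) + tail(tpr, -1L)) / 2)
  rec <- c(0, curve$recall)
  prec <- c(curve$precision[1L], curve$precision)
  pr_auc <- sum(diff(rec) * (head(prec, -1L) + tail(prec, -1L)) / 2)
  yj <- youden_cutoff(prob, y)
  structure(list(curve = curve, roc_auc = roc_auc, pr_auc = pr_auc,
                 prevalence = P / length(yy), youden = yj,
                 n = length(yy)),
            class = "mash_roc")
}

#' @export
print.mash_roc <- function(x, ...) {
  cat(sprintf(
    "<mash_roc> n = %d; ROC-AUC %.3f; PR-AUC %.3f (baseline %.3f); cutoff %.3f (sens %.1f%%, spec %.1f%%)\n",
    x$n, x$roc_auc, x$pr_auc, x$prevalence, x$youden$cutoff,
    100 * x$youden$sensitivity, 100 * x$youden$specificity))
  invisible(x)
}

iqr_string <- function(x) {
  q <- quantile(x, c(0.5, 0.25, 0.75), type = 7, na.rm = TRUE)
  sprintf("%.1f (%.1f, %.1f)", q[1L], q[2L], q[3L])
}

#' Summarize MASH corrections across compositions
#'
#' Medians and interquartile ranges (type-7 quantiles) of the per-day
#' correction minutes, per behavior and for total wake time, both over
#' all days and over corrected days only; paired t-tests of
#' pre-harmonization versus harmonized minutes per behavior. Sleep is
#' excluded from the t-tests because tier-2 days have no pre-harmonization
#' sleep measurement.
#'
#' @param compositions The `compositions` tibble of a `mash_harmony`.
#' @return A `mash_corrections` object with `summary`, `tests`, `n_days`,
#'   `n_corrected`, and the day-level `days` table used.
#' @export
summarize_corrections <- function(compositions) {
  cc <- compositions
  beh <- c(total_wake = "corr_total_wake_min", SB = "corr_sb_min",
           LLPA = "corr_llpa_min", HLPA = "corr_hlpa_min",
           MVPA = "corr_mvpa_min")
  qs <- function(x) {
    q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, na.rm = TRUE)
    tibble(q25 = q[[1L]], median = q[[2L]], q75 = q[[3L]])
  }
  summary <- map_dfr(names(beh), function(b) {
    x <- cc[[beh[[b]]]]
    bind_rows(
      qs(x) |> mutate(behavior = b, scope = "all_days", .before = 1L),
      qs(x[cc$corrected]) |> mutate(behavior = b, scope = "corrected_days",
                                    .before = 1L)
    )
  })
  pre_cols <- c(SB = "pre_sb_min", LLPA = "pre_llpa_min",
                HLPA = "pre_hlpa_min", MVPA = "pre_mvpa_min")
  post_cols <- c(SB = "sb_min", LLPA = "llpa_min", HLPA = "hlpa_min",
                 MVPA = "mvpa_min")
  tests <- map_dfr(names(pre_cols), function(b) {
    pre <- cc[[pre_cols[[b]]]]
    post <- cc[[post_cols[[b]]]]
    if (length(pre) < 2L || sd(post - pre, na.rm = TRUE) == 0 ||
        all(is.na(post - pre))) {
      return(tibble(behavior = b, statistic = NA_real_, p_value = NA_real_,
                    df = NA_real_, mean_diff = mean(post - pre, na.rm = TRUE),
                    note = "degenerate differences"))
    }
    tt <- t.test(post, pre, paired = TRUE)
    tibble(behavior = b, statistic = unname(tt$statistic),
           p_value = tt$p.value, df = unname(tt$parameter),
           mean_diff = unname(tt$estimate), note = NA_character_)
  })
  structure(list(summary = summary, tests = tests,
                 n_days = nrow(cc), n_corrected = sum(cc$corrected),
                 days = cc),
            class = "mash_corrections")
}

#' @export
print.mash_corrections <- function(x, ...) {
  med <- x$summary |>
    filter(.data$scope == "corrected_days")
  cat("<mash_corrections>", x$n_days, "days,", x$n_corrected,
      sprintf("corrected (%.1f%%)\n", 100 * x$n_corrected / x$n_days))
  for (i in seq_len(nrow(med))) {
    cat(sprintf("  %-10s median (IQR) %.1f (%.1f, %.1f) min\n",
                med$behavior[i], med$median[i], med$q25[i], med$q75[i]))
  }
  invisible(x)
}

#' Render a plain-text performance report
#'
#' Assembles the evaluation quantities (ROC/PR per model variant,
#' correction summaries) into a deterministic text report; every number is
#' traceable to a [roc_pr()] or [summarize_corrections()] result. Missing
#' variants produce a partial report with a warning.
#'
#' @param roc_dual,roc_hip `mash_roc` objects for the two variants.
#' @param corrections A `mash_corrections`.
#' @param out_dir Optional directory; when given, tables are written as
#'   CSV and curves as a PNG alongside the text report.
#' @return Character vector of report lines (class `mash_report`),
#'   invisibly when writing to `out_dir`.
#' @export
performance_report <- function(roc_dual = NULL, roc_hip = NULL,
                               corrections = NULL, out_dir = NULL) {
  lines <- c("MASH performance report", "=======================")
  fmt_roc <- function(r, label) {
    c(sprintf("%s model: ROC-AUC %.3f; PR-AUC %.3f (baseline %.3f)",
              label, r$roc_auc, r$pr_auc, r$prevalence),
      sprintf("  Youden cutoff %.3f: sensitivity %.1f%%, specificity %.1f%% (n = %d)",
              r$youden$cutoff, 100 * r$youden$sensitivity,
              100 * r$youden$specificity, r$n))
  }
  if (!is.null(roc_dual)) lines <- c(lines, fmt_roc(roc_dual, "Dual-device"))
  if (!is.null(roc_hip)) lines <- c(lines, fmt_roc(roc_hip, "Hip-only"))
  if (is.null(roc_dual) || is.null(roc_hip)) {
    warn("performance report covers a single model variant")
  }
  if (!is.null(corrections)) {
    med <- corrections$summary |> filter(.data$scope == "corrected_days")
    lines <- c(lines, sprintf(
      "Corrections: %d/%d days corrected (%.1f%%)",
      corrections$n_corrected, corrections$n_days,
      100 * corrections$n_corrected / corrections$n_days))
    lines <- c(lines, vapply(seq_len(nrow(med)), function(i) {
      sprintf("  %s correction median (IQR): %.1f (%.1f, %.1f) min",
              med$behavior[i], med$median[i], med$q25[i], med$q75[i])
    }, character(1)))
  }
  res <- structure(lines, class = "mash_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(lines, file.path(out_dir, "report.txt"))
    if (!is.null(corrections)) {
      readr::write_csv(corrections$summary,
                       file.path(out_dir, "correction_summary.csv"))
      readr::write_csv(corrections$tests,
                       file.path(out_dir, "paired_tests.csv"))
    }
    for (nm in c("dual", "hip")) {
      r <- if (nm == "dual") roc_dual else roc_hip
      if (!is.null(r)) {
        readr::write_csv(r$curve, file.path(out_dir,
                                            paste0("roc_", nm, ".csv")))
      }
    }
    return(invisible(res))
  }
  res
}

#' @export
print.mash_report <- function(x, ...) {
  cat(paste(unclass(x), collapse = "\n"), "\n")
  invisible(x)
}
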