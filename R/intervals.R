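# From epoch probabilities to a single predicted wake interval per day,
# and the bounded-KDE correction of CNN-predicted sleep onsets for the
# hip-removal confusion.

#' Predicted wake interval from epoch probabilities
#'
#' Binarizes the probabilities at the model cutoff, forms maximal runs of
#' supra-cutoff epochs, merges runs separated by sub-cutoff gaps shorter
#' than `merge_gap` minutes into clusters, and selects the cluster with
#' the largest summed probability (over its supra-cutoff epochs). The
#' interval is half-open over epochs: `[first epoch, last epoch + 1)`.
#'
#' @param prob Numeric vector of per-epoch probabilities on a contiguous
#'   60-s grid.
#' @param cutoff Classification cutoff (epoch is "wake" when
#'   `prob >= cutoff`).
#' @param merge_gap Maximum sub-cutoff gap (minutes) merged into one
#'   cluster.
#' @return A list with 1-based `start_idx`, `end_idx` (exclusive),
#'   `score`, and `n_runs`, or `NULL` when no epoch reaches the cutoff
#'   (day unresolvable).
#' @export
wake_interval_from_probs <- function(prob, cutoff, merge_gap = 120L) {
  above <- prob >= cutoff
  if (!any(above)) return(NULL)
  r <- runs_tbl(above) |> filter(.data$value)
  gap_prev <- c(Inf, r$start[-1L] - r$end[-nrow(r)] - 1L)
  cluster <- cumsum(gap_prev >= merge_gap)
  cs <- c(0, cumsum(prob))
  run_score <- cs[r$end + 1L] - cs[r$start]
  agg <- tibble(cluster = cluster, start = r$start, end = r$end,
                score = run_score) |>
    group_by(.data$cluster) |>
    summarise(start = min(.data$start), end = max(.data$end),
              score = sum(.data$score), n_runs = n(), .groups = "drop")
  best <- agg[which.max(agg$score), ]
  list(start_idx = best$start, end_idx = best$end + 1L,
       score = best$score, n_runs = best$n_runs)
}

#' Fit the bounded bivariate wake-length / removal-gap distribution
#'
#' From valid scored-sleep records with an observable hip removal (the hip
#' device is in Choi non-wear during the minute preceding scored onset,
#' and a wear-to-non-wear transition occurs within `lookback_min` minutes
#' before onset), computes the removal gap (scored onset minus the end of
#' the last hip-wear epoch, clamped at 0) and pairs it with the preceding
#' wake-interval length. Both variables are bounded below by their
#' observed minima and above by `max_value` (200 min); a Gaussian product
#' kernel with boundary reflection and plug-in (Silverman) bandwidths
#' represents the density through its fitted sample.
#'
#' @param sleep Sleep-record tibble with valid scored records.
#' @param epochs Aligned epoch tibble (for the hip wear mask).
#' @param wear Optional logical wear flag aligned to `epochs`; computed
#'   with [choi_nonwear()] per participant when omitted.
#' @param max_value Upper support bound for both variables, minutes.
#' @param lookback_min How far before onset to search for the removal.
#' @param min_records Minimum usable records, default 30.
#' @return A `mash_gapdist` object.
#' @export
fit_gap_distribution <- function(sleep, epochs, wear = NULL, max_value = 200,
                                 lookback_min = 360L, min_records = 30L) {
  if (is.null(wear)) {
    epochs <- epochs |>
      group_by(.data$participant_id) |>
      mutate(.wear = choi_nonwear(.data$hip_vm)) |>
      ungroup()
  } else {
    stopifnot(length(wear) == nrow(epochs))
    epochs$.wear <- wear
  }
  valid <- sleep |> filter(.data$valid) |> arrange(.data$participant_id,
                                                  .data$night_date)
  valid <- valid |>
    group_by(.data$participant_id) |>
    mutate(prev_offset = lag(.data$offset),
           prev_gap = as.numeric(difftime(.data$night_date,
                                          lag(.data$night_date),
                                          units = "days"))) |>
    ungroup() |>
    filter(!is.na(.data$prev_offset), .data$prev_gap %in% 1)

  pairs <- valid |>
    group_by(.data$participant_id) |>
    group_split() |>
    map(function(vv) {
      pe <- epochs[epochs$participant_id == vv$participant_id[1L], ,
                   drop = FALSE]
      map(seq_len(nrow(vv)), function(i) {
        onset <- vv$onset[i]
        pre <- pe$timestamp >= onset - lookback_min * 60 &
          pe$timestamp < onset
        if (!any(pre)) return(NULL)
        w <- pe$.wear[pre]
        if (length(w) == 0L || w[length(w)]) return(NULL) # still worn at onset
        if (!any(w)) return(NULL)                         # no transition seen
        last_wear <- max(which(w))
        gap <- length(w) - last_wear                       # minutes off before onset
        len <- as.numeric(difftime(onset, vv$prev_offset[i], units = "mins"))
        tibble(length = len, gap = max(gap, 0))
      }) |> bind_rows()
    }) |>
    bind_rows()

  if (nrow(pairs) < min_records) {
    abort(sprintf(paste(
      "only %d records with an observable hip removal (need >= %d);",
      "consider the constant-gap fallback of correct_cnn_onset()"),
      nrow(pairs), min_records), class = "mash_value_error")
  }
  bounds <- list(length = c(min(pairs$length), max_value),
                 gap = c(min(pairs$gap), max_value))
  pairs <- pairs |>
    mutate(length = pmin(pmax(.data$length, bounds$length[1L]),
                         bounds$length[2L]),
           gap = pmin(pmax(.data$gap, bounds$gap[1L]), bounds$gap[2L]))
  # Silverman plug-in bandwidth; degenerate (zero-spread) samples get a
  # vanishing bandwidth so the density collapses onto the observed value
  silverman <- function(x) {
    s <- min(sd(x), stats::IQR(x) / 1.349)
    max(0.9 * s * length(x)^(-1 / 5), 1e-3)
  }
  structure(list(
    samples = pairs,
    bw = c(length = silverman(pairs$length), gap = silverman(pairs$gap)),
    bounds = bounds, n = nrow(pairs)
  ), class = "mash_gapdist")
}

#' @export
print.mash_gapdist <- function(x, ...) {
  cat(sprintf(
    "<mash_gapdist> %d records; gap mean %.1f min on [%.0f, %.0f]; bw (%.1f, %.1f)\n",
    x$n, mean(x$samples$gap), x$bounds$gap[1L], x$bounds$gap[2L],
    x$bw[["length"]], x$bw[["gap"]]))
  invisible(x)
}

#' Sample removal gaps conditional on wake-interval length
#'
#' Conditions the fitted bivariate density on the observed wake length
#' (kernel-weighted slice at the length, clamped into the support),
#' samples fitted gap values with those weights, adds Gaussian kernel
#' noise, and reflects at the support bounds so every draw respects them.
#'
#' @param dist A `mash_gapdist`.
#' @param wake_len Observed wake-interval length, minutes.
#' @param n Number of draws.
#' @return Numeric vector of gap draws, all within the gap bounds.
#' @export
sample_gap <- function(dist, wake_len, n = 10L) {
  L0 <- min(max(wake_len, dist$bounds$length[1L]), dist$bounds$length[2L])
  w <- dnorm((L0 - dist$samples$length) / dist$bw[["length"]])
  if (sum(w) <= 0) w <- rep(1, nrow(dist$samples))
  i <- sample.int(nrow(dist$samples), n, replace = TRUE, prob = w)
  g <- dist$samples$gap[i] + dist$bw[["gap"]] * rnorm(n)
  lo <- dist$bounds$gap[1L]; hi <- dist$bounds$gap[2L]
  for (rep in 1:100) {
    out_lo <- g < lo; out_hi <- g > hi
    if (!any(out_lo | out_hi)) break
    g[out_lo] <- 2 * lo - g[out_lo]
    g[out_hi] <- 2 * hi - g[out_hi]
  }
  g <- pmin(pmax(g, lo), hi)
  stopifnot(all(g >= lo & g <= hi))
  g
}

#' Correct a CNN-predicted sleep onset for the hip-removal gap
#'
#' CNN wake intervals tend to end at hip-device removal rather than true
#' sleep onset; the correction draws `n_draws` removal gaps conditional on
#' the interval's length, averages them, and shifts the predicted onset
#' later by that average (shortening the predicted sleep interval). Only
#' the onset (evening) bound is corrected, never the morning offset.
#'
#' @param raw_onset POSIXct CNN-predicted sleep onset (wake-interval end).
#' @param wake_len Wake-interval length in minutes.
#' @param dist A `mash_gapdist`, or `NULL` to use `fallback_gap`.
#' @param n_draws Number of replicate draws to average (default 10).
#' @param fallback_gap Constant gap (minutes) used when `dist` is `NULL`.
#' @return List with `onset` (corrected POSIXct, minute resolution) and
#'   `shift_min` (the averaged gap, >= 0).
#' @export
correct_cnn_onset <- function(raw_onset, wake_len, dist, n_draws = 10L,
                              fallback_gap = NULL) {
  shift <- if (is.null(dist)) {
    if (is.null(fallback_gap)) {
      abort("need a fitted distribution or a fallback gap",
            class = "mash_value_error")
    }
    fallback_gap
  } else {
    mean(sample_gap(dist, wake_len, n_draws))
  }
  shift <- max(shift, 0)
  list(onset = raw_onset + round(shift) * 60, shift_min = shift)
}
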