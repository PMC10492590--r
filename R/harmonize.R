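# Two-tier harmonization engine: per-day flags, exclusion rules, tier
# routing, CNN interval construction with onset correction, device
# reconciliation, and night-day-night composition assembly.

pred_span <- function(date) {
  # prediction span for day t: 20:00 of day t-1 through 06:00 of day t+1
  d0 <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  c(d0 - 4 * 3600, d0 + 30 * 3600)
}

#' Per-day tier and exclusion flags
#'
#' For every participant calendar day, derives the flags that drive the
#' exclusion rules and the tier router: whether the day is the first day
#' of data collection, whether a preceding sleep interval is available
#' (valid scored sleep for the previous night, a short-but-bounded scored
#' record, or enough hip data for the CNN to estimate it), its scored
#' minutes when scored, which scored bounds are missing, the watch
#' coverage of the day's CNN prediction span, and whether the evening
#' sleep onset is observable within the data grid.
#'
#' @param epochs Aligned epoch tibble.
#' @param sleep Sleep-record tibble (see [score_sleep()]).
#' @return Tibble with one row per participant-day.
#' @export
day_flags <- function(epochs, sleep) {
  epochs |>
    group_by(.data$participant_id) |>
    group_split() |>
    map(function(pe) {
      pid <- pe$participant_id[1L]
      dates <- sort(unique(as.Date(pe$timestamp)))
      grid_end <- max(pe$timestamp)
      recs <- sleep[sleep$participant_id == pid, , drop = FALSE]
      rec_for <- function(d) {
        r <- recs[recs$night_date == d, , drop = FALSE]
        if (nrow(r) == 0L) NULL else r[1L, , drop = FALSE]
      }
      map(seq_along(dates), function(i) {
        d <- dates[i]
        r_prev <- rec_for(d - 1L)
        r_cur <- rec_for(d)
        valid_prev <- !is.null(r_prev) && isTRUE(r_prev$valid)
        valid_cur <- !is.null(r_cur) && isTRUE(r_cur$valid)
        prev_bounded <- !is.null(r_prev) && !is.na(r_prev$onset) &&
          !is.na(r_prev$offset)
        # hip data during the previous night's span -> CNN-estimable offset
        night_prev <- c(as.POSIXct(paste(d - 1L, "18:00:00"), tz = "UTC"),
                        as.POSIXct(paste(d, "12:00:00"), tz = "UTC"))
        hip_prev <- any(!is.na(pe$hip_vm[pe$timestamp >= night_prev[1L] &
                                           pe$timestamp < night_prev[2L]]))
        span <- pred_span(d)
        in_span <- pe$timestamp >= span[1L] & pe$timestamp < span[2L]
        n_span <- sum(in_span)
        wc <- if (n_span == 0L) 0 else
          mean(!is.na(pe$watch_activity[in_span]))
        tibble(
          participant_id = pid, date = d, day_index = i,
          first_day = i == 1L,
          preceding_sleep_available = valid_prev || prev_bounded || hip_prev,
          preceding_sleep_min = if (prev_bounded) r_prev$total_scored_sleep
                                else NA_real_,
          onset_missing = !valid_cur,
          offset_missing = !valid_prev,
          watch_coverage = wc,
          evening_observable = grid_end >= as.POSIXct(
            paste(d + 1L, "02:00:00"), tz = "UTC")
        )
      }) |> bind_rows()
    }) |>
    bind_rows()
}

#' Apply the three day-level exclusion rules
#'
#' In order: (1) the first day of data collection (partial day), (2) days
#' with no sleep data preceding the waking interval, (3) days whose
#' preceding sleep is under 60 minutes. A day matching several rules is
#' recorded under the first; the boundary is inclusive (exactly 60 min is
#' kept).
#'
#' @param flags Day-flag tibble from [day_flags()] or
#'   [fig1_day_fixture()].
#' @param min_sleep_min Exclusion-3 threshold, minutes.
#' @return `flags` with a `disposition` column (`kept`,
#'   `excluded_first_day`, `excluded_no_preceding_sleep`,
#'   `excluded_short_sleep`).
#' @export
apply_exclusions <- function(flags, min_sleep_min = 60) {
  flags |>
    mutate(disposition = case_when(
      .data$first_day ~ "excluded_first_day",
      !.data$preceding_sleep_available ~ "excluded_no_preceding_sleep",
      !is.na(.data$preceding_sleep_min) &
        .data$preceding_sleep_min < min_sleep_min ~ "excluded_short_sleep",
      TRUE ~ "kept"
    ))
}

#' Route kept days to the scored-sleep tier or a CNN variant
#'
#' Tier 1 (SCORED) requires valid scored sleep on both surrounding
#' nights; otherwise the day is tier 2 (CNN) with a sub-case recording
#' which bound is missing. The CNN variant is dual-device when the watch
#' channels cover at least `coverage_min` of the day's prediction span,
#' hip-only otherwise.
#'
#' @param flags Day-flag tibble (typically after [apply_exclusions()],
#'   filtered to kept days).
#' @param coverage_min Minimum watch coverage for the dual variant.
#' @return `flags` with `tier`, `subcase` and `variant` columns.
#' @export
route_days <- function(flags, coverage_min = 0.9) {
  flags |>
    mutate(
      tier = ifelse(!.data$onset_missing & !.data$offset_missing,
                    "SCORED", "CNN"),
      subcase = case_when(
        .data$tier == "SCORED" ~ NA_character_,
        .data$onset_missing & .data$offset_missing ~ "both_missing",
        .data$onset_missing ~ "onset_missing",
        TRUE ~ "offset_missing"
      ),
      variant = case_when(
        .data$tier == "SCORED" ~ NA_character_,
        .data$watch_coverage >= coverage_min ~ "DUAL",
        TRUE ~ "HIP_ONLY"
      )
    )
}

behavior_tally <- function(pe, a, b) {
  # per-behavior wear minutes in [a, b); minutes not classifiable count as
  # non-wear so totals always close
  span <- pe$timestamp >= a & pe$timestamp < b
  lev <- c("SB", "LLPA", "HLPA", "MVPA")
  cls <- pe$.intensity[span]
  ok <- pe$.wear[span] & !is.na(cls)
  counts <- table(factor(cls[ok], levels = lev))
  total <- as.numeric(round(difftime(b, a, units = "mins")))
  c(as.numeric(counts), max(total - sum(counts), 0))
}

harmonize_participant <- function(pe, recs, models, gap_dist, routing,
                                  merge_gap, n_draws, fallback_gap) {
  pid <- pe$participant_id[1L]
  pe$.wear <- choi_nonwear(pe$hip_vm)
  pe$.intensity <- classify_intensity(pe$hip_vm)
  fl <- routing[routing$participant_id == pid, , drop = FALSE]
  rec_for <- function(d) {
    r <- recs[recs$night_date == d, , drop = FALSE]
    if (nrow(r) == 0L) NULL else r[1L, , drop = FALSE]
  }

  # Days whose CNN interval is needed: the day itself is kept and tier-2,
  # or the following kept day needs this day's estimated evening onset.
  need_cnn <- logical(nrow(fl))
  for (i in seq_len(nrow(fl))) {
    own <- fl$disposition[i] == "kept" && fl$tier[i] %in% "CNN" &&
      fl$evening_observable[i]
    nxt <- i < nrow(fl) && fl$disposition[i + 1L] == "kept" &&
      fl$onset_missing[i] && fl$evening_observable[i]
    need_cnn[i] <- isTRUE(own) || isTRUE(nxt)
  }

  cnn <- vector("list", nrow(fl))
  for (i in which(need_cnn)) {
    variant <- fl$variant[i]
    if (is.na(variant)) {
      variant <- ifelse(fl$watch_coverage[i] >= 0.9, "DUAL", "HIP_ONLY")
    }
    model <- if (variant == "DUAL") models$dual %||% models$hip
             else models$hip %||% models$dual
    if (is.null(model)) next
    span <- pred_span(fl$date[i])
    sl <- pe[pe$timestamp >= span[1L] & pe$timestamp < span[2L], ,
             drop = FALSE]
    if (nrow(sl) < model$window_len) next
    pr <- predict_wake_prob(model, sl)
    iv <- wake_interval_from_probs(pr$prob, model$cutoff, merge_gap)
    if (is.null(iv)) {
      cnn[[i]] <- list(unresolvable = TRUE)
      next
    }
    raw_start <- sl$timestamp[iv$start_idx]
    raw_end <- sl$timestamp[iv$end_idx - 1L] + EPOCH_SEC
    raw_len <- as.numeric(difftime(raw_end, raw_start, units = "mins"))
    corr <- correct_cnn_onset(raw_end, raw_len, gap_dist, n_draws,
                              fallback_gap)
    cnn[[i]] <- list(unresolvable = FALSE, raw_start = raw_start,
                     raw_end = raw_end, corrected_end = corr$onset,
                     shift_min = corr$shift_min, variant = variant)
  }

  # Evening onset estimate per day: scored when valid, else corrected CNN.
  onset_est <- rep(as.POSIXct(NA_real_, tz = "UTC"), nrow(fl))
  onset_src <- rep(NA_character_, nrow(fl))
  for (i in seq_len(nrow(fl))) {
    r <- rec_for(fl$date[i])
    if (!is.null(r) && isTRUE(r$valid)) {
      onset_est[i] <- r$onset
      onset_src[i] <- "SCORED"
    } else if (!is.null(cnn[[i]]) && !isTRUE(cnn[[i]]$unresolvable)) {
      onset_est[i] <- cnn[[i]]$corrected_end
      onset_src[i] <- "CNN_CORRECTED"
    }
  }

  comps <- list()
  ledger <- fl |> select("participant_id", "date", "day_index",
                         "disposition")
  for (i in seq_len(nrow(fl))) {
    if (fl$disposition[i] != "kept") next
    if (!fl$evening_observable[i]) {
      ledger$disposition[i] <- "excluded_no_evening_onset"
      next
    }
    tier <- fl$tier[i]
    r_prev <- rec_for(fl$date[i] - 1L)
    if (tier == "CNN" && (is.null(cnn[[i]]) || isTRUE(cnn[[i]]$unresolvable))) {
      ledger$disposition[i] <- if (is.null(cnn[[i]])) "excluded_no_model"
                               else "excluded_unresolvable"
      next
    }
    offset_d <- if (!fl$offset_missing[i]) r_prev$offset
                else cnn[[i]]$raw_start
    onset_d <- if (!fl$onset_missing[i]) rec_for(fl$date[i])$onset
               else cnn[[i]]$corrected_end
    onset_prev <- if (i > 1L) onset_est[i - 1L]
                  else as.POSIXct(NA_real_, tz = "UTC")
    if (is.na(onset_prev) || is.na(offset_d) || is.na(onset_d)) {
      ledger$disposition[i] <- "excluded_no_preceding_sleep"
      next
    }
    if (!(onset_prev < offset_d && offset_d < onset_d)) {
      ledger$disposition[i] <- "excluded_unresolvable"
      next
    }
    pre <- behavior_tally(pe, onset_prev, onset_d)
    post <- behavior_tally(pe, offset_d, onset_d)
    sleep_min <- as.numeric(round(difftime(offset_d, onset_prev,
                                           units = "mins")))
    scored_total <- if (!fl$offset_missing[i]) r_prev$total_scored_sleep
                    else NA_real_
    corr_beh <- post[1:4] - pre[1:4]
    comps[[length(comps) + 1L]] <- tibble(
      participant_id = pid, date = fl$date[i], day_index = fl$day_index[i],
      tier = tier, subcase = fl$subcase[i],
      variant = if (tier == "CNN") cnn[[i]]$variant else NA_character_,
      onset_prev = onset_prev, offset = offset_d, onset = onset_d,
      onset_prev_source = if (i > 1L) onset_src[i - 1L] else NA_character_,
      sleep_min = sleep_min, total_scored_sleep = scored_total,
      latency_min = sleep_min - scored_total,
      sb_min = post[1L], llpa_min = post[2L], hlpa_min = post[3L],
      mvpa_min = post[4L], nonwear_within_wake_min = post[5L],
      pre_sb_min = pre[1L], pre_llpa_min = pre[2L], pre_hlpa_min = pre[3L],
      pre_mvpa_min = pre[4L],
      corr_sb_min = corr_beh[1L], corr_llpa_min = corr_beh[2L],
      corr_hlpa_min = corr_beh[3L], corr_mvpa_min = corr_beh[4L],
      corr_total_wake_min = sum(corr_beh),
      onset_shift_min = if (tier == "CNN" && fl$onset_missing[i])
        cnn[[i]]$shift_min else 0,
      interval_size_h = as.numeric(difftime(onset_d, onset_prev,
                                            units = "hours")),
      corrected = tier == "CNN" || any(corr_beh != 0)
    )
  }
  list(compositions = bind_rows(comps), ledger = ledger)
}

#' Harmonize sleep and activity data into sleep-wake compositions
#'
#' Runs the full two-tier engine: Choi wear detection and Evenson
#' intensity classification on the hip stream, day-level exclusions, tier
#' routing, CNN wake-interval prediction with bounded-KDE onset
#' correction for days lacking scored bounds, device reconciliation
#' (waking behavior outside the final wake interval is stripped, never
#' added), and night(t-1)-day(t)-night(t) composition assembly.
#'
#' @param epochs Aligned epoch tibble.
#' @param sleep Sleep-record tibble.
#' @param model_dual,model_hip `mash_cnn` bundles; days needing a missing
#'   variant fall back to the other, and tier-2 days are excluded with
#'   reason `excluded_no_model` when neither is supplied.
#' @param gap_dist A `mash_gapdist` for the onset correction, or `NULL`
#'   with `fallback_gap` set.
#' @param fallback_gap Constant onset correction (minutes) when no
#'   distribution is available.
#' @param merge_gap Cluster merge gap for [wake_interval_from_probs()].
#' @param n_draws Gap draws averaged per corrected onset (default 10).
#' @param coverage_min Watch coverage for dual-variant routing.
#' @param seed Integer seed for the correction draws.
#' @return A `mash_harmony` list: `compositions` (one row per kept day),
#'   `ledger` (disposition of every day), `routing` (flag table).
#' @export
harmonize <- function(epochs, sleep, model_dual = NULL, model_hip = NULL,
                      gap_dist = NULL, fallback_gap = NULL,
                      merge_gap = 120L, n_draws = 10L, coverage_min = 0.9,
                      seed = 1L) {
  if (is.null(gap_dist) && is.null(fallback_gap)) fallback_gap <- 0
  flags <- day_flags(epochs, sleep)
  routed <- apply_exclusions(flags) |> route_days(coverage_min)
  models <- list(dual = model_dual, hip = model_hip)
  parts <- with_local_seed(seed, {
    epochs |>
      group_by(.data$participant_id) |>
      group_split() |>
      map(function(pe) {
        harmonize_participant(
          pe, sleep[sleep$participant_id == pe$participant_id[1L], ,
                    drop = FALSE],
          models, gap_dist, routed, merge_gap, n_draws, fallback_gap)
      })
  })
  out <- list(
    compositions = bind_rows(lapply(parts, `[[`, "compositions")),
    ledger = bind_rows(lapply(parts, `[[`, "ledger")),
    routing = routed
  )
  class(out) <- "mash_harmony"
  out
}

#' @export
print.mash_harmony <- function(x, ...) {
  n_kept <- nrow(x$compositions)
  cat("<mash_harmony>", n_kept, "compositions;",
      sum(x$compositions$tier == "SCORED"), "scored /",
      sum(x$compositions$tier == "CNN"), "CNN;",
      sprintf("%.1f%% corrected\n",
              100 * mean(x$compositions$corrected)))
  invisible(x)
}
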