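# Actiware-style wrist-actigraph sleep scorer: weighted wake score per
# epoch, rest-interval anchoring (event marker > diary > heuristic),
# onset/offset by the 10-consecutive-immobile-minute rule, and validity
# screening.

#' Sleep-scoring parameters
#'
#' Defaults follow the widely published default scorer for 60-s epochs:
#' a five-epoch weighted activity score (weights 0.04 / 0.20 / 1.00 /
#' 0.20 / 0.04) compared against a 40 counts/min wake threshold, sleep
#' onset/offset located by runs of 10 consecutive immobile minutes
#' (immobile: count <= `immobile_count_max`), and a minimum of 60 min of
#' scored sleep for a valid night.
#'
#' @param wake_threshold Wake threshold for the weighted score, counts/min.
#' @param immobility_run Run length defining onset/offset, minutes.
#' @param immobile_count_max Maximum count of an immobile minute.
#' @param weights Five-epoch weight profile, centered.
#' @param min_sleep_min Minimum scored sleep for a valid record, minutes.
#' @param heuristic_window_min Width of the lowest-activity fallback rest
#'   window, minutes.
#' @return An object of class `mash_scoring_params`.
#' @export
scoring_params <- function(wake_threshold = 40,
                           immobility_run = 10L,
                           immobile_count_max = 0,
                           weights = c(0.04, 0.20, 1.00, 0.20, 0.04),
                           min_sleep_min = 60L,
                           heuristic_window_min = 360L) {
  stopifnot(wake_threshold > 0, immobility_run >= 1L,
            length(weights) %% 2L == 1L)
  structure(list(wake_threshold = wake_threshold,
                 immobility_run = as.integer(immobility_run),
                 immobile_count_max = immobile_count_max,
                 weights = weights,
                 min_sleep_min = as.integer(min_sleep_min),
                 heuristic_window_min = as.integer(heuristic_window_min)),
            class = "mash_scoring_params")
}

#' Weighted wake score per epoch
#'
#' For epoch i the score is the weighted sum of the activity counts of the
#' epoch and its neighbours (out-of-range neighbours contribute 0). An
#' epoch is scored WAKE when the score strictly exceeds the wake
#' threshold.
#'
#' @param counts Watch activity counts/min; `NA` treated as 0.
#' @param params A [scoring_params()].
#' @return Numeric vector of weighted scores, same length as `counts`.
#' @examples
#' wake_score(c(0, 0, 41, 0, 0))[3] # 41 -> WAKE at threshold 40
#' @export
wake_score <- function(counts, params = scoring_params()) {
  x <- ifelse(is.na(counts), 0, counts)
  w <- params$weights
  half <- (length(w) - 1L) %/% 2L
  xp <- c(rep(0, half), x, rep(0, half))
  out <- numeric(length(x))
  for (k in seq_along(w)) {
    out <- out + w[k] * xp[k:(k + length(x) - 1L)]
  }
  out
}

#' @rdname wake_score
#' @return For `score_epochs()`: logical vector, `TRUE` where the epoch is
#'   scored WAKE (score strictly above threshold).
#' @export
score_epochs <- function(counts, params = scoring_params()) {
  wake_score(counts, params) > params$wake_threshold
}

# First/last run of >= run_len consecutive TRUE values.
# Returns c(first_start, last_end) indices, or NULL when no run qualifies.
immobility_bounds <- function(immobile, run_len) {
  r <- runs_tbl(immobile)
  ok <- r$value & r$length >= run_len
  if (!any(ok)) return(NULL)
  c(r$start[which(ok)[1L]], r$end[tail(which(ok), 1L)])
}

#' Locate sleep onset/offset inside a rest window
#'
#' Onset is the start of the first run of at least `immobility_run`
#' consecutive immobile minutes; offset is the last minute of the last
#' such run. Returns epoch indices into `counts` (`offset_end` is the
#' index of that last immobile minute), or `NULL` when no run qualifies
#' (a no/poor-sleep night).
#'
#' @param counts Watch activity counts within the anchored rest window;
#'   `NA` counts as mobile.
#' @param params A [scoring_params()].
#' @return Named integer vector `c(onset, offset_end)` or `NULL`.
#' @export
find_onset_offset <- function(counts, params = scoring_params()) {
  immobile <- !is.na(counts) & counts <= params$immobile_count_max
  b <- immobility_bounds(immobile, params$immobility_run)
  if (is.null(b)) return(NULL)
  c(onset = b[1L], offset_end = b[2L])
}

#' Anchor the candidate rest window for one night
#'
#' Priority: two event markers inside the night span; else diary bed/rise
#' times; else the lowest-activity window of `heuristic_window_min`
#' minutes (ties broken toward the earliest start), flagged low
#' confidence.
#'
#' @param night_epochs Epoch tibble restricted to one night span (noon to
#'   noon).
#' @param diary_row Optional one-row diary tibble for the night.
#' @param params A [scoring_params()].
#' @return List with POSIXct `start`, `end`, `anchor`
#'   (`"marker"`/`"diary"`/`"heuristic"`), `low_confidence`.
#' @export
anchor_rest_interval <- function(night_epochs, diary_row = NULL,
                                 params = scoring_params()) {
  mk <- night_epochs$timestamp[which(night_epochs$event_marker %in% TRUE)]
  if (length(mk) >= 2L) {
    return(list(start = min(mk), end = max(mk), anchor = "marker",
                low_confidence = FALSE))
  }
  if (!is.null(diary_row) && nrow(diary_row) == 1L &&
      !is.na(diary_row$bed_time) && !is.na(diary_row$rise_time)) {
    return(list(start = diary_row$bed_time, end = diary_row$rise_time,
                anchor = "diary", low_confidence = FALSE))
  }
  act <- ifelse(is.na(night_epochs$watch_activity), 0,
                night_epochs$watch_activity)
  w <- min(params$heuristic_window_min, length(act))
  cs <- c(0, cumsum(act))
  tot <- cs[(w + 1L):length(cs)] - cs[1L:(length(cs) - w)]
  i0 <- which.min(tot) # which.min takes the earliest tie
  list(start = night_epochs$timestamp[i0],
       end = night_epochs$timestamp[i0 + w - 1L] + EPOCH_SEC,
       anchor = "heuristic", low_confidence = TRUE)
}

score_one_night <- function(night_epochs, diary_row, params, pid, nd) {
  rec <- tibble(participant_id = pid, night_date = nd,
                onset = as.POSIXct(NA_real_, tz = "UTC"),
                offset = as.POSIXct(NA_real_, tz = "UTC"),
                total_scored_sleep = NA_real_, valid = FALSE,
                reason = NA_character_, source = "SCORED",
                anchor = NA_character_, low_confidence = NA)
  act <- night_epochs$watch_activity
  if (all(is.na(act)) ||
      (all(act == 0, na.rm = TRUE) &&
         sd(night_epochs$watch_lux, na.rm = TRUE) %in% c(0, NA))) {
    rec$reason <- "malfunction/non-wear"
    return(rec)
  }
  win <- anchor_rest_interval(night_epochs, diary_row, params)
  inside <- night_epochs$timestamp >= win$start &
    night_epochs$timestamp < win$end
  we <- night_epochs[inside, , drop = FALSE]
  rec$anchor <- win$anchor
  rec$low_confidence <- win$low_confidence
  if (nrow(we) == 0L) {
    rec$reason <- "empty rest window"
    return(rec)
  }
  immobile <- !is.na(we$watch_activity) &
    we$watch_activity <= params$immobile_count_max
  b <- immobility_bounds(immobile, params$immobility_run)
  if (is.null(b)) {
    rec$reason <- "no/poor sleep"
    return(rec)
  }
  onset <- we$timestamp[b[1L]]
  offset <- we$timestamp[b[2L]] + EPOCH_SEC # half-open: past the last immobile minute
  span <- we$timestamp >= onset & we$timestamp < offset
  total <- sum(!score_epochs(we$watch_activity[span], params))
  rec$onset <- onset
  rec$offset <- offset
  rec$total_scored_sleep <- total
  if (total < params$min_sleep_min) {
    rec$reason <- "short sleep"
  } else {
    rec$valid <- TRUE
  }
  rec
}

#' Score overnight sleep for every participant-night
#'
#' Splits each participant's aligned epoch stream into noon-to-noon night
#' spans, anchors a rest window per night (markers, then diary, then a
#' lowest-activity heuristic), finds onset/offset via the
#' 10-consecutive-immobile-minute rule, totals the sleep-scored minutes
#' between them, and applies validity screening (watch malfunction /
#' non-wear, no qualifying immobility run, under 60 min of scored sleep).
#'
#' @param epochs Aligned epoch tibble (multiple participants allowed).
#' @param diary Optional diary tibble (see [read_sleep_diary()]).
#' @param params A [scoring_params()].
#' @return A sleep-record tibble: one row per participant-night with
#'   `onset`, `offset`, `total_scored_sleep`, `valid`, `reason`, `source`,
#'   `anchor`, `low_confidence`. `night_date` is the calendar date of the
#'   evening.
#' @export
score_sleep <- function(epochs, diary = NULL, params = scoring_params()) {
  epochs |>
    group_by(.data$participant_id) |>
    group_split() |>
    map(function(pe) {
      pid <- pe$participant_id[1L]
      dates <- sort(unique(as.Date(pe$timestamp)))
      nights <- head(dates, -1L)
      map(nights, function(nd) {
        span0 <- as.POSIXct(paste(nd, "12:00:00"), tz = "UTC")
        span1 <- span0 + 24 * 3600
        ne <- pe[pe$timestamp >= span0 & pe$timestamp < span1, , drop = FALSE]
        if (nrow(ne) == 0L) return(NULL)
        dr <- if (!is.null(diary)) {
          diary[diary$participant_id == pid & diary$night_date == nd, ,
                drop = FALSE]
        } else NULL
        if (!is.null(dr) && nrow(dr) == 0L) dr <- NULL
        score_one_night(ne, dr, params, pid, nd)
      }) |> bind_rows()
    }) |>
    bind_rows()
}
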