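# Synthetic dual-device cohort generator.
#
# Emulates the structure the harmonizer consumes: per participant a
# contiguous 60-s epoch grid carrying hip triaxial counts, watch activity
# counts, white-light lux and event markers, generated conditionally on a
# latent per-minute behavior state sequence with known sleep onsets/offsets,
# a hip-removal lag before sleep onset, and night-level missingness
# patterns (watch malfunction, watch removal, hip worn to bed).

#' Specification for a synthetic dual-device cohort
#'
#' The defaults define the study conditions the generator emulates: a
#' roughly 66/33 split of epochs inside versus outside the waking interval
#' (so mean nightly sleep is `(1 - wake_fraction) * 24` h), a hip-removal
#' lag before sleep onset drawn from a truncated normal with mean 44.4 min
#' and an imposed maximum of 200 min (the 200-min bound sits about three
#' SDs above the mean, giving the 51.9-min default SD), and night-level
#' missingness rates for watch malfunction, watch removal and sleeping with
#' the hip device on.
#'
#' @param n_participants Number of participants (> 0).
#' @param n_days Number of nights per participant (> 0); the epoch grid
#'   spans `n_days + 1` calendar days so every night is complete.
#' @param wake_fraction Target fraction of each night-to-night span spent
#'   inside the waking interval.
#' @param removal_lag_mean,removal_lag_sd,removal_lag_max Truncated-normal
#'   parameters (minutes) of the hip-removal lag before sleep onset;
#'   `removal_lag_mean` is the mean *after* truncation to
#'   `[0, removal_lag_max]`.
#' @param missing_night_rates Named per-night probabilities for
#'   `watch_malfunction_night`, `watch_removed_night`, `hip_worn_to_bed`.
#' @param marker_compliance Probability that a night's event markers are
#'   pressed.
#' @param nonwear_bout_rate Probability per day of one daytime hip
#'   non-wear bout (95-150 min).
#' @param onset_sd_min,duration_sd_min Night-to-night jitter (minutes) of
#'   sleep onset clock time and sleep duration.
#' @param state_count_means,state_count_sdlog Lognormal hip
#'   vector-magnitude count parameters per behavior state; means are
#'   placed inside the Evenson bands so the intensity classifier is
#'   exercised (simulator conventions).
#' @param seed Integer seed; identical spec + seed reproduce the cohort
#'   byte for byte.
#' @return An object of class `mash_sim_spec`.
#' @export
sim_spec <- function(n_participants,
                     n_days = 7L,
                     wake_fraction = 0.66,
                     removal_lag_mean = 44.4,
                     removal_lag_sd = 51.9,
                     removal_lag_max = 200,
                     missing_night_rates = c(watch_malfunction_night = 0.06,
                                             watch_removed_night = 0.04,
                                             hip_worn_to_bed = 0.10),
                     marker_compliance = 0.8,
                     nonwear_bout_rate = 0.25,
                     onset_sd_min = 40,
                     duration_sd_min = 40,
                     state_count_means = c(SLEEP = 8, SB = 20, LLPA = 400,
                                           HLPA = 1400, MVPA = 3500),
                     state_count_sdlog = c(SLEEP = 1.0, SB = 0.6, LLPA = 0.4,
                                           HLPA = 0.22, MVPA = 0.35),
                     seed = 1L) {
  if (n_participants < 1L || n_days < 1L) {
    abort("n_participants and n_days must be positive",
          class = "mash_value_error")
  }
  rates <- c(watch_malfunction_night = 0, watch_removed_night = 0,
             hip_worn_to_bed = 0)
  rates[names(missing_night_rates)] <- missing_night_rates
  if (any(rates < 0 | rates > 1) || wake_fraction <= 0 || wake_fraction >= 1 ||
      marker_compliance < 0 || marker_compliance > 1) {
    abort("all rates must lie in [0, 1]", class = "mash_value_error")
  }
  if (removal_lag_max < removal_lag_mean) {
    abort("removal_lag_max must be >= removal_lag_mean",
          class = "mash_value_error")
  }
  structure(list(
    n_participants = as.integer(n_participants), n_days = as.integer(n_days),
    wake_fraction = wake_fraction, removal_lag_mean = removal_lag_mean,
    removal_lag_sd = removal_lag_sd, removal_lag_max = removal_lag_max,
    missing_night_rates = rates, marker_compliance = marker_compliance,
    nonwear_bout_rate = nonwear_bout_rate, onset_sd_min = onset_sd_min,
    duration_sd_min = duration_sd_min, state_count_means = state_count_means,
    state_count_sdlog = state_count_sdlog, seed = as.integer(seed)
  ), class = "mash_sim_spec")
}

#' @export
print.mash_sim_spec <- function(x, ...) {
  cat("<mash_sim_spec>", x$n_participants, "participants x", x$n_days,
      "nights; wake fraction", x$wake_fraction, "; removal lag",
      x$removal_lag_mean, "min (max", x$removal_lag_max, "); seed",
      x$seed, "\n")
  invisible(x)
}

#' Draw hip-removal lags from the truncated lag distribution
#'
#' Samples from a normal distribution truncated to
#' `[0, removal_lag_max]` whose *post-truncation* mean equals
#' `removal_lag_mean`: the location parameter is solved numerically so the
#' truncated mean hits the target. Draws use the current RNG state.
#'
#' @param spec A [sim_spec()].
#' @param n Number of draws.
#' @return Numeric vector of lags in minutes, all in
#'   `[0, removal_lag_max]`.
#' @export
draw_removal_lag <- function(spec, n = 1L) {
  hi <- spec$removal_lag_max
  if (hi <= 0) return(rep(0, n))
  s <- spec$removal_lag_sd
  if (s <= 0) return(rep(min(spec$removal_lag_mean, hi), n))
  trunc_mean <- function(mu) {
    a <- (0 - mu) / s
    b <- (hi - mu) / s
    z <- pnorm(b) - pnorm(a)
    mu + s * (dnorm(a) - dnorm(b)) / z
  }
  mu0 <- uniroot(function(mu) trunc_mean(mu) - spec$removal_lag_mean,
                 interval = c(-4 * s, hi), extendInt = "yes")$root
  a <- pnorm((0 - mu0) / s)
  b <- pnorm((hi - mu0) / s)
  u <- runif(n, a, b)
  pmin(pmax(mu0 + s * qnorm(u), 0), hi)
}

# Lux profile by minute-of-day: dark before dawn, ramp up, bright daytime,
# evening decay before typical sleep onset.
lux_profile <- function(minute_of_day) {
  p <- rep(1, length(minute_of_day))
  p[minute_of_day < 300] <- 0.02
  ramp <- minute_of_day >= 300 & minute_of_day < 480
  p[ramp] <- 0.02 + 0.98 * (minute_of_day[ramp] - 300) / 180
  eve <- minute_of_day >= 1080
  p[eve] <- pmax(0.05, 1 - 0.95 * (minute_of_day[eve] - 1080) / 300)
  p
}

# Sample alternating-intensity waking bouts covering `len` minutes.
# Bout types chosen so stationary occupancy approximates daily time-use
# proportions typical for older adults (SB-heavy), dwell times geometric.
sample_wake_bouts <- function(len) {
  if (len <= 0L) return(character(0))
  states <- c("SB", "LLPA", "HLPA", "MVPA")
  occupancy <- c(0.49, 0.30, 0.15, 0.06)
  dwell <- c(SB = 20, LLPA = 10, HLPA = 6, MVPA = 4)
  p_start <- occupancy / dwell
  p_start <- p_start / sum(p_start)
  out <- character(len)
  filled <- 0L
  while (filled < len) {
    k <- max(8L, ceiling((len - filled) / 8))
    st <- sample(states, k, replace = TRUE, prob = p_start)
    bl <- 1L + rgeom(k, prob = 1 / dwell[st])
    seg <- rep(st, bl)
    take <- min(length(seg), len - filled)
    out[(filled + 1L):(filled + take)] <- seg[seq_len(take)]
    filled <- filled + take
  }
  out
}

simulate_participant <- function(pid, spec) {
  nd <- spec$n_days
  n_min <- (nd + 1L) * 1440L
  origin <- mash_origin()
  rates <- spec$missing_night_rates

  onset <- integer(nd); offset <- integer(nd)
  dur_mean <- (1 - spec$wake_fraction) * 1440
  for (t in seq_len(nd)) {
    o <- (t - 1L) * 1440L +
      as.integer(pmin(pmax(round(rnorm(1, 1380, spec$onset_sd_min)), 1290), 1470))
    d <- as.integer(pmin(pmax(round(rnorm(1, dur_mean, spec$duration_sd_min)),
                              300), 780))
    onset[t] <- o
    offset[t] <- o + d
  }

  worn_to_bed <- runif(nd) < rates[["hip_worn_to_bed"]]
  malfunction <- runif(nd) < rates[["watch_malfunction_night"]]
  removed <- runif(nd) < rates[["watch_removed_night"]]
  lag <- round(draw_removal_lag(spec, nd))
  placement <- as.integer(round(runif(1, 540, 660)))

  # Latent minute states over the full grid (0-based minute indexing).
  st <- rep("SB", n_min)
  hip_worn <- rep(TRUE, n_min)
  watch_worn <- rep(TRUE, n_min)
  idx <- function(a, b) if (b > a) (a + 1L):b else integer(0) # (a,b] 0-based -> 1-based

  for (t in seq_len(nd + 1L)) {
    wake_start <- if (t == 1L) 0L else offset[t - 1L]
    wake_end <- if (t <= nd) onset[t] - lag[t] else n_min
    if (wake_end > wake_start) {
      st[idx(wake_start, wake_end)] <- sample_wake_bouts(wake_end - wake_start)
    }
    # occasional daytime hip non-wear bout
    region <- wake_end - wake_start
    if (region > 260L && runif(1) < spec$nonwear_bout_rate) {
      bl <- as.integer(round(runif(1, 95, 150)))
      bs <- wake_start + as.integer(round(runif(1, 30, region - bl - 30)))
      st[idx(bs, bs + bl)] <- "NONWEAR_HIP"
      hip_worn[idx(bs, bs + bl)] <- FALSE
    }
    if (t <= nd) {
      st[idx(onset[t] - lag[t], onset[t])] <- "SB"     # quiet in-bed wakefulness
      st[idx(onset[t], offset[t])] <- "SLEEP"
      if (worn_to_bed[t]) {
        # device stays on all night: near-sedentary counts through sleep
      } else {
        hip_worn[idx(onset[t] - lag[t], offset[t])] <- FALSE
      }
      if (malfunction[t]) {
        watch_worn[idx((t - 1L) * 1440L + 1080L,
                       min(t * 1440L + 600L, n_min))] <- FALSE
      }
      if (removed[t]) {
        watch_worn[idx((t - 1L) * 1440L + 720L,
                       min(t * 1440L + 720L, n_min))] <- FALSE
      }
    }
  }
  st[seq_len(placement)] <- "SB"
  hip_worn[seq_len(placement)] <- FALSE
  watch_worn[seq_len(placement)] <- FALSE

  # Hip channels conditional on state and wear.
  mu <- spec$state_count_means
  sl <- spec$state_count_sdlog
  hip_state <- ifelse(st == "NONWEAR_HIP", "SB", st)
  m <- mu[hip_state]; s <- sl[hip_state]
  vm <- round(rlnorm(n_min, meanlog = log(m) - s^2 / 2, sdlog = s))
  vm[!hip_worn] <- 0
  dir <- matrix(abs(rnorm(3L * n_min)), ncol = 3L)
  dir <- dir / sqrt(rowSums(dir^2))
  ax <- round(dir * vm)
  vm_out <- sqrt(rowSums(ax^2))
  pre <- seq_len(placement)
  ax[pre, ] <- NA_real_; vm_out[pre] <- NA_real_

  # Watch activity: state-dependent by day; immobility runs with brief
  # arousal bursts during sleep.
  wmu <- c(SB = 110, LLPA = 260, HLPA = 420, MVPA = 700, NONWEAR_HIP = 260,
           SLEEP = 0)
  wm <- wmu[st]
  wact <- numeric(n_min)
  wake_i <- which(st != "SLEEP")
  wact[wake_i] <- round(rlnorm(length(wake_i),
                               meanlog = log(wm[wake_i]) - 0.7^2 / 2,
                               sdlog = 0.7))
  sleep_i <- which(st == "SLEEP")
  if (length(sleep_i) > 0L) {
    burst_start <- runif(length(sleep_i)) < 1 / 40
    bl <- 1L + rgeom(length(sleep_i), 0.6)
    act <- rep(0, length(sleep_i))
    for (j in which(burst_start)) {
      span <- j:min(j + bl[j] - 1L, length(sleep_i))
      act[span] <- round(rlnorm(length(span), meanlog = log(120) - 0.125,
                                sdlog = 0.5))
    }
    wact[sleep_i] <- act
  }
  wact[!watch_worn] <- NA_real_

  mod <- (seq_len(n_min) - 1L) %% 1440L
  lux <- round(400 * lux_profile(mod) *
                 rlnorm(n_min, meanlog = -0.18, sdlog = 0.6), 1)
  lux[st == "SLEEP"] <- round(lux[st == "SLEEP"] * 0.02, 1)
  lux[!watch_worn] <- NA_real_

  marker <- rep(FALSE, n_min)
  bed_min <- integer(nd); rise_min <- integer(nd)
  for (t in seq_len(nd)) {
    bed_min[t] <- onset[t] - lag[t] - as.integer(round(runif(1, 0, 10)))
    rise_min[t] <- offset[t] + as.integer(round(runif(1, 2, 15)))
    if (runif(1) < spec$marker_compliance) {
      for (mm in c(bed_min[t], rise_min[t])) {
        if (mm >= 0L && mm < n_min && watch_worn[mm + 1L]) marker[mm + 1L] <- TRUE
      }
    }
  }

  ts <- origin + as.difftime(0:(n_min - 1L), units = "mins")
  epochs <- tibble(
    participant_id = pid, timestamp = ts,
    hip_axis1 = ax[, 1L], hip_axis2 = ax[, 2L], hip_axis3 = ax[, 3L],
    hip_vm = vm_out,
    watch_activity = wact, watch_lux = lux, event_marker = marker
  )

  truth_minutes <- tibble(
    participant_id = pid, timestamp = ts,
    state = factor(st, levels = c("SLEEP", "SB", "LLPA", "HLPA", "MVPA",
                                  "NONWEAR_HIP")),
    hip_worn = hip_worn, watch_worn = watch_worn
  )

  truth_days <- tibble(
    participant_id = pid,
    day = seq_len(nd + 1L),
    true_sleep_offset = origin + as.difftime(
      c(NA_integer_, offset), units = "mins"),
    true_sleep_onset = origin + as.difftime(
      c(onset, NA_integer_), units = "mins"),
    hip_removal_lag = c(ifelse(worn_to_bed, NA_real_, lag), NA_real_),
    hip_worn_to_bed = c(worn_to_bed, NA),
    watch_malfunction_night = c(malfunction, NA),
    watch_removed_night = c(removed, NA)
  )

  diary <- tibble(
    participant_id = pid,
    night_date = as.Date(origin) + (seq_len(nd) - 1L),
    bed_time = origin + as.difftime(
      bed_min - as.integer(round(rnorm(nd, 0, 5))), units = "mins"),
    try_sleep_time = origin + as.difftime(
      onset - as.integer(round(runif(nd, 0, 10))), units = "mins"),
    wake_time = origin + as.difftime(
      offset + as.integer(round(runif(nd, 0, 5))), units = "mins"),
    rise_time = origin + as.difftime(
      offset + as.integer(round(runif(nd, 8, 25))), units = "mins")
  )

  list(epochs = epochs, truth_minutes = truth_minutes,
       truth_days = truth_days, diary = diary)
}

#' Simulate a dual-device cohort with ground truth
#'
#' Generates, per participant, a contiguous 60-s epoch grid of hip triaxial
#' counts, watch activity counts, white-light lux and event markers,
#' conditional on latent per-minute behavior states with known sleep
#' onsets/offsets, a hip-removal lag before each sleep onset, and
#' night-level missingness (watch malfunction / watch removal wipe the
#' watch channels for the night; hip worn to bed keeps near-sedentary hip
#' counts flowing through the sleep interval). The first calendar day is a
#' partial day beginning at device placement mid-morning.
#'
#' @param spec A [sim_spec()].
#' @return A `mash_cohort` list with elements `epochs`, `truth_minutes`,
#'   `truth_days`, `diary`, `spec`.
#' @examples
#' co <- simulate_cohort(sim_spec(n_participants = 2, n_days = 3, seed = 7))
#' dplyr::count(co$truth_minutes, state)
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "mash_sim_spec"))
  pids <- sprintf("P%04d", seq_len(spec$n_participants))
  parts <- with_local_seed(spec$seed, lapply(pids, simulate_participant,
                                             spec = spec))
  out <- list(
    epochs = bind_rows(lapply(parts, `[[`, "epochs")),
    truth_minutes = bind_rows(lapply(parts, `[[`, "truth_minutes")),
    truth_days = bind_rows(lapply(parts, `[[`, "truth_days")),
    diary = bind_rows(lapply(parts, `[[`, "diary")),
    spec = spec
  )
  class(out) <- "mash_cohort"
  out
}

#' @export
print.mash_cohort <- function(x, ...) {
  cat("<mash_cohort>", x$spec$n_participants, "participants,",
      format(nrow(x$epochs), big.mark = ","), "epochs,",
      x$spec$n_days, "nights each\n")
  invisible(x)
}

#' Ground-truth sleep records from a simulated cohort
#'
#' Convenience accessor returning one row per night in the scored-sleep
#' record shape (`night_date` is the calendar date of the evening).
#'
#' @param cohort A `mash_cohort`.
#' @return Tibble with `participant_id`, `night_date`, `onset`, `offset`.
#' @export
truth_sleep_records <- function(cohort) {
  cohort$truth_days |>
    group_by(.data$participant_id) |>
    mutate(night_offset = lead(.data$true_sleep_offset)) |>
    ungroup() |>
    filter(!is.na(.data$true_sleep_onset)) |>
    transmute(
      participant_id = .data$participant_id,
      night_date = as.Date(mash_origin()) + .data$day - 1L,
      onset = .data$true_sleep_onset,
      offset = .data$night_offset,
      hip_removal_lag = .data$hip_removal_lag,
      hip_worn_to_bed = .data$hip_worn_to_bed
    )
}
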