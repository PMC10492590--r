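# Hip-device wear/non-wear detection (Choi) and Evenson vector-magnitude
# intensity classification, plus day/participant adherence screening.

#' Evenson vector-magnitude intensity cut points (60-s epochs)
#'
#' Band edges in counts/min for the four waking intensity categories:
#' sedentary behavior (SB, < 76), low light physical activity (LLPA,
#' 76 to < 903), high light (HLPA, 903 to < 2075) and moderate-to-vigorous
#' (MVPA, >= 2075). Upper edges are exclusive, so the bands partition
#' `[0, Inf)`.
#'
#' @return A named list with elements `sb_upper`, `llpa_upper`, `hlpa_upper`.
#' @export
evenson_thresholds <- function() {
  list(sb_upper = 76, llpa_upper = 903, hlpa_upper = 2075)
}

#' Classify epoch vector-magnitude counts into intensity categories
#'
#' @param vm Numeric vector of vector-magnitude counts/min (>= 0). `NA` is
#'   propagated.
#' @param thresholds Band edges, see [evenson_thresholds()].
#' @return Factor with levels `SB`, `LLPA`, `HLPA`, `MVPA`.
#' @examples
#' classify_intensity(c(0, 75, 76, 903, 2075))
#' @export
classify_intensity <- function(vm, thresholds = evenson_thresholds()) {
  if (any(vm < 0, na.rm = TRUE)) {
    abort("negative vector-magnitude counts are not allowed",
          class = "mash_value_error")
  }
  cut(vm,
      breaks = c(0, thresholds$sb_upper, thresholds$llpa_upper,
                 thresholds$hlpa_upper, Inf),
      labels = c("SB", "LLPA", "HLPA", "MVPA"),
      right = FALSE, include.lowest = TRUE)
}

#' Choi non-wear detection on a 60-s vector-magnitude count sequence
#'
#' Non-wear is any run of at least `window_min` minutes of zero counts,
#' where up to `allowed_spike` consecutive nonzero minutes are tolerated
#' inside the run provided they are flanked by at least `flank_min` minutes
#' of zero counts on both sides. Missing counts are treated as zero for
#' detection. Defaults follow the published 60-s-epoch parameters of the
#' Choi algorithm (90 / 2 / 30).
#'
#' @param vm Numeric vector of vector-magnitude counts/min.
#' @param window_min Minimum non-wear run length, minutes.
#' @param allowed_spike Maximum tolerated consecutive nonzero minutes.
#' @param flank_min Zero-count flank required on each side of a spike.
#' @return Logical vector, `TRUE` where the device is classified as worn.
#' @export
choi_nonwear <- function(vm, window_min = 90L, allowed_spike = 2L,
                         flank_min = 30L) {
  if (length(vm) == 0L) {
    abort("empty count sequence", class = "mash_value_error")
  }
  vm <- ifelse(is.na(vm), 0, vm)
  zero <- vm <= 0

  # Absorb qualifying spikes: short nonzero runs flanked by long zero runs.
  r <- runs_tbl(zero)
  eff_zero <- zero
  nz <- which(!r$value)
  for (i in nz) {
    if (r$length[i] > allowed_spike) next
    left_ok <- i > 1L && r$value[i - 1L] && r$length[i - 1L] >= flank_min
    right_ok <- i < nrow(r) && r$value[i + 1L] && r$length[i + 1L] >= flank_min
    if (left_ok && right_ok) {
      eff_zero[r$start[i]:r$end[i]] <- TRUE
    }
  }

  wear <- rep(TRUE, length(vm))
  r2 <- runs_tbl(eff_zero)
  long <- r2$value & r2$length >= window_min
  for (i in which(long)) {
    wear[r2$start[i]:r2$end[i]] <- FALSE
  }
  wear
}

#' Per-day wear adherence and participant inclusion
#'
#' A calendar day (midnight to midnight, local clock) is adherent when it
#' contains at least `min_wear_min` minutes of hip-device wear. Use
#' [adherent_participants()] to apply the participant-level rule (at least
#' `min_days` adherent days, not necessarily consecutive).
#'
#' @param epochs Epoch tibble with `participant_id`, `timestamp`, `hip_vm`.
#' @param wear Optional logical wear flag aligned to `epochs`; computed with
#'   [choi_nonwear()] per participant when omitted.
#' @param min_wear_min Minimum daily wear minutes, default 600.
#' @return Tibble with one row per participant-day: `participant_id`,
#'   `date`, `wear_min`, `adherent`.
#' @export
adherent_days <- function(epochs, wear = NULL, min_wear_min = 600L) {
  if (is.null(wear)) {
    epochs <- epochs |>
      group_by(.data$participant_id) |>
      mutate(.wear = choi_nonwear(.data$hip_vm)) |>
      ungroup()
  } else {
    stopifnot(length(wear) == nrow(epochs))
    epochs$.wear <- wear
  }
  epochs |>
    mutate(date = as.Date(.data$timestamp)) |>
    group_by(.data$participant_id, .data$date) |>
    summarise(wear_min = sum(.data$.wear), .groups = "drop") |>
    mutate(adherent = .data$wear_min >= min_wear_min)
}

#' @param day_tbl Output of [adherent_days()].
#' @param min_days Minimum adherent days for inclusion, default 4.
#' @return Tibble with `participant_id`, `n_adherent_days`, `adherent`.
#' @rdname adherent_days
#' @export
adherent_participants <- function(day_tbl, min_days = 4L) {
  day_tbl |>
    group_by(.data$participant_id) |>
    summarise(n_adherent_days = sum(.data$adherent), .groups = "drop") |>
    mutate(adherent = .data$n_adherent_days >= min_days)
}
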