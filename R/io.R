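# Reading/writing minute-epoch device CSVs and aligning the two device
# streams onto one 60-s grid per participant.
#
# File dialects:
#   hip   : timestamp,axis1,axis2,axis3[,vm]
#   watch : timestamp,activity,white_light[,marker]
#   scored sleep : participant_id,night_date,onset,offset,total_sleep_min,valid
#   diary : participant_id,night_date,bed_time,try_sleep_time,wake_time,rise_time
# Timestamps are ISO-8601 local clock times at minute precision; non-standard
# column names are handled through an explicit `col_map`, never by sniffing.

empty_epochs <- function() {
  tibble(
    participant_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
    hip_axis1 = double(), hip_axis2 = double(), hip_axis3 = double(),
    hip_vm = double(), watch_activity = double(), watch_lux = double(),
    event_marker = logical()
  )
}

read_epoch_csv <- function(path, col_map, required) {
  x <- readr::read_csv(path, show_col_types = FALSE,
                       locale = readr::locale(tz = "UTC"))
  for (std in names(col_map)) {
    if (col_map[[std]] %in% names(x) && std != col_map[[std]]) {
      names(x)[names(x) == col_map[[std]]] <- std
    }
  }
  missing_req <- setdiff(required, names(x))
  if (length(missing_req) > 0L) {
    abort(sprintf("missing required column(s): %s",
                  paste(missing_req, collapse = ", ")),
          class = "mash_value_error")
  }
  if (!inherits(x$timestamp, "POSIXct")) {
    x$timestamp <- as.POSIXct(x$timestamp, tz = "UTC")
  }
  check_epoch_grid(x$timestamp, basename(path))
  x
}

#' Read a hip-accelerometer epoch CSV
#'
#' Expects columns `timestamp,axis1,axis2,axis3` and optionally `vm`. When
#' `vm` is absent it is computed as the Euclidean norm of the three axes;
#' when present it must agree with the norm to within 0.5 counts.
#'
#' @param path CSV path.
#' @param participant_id Participant label; defaults to the file name.
#' @param col_map Named character vector mapping standard names
#'   (`timestamp`, `axis1`, ...) to the file's column names.
#' @return An epoch tibble with hip channels populated and watch channels
#'   missing.
#' @export
read_hip_epochs <- function(path, participant_id = NULL, col_map = NULL) {
  map0 <- c(timestamp = "timestamp", axis1 = "axis1", axis2 = "axis2",
            axis3 = "axis3", vm = "vm")
  if (!is.null(col_map)) map0[names(col_map)] <- col_map
  x <- read_epoch_csv(path, map0, c("timestamp", "axis1", "axis2", "axis3"))
  for (a in c("axis1", "axis2", "axis3")) {
    if (any(x[[a]] < 0, na.rm = TRUE)) {
      abort(sprintf("negative counts in column %s", a),
            class = "mash_value_error")
    }
  }
  norm <- sqrt(x$axis1^2 + x$axis2^2 + x$axis3^2)
  if ("vm" %in% names(x)) {
    if (any(abs(x$vm - norm) > 0.5, na.rm = TRUE)) {
      abort("vm column disagrees with the Euclidean norm of the axes by > 0.5 counts",
            class = "mash_value_error")
    }
    vm <- x$vm
  } else {
    vm <- norm
  }
  tibble(
    participant_id = participant_id %||% sub("\\.[^.]*$", "", basename(path)),
    timestamp = x$timestamp,
    hip_axis1 = as.double(x$axis1), hip_axis2 = as.double(x$axis2),
    hip_axis3 = as.double(x$axis3), hip_vm = as.double(vm),
    watch_activity = NA_real_, watch_lux = NA_real_, event_marker = NA
  )
}

#' Read a wrist-actigraph epoch CSV
#'
#' Expects columns `timestamp,activity` and optionally `white_light` and
#' `marker`. Marker values `"M"`, `"1"`, `1` and `TRUE` map to a pressed
#' event marker; blank, `"0"` and `NA` map to not pressed. A missing lux
#' column loads with a warning and all-missing lux.
#'
#' @inheritParams read_hip_epochs
#' @return An epoch tibble with watch channels populated and hip channels
#'   missing.
#' @export
read_watch_epochs <- function(path, participant_id = NULL, col_map = NULL) {
  map0 <- c(timestamp = "timestamp", activity = "activity",
            white_light = "white_light", marker = "marker")
  if (!is.null(col_map)) map0[names(col_map)] <- col_map
  x <- read_epoch_csv(path, map0, c("timestamp", "activity"))
  if (any(x$activity < 0, na.rm = TRUE)) {
    abort("negative activity counts", class = "mash_value_error")
  }
  if (!"white_light" %in% names(x)) {
    warn("no lux column found; white light set to missing")
    x$white_light <- NA_real_
  }
  marker <- if ("marker" %in% names(x)) {
    as.character(x$marker) %in% c("M", "m", "1", "TRUE")
  } else {
    rep(FALSE, nrow(x))
  }
  tibble(
    participant_id = participant_id %||% sub("\\.[^.]*$", "", basename(path)),
    timestamp = x$timestamp,
    hip_axis1 = NA_real_, hip_axis2 = NA_real_, hip_axis3 = NA_real_,
    hip_vm = NA_real_,
    watch_activity = as.double(x$activity),
    watch_lux = as.double(x$white_light),
    event_marker = marker
  )
}

#' Write epoch tibbles back to the device CSV dialects
#'
#' @param epochs Epoch tibble (see [read_hip_epochs()]).
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_hip_epochs <- function(epochs, path) {
  readr::write_csv(
    tibble(timestamp = format(epochs$timestamp, "%Y-%m-%dT%H:%M:%SZ"),
           axis1 = epochs$hip_axis1, axis2 = epochs$hip_axis2,
           axis3 = epochs$hip_axis3, vm = epochs$hip_vm),
    path)
  invisible(path)
}

#' @rdname write_hip_epochs
#' @export
write_watch_epochs <- function(epochs, path) {
  readr::write_csv(
    tibble(timestamp = format(epochs$timestamp, "%Y-%m-%dT%H:%M:%SZ"),
           activity = epochs$watch_activity,
           white_light = epochs$watch_lux,
           marker = ifelse(is.na(epochs$event_marker), "",
                           ifelse(epochs$event_marker, "M", ""))),
    path)
  invisible(path)
}

#' Align hip and watch epoch streams onto one 60-s grid
#'
#' Produces a contiguous 60-s grid spanning the union of both devices'
#' coverage. Minutes covered by only one device carry missing values for
#' the other device's channels; zero temporal overlap triggers a warning
#' (not an error) because the hip-only pipeline must still run.
#'
#' @param hip,watch Epoch tibbles from [read_hip_epochs()] /
#'   [read_watch_epochs()] for the same participant.
#' @return A joined epoch tibble.
#' @export
align_streams <- function(hip, watch) {
  pid <- unique(c(hip$participant_id, watch$participant_id))
  pid <- pid[!is.na(pid)]
  if (length(pid) > 1L) {
    abort("hip and watch series belong to different participants",
          class = "mash_value_error")
  }
  if (nrow(hip) > 0L && nrow(watch) > 0L) {
    if (max(hip$timestamp) < min(watch$timestamp) ||
        max(watch$timestamp) < min(hip$timestamp)) {
      warn("hip and watch streams do not overlap in time")
    }
  }
  ts_all <- c(hip$timestamp, watch$timestamp)
  grid <- tibble(timestamp = seq(min(ts_all), max(ts_all), by = EPOCH_SEC))
  out <- grid |>
    left_join(hip |> select("timestamp", "hip_axis1", "hip_axis2",
                            "hip_axis3", "hip_vm"),
              by = "timestamp") |>
    left_join(watch |> select("timestamp", "watch_activity", "watch_lux",
                              "event_marker"),
              by = "timestamp") |>
    mutate(participant_id = pid[1L], .before = 1L)
  check_epoch_grid(out$timestamp, "aligned series")
  out
}

#' Read and write scored-sleep record CSVs
#'
#' Dialect: `participant_id,night_date,onset,offset,total_sleep_min,valid`.
#'
#' @param path CSV path.
#' @return A sleep-record tibble.
#' @export
read_scored_sleep <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE,
                       locale = readr::locale(tz = "UTC"))
  tibble(
    participant_id = as.character(x$participant_id),
    night_date = as.Date(x$night_date),
    onset = as.POSIXct(x$onset, tz = "UTC"),
    offset = as.POSIXct(x$offset, tz = "UTC"),
    total_scored_sleep = as.double(x$total_sleep_min),
    valid = as.logical(x$valid),
    source = if ("source" %in% names(x)) as.character(x$source) else "SCORED"
  )
}

#' @param sleep Sleep-record tibble.
#' @rdname read_scored_sleep
#' @export
write_scored_sleep <- function(sleep, path) {
  readr::write_csv(
    tibble(participant_id = sleep$participant_id,
           night_date = sleep$night_date,
           onset = format(sleep$onset, "%Y-%m-%dT%H:%M:%SZ"),
           offset = format(sleep$offset, "%Y-%m-%dT%H:%M:%SZ"),
           total_sleep_min = sleep$total_scored_sleep,
           valid = sleep$valid,
           source = sleep$source),
    path)
  invisible(path)
}

#' Read a sleep-diary CSV
#'
#' Dialect:
#' `participant_id,night_date,bed_time,try_sleep_time,wake_time,rise_time`.
#'
#' @param path CSV path.
#' @return A diary tibble with POSIXct clock-time columns.
#' @export
read_sleep_diary <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE,
                       locale = readr::locale(tz = "UTC"))
  tibble(
    participant_id = as.character(x$participant_id),
    night_date = as.Date(x$night_date),
    bed_time = as.POSIXct(x$bed_time, tz = "UTC"),
    try_sleep_time = as.POSIXct(x$try_sleep_time, tz = "UTC"),
    wake_time = as.POSIXct(x$wake_time, tz = "UTC"),
    rise_time = as.POSIXct(x$rise_time, tz = "UTC")
  )
}
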