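# Shared internal helpers: epoch grid conventions and run-length utilities.
#
# Conventions used package-wide:
#   * one epoch = 60 s; a timestamp marks the epoch START
#   * intervals are half-open [start, end) in minutes
#   * timestamps are timezone-naive local clock times carried as POSIXct/UTC

EPOCH_SEC <- 60

mash_origin <- function() as.POSIXct("2024-01-06 00:00:00", tz = "UTC")

minutes_of <- function(ts, origin) {
  as.numeric(difftime(ts, origin, units = "mins"))
}

# Validate a strictly increasing, exactly 60-s-spaced timestamp grid.
check_epoch_grid <- function(ts, what = "series") {
  if (length(ts) < 2L) return(invisible(TRUE))
  dt <- as.numeric(difftime(ts[-1L], ts[-length(ts)], units = "secs"))
  bad <- which(dt != EPOCH_SEC)
  if (length(bad) > 0L) {
    abort(sprintf(
      "%s is not on a 60-s epoch grid: spacing of %.0f s before %s",
      what, dt[bad[1L]], format(ts[bad[1L] + 1L], "%Y-%m-%d %H:%M:%S")
    ), class = "mash_grid_error")
  }
  if (anyDuplicated(ts)) {
    abort(sprintf("%s contains duplicated timestamps", what),
          class = "mash_grid_error")
  }
  invisible(TRUE)
}

# Run-length encoding as a tibble of [start, end] index ranges.
runs_tbl <- function(x) {
  r <- rle(x)
  len <- r$lengths
  end <- cumsum(len)
  tibble(
    start = end - len + 1L,
    end = end,
    length = len,
    value = r$values
  )
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so library calls do not perturb user streams.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed derivation, kept below 2^31.
sub_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 1009) %% 2147483587)
}
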