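# Actiware-style scorer: weighted wake score, immobility-rule bounds,
# rest-window anchoring, validity screening.

night_start <- as.POSIXct("2024-02-01 12:00:00", tz = "UTC")

# A hand-built night: active evening, immobile sleep block, active morning.
# Flank activity of 150 counts/min keeps the weighted wake score of the
# boundary sleep epochs at 36 (under the 40 threshold).
build_night <- function(pid = "N1", evening = 540, sleep = 420,
                        morning = 480, marker_at = NULL,
                        sleep_counts = 0, active_counts = 150) {
  act <- c(rep(active_counts, evening), rep_len(sleep_counts, sleep),
           rep(active_counts, morning))
  marker <- rep(FALSE, length(act))
  if (!is.null(marker_at)) marker[marker_at] <- TRUE
  make_epochs(pid, night_start, activity = act, hip_vm = 10,
              lux = 50, marker = marker)
}

test_that("weighted wake score reproduces the direct evaluation", {
  expect_equal(wake_score(c(0, 0, 41, 0, 0))[3], 41)
  expect_true(score_epochs(c(0, 0, 41, 0, 0))[3])      # 41 > 40 -> WAKE
  expect_false(score_epochs(c(0, 0, 40, 0, 0))[3])     # 40 is not > 40
  expect_equal(wake_score(rep(0, 5)), rep(0, 5))
  # weights act on the neighbours
  w <- wake_score(c(0, 100, 0, 0, 0))
  expect_equal(w[1], 20)   # 0.20 * 100
  expect_equal(w[3], 20)
  expect_equal(w[4], 4)    # 0.04 * 100
})

test_that("onset/offset follow the 10-consecutive-immobile-minute rule", {
  # window whose first 10 minutes are immobile: onset at window start
  b <- find_onset_offset(c(rep(0, 10), rep(100, 50)))
  expect_equal(b[["onset"]], 1L)
  # 9 zeros, 1 nonzero, then 10 zeros: onset at the later run
  cnt <- c(rep(0, 9), 50, rep(0, 10), rep(100, 30))
  b2 <- find_onset_offset(cnt)
  expect_equal(b2[["onset"]], 11L)
  expect_equal(b2, oracle_onset_offset(cnt)[c("onset", "offset_end")],
               ignore_attr = TRUE)
  # entirely mobile window: no bounds
  expect_null(find_onset_offset(rep(100, 60)))
})

test_that("immobility bounds match the exhaustive scan on random nights", {
  set.seed(7)
  for (i in 1:40) {
    n <- sample(60:400, 1)
    cnt <- sample(c(0, 0, 0, 0, 20, 150), n, replace = TRUE)
    got <- find_onset_offset(cnt)
    want <- oracle_onset_offset(cnt)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got, want[c("onset", "offset_end")], ignore_attr = TRUE)
    }
  }
})

test_that("rest-window anchors follow marker > diary > heuristic priority", {
  ne <- build_night(marker_at = c(660, 1100))     # 23:00 and ~06:20
  a <- anchor_rest_interval(ne)
  expect_equal(a$anchor, "marker")
  expect_equal(a$start, ne$timestamp[660])
  expect_equal(a$end, ne$timestamp[1100])

  ne2 <- build_night()
  diary <- tibble::tibble(participant_id = "N1",
                          night_date = as.Date("2024-02-01"),
                          bed_time = ne2$timestamp[630],
                          try_sleep_time = ne2$timestamp[640],
                          wake_time = ne2$timestamp[1000],
                          rise_time = ne2$timestamp[1010])
  a2 <- anchor_rest_interval(ne2, diary)
  expect_equal(a2$anchor, "diary")
  expect_equal(a2$start, ne2$timestamp[630])

  a3 <- anchor_rest_interval(ne2)
  expect_equal(a3$anchor, "heuristic")
  expect_true(a3$low_confidence)
  # the heuristic window sits over the immobile block
  expect_true(a3$start >= ne2$timestamp[400] &&
                a3$start <= ne2$timestamp[700])
})

test_that("validity screening applies the 60-min rule and malfunction flag", {
  # 59 immobile (sleep-scored) minutes -> invalid; 60 -> valid
  mk <- function(sleep_min) {
    ne <- build_night(evening = 540, sleep = sleep_min, morning = 900,
                      marker_at = c(535, 540 + sleep_min + 5))
    score_sleep(ne)
  }
  r59 <- mk(59)
  expect_false(r59$valid)
  expect_equal(r59$reason, "short sleep")
  expect_equal(r59$total_scored_sleep, 59)
  r60 <- mk(60)
  expect_true(r60$valid)
  expect_equal(r60$total_scored_sleep, 60)

  # all-missing watch channels -> malfunction
  ne <- build_night()
  ne$watch_activity <- NA_real_
  ne$watch_lux <- NA_real_
  rm <- score_sleep(ne)
  expect_false(rm$valid)
  expect_match(rm$reason, "malfunction")

  # entirely mobile night -> no/poor sleep
  ne2 <- make_epochs("N1", night_start, activity = 200, hip_vm = 10,
                     n = 1440)
  rp <- score_sleep(ne2)
  expect_false(rp$valid)
  expect_match(rp$reason, "no/poor sleep")
})

test_that("scoring is translation-invariant under a k-minute shift", {
  k <- 23L
  ne <- build_night(marker_at = c(520, 1020))
  shifted <- ne
  shifted$watch_activity <- c(rep(150, k),
                              ne$watch_activity[1:(nrow(ne) - k)])
  shifted$event_marker <- c(rep(FALSE, k),
                            ne$event_marker[1:(nrow(ne) - k)])
  r1 <- score_sleep(ne)
  r2 <- score_sleep(shifted)
  expect_equal(as.numeric(difftime(r2$onset, r1$onset, units = "mins")), k)
  expect_equal(as.numeric(difftime(r2$offset, r1$offset, units = "mins")),
               k)
  # and the bounds stay inside the anchored window
  expect_gte(as.numeric(r1$onset), as.numeric(ne$timestamp[520]))
  expect_lte(as.numeric(r1$offset), as.numeric(ne$timestamp[1020]) + 60)
})

test_that("scored onsets track simulated truth to immobility granularity", {
  co <- simulate_cohort(sim_spec(n_participants = 30, n_days = 7,
                                 marker_compliance = 1,
                                 seed = 90909))
  sl <- score_sleep(co$epochs, co$diary)
  tr <- truth_sleep_records(co)
  j <- dplyr::inner_join(dplyr::filter(sl, .data$valid), tr,
                         by = c("participant_id", "night_date"))
  expect_gte(nrow(j), 150)
  err <- abs(as.numeric(difftime(j$onset.x, j$onset.y, units = "mins")))
  expect_lte(median(err), 10)
})
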