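# Exclusion rules, tier routing, device reconciliation and composition
# closure.

test_that("degenerate fixtures route and exclude as constructed", {
  # all flags cleared: nothing is excluded
  fx0 <- fig1_day_fixture(counts = list(
    participants = 5L, first_days = 0L, no_preceding = 0L,
    short_sleep = 0L, scored = 40L, onset_missing = 0L,
    offset_missing = 0L, both_missing = 0L))
  ex0 <- apply_exclusions(fx0)
  expect_true(all(ex0$disposition == "kept"))

  # a scaled fixture reproduces its own marginals through the real router
  fx <- fig1_day_fixture(counts = list(
    participants = 20L, no_preceding = 6L, short_sleep = 2L,
    scored = 80L, onset_missing = 10L, offset_missing = 3L,
    both_missing = 9L))
  ex <- apply_exclusions(fx)
  expect_equal(sum(ex$disposition == "excluded_first_day"), 20L)
  expect_equal(sum(ex$disposition == "excluded_no_preceding_sleep"), 6L)
  expect_equal(sum(ex$disposition == "excluded_short_sleep"), 2L)
  kept <- route_days(dplyr::filter(ex, .data$disposition == "kept"))
  expect_equal(sum(kept$tier == "SCORED"), 80L)
  expect_equal(sum(kept$subcase %in% "onset_missing"), 10L)
  expect_equal(sum(kept$subcase %in% "offset_missing"), 3L)
  expect_equal(sum(kept$subcase %in% "both_missing"), 9L)
})

test_that("exclusion order and boundaries follow the printed rules", {
  flags <- tibble::tibble(
    participant_id = "X", day_index = 1:5,
    first_day = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    preceding_sleep_available = c(FALSE, FALSE, TRUE, TRUE, TRUE),
    preceding_sleep_min = c(NA, NA, 59, 60, NA),
    onset_missing = FALSE, offset_missing = FALSE, watch_coverage = 1)
  ex <- apply_exclusions(flags)
  # first-day rule wins even when other rules also match
  expect_equal(ex$disposition,
               c("excluded_first_day", "excluded_no_preceding_sleep",
                 "excluded_short_sleep", "kept", "kept"))
})

test_that("tier routing covers the three missing-bound sub-cases", {
  flags <- tibble::tibble(
    participant_id = "X", day_index = 1:4,
    first_day = FALSE, preceding_sleep_available = TRUE,
    preceding_sleep_min = NA_real_,
    onset_missing = c(FALSE, TRUE, FALSE, TRUE),
    offset_missing = c(FALSE, FALSE, TRUE, TRUE),
    watch_coverage = c(1, 1, 0.2, 0.2))
  r <- route_days(flags)
  expect_equal(r$tier, c("SCORED", "CNN", "CNN", "CNN"))
  expect_equal(r$subcase, c(NA, "onset_missing", "offset_missing",
                            "both_missing"))
  expect_equal(r$variant, c(NA, "DUAL", "HIP_ONLY", "HIP_ONLY"))
})

# Hand-built two-night participant for the reconciliation rules: scored
# sleep 23:00 -> 07:00 and 23:30 -> 06:30; hip worn 30 min into the first
# night's sleep at sedentary-range counts.
build_recon_case <- function(sleep_intrusion_min = 30L) {
  origin <- as.POSIXct("2024-02-01 00:00:00", tz = "UTC")
  n <- 3 * 1440
  hip <- numeric(n)
  day1_on <- 1380L                      # 23:00 day 1
  day2_off <- 1440L + 420L              # 07:00 day 2
  day2_on <- 1440L + 1410L              # 23:30 day 2
  hip[601:day1_on] <- 400                         # day-1 waking LLPA
  if (sleep_intrusion_min > 0) {
    hip[(day1_on + 1):(day1_on + sleep_intrusion_min)] <- 20  # SB-range
  }
  hip[(day2_off + 1):day2_on] <- 400              # day-2 waking LLPA
  ep <- make_epochs("R1", origin, activity = 30, hip_vm = hip, lux = 10)
  sl <- tibble::tibble(
    participant_id = "R1",
    night_date = as.Date(origin) + 0:1,
    onset = origin + c(day1_on, day2_on) * 60,
    offset = origin + c(day2_off, 2 * 1440 + 390) * 60,
    total_scored_sleep = c(440, 420), valid = TRUE, source = "SCORED")
  list(ep = ep, sl = sl)
}

test_that("reconciliation strips waking behavior inside sleep, never adds", {
  cs <- build_recon_case(30L)
  h <- harmonize(cs$ep, cs$sl)
  cc <- h$compositions
  expect_equal(nrow(cc), 1L)             # day 2 only (day 1 first, day 3 no onset)
  expect_equal(cc$tier, "SCORED")
  expect_equal(cc$corr_sb_min, -30)      # the 30 intruding SB minutes
  expect_equal(cc$corr_llpa_min, 0)
  expect_equal(cc$corr_hlpa_min, 0)
  expect_equal(cc$corr_mvpa_min, 0)
  expect_true(cc$corrected)
  # interval size: 23:00 -> 23:30 next day = 24.5 h
  expect_equal(cc$interval_size_h, 24.5)
  # closure: sleep + behaviors + non-wear = interval exactly
  expect_equal(cc$sleep_min + cc$sb_min + cc$llpa_min + cc$hlpa_min +
                 cc$mvpa_min + cc$nonwear_within_wake_min,
               cc$interval_size_h * 60)

  # hip removed exactly at onset: zero correction
  cs0 <- build_recon_case(0L)
  h0 <- harmonize(cs0$ep, cs0$sl)
  cc0 <- h0$compositions
  expect_equal(cc0$corr_sb_min, 0)
  expect_equal(cc0$corr_total_wake_min, 0)
  expect_false(cc0$corrected)
  # the last day is ledgered as lacking an evening onset
  expect_true("excluded_no_evening_onset" %in% h0$ledger$disposition)
})

test_that("single-day participants keep no compositions", {
  origin <- as.POSIXct("2024-02-01 00:00:00", tz = "UTC")
  ep <- make_epochs("S1", origin, activity = 30, hip_vm = 100, n = 1440)
  h <- harmonize(ep, tibble::tibble(
    participant_id = character(), night_date = as.Date(character()),
    onset = as.POSIXct(character(), tz = "UTC"),
    offset = as.POSIXct(character(), tz = "UTC"),
    total_scored_sleep = double(), valid = logical(),
    source = character()))
  expect_equal(nrow(h$compositions), 0L)
})

test_that("consecutive kept days share their night bound (bi-directional)", {
  h <- eval_harmony()
  cc <- h$compositions |>
    dplyr::arrange(.data$participant_id, .data$date) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(consecutive = !is.na(dplyr::lag(.data$date)) &
                    .data$date == dplyr::lag(.data$date) + 1,
                  prev_onset_match = .data$onset_prev ==
                    dplyr::lag(.data$onset)) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$consecutive)
  expect_gt(nrow(cc), 50)
  expect_true(all(cc$prev_onset_match))
})

test_that("harmonized interval sizes sit in the expected daily band", {
  cc <- eval_harmony()$compositions
  expect_gt(nrow(cc), 150)
  expect_true(mean(cc$interval_size_h) > 23 &&
                mean(cc$interval_size_h) < 25)
})
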