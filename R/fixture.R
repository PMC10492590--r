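# Deterministic day-level routing fixture encoding the published
# participant-flow of the development cohort: 10,123 device days across
# 1,285 participants, the three exclusion rules (first day 1,285; no
# preceding sleep 269; under 60 min of sleep 9), and the tier routing of
# the 8,560 analytic days (7,270 scored; 503 onset-only missing; 32
# offset-only missing; 755 both missing).

#' Day-level participant-flow fixture
#'
#' Builds, fully in code and without randomness, a day-level table whose
#' marginal flag counts equal the published flow counts, in the exact
#' column layout consumed by [apply_exclusions()] and [route_days()]. Row
#' order and participant assignment are deterministic conventions; only
#' the marginal counts are meaningful.
#'
#' @param counts Named list of the flow counts; override to build scaled
#'   or degenerate variants (e.g., all flags cleared). An optional
#'   `first_days` entry (default `participants`) sets how many first-day
#'   rows are flagged.
#' @return Tibble with one row per device day: `participant_id`,
#'   `day_index`, `first_day`, `preceding_sleep_available`,
#'   `preceding_sleep_min`, `onset_missing`, `offset_missing`,
#'   `watch_coverage`.
#' @examples
#' fx <- fig1_day_fixture()
#' nrow(fx) # 10123
#' @export
fig1_day_fixture <- function(counts = list(
                               participants = 1285L,
                               no_preceding = 269L,
                               short_sleep = 9L,
                               scored = 7270L,
                               onset_missing = 503L,
                               offset_missing = 32L,
                               both_missing = 755L)) {
  np <- counts$participants
  n_first <- counts$first_days %||% np
  cat_counts <- c(scored = counts$scored,
                  onset = counts$onset_missing,
                  offset = counts$offset_missing,
                  both = counts$both_missing,
                  no_preceding = counts$no_preceding,
                  short = counts$short_sleep)
  categories <- rep(names(cat_counts), cat_counts)
  # Deterministic interleave across participants: day k of the cycle goes
  # to participant (k mod np) + 1.
  n_rest <- length(categories)
  pid_rest <- (seq_len(n_rest) - 1L) %% np + 1L
  ord <- order(pid_rest)
  rest <- tibble(
    pid = pid_rest[ord],
    category = categories[ord]
  ) |>
    group_by(.data$pid) |>
    mutate(day_index = row_number() + 1L) |>
    ungroup()

  first_days <- tibble(pid = seq_len(n_first), category = "first",
                       day_index = 1L)
  all_days <- bind_rows(first_days, rest) |>
    arrange(.data$pid, .data$day_index)

  tibble(
    participant_id = sprintf("F%04d", all_days$pid),
    day_index = all_days$day_index,
    first_day = all_days$category == "first",
    preceding_sleep_available = all_days$category != "no_preceding",
    preceding_sleep_min = dplyr::case_when(
      all_days$category == "short" ~ 45,
      all_days$category %in% c("scored", "onset") ~ 430,
      all_days$category == "first" ~ 430,
      TRUE ~ NA_real_
    ),
    onset_missing = all_days$category %in% c("onset", "both"),
    offset_missing = all_days$category %in% c("offset", "both"),
    watch_coverage = ifelse(all_days$category %in% c("offset", "both",
                                                     "onset"), 0.3, 1.0)
  )
}
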