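# Shared fixtures, built once per test run and cached in an environment so
# the expensive pieces (the evaluation cohort and the trained CNNs) are
# reused across test files.

.mash_test_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .mash_test_cache, inherits = FALSE)) {
    assign(name, force(expr), envir = .mash_test_cache)
  }
  get(name, envir = .mash_test_cache)
}

# Desk-scale network used throughout the suite (the full-size default
# architecture is exercised by the gradient and shape tests).
test_arch <- function() cnn_architecture(filters = c(16L, 32L),
                                         kernels = c(7L, 5L),
                                         dense_units = 32L)

small_cohort <- function() {
  cached("small_cohort",
         simulate_cohort(sim_spec(n_participants = 10, n_days = 4,
                                  seed = 424241)))
}

# Evaluation cohort: 100 participants x 7 nights at generator defaults.
eval_cohort <- function() {
  cached("eval_cohort",
         simulate_cohort(sim_spec(n_participants = 100, n_days = 7,
                                  seed = 20260928)))
}

eval_sleep <- function() {
  cached("eval_sleep", score_sleep(eval_cohort()$epochs, eval_cohort()$diary))
}

eval_labels <- function() {
  cached("eval_labels", label_epochs(eval_cohort()$epochs, eval_sleep()))
}

eval_split <- function() {
  cached("eval_split",
         make_split(unique(eval_cohort()$epochs$participant_id),
                    seed = 710710))
}

eval_model <- function(variant) {
  cached(paste0("eval_model_", variant), {
    train_wake_cnn(eval_cohort()$epochs, eval_labels(), eval_split(),
                   variant = variant, arch = test_arch(),
                   n_train_windows = 6000L, n_val_windows = 1200L,
                   n_test_windows = 2400L, n_epochs = 5L, seed = 885511)
  })
}

# Held-out evaluation scores: per-epoch probabilities and labels on two
# full days of each test-split participant.
eval_heldout <- function(variant) {
  cached(paste0("eval_heldout_", variant), {
    co <- eval_cohort()
    ids <- eval_split()$participant_id[eval_split()$split == "test"]
    d0 <- as.Date(min(co$epochs$timestamp))
    sl <- co$epochs |>
      dplyr::filter(.data$participant_id %in% ids,
                    as.Date(.data$timestamp) %in% (d0 + c(2L, 3L)))
    pr <- predict_wake_prob(eval_model(variant), sl)
    dplyr::inner_join(pr, eval_labels(),
                      by = c("participant_id", "timestamp"))
  })
}

eval_gapdist <- function() {
  cached("eval_gapdist",
         fit_gap_distribution(eval_sleep(), eval_cohort()$epochs))
}

# Harmonization of a 50-participant subset with both models and the
# fitted gap distribution.
eval_harmony <- function() {
  cached("eval_harmony", {
    co <- eval_cohort()
    ids <- sprintf("P%04d", 1:50)
    ep <- co$epochs |> dplyr::filter(.data$participant_id %in% ids)
    sl <- eval_sleep() |> dplyr::filter(.data$participant_id %in% ids)
    harmonize(ep, sl, model_dual = eval_model("dual"),
              model_hip = eval_model("hip"), gap_dist = eval_gapdist(),
              seed = 515151)
  })
}

# Onset-correction evaluation: a dedicated cohort where most nights lack
# watch data, so the CNN path is exercised on >= 200 nights. Returns one
# row per evaluated night with true onset, raw CNN onset and corrected
# onset.
correction_eval <- function() {
  cached("correction_eval", {
    co <- simulate_cohort(sim_spec(
      n_participants = 50, n_days = 5,
      missing_night_rates = c(watch_malfunction_night = 0.85,
                              watch_removed_night = 0,
                              hip_worn_to_bed = 0.10),
      seed = 33003300))
    model <- eval_model("hip")
    dist <- eval_gapdist()
    truth <- truth_sleep_records(co)
    nights <- co$truth_days |>
      dplyr::filter(.data$watch_malfunction_night %in% TRUE)
    rows <- list()
    set.seed(606060)
    for (i in seq_len(nrow(nights))) {
      pid <- nights$participant_id[i]
      tr <- truth[truth$participant_id == pid &
                    truth$night_date == as.Date(mash_origin()) +
                    nights$day[i] - 1L, ]
      if (nrow(tr) != 1L) next
      # evening span 16:00 -> 04:00 around the night
      a <- as.POSIXct(paste(tr$night_date, "16:00:00"), tz = "UTC")
      b <- a + 12 * 3600
      sl <- co$epochs[co$epochs$participant_id == pid &
                        co$epochs$timestamp >= a &
                        co$epochs$timestamp < b, ]
      pr <- predict_wake_prob(model, sl)
      iv <- wake_interval_from_probs(pr$prob, model$cutoff)
      if (is.null(iv)) next
      raw_onset <- sl$timestamp[iv$end_idx - 1L] + 60
      wake_len <- as.numeric(difftime(raw_onset, sl$timestamp[iv$start_idx],
                                      units = "mins"))
      corr <- correct_cnn_onset(raw_onset, wake_len, dist)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        participant_id = pid, night_date = tr$night_date,
        true_onset = tr$onset, raw_onset = raw_onset,
        corrected_onset = corr$onset)
    }
    dplyr::bind_rows(rows)
  })
}

mash_origin <- function() as.POSIXct("2024-01-06 00:00:00", tz = "UTC")

# Hand-built epoch stream: one participant, arbitrary channel vectors.
make_epochs <- function(pid, start, activity = NULL, hip_vm = NULL,
                        lux = NULL, marker = NULL, n = NULL) {
  n <- n %||% max(length(activity), length(hip_vm))
  rep_or_na <- function(x) if (is.null(x)) rep(NA_real_, n) else
    rep_len(as.double(x), n)
  vm <- rep_or_na(hip_vm)
  tibble::tibble(
    participant_id = pid,
    timestamp = start + as.difftime(0:(n - 1L), units = "mins"),
    hip_axis1 = vm, hip_axis2 = 0, hip_axis3 = 0, hip_vm = vm,
    watch_activity = rep_or_na(activity),
    watch_lux = rep_or_na(lux),
    event_marker = if (is.null(marker)) rep(FALSE, n) else
      rep_len(as.logical(marker), n)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
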