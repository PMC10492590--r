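# CNN engine correctness (gradient check, shapes), splits, labeling,
# Youden cutoff, and learnability on a separable toy stream.

test_that("backpropagated gradients match finite differences", {
  set.seed(12)
  arch <- cnn_architecture(filters = c(2L, 3L), kernels = c(3L, 3L),
                           pool = c(2L, 2L), dense_units = 4L)
  X <- array(rnorm(4 * 15 * 2), c(4, 15, 2))
  y <- c(0, 1, 1, 0)
  params <- mash:::cnn_init(arch, 15L, 2L)
  cache <- mash:::cnn_forward(params, arch, X)
  grads <- mash:::cnn_backward(params, arch, cache, y)
  eps <- 1e-5
  for (nm in names(params)) {
    p <- params[[nm]]
    idx <- seq_len(min(length(p), 6L))
    for (i in idx) {
      pp <- params
      pp[[nm]][i] <- pp[[nm]][i] + eps
      up <- mash:::bce_loss(mash:::cnn_forward(pp, arch, X,
                                               keep_cache = FALSE)$prob, y)
      pp[[nm]][i] <- pp[[nm]][i] - 2 * eps
      dn <- mash:::bce_loss(mash:::cnn_forward(pp, arch, X,
                                               keep_cache = FALSE)$prob, y)
      num <- (up - dn) / (2 * eps)
      expect_equal(grads[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("participant splits are disjoint, exhaustive and reproducible", {
  ids <- sprintf("S%04d", 1:1112)
  sp <- make_split(ids, seed = 9)
  expect_equal(as.integer(table(sp$split)[c("training", "test",
                                            "validation")]),
               c(625L, 278L, 209L))
  expect_setequal(sp$participant_id, ids)
  expect_equal(anyDuplicated(sp$participant_id), 0L)
  expect_identical(sp, make_split(ids, seed = 9))
  expect_false(identical(sp, make_split(ids, seed = 10)))
})

test_that("epoch labels are half-open at offset and onset", {
  origin <- as.POSIXct("2024-02-01 00:00:00", tz = "UTC")
  ep <- make_epochs("L1", origin, activity = 10, hip_vm = 10, n = 3 * 1440)
  mkrec <- function(date, on_h, off_h, valid = TRUE) {
    tibble::tibble(participant_id = "L1", night_date = as.Date(date),
                   onset = as.POSIXct(paste(date, on_h), tz = "UTC"),
                   offset = as.POSIXct(paste(as.Date(date) + 1, off_h),
                                       tz = "UTC"),
                   total_scored_sleep = 420, valid = valid,
                   source = "SCORED")
  }
  sl <- dplyr::bind_rows(mkrec("2024-02-01", "23:00:00", "07:00:00"),
                         mkrec("2024-02-02", "22:30:00", "06:30:00"))
  lab <- label_epochs(ep, sl)
  off <- as.POSIXct("2024-02-02 07:00:00", tz = "UTC")
  on2 <- as.POSIXct("2024-02-02 22:30:00", tz = "UTC")
  expect_equal(lab$label[lab$timestamp == off], 1L)           # at offset: wake
  expect_equal(lab$label[lab$timestamp == off - 60], 0L)      # one before: sleep
  expect_equal(lab$label[lab$timestamp == on2], 0L)           # at onset: sleep
  expect_equal(lab$label[lab$timestamp == on2 - 60], 1L)
  # labels only between the two valid onsets
  expect_true(all(lab$timestamp >= sl$onset[1] &
                    lab$timestamp <= sl$onset[2]))

  # an invalid night removes the surrounding days' labels
  sl2 <- sl
  sl2$valid[2] <- FALSE
  expect_equal(nrow(label_epochs(ep, sl2)), 0L)

  # overlapping records are inconsistent
  sl3 <- sl
  sl3$onset[2] <- sl3$offset[1] - 3600
  expect_error(label_epochs(ep, sl3), class = "mash_value_error")
})

test_that("pooled label prevalence sits at the 66/33 design split", {
  lab <- eval_labels()
  expect_lt(abs(mean(lab$label) - 0.66), 0.03)
})

test_that("youden cutoff maximizes J with ties toward the higher cutoff", {
  # perfect separation: J = 1 anywhere in (0.2, 0.8]; tie-break -> 0.8
  y1 <- youden_cutoff(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(y1$cutoff, 0.8)
  expect_equal(y1$j, 1)
  # interleaved case checked against exhaustive enumeration
  p2 <- c(0.2, 0.4, 0.6, 0.8)
  l2 <- c(0, 1, 0, 1)
  y2 <- youden_cutoff(p2, l2)
  o2 <- oracle_youden(p2, l2)
  expect_equal(y2$cutoff, o2$cutoff)
  expect_equal(y2$cutoff, 0.8)
  expect_equal(y2$j, o2$j)
  # flipping all labels yields the complementary classifier's J
  set.seed(3)
  p <- runif(200)
  l <- rbinom(200, 1, plogis(4 * (p - 0.5)))
  l[1:2] <- c(0L, 1L)
  jf <- youden_cutoff(p, l)$j
  jc <- youden_cutoff(-p, 1 - l)$j
  expect_equal(jf, jc, tolerance = 1e-12)
  expect_error(youden_cutoff(p, rep(1, 200)), class = "mash_value_error")
})

test_that("youden agrees with exhaustive search on random score sets", {
  set.seed(11)
  for (i in 1:30) {
    n <- sample(c(20L, 87L, 200L), 1L)
    p <- round(runif(n), sample(1:3, 1))   # force ties
    l <- rbinom(n, 1, 0.5)
    if (length(unique(l)) < 2L) l[1:2] <- c(0L, 1L)
    got <- youden_cutoff(p, l)
    want <- oracle_youden(p, l)
    expect_equal(got$cutoff, want$cutoff)
    expect_equal(got$j, want$j, tolerance = 1e-12)
  }
})

test_that("a separable toy stream is learned to near-perfect AUC", {
  # constant high hip counts by day, zeros by night: separable by design
  origin <- as.POSIXct("2024-02-01 00:00:00", tz = "UTC")
  n_days <- 3
  eps <- list(); sls <- list()
  set.seed(21)
  for (p in 1:8) {
    pid <- sprintf("T%02d", p)
    act <- hip <- numeric(n_days * 1440)
    sl <- list()
    prev_off <- 0L
    for (d in 1:n_days) {
      on <- (d - 1) * 1440 + 1380
      off <- min(d * 1440 + 450, n_days * 1440)
      day_idx <- (prev_off + 1):on        # wake runs from the prior offset
      hip[day_idx] <- 800 + round(rnorm(length(day_idx), 0, 20))
      act[day_idx] <- 300
      if (off > on) {
        hip[(on + 1):off] <- 0
        act[(on + 1):off] <- 0
      }
      prev_off <- off
      date <- as.Date(origin) + d - 1
      sl[[d]] <- tibble::tibble(
        participant_id = pid, night_date = date,
        onset = origin + on * 60,
        offset = origin + off * 60,
        total_scored_sleep = off - on, valid = off - on >= 60,
        source = "SCORED")
    }
    eps[[p]] <- make_epochs(pid, origin, activity = act, hip_vm = hip,
                            lux = 10)
    sls[[p]] <- dplyr::bind_rows(sl)
  }
  ep <- dplyr::bind_rows(eps)
  sl <- dplyr::bind_rows(sls)
  lab <- label_epochs(ep, sl)
  sp <- make_split(unique(ep$participant_id),
                   fractions = c(training = 0.5, test = 0.25,
                                 validation = 0.25), seed = 4)
  m <- train_wake_cnn(ep, lab, sp, "hip",
                      arch = cnn_architecture(filters = c(4L, 8L),
                                              dense_units = 8L),
                      n_train_windows = 1200L, n_val_windows = 300L,
                      n_test_windows = 300L, n_epochs = 8L, batch = 32L,
                      lr = 3e-3, patience = 4L, seed = 14)
  # training loss decreases from its starting point
  h <- tidy(m)
  expect_lt(utils::tail(h$train_loss, 1), h$train_loss[1] + 1e-6)
  # held-out participants separate almost perfectly
  ids <- sp$participant_id[sp$split == "test"]
  pe <- ep |> dplyr::filter(.data$participant_id %in% ids)
  pr <- predict_wake_prob(m, pe) |>
    dplyr::inner_join(lab, by = c("participant_id", "timestamp"))
  expect_gte(roc_pr(pr$prob, pr$label)$roc_auc, 0.99)
  expect_true(all(pr$prob >= 0 & pr$prob <= 1))
  expect_false(any(pr$fully_padded))
})

test_that("hip-only variant trains when watch channels are entirely absent", {
  origin <- as.POSIXct("2024-02-01 00:00:00", tz = "UTC")
  set.seed(31)
  eps <- list(); sls <- list()
  for (p in 1:6) {
    pid <- sprintf("H%02d", p)
    hip <- numeric(2 * 1440)
    sl <- list()
    prev_off <- 0L
    for (d in 1:2) {
      on <- (d - 1) * 1440 + 1380
      off <- min(d * 1440 + 450, 2 * 1440)
      hip[(prev_off + 1):on] <- 500
      prev_off <- off
      sl[[d]] <- tibble::tibble(
        participant_id = pid, night_date = as.Date(origin) + d - 1,
        onset = origin + on * 60, offset = origin + off * 60,
        total_scored_sleep = off - on, valid = off - on >= 60,
        source = "SCORED")
    }
    eps[[p]] <- make_epochs(pid, origin, hip_vm = hip)
    sls[[p]] <- dplyr::bind_rows(sl)
  }
  ep <- dplyr::bind_rows(eps)
  expect_true(all(is.na(ep$watch_activity)))
  lab <- label_epochs(ep, dplyr::bind_rows(sls))
  sp <- make_split(unique(ep$participant_id),
                   fractions = c(training = 0.5, test = 0.25,
                                 validation = 0.25), seed = 2)
  m <- train_wake_cnn(ep, lab, sp, "hip",
                      arch = cnn_architecture(filters = c(4L, 8L),
                                              dense_units = 8L),
                      n_train_windows = 400L, n_val_windows = 200L,
                      n_test_windows = 200L, n_epochs = 2L, seed = 3)
  expect_s3_class(m, "mash_cnn")
  expect_equal(m$variant, "HIP_ONLY")
  expect_error(
    train_wake_cnn(ep, lab, sp[sp$split != "training", ], "hip"),
    class = "mash_value_error")
})

test_that("constant input yields constant interior probabilities", {
  origin <- as.POSIXct("2024-02-01 00:00:00", tz = "UTC")
  m <- eval_model("hip")
  ep <- make_epochs("C1", origin, hip_vm = 300, n = 400)
  pr <- predict_wake_prob(m, ep)
  interior <- pr$prob[51:350]
  expect_lt(max(interior) - min(interior), 1e-10)
  expect_true(all(pr$prob >= 0 & pr$prob <= 1))
})
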