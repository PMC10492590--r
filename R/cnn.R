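# Wake-interval epoch classification: participant-level splits, epoch
# labeling from surrounding scored sleep, centered-101-epoch window
# extraction with train-split normalization, CNN training, prediction, and
# Youden-J cutoff selection.

cnn_channels <- function(variant) {
  switch(variant,
         dual = c("hip_axis1", "hip_axis2", "hip_axis3",
                  "watch_activity", "watch_lux"),
         hip = c("hip_axis1", "hip_axis2", "hip_axis3"),
         abort("unknown variant"))
}

#' Split participants into training/test/validation sets
#'
#' Random partition *by participant* (never by day) at the stated
#' fractions; the default fractions mirror a 625/278/209 split of 1112
#' participants.
#'
#' @param participants Character vector of participant ids.
#' @param fractions Named fractions for `training`, `test`, `validation`;
#'   must sum to 1.
#' @param seed Integer seed.
#' @return Tibble with `participant_id` and factor `split`.
#' @export
make_split <- function(participants,
                       fractions = c(training = 625, test = 278,
                                     validation = 209) / 1112,
                       seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8)
  participants <- unique(participants)
  n <- length(participants)
  target <- fractions * n
  sizes <- floor(target)
  rem <- n - sum(sizes)
  if (rem > 0L) {
    extra <- order(target - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1L
  }
  shuffled <- with_local_seed(seed, sample(participants))
  split <- rep(names(fractions), sizes)
  tibble(participant_id = shuffled,
         split = factor(split, levels = names(fractions))) |>
    arrange(.data$participant_id)
}

#' Label epochs as within/outside the waking interval
#'
#' For every day bounded by two valid scored-sleep nights, epochs between
#' the previous night's onset and the current night's onset are labeled:
#' 1 inside the waking interval `[offset_t, onset_t)` (half-open: the
#' epoch at the morning offset is 1, the epoch at the evening onset is 0),
#' 0 inside the sleep intervals. Days lacking valid surrounding sleep
#' contribute no labels.
#'
#' @param epochs Aligned epoch tibble.
#' @param sleep Sleep-record tibble (see [score_sleep()]).
#' @return Tibble `participant_id`, `timestamp`, `label` (0/1).
#' @export
label_epochs <- function(epochs, sleep) {
  valid <- sleep |> filter(.data$valid) |> arrange(.data$participant_id,
                                                  .data$night_date)
  ovl <- valid |>
    group_by(.data$participant_id) |>
    filter(.data$onset < lag(.data$offset, default = first(.data$onset) - 1)) |>
    ungroup()
  if (nrow(ovl) > 0L) {
    abort("overlapping valid sleep records", class = "mash_value_error")
  }
  pairs <- valid |>
    group_by(.data$participant_id) |>
    mutate(next_gap = as.numeric(difftime(lead(.data$night_date),
                                          .data$night_date, units = "days")),
           next_onset = lead(.data$onset)) |>
    ungroup() |>
    filter(.data$next_gap %in% 1)        # consecutive valid nights only
  if (nrow(pairs) == 0L) {
    return(tibble(participant_id = character(),
                  timestamp = as.POSIXct(character(), tz = "UTC"),
                  label = integer()))
  }
  out <- pairs |>
    group_by(.data$participant_id) |>
    group_split() |>
    map(function(pp) {
      pe <- epochs[epochs$participant_id == pp$participant_id[1L], ,
                   drop = FALSE]
      map(seq_len(nrow(pp)), function(i) {
        span <- pe$timestamp >= pp$onset[i] & pe$timestamp <= pp$next_onset[i]
        ts <- pe$timestamp[span]
        tibble(participant_id = pp$participant_id[1L], timestamp = ts,
               label = as.integer(ts >= pp$offset[i] & ts < pp$next_onset[i]))
      }) |> bind_rows()
    }) |>
    bind_rows() |>
    distinct(.data$participant_id, .data$timestamp, .keep_all = TRUE)
  out
}

# log1p + z-score channel stats computed on the training split only.
norm_stats <- function(epochs, channels) {
  map_dfr(channels, function(ch) {
    x <- log1p(pmax(epochs[[ch]], 0))
    x[is.na(x)] <- 0
    tibble(channel = ch, mean = mean(x), sd = max(sd(x), 1e-6))
  })
}

# Normalized series matrix (T x C) for one participant's epochs.
series_matrix <- function(pe, channels, stats) {
  mat <- matrix(0, nrow(pe), length(channels))
  for (i in seq_along(channels)) {
    x <- log1p(pmax(pe[[channels[i]]], 0))
    x[is.na(x)] <- 0
    mat[, i] <- (x - stats$mean[i]) / stats$sd[i]
  }
  mat
}

# Centered windows around `centers` (row indices into `mat`), zero-padded
# at the edges, with a trailing 0/1 validity-mask channel.
extract_windows <- function(mat, centers, window_len = 101L) {
  half <- (window_len - 1L) %/% 2L
  n <- length(centers)
  Tn <- nrow(mat)
  C <- ncol(mat)
  idx <- outer(centers, (-half):half, "+")
  ok <- idx >= 1L & idx <= Tn
  idc <- pmin(pmax(idx, 1L), Tn)
  X <- array(0, c(n, window_len, C + 1L))
  for (c in seq_len(C)) {
    v <- matrix(mat[idc, c], n, window_len)
    v[!ok] <- 0
    X[, , c] <- v
  }
  X[, , C + 1L] <- ok * 1
  X
}

# Sample labeled window centers for one split and build the window array.
build_split_windows <- function(epochs, labeled, ids, channels, stats,
                                n_windows, window_len) {
  lab <- labeled |> filter(.data$participant_id %in% ids)
  if (nrow(lab) == 0L) {
    abort("no labeled epochs in split", class = "mash_value_error")
  }
  take <- if (nrow(lab) > n_windows) {
    lab[sample.int(nrow(lab), n_windows), , drop = FALSE]
  } else lab
  parts <- split(take, take$participant_id)
  Xs <- list(); ys <- list()
  for (pid in names(parts)) {
    pe <- epochs[epochs$participant_id == pid, , drop = FALSE]
    mat <- series_matrix(pe, channels, stats)
    centers <- as.integer(round(as.numeric(difftime(
      parts[[pid]]$timestamp, pe$timestamp[1L], units = "mins")))) + 1L
    Xs[[pid]] <- extract_windows(mat, centers, window_len)
    ys[[pid]] <- parts[[pid]]$label
  }
  X <- do.call(abind1, Xs)
  list(X = X, y = unlist(ys, use.names = FALSE))
}

# Bind window arrays along the first (batch) dimension.
abind1 <- function(...) {
  arrs <- list(...)
  ns <- vapply(arrs, function(a) dim(a)[1L], integer(1))
  d <- dim(arrs[[1L]])
  out <- array(0, c(sum(ns), d[2L], d[3L]))
  at <- 0L
  for (a in arrs) {
    out[(at + 1L):(at + dim(a)[1L]), , ] <- a
    at <- at + dim(a)[1L]
  }
  out
}

#' Train a wake-interval CNN (dual-device or hip-only)
#'
#' Trains a 1-D CNN on centered 101-epoch windows of the training-split
#' participants, using the validation split for early stopping, then picks
#' the classification cutoff on the test split with Youden's J. Channel
#' normalization (log1p, then z-score) uses training-split statistics
#' only, frozen into the returned bundle. A validity-mask channel marks
#' zero-padded window positions at stream edges.
#'
#' @param epochs Aligned epoch tibble.
#' @param labeled Output of [label_epochs()].
#' @param split Output of [make_split()].
#' @param variant `"dual"` (hip axes + watch activity + lux) or `"hip"`
#'   (hip axes only).
#' @param arch A [cnn_architecture()].
#' @param window_len Centered window length in epochs (odd).
#' @param n_train_windows,n_val_windows,n_test_windows Windows sampled
#'   per split.
#' @param n_epochs,batch,lr,patience Optimizer settings (Adam, mean
#'   binary cross-entropy, early stopping on validation loss).
#' @param seed Integer seed controlling initialization, sampling and
#'   shuffling.
#' @return A `mash_cnn` bundle: parameters, architecture, window spec,
#'   normalization statistics, Youden cutoff with test-split sensitivity
#'   and specificity, and the training history.
#' @export
train_wake_cnn <- function(epochs, labeled, split,
                           variant = c("dual", "hip"),
                           arch = cnn_architecture(),
                           window_len = 101L,
                           n_train_windows = 4096L, n_val_windows = 1024L,
                           n_test_windows = 2048L,
                           n_epochs = 6L, batch = 128L, lr = 1e-3,
                           patience = 2L, seed = 1L) {
  variant <- match.arg(variant)
  stopifnot(window_len %% 2L == 1L)
  channels <- cnn_channels(variant)
  ids <- split(split$participant_id, split$split)
  if (length(ids$training) == 0L) {
    abort("empty training split", class = "mash_value_error")
  }
  labeled <- semi_join(labeled, distinct(epochs, .data$participant_id),
                       by = "participant_id")
  stats <- norm_stats(
    epochs |> filter(.data$participant_id %in% ids$training), channels)

  fitted <- with_local_seed(seed, {
    tr <- build_split_windows(epochs, labeled, ids$training, channels, stats,
                              n_train_windows, window_len)
    va <- build_split_windows(epochs, labeled, ids$validation, channels,
                              stats, n_val_windows, window_len)
    fit <- cnn_fit(tr$X, tr$y, va$X, va$y, arch, epochs = n_epochs,
                   batch = batch, lr = lr, patience = patience)
    te <- build_split_windows(epochs, labeled, ids$test, channels, stats,
                              n_test_windows, window_len)
    te_prob <- cnn_predict_array(fit$params, arch, te$X)$prob
    cut <- youden_cutoff(te_prob, te$y)
    list(fit = fit, cut = cut, n_test = length(te$y))
  })

  structure(list(
    variant = toupper(ifelse(variant == "hip", "HIP_ONLY", "DUAL")),
    channels = channels, arch = arch, window_len = as.integer(window_len),
    norm = stats, params = fitted$fit$params, history = fitted$fit$history,
    cutoff = fitted$cut$cutoff, cutoff_j = fitted$cut$j,
    cutoff_sensitivity = fitted$cut$sensitivity,
    cutoff_specificity = fitted$cut$specificity,
    cutoff_n = fitted$n_test, seed = seed
  ), class = "mash_cnn")
}

#' @export
print.mash_cnn <- function(x, ...) {
  cat("<mash_cnn>", x$variant, "variant;", length(x$channels),
      "channels + mask; window", x$window_len,
      sprintf("; cutoff %.3f (J = %.3f)\n", x$cutoff, x$cutoff_j))
  invisible(x)
}

#' Save or load a trained CNN bundle
#'
#' The bundle (weights, architecture, window spec, normalization
#' statistics and cutoff contract) is stored as an RDS archive with a
#' JSON manifest alongside describing the contract for inspection.
#'
#' @param bundle A `mash_cnn`.
#' @param path Path to the `.rds` archive.
#' @return `write_cnn_bundle()` the path invisibly; `read_cnn_bundle()`
#'   the bundle.
#' @export
write_cnn_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "mash_cnn"))
  saveRDS(bundle, path)
  manifest <- list(variant = bundle$variant, channels = bundle$channels,
                   window_len = bundle$window_len, cutoff = bundle$cutoff,
                   cutoff_j = bundle$cutoff_j,
                   architecture = unclass(bundle$arch))
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_cnn_bundle
#' @export
read_cnn_bundle <- function(path) {
  bundle <- readRDS(path)
  stopifnot(inherits(bundle, "mash_cnn"))
  bundle
}

#' Per-epoch wake-interval probabilities
#'
#' Slides the bundle's centered window over each participant's epoch grid
#' and returns one probability per epoch. Epochs whose window contains no
#' observed data (fully padded) are flagged.
#'
#' @param bundle A `mash_cnn` from [train_wake_cnn()].
#' @param epochs Aligned epoch tibble.
#' @return Tibble `participant_id`, `timestamp`, `prob`, `fully_padded`.
#' @export
predict_wake_prob <- function(bundle, epochs) {
  epochs |>
    group_by(.data$participant_id) |>
    group_split() |>
    map(function(pe) {
      mat <- series_matrix(pe, bundle$channels, bundle$norm)
      X <- extract_windows(mat, seq_len(nrow(pe)), bundle$window_len)
      prob <- cnn_predict_array(bundle$params, bundle$arch, X)$prob
      padded <- rowSums(X[, , dim(X)[3L], drop = FALSE]) == 0
      tibble(participant_id = pe$participant_id[1L],
             timestamp = pe$timestamp, prob = prob, fully_padded = padded)
    }) |>
    bind_rows()
}

#' Youden-J optimal classification cutoff
#'
#' Maximizes sensitivity + specificity - 1 over the observed probability
#' values (classification rule: positive when probability >= cutoff), with
#' ties broken toward the higher cutoff. Equal-cost framing: both error
#' types weigh the same.
#'
#' @param prob Numeric scores/probabilities.
#' @param labels Binary labels (0/1 or logical).
#' @return List with `cutoff`, `j`, `sensitivity`, `specificity`.
#' @export
youden_cutoff <- function(prob, labels) {
  y <- as.integer(labels)
  if (length(unique(y)) < 2L) {
    abort("both classes must be present", class = "mash_value_error")
  }
  ord <- order(prob, decreasing = TRUE)
  p <- prob[ord]; yy <- y[ord]
  P <- sum(yy); N <- length(yy) - P
  tp <- cumsum(yy); fp <- cumsum(1L - yy)
  last <- which(!duplicated(p, fromLast = TRUE))   # last index of each value
  sens <- tp[last] / P
  spec <- 1 - fp[last] / N
  j <- sens + spec - 1
  best <- which.max(j)   # thresholds are in decreasing order: first max = highest cutoff
  list(cutoff = p[last][best], j = j[best],
       sensitivity = sens[best], specificity = spec[best])
}
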