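# Independent brute-force reference implementations used to cross-check
# the package's algorithms. Deliberately written with direct per-minute /
# per-pair scans, not shared code paths.

# Non-wear: explicit state-machine scan over minutes with literal flank
# checks for tolerated spikes.
oracle_choi <- function(vm, window_min = 90, allowed_spike = 2,
                        flank_min = 30) {
  vm[is.na(vm)] <- 0
  n <- length(vm)
  z <- vm <= 0
  effz <- z
  i <- 1L
  while (i <= n) {
    if (!z[i]) {
      j <- i
      while (j < n && !z[j + 1L]) j <- j + 1L
      if (j - i + 1L <= allowed_spike) {
        lo <- i - flank_min
        hi <- j + flank_min
        if (lo >= 1L && hi <= n && all(z[lo:(i - 1L)]) &&
            all(z[(j + 1L):hi])) {
          effz[i:j] <- TRUE
        }
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  wear <- rep(TRUE, n)
  i <- 1L
  while (i <= n) {
    if (effz[i]) {
      j <- i
      while (j < n && effz[j + 1L]) j <- j + 1L
      if (j - i + 1L >= window_min) wear[i:j] <- FALSE
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  wear
}

# Youden cutoff: literal loop over every observed threshold.
oracle_youden <- function(prob, labels) {
  y <- as.integer(labels)
  best <- list(cutoff = NA_real_, j = -Inf)
  for (th in sort(unique(prob))) {
    sens <- mean(prob[y == 1] >= th)
    spec <- mean(prob[y == 0] < th)
    j <- sens + spec - 1
    if (j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && th > best$cutoff)) {
      best <- list(cutoff = th, j = j)
    }
  }
  best
}

# ROC AUC as pairwise concordance with half credit for ties.
oracle_auc <- function(prob, labels) {
  y <- as.integer(labels)
  pos <- prob[y == 1]
  neg <- prob[y == 0]
  cmp <- outer(pos, neg, FUN = function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Onset/offset: exhaustive scan of every candidate immobility run start.
oracle_onset_offset <- function(counts, run_len = 10, immobile_max = 0) {
  n <- length(counts)
  imm <- !is.na(counts) & counts <= immobile_max
  starts <- integer(0)
  for (s in seq_len(n - run_len + 1L)) {
    if (all(imm[s:(s + run_len - 1L)])) starts <- c(starts, s)
  }
  if (length(starts) == 0L) return(NULL)
  # extend the last qualifying run to its final immobile minute
  last_start <- max(starts)
  e <- last_start + run_len - 1L
  while (e < n && imm[e + 1L]) e <- e + 1L
  c(onset = min(starts), offset_end = e)
}

# Wake-interval cluster choice: enumerate merge-consistent clusters by a
# direct pairwise-gap grouping, score each by a literal sum.
oracle_best_cluster <- function(prob, cutoff, merge_gap = 120) {
  above <- which(prob >= cutoff)
  if (length(above) == 0L) return(NULL)
  runs <- list()
  s <- above[1L]
  prev <- above[1L]
  for (i in above[-1L]) {
    if (i == prev + 1L) {
      prev <- i
    } else {
      runs[[length(runs) + 1L]] <- c(s, prev)
      s <- i
      prev <- i
    }
  }
  runs[[length(runs) + 1L]] <- c(s, prev)
  groups <- list(list(runs[[1L]]))
  if (length(runs) > 1L) {
    for (r in runs[-1L]) {
      last_group <- groups[[length(groups)]]
      last_run <- last_group[[length(last_group)]]
      if (r[1L] - last_run[2L] - 1L < merge_gap) {
        groups[[length(groups)]] <- c(last_group, list(r))
      } else {
        groups[[length(groups) + 1L]] <- list(r)
      }
    }
  }
  scores <- vapply(groups, function(g) {
    sum(vapply(g, function(r) sum(prob[r[1L]:r[2L]]), numeric(1)))
  }, numeric(1))
  g <- groups[[which.max(scores)]]
  c(start = g[[1L]][1L], end_excl = g[[length(g)]][2L] + 1L,
    score = max(scores))
}

# Type-7 quantile by the textbook interpolation formula.
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
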