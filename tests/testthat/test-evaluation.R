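# ROC/PR machinery, correction summaries, report rendering.

test_that("ROC endpoints behave for perfect and random classifiers", {
  r <- roc_pr(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(r$roc_auc, 1)
  expect_equal(r$pr_auc, 1)
  set.seed(42)
  p <- runif(1e4)
  y <- rbinom(1e4, 1, 0.5)
  r2 <- roc_pr(p, y)
  expect_lt(abs(r2$roc_auc - 0.5), 0.02)
  expect_lt(abs(r2$pr_auc - mean(y)), 0.02)
  expect_equal(r2$prevalence, mean(y))
  expect_error(roc_pr(p, rep(1, 1e4)), class = "mash_value_error")
})

test_that("trapezoid ROC AUC equals pairwise concordance with tie credit", {
  set.seed(13)
  for (i in 1:20) {
    n <- sample(c(50L, 200L, 500L), 1L)
    p <- round(runif(n), sample(c(1L, 2L, 6L), 1L))   # include heavy ties
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2L) y[1:2] <- c(0L, 1L)
    expect_equal(roc_pr(p, y)$roc_auc, oracle_auc(p, y),
                 tolerance = 1e-10)
  }
})

test_that("ROC AUC agrees with an established implementation", {
  set.seed(77)
  p <- runif(400)
  y <- rbinom(400, 1, plogis(3 * (p - 0.5)))
  y[1:2] <- c(0L, 1L)
  ours <- roc_pr(p, y)$roc_auc
  ref <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-10)
})

fake_comps <- function(corr) {
  n <- length(corr)
  tibble::tibble(
    participant_id = "Z", date = as.Date("2024-02-01") + seq_len(n),
    tier = "SCORED", corrected = corr != 0,
    pre_sb_min = 400, sb_min = 400 + corr,
    pre_llpa_min = 250, llpa_min = 250,
    pre_hlpa_min = 120, hlpa_min = 120,
    pre_mvpa_min = 40, mvpa_min = 40,
    corr_sb_min = corr, corr_llpa_min = 0, corr_hlpa_min = 0,
    corr_mvpa_min = 0, corr_total_wake_min = corr)
}

test_that("correction medians and IQRs match hand arithmetic (type 7)", {
  corr <- c(-50, -20, -10, 0, 5)
  s <- summarize_corrections(fake_comps(corr))
  all_sb <- s$summary[s$summary$behavior == "SB" &
                        s$summary$scope == "all_days", ]
  expect_equal(all_sb$median, oracle_quantile7(corr, 0.5))
  expect_equal(all_sb$q25, oracle_quantile7(corr, 0.25))
  expect_equal(all_sb$q75, oracle_quantile7(corr, 0.75))
  expect_equal(all_sb$median, -10)
  expect_equal(all_sb$q25, -20)
  expect_equal(all_sb$q75, 0)
  corrected_sb <- s$summary[s$summary$behavior == "SB" &
                              s$summary$scope == "corrected_days", ]
  expect_equal(corrected_sb$median, oracle_quantile7(c(-50, -20, -10, 5),
                                                     0.5))
  expect_equal(s$n_corrected, 4L)
  # the paired t statistic matches a direct computation
  tt <- s$tests[s$tests$behavior == "SB", ]
  d <- corr
  expect_equal(tt$statistic, mean(d) / (sd(d) / sqrt(length(d))),
               tolerance = 1e-12)
  expect_true(all(is.na(s$tests$statistic[s$tests$behavior != "SB"])))
})

test_that("all-zero corrections flag degenerate t-tests", {
  s <- summarize_corrections(fake_comps(rep(0, 6)))
  all_days <- s$summary[s$summary$scope == "all_days", ]
  expect_true(all(all_days$median == 0))
  expect_true(all(all_days$q25 == 0 & all_days$q75 == 0))
  expect_true(all(is.na(s$tests$statistic)))
  expect_equal(s$n_corrected, 0L)
})

test_that("report rendering is deterministic and handles missing variants", {
  set.seed(4)
  p <- runif(300)
  y <- rbinom(300, 1, plogis(5 * (p - 0.6)))
  y[1:2] <- c(0L, 1L)
  r <- roc_pr(p, y)
  s <- summarize_corrections(fake_comps(c(-30, -5, 0, 0, 2)))
  rep1 <- performance_report(roc_dual = r, roc_hip = r, corrections = s)
  rep2 <- performance_report(roc_dual = r, roc_hip = r, corrections = s)
  expect_identical(rep1, rep2)
  expect_true(any(grepl("Dual-device", rep1)))
  expect_true(any(grepl("Hip-only", rep1)))
  expect_warning(performance_report(roc_dual = r), "single model variant")
})

test_that("tidiers and autoplots return the advertised shapes", {
  set.seed(6)
  p <- runif(200)
  y <- rbinom(200, 1, plogis(5 * (p - 0.5)))
  y[1:2] <- c(0L, 1L)
  r <- roc_pr(p, y)
  expect_s3_class(tidy(r), "tbl_df")
  g <- glance(r)
  expect_equal(nrow(g), 1L)
  expect_true(all(c("roc_auc", "pr_auc", "youden_cutoff") %in% names(g)))
  expect_s3_class(autoplot(r), "ggplot")
  expect_s3_class(autoplot(r, type = "pr"), "ggplot")
  s <- summarize_corrections(fake_comps(c(-30, -5, 0, 0, 2)))
  expect_s3_class(autoplot(s), "ggplot")
  expect_s3_class(tidy(s), "tbl_df")
})
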