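mk_svt <- function(rt_raw, response = TRUE, truth = TRUE, id = "P01") {
  n <- length(rt_raw)
  data.frame(participant_id = id, session = "test", order = "4_first",
             snr_condition = 4, item_id = sprintf("T%02d", seq_len(n)),
             item_truth = rep_len(truth, n), response = rep_len(response, n),
             answer_correct = rep_len(response, n) == rep_len(truth, n),
             rt_raw_s = rt_raw, rt_shifted_s = NA_real_, valid = NA,
             stringsAsFactors = FALSE)
}

test_that("the response-validity window is [-0.8, 3.0] s with inclusive boundaries", {
  tr <- validate_svt_responses(mk_svt(c(-0.9, -0.8, 0.0, 3.0, 3.1, NA)))
  expect_equal(tr$valid, c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_true(all(is.na(tr$response[!tr$valid])))
  expect_true(all(is.na(tr$answer_correct[!tr$valid])))
  expect_equal(nrow(tr), 6)  # flagged, never deleted
})

test_that("shifting maps the earliest valid response to 0 s", {
  tr <- shift_rt(validate_svt_responses(mk_svt(c(-0.8, 0.0, 2.2))))
  expect_equal(tr$rt_shifted_s, c(0.0, 0.8, 3.0))
  bad <- mk_svt(-0.9); bad$valid <- TRUE
  expect_error(shift_rt(bad), "inconsistency")
})

test_that("an item far below the pooled binomial success rate is flagged at the 1% criterion", {
  # pooled success 0.9; one unit with 10/20 successes
  units <- c(rep("ok", 25), "bad")
  tr <- do.call(rbind, lapply(seq_along(units), function(i) {
    k <- if (units[i] == "bad") 10 else 18
    data.frame(item_id = sprintf("i%02d", i), snr_condition = 4,
               y = c(rep(TRUE, k), rep(FALSE, 20 - k)))
  }))
  rep <- detect_item_outliers(tr, "y", "binary", hardest = 4)
  bad_row <- rep[rep$unit_mean == 0.5, ]
  expect_true(bad_row$flagged)
  # independent oracle: exact binomial lower tail at the pooled estimate
  p <- mean(tr$y)
  expect_equal(bad_row$tail_probability, min(1, 2 * pbinom(10, 20, p)), tolerance = 1e-12)
  expect_lt(bad_row$tail_probability, 0.005)
  # a unit sitting exactly on the pooled mean is never flagged
  even <- data.frame(item_id = rep(c("a", "b"), each = 10), snr_condition = 4,
                     y = rep(c(rep(TRUE, 7), rep(FALSE, 3)), 2))
  rep2 <- detect_item_outliers(even, "y", "binary", hardest = 4)
  expect_false(any(rep2$flagged))
})

test_that("under its own null the outlier detector flags at most 1% of units", {
  set.seed(20)
  n_items <- 4000
  tr <- data.frame(item_id = rep(sprintf("i%04d", seq_len(n_items)), each = 30),
                   snr_condition = 4,
                   y = rbinom(30 * n_items, 1, 0.9) == 1)
  rep <- detect_item_outliers(tr, "y", "binary", hardest = 4)
  expect_lte(mean(rep$flagged), 0.01)
})

test_that("reaction-time outliers are judged against the Gamma distribution of a unit mean", {
  set.seed(21)
  n_items <- 40
  tr <- data.frame(item_id = rep(sprintf("i%02d", seq_len(n_items)), each = 25),
                   snr_condition = 4,
                   rt = rgamma(25 * n_items, shape = 6, rate = 6 / 1.6))
  tr$rt[tr$item_id == "i01"] <- tr$rt[tr$item_id == "i01"] + 1.5  # slow item
  rep <- detect_item_outliers(tr, "rt", "rt", hardest = 4)
  expect_true(rep$flagged[rep$unit_id == "i01"])
  expect_lte(sum(rep$flagged), 3)
  expect_error(detect_item_outliers(transform(tr, rt = rt - 5), "rt", "rt", hardest = 4),
               "positive")
})

lc_fixture <- function(retest_fun, n = 12, sd_trial = 0) {
  base <- seq(1.2, 2.4, length.out = n)
  do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(participant_id = sprintf("P%02d", i),
               session = rep(c("test", "retest"), each = 20),
               rt_raw_s = c(rep(base[i], 20), rep(retest_fun(base[i]), 20)) +
                 rnorm(40, 0, sd_trial) - 0.8,
               stringsAsFactors = FALSE)
  }))
}

test_that("learning correction restores retest to the test level exactly under a linear shift", {
  tr <- shift_rt(lc_fixture(function(m) m - 0.1))
  res <- correct_learning_effect(tr)
  m <- tapply(res$trials$rt_shifted_s, list(res$trials$participant_id, res$trials$session), mean)
  expect_equal(unname(m[, "retest"]), unname(m[, "test"]), tolerance = 1e-10)
  expect_equal(res$model$slope, 1, tolerance = 1e-8)
  expect_equal(res$model$intercept_s, -0.1, tolerance = 1e-8)
  expect_equal(res$model$r_squared, 1, tolerance = 1e-8)
})

test_that("corrected retest means regress on test means with slope 1 and intercept 0", {
  set.seed(22)
  tr <- shift_rt(lc_fixture(function(m) 0.3 + 0.8 * m, sd_trial = 0.15))
  res <- correct_learning_effect(tr)
  m <- tapply(res$trials$rt_shifted_s, list(res$trials$participant_id, res$trials$session), mean)
  refit <- lm(m[, "retest"] ~ m[, "test"])
  expect_equal(unname(coef(refit)), c(0, 1), tolerance = 1e-8)
  # least-squares residuals sum to zero: grand means agree
  expect_equal(mean(m[, "retest"]), mean(m[, "test"]), tolerance = 1e-10)
  # idempotence: a second pass changes nothing
  res2 <- correct_learning_effect(res$trials)
  expect_equal(res2$trials$rt_shifted_s, res$trials$rt_shifted_s, tolerance = 1e-10)
  expect_equal(nrow(res$trials), nrow(tr))
})

test_that("participants missing a session are excluded from the learning fit with a warning", {
  tr <- shift_rt(lc_fixture(function(m) m - 0.1))
  tr <- tr[!(tr$participant_id == "P01" & tr$session == "retest"), ]
  expect_warning(res <- correct_learning_effect(tr), "missing a session")
  expect_false("P01" %in% names(res$model$correction_s))
})
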