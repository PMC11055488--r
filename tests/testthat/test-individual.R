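test_that("the threshold is the mean absolute 5th/95th percentile of the ML normal fit", {
  # mu = 0, sigma = 0.1: both percentiles at 1.6449 * sigma
  d1 <- c(-0.1, 0.1, -0.1, 0.1)           # mean 0, ML sd 0.1
  t1 <- testretest_threshold(d1)
  expect_equal(t1$sigma, 0.1, tolerance = 1e-12)
  expect_equal(t1$threshold, qnorm(0.95) * 0.1, tolerance = 1e-9)
  expect_equal(t1$threshold, 0.1645, tolerance = 1e-4)

  # a mean shift below 1.645 sigma leaves the threshold unchanged
  t2 <- testretest_threshold(d1 + 0.05)
  expect_equal(t2$mu, 0.05, tolerance = 1e-12)
  expect_equal(t2$threshold, qnorm(0.95) * 0.1, tolerance = 1e-9)

  # degenerate fit: all differences identical
  expect_warning(t3 <- testretest_threshold(rep(0.2, 5)), "degenerate")
  expect_equal(t3$threshold, 0.2)
  expect_error(testretest_threshold(c(0.1, 0.2)), "at least 3")
})

test_that("the threshold ignores the direction of the test-retest differences", {
  set.seed(50)
  d <- rnorm(40, 0.03, 0.12)
  expect_equal(testretest_threshold(d)$threshold,
               testretest_threshold(-d)$threshold, tolerance = 1e-12)
})

test_that("detections are counted in the correct direction only", {
  res <- count_detections(c(P1 = 0.25, P2 = 0.05, P3 = -0.10), 0.211)
  expect_equal(res$n_significant, 1)
  expect_equal(res$n_correct_direction, 2)
  expect_equal(res$max_detection_rate, 2 / 3)
  expect_lte(res$n_significant, res$n_correct_direction)

  zero <- count_detections(c(0.2, 0.1, -0.3), 0)
  expect_equal(zero$n_significant, zero$n_correct_direction)
  none <- count_detections(c(-0.2, -0.1, -0.3), 0.1)
  expect_equal(none$n_significant, 0)
  expect_equal(none$max_detection_rate, 0)
  expect_error(count_detections(c(0.1), -0.5), ">= 0")
})

test_that("per-participant condition differences follow the better-at-easier sign convention", {
  tr <- data.frame(participant_id = rep(c("A", "B"), each = 4),
                   snr_condition = rep(c(4, 4, 8, 8), 2),
                   rt = c(1.40, 1.40, 1.25, 1.25, 1.0, 1.0, 1.1, 1.1),
                   acc = c(0.6, 0.6, 0.7, 0.7, 0.5, 0.5, 0.5, 0.5))
  d_rt <- participant_condition_diffs(tr, "rt", "lower")
  expect_equal(unname(d_rt["A"]), 0.15, tolerance = 1e-12)   # faster at +8
  expect_equal(unname(d_rt["B"]), -0.10, tolerance = 1e-12)
  d_acc <- participant_condition_diffs(tr, "acc", "higher")
  expect_equal(unname(d_acc["A"]), 0.10, tolerance = 1e-12)
  expect_equal(unname(d_acc["B"]), 0.0, tolerance = 1e-12)
  tr2 <- tr[!(tr$participant_id == "B" & tr$snr_condition == 8), ]
  expect_warning(d3 <- participant_condition_diffs(tr2, "rt", "lower"), "missing a condition")
  expect_equal(names(d3), "A")
})

test_that("under the null the detection threshold flags about 5% of participants", {
  res <- threshold_null_rate(n = 2000, sd = 0.15, seed = 3)
  expect_lt(abs(res$rate - 0.05), 0.007)
})

test_that("detection rate is nondecreasing in the simulated condition effect", {
  set.seed(51)
  n <- 3000; sigma <- 0.1
  rates <- sapply(c(0, 0.5, 1, 2, 4), function(k) {
    diffs <- rnorm(n, k * sigma, sigma)
    thr <- testretest_threshold(rnorm(n, 0, sigma))
    count_detections(diffs, thr)$n_significant / n
  })
  expect_true(all(diff(rates) >= -0.01))
  expect_gt(rates[5], 0.95)
})
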