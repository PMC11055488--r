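test_that("the stochastic-approximation step follows 4*(0.5 - Pc) with +/-2 dB extremes", {
  expect_equal(next_snr(2.0, 1.0), 0.0)
  expect_equal(next_snr(2.0, 0.5), 2.0)
  expect_equal(next_snr(0.0, 0.0), 2.0)
  expect_error(next_snr(2.0, 1.2), "\\[0, 1\\]")
  expect_error(next_snr(2.0, -0.1), "\\[0, 1\\]")
})

test_that("a track has 27 SNRs from 26 scores, starts at +2 dB, and averages SNRs 5..27", {
  tr <- run_track(function(snr) 0.5)
  expect_length(tr$snr_sequence_db, 27)
  expect_length(tr$word_scores, 26)
  expect_equal(tr$snr_sequence_db[1], 2.0)
  expect_true(all(tr$snr_sequence_db == 2.0))   # fixed point at the 50% target
  expect_equal(tr$srt50_db, 2.0)
})

test_that("estimate_srt50 is the arithmetic mean of entries 5 through 27", {
  flat <- structure(list(snr_sequence_db = rep(3, 27), word_scores = rep(0.5, 26)),
                    class = "adaptive_track")
  expect_equal(estimate_srt50(flat), 3.0)
  ramp <- structure(list(snr_sequence_db = c(9, 9, 9, 9, 0:22), word_scores = rep(0.5, 26)),
                    class = "adaptive_track")
  expect_equal(estimate_srt50(ramp), 11.0)
  expect_equal(estimate_srt50(ramp), sum(ramp$snr_sequence_db[5:27]) / 23)
  broken <- structure(list(snr_sequence_db = rep(3, 20), word_scores = rep(0.5, 26)),
                      class = "adaptive_track")
  expect_error(estimate_srt50(broken), "incomplete")
})

test_that("against a deterministic psychometric responder the track converges to the SRT50", {
  l <- psychometric_listener(srt50_db = -1.5, growth_rate = 0.6, p_max = 1, guess_rate = 0)
  tr <- run_track(function(snr) p_correct(l, snr))
  # independent oracle: iterate the deterministic map by hand
  snr <- 2
  for (i in 1:26) snr <- c(snr, snr[length(snr)] + 4 * (0.5 - p_correct(l, snr[length(snr)])))
  expect_equal(tr$snr_sequence_db, snr, tolerance = 1e-12)
  gaps <- abs(tr$snr_sequence_db - l$srt50_db)
  expect_true(all(diff(gaps) < 1e-12))          # monotone approach
  expect_lt(gaps[27], 0.05)
})

test_that("step sizes never exceed +/-2 dB for any responder", {
  set.seed(7)
  for (r in 1:20) {
    tr <- run_track(function(snr) runif(1))
    expect_true(all(abs(diff(tr$snr_sequence_db)) <= 2 + 1e-12))
  }
})

test_that("responder failures and invalid scores carry the sentence index", {
  boom <- function(snr) if (snr < 1) stop("lost contact") else 0.9
  expect_error(run_track(boom), "sentence [0-9]+")
  expect_error(run_track(function(snr) 1.5), "invalid word score")
})

test_that("simulated tracks estimate the true SRT50 within 0.3 dB on average, at 50% intelligibility", {
  l <- psychometric_listener(srt50_db = 3, growth_rate = 0.5, p_max = 1, guess_rate = 0)
  st <- run_srt_study(l, n_tracks = 1000, n_words = 6, seed = 2)
  expect_lt(abs(st$bias), 0.3)
  expect_lt(abs(st$mean_p_at_estimate - 0.5), 0.01)
  # bit-reproducible given the same seed
  st2 <- run_srt_study(l, n_tracks = 25, n_words = 6, seed = 2)
  expect_identical(st$estimates[1:25], st2$estimates)
})
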