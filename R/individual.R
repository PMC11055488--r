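# Intra-individual detection analysis: a smallest-detectable-change
# threshold from test-retest variability, and counts of participants whose
# SNR-condition difference exceeds it.

#' Per-participant condition differences
#'
#' Computes, for each participant, the difference in the mean outcome
#' between the two SNR conditions, pooled over the test and (corrected)
#' retest sessions. The sign convention makes positive values mean "did
#' better in the easier SRT50 + 8 dB condition": for measures where lower is
#' better (reaction time) the difference is mean(+4) - mean(+8); for
#' proportion-correct measures it is mean(+8) - mean(+4).
#'
#' @param trials Trial data.frame with `participant_id`, `snr_condition` and
#'   the outcome column.
#' @param value Name of the outcome column (missing values ignored).
#' @param direction `"lower"` when smaller outcomes are better (RT) or
#'   `"higher"` when larger are better (proportions correct).
#' @param easier,harder The two values of `snr_condition` (defaults 8 and 4).
#' @return Named numeric vector of signed differences, one per participant
#'   with both conditions; participants missing a condition are excluded
#'   with a warning.
#' @export
participant_condition_diffs <- function(trials, value,
                                        direction = c("higher", "lower"),
                                        easier = 8, harder = 4) {
  direction <- match.arg(direction)
  stopifnot(is.data.frame(trials), value %in% names(trials))
  ok <- !is.na(trials[[value]])
  m <- tapply(as.numeric(trials[[value]][ok]),
              list(trials$participant_id[ok], trials$snr_condition[ok]), mean)
  need <- as.character(c(easier, harder))
  if (!all(need %in% colnames(m))) stop("both SNR conditions must be present")
  complete <- !is.na(m[, need[1]]) & !is.na(m[, need[2]])
  if (any(!complete))
    warning(sprintf("excluding %d participant(s) missing a condition", sum(!complete)))
  d <- if (direction == "higher") m[complete, need[1]] - m[complete, need[2]]
       else m[complete, need[2]] - m[complete, need[1]]
  stats::setNames(as.numeric(d), rownames(m)[complete])
}

#' Test-retest significance threshold
#'
#' Fits a normal distribution by maximum likelihood (SD with divisor n) to
#' the per-participant mean test-retest differences and derives the
#' significance threshold as the mean of the absolute values of the 5th and
#' 95th percentiles of the fitted normal. A condition difference larger than
#' this threshold is unlikely (5% one-sided) to be test-retest noise. The
#' threshold is invariant to flipping the sign of every input difference.
#'
#' @param diffs Numeric vector of per-participant test-retest differences
#'   (for reaction times, computed after learning-effect correction).
#' @return An object of class `trt_threshold`: list with `mu`, `sigma`
#'   (ML fit), `threshold` and `n`.
#' @export
#' @examples
#' testretest_threshold(c(-0.1, 0.05, 0.12, -0.03, 0.02))
testretest_threshold <- function(diffs) {
  diffs <- diffs[!is.na(diffs)]
  if (length(diffs) < 3) stop("need at least 3 participants to fit the normal")
  mu <- mean(diffs)
  sigma <- sqrt(mean((diffs - mu)^2))
  if (sigma == 0) {
    warning("degenerate fit: all differences identical (sigma = 0)")
    threshold <- abs(mu)
  } else {
    q <- stats::qnorm(c(0.05, 0.95), mean = mu, sd = sigma)
    threshold <- mean(abs(q))
  }
  structure(list(mu = mu, sigma = sigma, threshold = threshold, n = length(diffs)),
            class = "trt_threshold")
}

#' @export
print.trt_threshold <- function(x, ...) {
  cat(sprintf("Test-retest normal fit: mu = %+.4g, sigma = %.4g (n = %d)\n",
              x$mu, x$sigma, x$n))
  cat(sprintf("  significance threshold (mean |5th|, |95th| percentile): %.4g\n",
              x$threshold))
  invisible(x)
}

#' Count detectable intra-individual condition differences
#'
#' Given per-participant signed condition differences (positive = better in
#' the easier condition) and a test-retest threshold, counts how many
#' participants show a significant difference (difference above the
#' threshold, correct direction only) and how many show an effect in the
#' correct direction at all. The latter proportion is the maximum detection
#' rate: the ceiling any threshold could reach for this measure.
#'
#' @param condition_diffs Named numeric vector from
#'   [participant_condition_diffs()].
#' @param threshold A [testretest_threshold()] object or a nonnegative
#'   number.
#' @return An object of class `threshold_result`: list with the inputs plus
#'   `n_participants`, `n_significant`, `n_correct_direction` and
#'   `max_detection_rate`.
#' @export
count_detections <- function(condition_diffs, threshold) {
  thr <- if (inherits(threshold, "trt_threshold")) threshold$threshold else threshold
  if (!is.numeric(thr) || thr < 0) stop("threshold must be >= 0")
  d <- condition_diffs[!is.na(condition_diffs)]
  structure(list(
    condition_diffs = d,
    fit = if (inherits(threshold, "trt_threshold")) threshold else NULL,
    threshold = thr,
    n_participants = length(d),
    n_significant = sum(d > thr),
    n_correct_direction = sum(d > 0),
    max_detection_rate = sum(d > 0) / length(d)
  ), class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("Intra-individual detection: threshold %.4g\n", x$threshold))
  cat(sprintf("  %d / %d participants significant; %d / %d in the correct direction (max detection rate %.0f%%)\n",
              x$n_significant, x$n_participants, x$n_correct_direction,
              x$n_participants, 100 * x$max_detection_rate))
  invisible(x)
}

#' Null calibration of the test-retest threshold
#'
#' Simulates participants with no condition effect whose test-retest
#' differences are normal, derives the threshold from the simulated
#' differences themselves, and returns the proportion flagged as a
#' significant detection (difference beyond the threshold in the detection
#' direction). By construction of the 5th/95th-percentile rule this
#' false-positive rate converges to 5%.
#'
#' @param n Number of simulated null participants.
#' @param sd SD of the test-retest noise (the rate is scale-invariant).
#' @param seed RNG seed.
#' @return A list with `rate`, the derived `threshold` and the fitted
#'   normal.
#' @export
threshold_null_rate <- function(n = 2000, sd = 1, seed = 1L) {
  diffs <- with_substream(seed, "null-threshold", expr = stats::rnorm(n, 0, sd))
  fit <- testretest_threshold(diffs)
  list(rate = mean(diffs > fit$threshold), threshold = fit$threshold, fit = fit)
}
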