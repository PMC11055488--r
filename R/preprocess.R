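# Data conditioning before model fitting: response-validity filtering,
# reaction-time shifting, item/list outlier detection and learning-effect
# correction. All steps flag rather than delete: trial counts are conserved.

#' Flag valid SVT responses
#'
#' A response is valid when it was given between `window_lo_s` before and
#' `window_hi_s` after the end of the sentence (both boundaries inclusive).
#' Trials with a reaction time outside the window, or with no response, are
#' retained but their outcome columns (`response`, `answer_correct`,
#' `rt_raw_s`, `rt_shifted_s` if present) are set to missing and `valid` to
#' `FALSE`.
#'
#' @param trials SVT trial data.frame with `rt_raw_s` and `response`.
#' @param window_lo_s Earliest valid raw RT (default -0.8 s, i.e. 0.8 s
#'   before the sentence end).
#' @param window_hi_s Latest valid raw RT (default 3.0 s).
#' @return The data.frame with the same number of rows and an updated
#'   `valid` flag.
#' @export
validate_svt_responses <- function(trials, window_lo_s = -0.8, window_hi_s = 3.0) {
  stopifnot(is.data.frame(trials), all(c("rt_raw_s", "response") %in% names(trials)))
  ok <- !is.na(trials$response) & !is.na(trials$rt_raw_s) &
    trials$rt_raw_s >= window_lo_s & trials$rt_raw_s <= window_hi_s
  trials$response[!ok] <- NA
  if ("answer_correct" %in% names(trials)) trials$answer_correct[!ok] <- NA
  trials$rt_raw_s[!ok] <- NA_real_
  if ("rt_shifted_s" %in% names(trials)) trials$rt_shifted_s[!ok] <- NA_real_
  trials$valid <- ok
  trials
}

#' Shift reaction times to a positive scale
#'
#' Adds `shift_s` (default 0.8 s) to the raw reaction time so that all valid
#' reaction times are nonnegative and 0 s corresponds to the earliest
#' possible response that counted; the shifted values can then be modeled
#' with a Gamma distribution.
#'
#' @param trials Trial data.frame with `rt_raw_s` and a `valid` flag.
#' @param shift_s The shift in seconds.
#' @return The data.frame with `rt_shifted_s` filled in.
#' @export
shift_rt <- function(trials, shift_s = 0.8) {
  stopifnot(is.data.frame(trials), "rt_raw_s" %in% names(trials))
  valid <- if ("valid" %in% names(trials)) trials$valid else !is.na(trials$rt_raw_s)
  bad <- valid & !is.na(trials$rt_raw_s) & trials$rt_raw_s < -shift_s
  if (any(bad))
    stop("internal inconsistency: valid trial with rt_raw_s below -shift_s")
  trials$rt_shifted_s <- trials$rt_raw_s + shift_s
  trials
}

#' Detect outlying items or lists by exact tail probabilities
#'
#' Pools all trials measured in the most difficult condition (SRT50 + 4 dB
#' by default), fits the variable's reference distribution to the pool, and
#' computes for every item (or list) the two-sided probability of a mean at
#' least as extreme as the one observed, given that unit's own trial count.
#' Units with tail probability below `alpha` (1% by default) are flagged as
#' outliers.
#'
#' For binary variables the pooled fit is the maximum-likelihood binomial
#' success probability and the per-unit tail is the exact binomial tail
#' (doubled smaller tail, capped at 1). For reaction times the pooled fit is
#' a maximum-likelihood Gamma; the mean of n iid Gamma(k, scale s) draws is
#' Gamma(n k, scale s/n), and the unit mean is referred to that
#' distribution.
#'
#' @param trials Trial data.frame.
#' @param value Name of the outcome column (logical/0-1, or positive RT).
#' @param type `"binary"` or `"rt"`.
#' @param unit Name of the unit column (item or list id).
#' @param condition Name of the condition column.
#' @param hardest Value of `condition` identifying the most difficult
#'   condition; only those trials are used.
#' @param alpha Flagging criterion on the two-sided tail probability.
#' @return A data.frame of class `outlier_report`: one row per unit with
#'   `unit_id`, `n_trials`, `unit_mean`, the pooled fit parameters,
#'   `tail_probability` and `flagged`.
#' @export
detect_item_outliers <- function(trials, value, type = c("binary", "rt"),
                                 unit = "item_id", condition = "snr_condition",
                                 hardest = 4, alpha = 0.01) {
  type <- match.arg(type)
  stopifnot(is.data.frame(trials), value %in% names(trials), unit %in% names(trials))
  d <- trials[trials[[condition]] == hardest & !is.na(trials[[value]]), , drop = FALSE]
  units <- split(d[[value]], d[[unit]])
  units <- units[order(names(units))]
  if (length(units) < 2) stop("need at least 2 units with data in the hardest condition")
  empty <- vapply(units, length, integer(1)) == 0
  if (any(empty)) {
    warning(sprintf("skipping %d unit(s) with zero trials", sum(empty)))
    units <- units[!empty]
  }
  y <- d[[value]]

  if (type == "binary") {
    y <- as.numeric(y)
    p <- mean(y)  # ML estimate of the pooled success probability
    rep <- lapply(names(units), function(u) {
      v <- as.numeric(units[[u]]); n <- length(v); x <- sum(v)
      lo <- stats::pbinom(x, n, p)
      hi <- stats::pbinom(x - 1, n, p, lower.tail = FALSE)
      tail <- min(1, 2 * min(lo, hi))
      data.frame(unit_id = u, n_trials = n, unit_mean = x / n,
                 pooled_prob = p, tail_probability = tail,
                 flagged = tail < alpha, stringsAsFactors = FALSE)
    })
  } else {
    y <- as.numeric(y)
    if (any(y <= 0)) stop("rt outlier detection requires strictly positive (shifted) values")
    fit <- suppressWarnings(MASS::fitdistr(y, "gamma"))  # NaN probes off the boundary
    k <- fit$estimate[["shape"]]; r <- fit$estimate[["rate"]]
    rep <- lapply(names(units), function(u) {
      v <- as.numeric(units[[u]]); n <- length(v); m <- mean(v)
      lo <- stats::pgamma(m, shape = n * k, rate = n * r)
      tail <- min(1, 2 * min(lo, 1 - lo))
      data.frame(unit_id = u, n_trials = n, unit_mean = m,
                 pooled_shape = k, pooled_rate = r, tail_probability = tail,
                 flagged = tail < alpha, stringsAsFactors = FALSE)
    })
  }
  out <- do.call(rbind, rep)
  rownames(out) <- NULL
  class(out) <- c("outlier_report", "data.frame")
  attr(out, "alpha") <- alpha
  out
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("Outlier report: %d units, %d flagged (two-sided tail < %g)\n",
              nrow(x), sum(x$flagged), attr(x, "alpha")))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Correct retest reaction times for the learning effect
#'
#' Participants respond faster at retest. The correction fits, by least
#' squares, the linear relation between each participant's mean (shifted)
#' reaction time in the retest and in the test session, collapsed across SNR
#' conditions and condition order. Each participant's individual correction
#' factor is the difference between their test mean and their fitted retest
#' mean; that factor is added to every retest trial of the participant, so
#' that corrected retest data sit at the test session's expected level. Test
#' trials are unchanged. Applying the correction a second time changes
#' nothing (the second-stage fit is the identity).
#'
#' @param trials SVT trial data.frame with `participant_id`, `session` and
#'   the reaction-time column.
#' @param rt_col Reaction-time column to correct (default `rt_shifted_s`;
#'   `rt_raw_s`, when present, is corrected by the same amount so the two
#'   columns stay offset by the shift constant).
#' @return A list with `trials` (corrected data.frame) and `model`, an
#'   object of class `learning_model` with elements `intercept_s`, `slope`,
#'   `r_squared` and the named `correction_s` vector (seconds, per
#'   participant).
#' @export
correct_learning_effect <- function(trials, rt_col = "rt_shifted_s") {
  stopifnot(is.data.frame(trials),
            all(c("participant_id", "session", rt_col) %in% names(trials)))
  ok <- !is.na(trials[[rt_col]])
  means <- tapply(trials[[rt_col]][ok],
                  list(trials$participant_id[ok], trials$session[ok]), mean)
  if (!all(c("test", "retest") %in% colnames(means)))
    stop("both 'test' and 'retest' sessions are required")
  complete <- !is.na(means[, "test"]) & !is.na(means[, "retest"])
  if (any(!complete))
    warning(sprintf("excluding %d participant(s) missing a session from the learning fit",
                    sum(!complete)))
  if (sum(complete) < 2) stop("need at least 2 participants with both sessions")
  test_m <- means[complete, "test"]; retest_m <- means[complete, "retest"]
  fit <- stats::lm(retest_m ~ test_m)
  a <- unname(stats::coef(fit)[1]); b <- unname(stats::coef(fit)[2])
  corr <- test_m - (a + b * test_m)
  names(corr) <- rownames(means)[complete]

  idx <- trials$session == "retest" & trials$participant_id %in% names(corr)
  add <- corr[trials$participant_id[idx]]
  trials[[rt_col]][idx] <- trials[[rt_col]][idx] + add
  if (rt_col != "rt_raw_s" && "rt_raw_s" %in% names(trials))
    trials$rt_raw_s[idx] <- trials$rt_raw_s[idx] + add

  ss_tot <- sum((retest_m - mean(retest_m))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::resid(fit)^2) / ss_tot else 1
  model <- structure(list(intercept_s = a, slope = b,
                          r_squared = r2,
                          correction_s = corr),
                     class = "learning_model")
  list(trials = trials, model = model)
}

#' @export
print.learning_model <- function(x, ...) {
  cat(sprintf("Learning-effect model: retest = %.3f + %.3f * test (R^2 = %.2f)\n",
              x$intercept_s, x$slope, x$r_squared))
  cat(sprintf("  correction factors: %d participants, mean %+.3f s\n",
              length(x$correction_s), mean(x$correction_s)))
  invisible(x)
}
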