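# Trial-level simulators for the two dual-task tests and for word scores
# used by the adaptive SRT50 procedure.

.session_levels <- c("test", "retest")
.order_levels <- c("4_first", "8_first")

# log-mean RT item effect for an SVT item, derived deterministically from the
# base seed so all participants and sessions share item difficulties.
.svt_item_effect <- function(item_id, seed, sd) {
  vapply(item_id, function(id)
    with_substream(seed, "svt-item-effect", id, expr = stats::rnorm(1, 0, sd)),
    numeric(1))
}

#' Simulate one SVT session
#'
#' Generates one participant-session-condition block of the sentence
#' verification test: `n_items` spoken statements (half true, half false)
#' that the listener categorizes as true or false while their reaction time
#' relative to the sentence end is recorded.
#'
#' Comprehension of each statement is Bernoulli with a logit that includes
#' the SNR condition, the listener's word score in quiet and a participant
#' offset. An understood statement is answered according to its truth value;
#' otherwise the listener guesses, with a bias toward answering "false"
#' (an unintelligible statement cannot be verified), which produces the
#' higher accuracy on false than on true statements seen in CI users.
#'
#' Shifted reaction times (raw RT + `rt_shift_s`) are Gamma with a constant
#' per-participant shape; the log-mean includes condition, session
#' (learning), within-session order, answer correctness and truth-type terms
#' plus participant, item and per-session random effects. Draws that land
#' beyond the response window are recorded as missing responses - misses
#' arise mechanistically from window censoring, not from a separate coin
#' flip. With default calibration about 2.2% of trials are missing and
#' accuracy is about 93.1% for false vs 86.8% for true statements.
#'
#' @param listener A [psychometric_listener()].
#' @param session `"test"` or `"retest"`.
#' @param order Which SNR condition came first for this participant,
#'   `"4_first"` or `"8_first"` (defaults to the listener's assignment).
#' @param snr_condition Condition offset above SRT50 in dB: 4 or 8.
#' @param n_items Number of statements; must be even (half true, half false).
#' @param seed Base seed; trial draws use a substream named by participant,
#'   session and condition.
#' @param config A [cohort_config()] providing the shared effect sizes.
#' @return A data.frame with one row per trial: `participant_id`, `session`,
#'   `order`, `snr_condition`, `item_id`, `item_truth`, `response`,
#'   `answer_correct`, `rt_raw_s`, `rt_shifted_s`, `valid`.
#' @export
#' @examples
#' l <- psychometric_listener(id = "P01")
#' l$order <- "4_first"
#' head(simulate_svt_session(l, "test", snr_condition = 4, seed = 1))
simulate_svt_session <- function(listener, session = "test", order = listener$order,
                                 snr_condition = 4, n_items = 30, seed = 1L,
                                 config = cohort_config()) {
  stopifnot(inherits(listener, "psychometric_listener"))
  session <- match.arg(session, .session_levels)
  order <- match.arg(order, .order_levels)
  if (!snr_condition %in% c(4, 8)) stop("snr_condition must be 4 or 8")
  if (n_items %% 2 != 0) stop("n_items must be even (half true, half false items)")

  # item identities: sampled without replacement from the 95 true / 95 false
  # statement pool, per session and condition
  items <- with_substream(seed, "svt-items", listener$id, session, snr_condition, expr = {
    truth <- sample(rep(c(TRUE, FALSE), n_items / 2))
    ids <- character(n_items)
    ids[truth] <- sprintf("T%02d", sample(95, sum(truth)))
    ids[!truth] <- sprintf("F%02d", sample(95, sum(!truth)))
    list(ids = ids, truth = truth)
  })
  item_eff <- .svt_item_effect(items$ids, seed, config$rt_item_sd)

  condsign <- if (snr_condition == 8) 1 else -1          # +1 = easier
  measured_second <- (order == "4_first") == (snr_condition == 8)

  tr <- with_substream(seed, "svt-trials", listener$id, session, snr_condition, expr = {
    sess_shift <- stats::rnorm(1, 0, listener$session_noise_sd)
    p_comp <- stats::plogis(config$svt_comp_intercept + listener$svt_comp_offset +
                              0.5 * config$svt_cond_logit * condsign +
                              config$svt_wsq_slope * (listener$word_score_quiet - 0.875))
    understood <- stats::runif(n_items) < p_comp
    guess_false <- stats::runif(n_items) < config$false_guess_bias
    response <- ifelse(understood, items$truth, !guess_false)
    correct <- response == items$truth

    mu <- listener$rt_base_log + item_eff + sess_shift -
      0.5 * config$rt_condition_log * condsign +
      (session == "retest") * log(listener$learning_gain) -
      measured_second * config$rt_order_log +
      (!correct) * config$rt_incorrect_log +
      (!items$truth) * config$rt_false_log
    rt_shifted <- stats::rgamma(n_items, shape = listener$rt_shape,
                                rate = listener$rt_shape / exp(mu))
    list(response = response, correct = correct, rt_shifted = rt_shifted)
  })

  rt_raw <- tr$rt_shifted - config$rt_shift_s
  miss <- rt_raw > config$response_window_s
  out <- data.frame(
    participant_id = listener$id, session = session, order = order,
    snr_condition = snr_condition, item_id = items$ids, item_truth = items$truth,
    response = ifelse(miss, NA, tr$response),
    answer_correct = ifelse(miss, NA, tr$correct),
    rt_raw_s = ifelse(miss, NA_real_, rt_raw),
    rt_shifted_s = ifelse(miss, NA_real_, tr$rt_shifted),
    valid = !miss,
    stringsAsFactors = FALSE
  )
  out
}

#' Simulate one SWIRT session
#'
#' Generates one participant-session-condition block of the sentence-final
#' word identification and recall test: `n_lists` lists of sentences whose
#' final word the listener repeats after each sentence (speech
#' intelligibility) and recalls after the whole list (listening effort).
#'
#' The list length follows the adaptive training rule: participants who
#' recalled 0-4 of the 5 training words get lists of five sentences, those
#' who recalled all 5 get lists of seven. Repetition of each final word is
#' Bernoulli with probability given by the listener's psychometric function
#' at the condition SNR minus a final-word difficulty penalty. Recall is
#' Bernoulli on the logit scale with strong list-position effects (a large
#' last-item recency boost), an SNR-condition effect, a session effect and
#' the participant's recall ability. Because participants are instructed to
#' name and remember a substitute word when the final word is not
#' understood, a misheard word whose token is reproduced counts as a correct
#' recall (so recall does not require correct repetition); set
#' `count_misheard_recall = FALSE` in the config to make recall conditional
#' on repetition instead.
#'
#' @inheritParams simulate_svt_session
#' @param n_lists Number of lists (default 5 per condition).
#' @param training_recall Number of words (0-5) recalled in the five-word
#'   training list; determines the list length.
#' @return A data.frame with one row per sentence: `participant_id`,
#'   `session`, `order`, `snr_condition`, `list_id`, `list_length`,
#'   `position_in_list`, `position_category` (first/middle/last),
#'   `word_type`, `repeated_correct`, `recalled_correct`.
#' @export
simulate_swirt_session <- function(listener, session = "test", order = listener$order,
                                   snr_condition = 4, n_lists = 5,
                                   training_recall = 3, seed = 1L,
                                   config = cohort_config()) {
  stopifnot(inherits(listener, "psychometric_listener"))
  session <- match.arg(session, .session_levels)
  order <- match.arg(order, .order_levels)
  if (!snr_condition %in% c(4, 8)) stop("snr_condition must be 4 or 8")
  if (n_lists < 1) stop("n_lists must be >= 1")
  if (!is.numeric(training_recall) || training_recall < 0 || training_recall > 5)
    stop("training_recall must lie in 0..5")

  list_length <- if (training_recall <= 4) 5L else 7L
  L <- list_length
  n <- n_lists * L
  pos <- rep(seq_len(L), n_lists)
  pos_cat <- ifelse(pos == 1, "first", ifelse(pos == L, "last", "middle"))
  list_id <- rep(sprintf("L%02d", seq_len(n_lists)), each = L)

  p_rep <- p_correct(listener, listener$srt50_db + snr_condition - listener$repeat_penalty_db)
  condsign <- if (snr_condition == 8) 1 else -1
  sesssign <- if (session == "retest") 1 else -1
  logit_recall <- config$recall_pos_logit[pos_cat] +
    0.5 * config$recall_cond_logit * condsign +
    0.5 * config$recall_session_logit * sesssign +
    listener$recall_ability

  tr <- with_substream(seed, "swirt-trials", listener$id, session, snr_condition, expr = {
    list(word_type = sample(c("noun", "verb", "adjective", "other"), n, TRUE,
                            prob = c(0.55, 0.20, 0.15, 0.10)),
         repeated = stats::runif(n) < p_rep,
         recalled_token = stats::runif(n) < stats::plogis(logit_recall))
  })
  recalled <- if (isTRUE(config$count_misheard_recall)) tr$recalled_token
              else tr$recalled_token & tr$repeated

  data.frame(
    participant_id = listener$id, session = session, order = order,
    snr_condition = snr_condition, list_id = list_id, list_length = L,
    position_in_list = pos, position_category = pos_cat,
    word_type = tr$word_type, repeated_correct = tr$repeated,
    recalled_correct = recalled, stringsAsFactors = FALSE
  )
}

#' Simulate the word score of one sentence
#'
#' Draws the proportion of correctly repeated words for a sentence presented
#' at `snr_db`: the mean of `n_words` independent Bernoulli draws with
#' success probability given by the listener's psychometric function. When
#' `n_words` is not supplied, the sentence length is sampled uniformly from
#' 5 to 9 words, matching the 5-9 word range of the sentence material.
#'
#' @inheritParams p_correct
#' @param n_words Number of words in the sentence (>= 1), or `NULL` to
#'   sample the length.
#' @param seed Optional seed; `NULL` (default) uses the current RNG state,
#'   which is what [run_track()] relies on.
#' @return A proportion in `[0, 1]`.
#' @export
simulate_word_score <- function(listener, snr_db, n_words = NULL, seed = NULL) {
  draw <- function() {
    if (is.null(n_words)) n_words <- sample(5:9, 1)
    if (n_words < 1) stop("n_words must be >= 1")
    mean(stats::runif(n_words) < p_correct(listener, snr_db))
  }
  if (is.null(seed)) draw() else with_substream(seed, "word-score", expr = draw())
}

#' Simulate a full cohort's trial tables
#'
#' Runs [simulate_svt_session()] and [simulate_swirt_session()] for every
#' participant, session (test/retest) and SNR condition (SRT50 + 4 and
#' SRT50 + 8 dB), returning the two stacked tidy trial tables.
#'
#' @param cohort A list of listeners from [make_cohort()].
#' @param n_svt_items SVT statements per condition (default 30).
#' @param n_swirt_lists SWIRT lists per condition (default 5).
#' @param training_recall Training recall score (0-5) shared by the cohort,
#'   or a vector with one value per participant.
#' @param seed Base seed for all trial substreams.
#' @return A list with data.frames `svt` and `swirt`.
#' @export
simulate_cohort_trials <- function(cohort, n_svt_items = 30, n_swirt_lists = 5,
                                   training_recall = 3, seed = 1L) {
  config <- attr(cohort, "config")
  if (is.null(config)) config <- cohort_config()
  tr <- rep_len(training_recall, length(cohort))
  svt <- list(); swirt <- list()
  k <- 0
  for (i in seq_along(cohort)) {
    l <- cohort[[i]]
    for (session in .session_levels) for (cond in c(4, 8)) {
      k <- k + 1
      svt[[k]] <- simulate_svt_session(l, session, l$order, cond,
                                       n_items = n_svt_items, seed = seed, config = config)
      swirt[[k]] <- simulate_swirt_session(l, session, l$order, cond,
                                           n_lists = n_swirt_lists,
                                           training_recall = tr[i],
                                           seed = seed, config = config)
    }
  }
  list(svt = do.call(rbind, svt), swirt = do.call(rbind, swirt))
}
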