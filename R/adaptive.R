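# Stochastic-approximation adaptive procedure for the 50% speech reception
# threshold (SRT50).

#' Next SNR of the adaptive track
#'
#' One step of the stochastic-approximation rule: the SNR presented for
#' sentence n is the previous SNR plus `4 * (0.5 - Pc)`, where `Pc` is the
#' proportion of correctly repeated words in the previous sentence. The step
#' is therefore bounded in \[-2, +2\] dB.
#'
#' @param current_snr_db SNR of the previous sentence in dB.
#' @param prev_word_score Word score of the previous sentence, in `[0, 1]`.
#' @return The next SNR in dB.
#' @export
#' @examples
#' next_snr(2, 1)    # -> 0: full downward step of -2 dB
#' next_snr(2, 0.5)  # -> 2: at target, no step
next_snr <- function(current_snr_db, prev_word_score) {
  stopifnot(is.finite(current_snr_db))
  if (!is.numeric(prev_word_score) || is.na(prev_word_score) ||
      prev_word_score < 0 || prev_word_score > 1)
    stop("prev_word_score must lie in [0, 1]")
  current_snr_db + 4 * (0.5 - prev_word_score)
}

#' Run one adaptive SRT50 track
#'
#' Presents `n_sentences` sentences (default 26) starting at +2 dB SNR,
#' adapting the SNR after each sentence with [next_snr()]. The SNR following
#' the last sentence is computed from its word score but never presented,
#' giving 27 SNR values in total; the SRT50 estimate is the mean of SNRs 5
#' through 27 (the first four are discarded as burn-in of the staircase).
#'
#' @param responder A function `snr_db -> word score in [0, 1]`; typically a
#'   closure over a [psychometric_listener()] calling
#'   [simulate_word_score()], but any callable (including a deterministic
#'   psychometric function) works.
#' @param n_sentences Number of sentences presented (default 26).
#' @param start_snr_db Initial SNR (default +2 dB).
#' @param seed Optional seed set (via a substream) before the first draw, so
#'   a stochastic responder yields a reproducible track.
#' @return An object of class `adaptive_track`: list with `snr_sequence_db`
#'   (length `n_sentences + 1`), `word_scores` (length `n_sentences`) and
#'   `srt50_db`.
#' @export
#' @examples
#' run_track(function(snr) 0.5)  # fixed point: every SNR is +2 dB
run_track <- function(responder, n_sentences = 26, start_snr_db = 2, seed = NULL) {
  stopifnot(is.function(responder), n_sentences >= 1)
  body <- function() {
    snr <- numeric(n_sentences + 1)
    score <- numeric(n_sentences)
    snr[1] <- start_snr_db
    for (n in seq_len(n_sentences)) {
      s <- tryCatch(responder(snr[n]),
                    error = function(e) stop(sprintf("responder failed at sentence %d: %s",
                                                     n, conditionMessage(e)), call. = FALSE))
      if (!is.numeric(s) || is.na(s) || s < 0 || s > 1)
        stop(sprintf("responder returned an invalid word score at sentence %d", n))
      score[n] <- s
      snr[n + 1] <- next_snr(snr[n], s)
    }
    structure(list(snr_sequence_db = snr, word_scores = score,
                   srt50_db = mean(snr[5:(n_sentences + 1)])),
              class = "adaptive_track")
  }
  if (is.null(seed)) body() else with_substream(seed, "track", expr = body())
}

#' @export
print.adaptive_track <- function(x, ...) {
  cat(sprintf("Adaptive SRT50 track: %d sentences, start %+.1f dB\n",
              length(x$word_scores), x$snr_sequence_db[1]))
  cat(sprintf("  SRT50 estimate (mean of SNRs 5..%d): %.2f dB\n",
              length(x$snr_sequence_db), x$srt50_db))
  invisible(x)
}

#' SRT50 estimate of a completed track
#'
#' The SRT50 is defined as the arithmetic mean of SNR values 5 through 27
#' (for the standard 26-sentence track): the initial SNRs are discarded, and
#' the never-presented 27th SNR, computed from the final word score, is
#' included.
#'
#' @param track An [run_track()] result.
#' @return The SRT50 estimate in dB.
#' @export
estimate_srt50 <- function(track) {
  if (!inherits(track, "adaptive_track")) stop("not an adaptive_track")
  snr <- track$snr_sequence_db
  n <- length(track$word_scores)
  if (length(snr) != n + 1 || anyNA(snr))
    stop("incomplete track: need n_sentences + 1 SNR values without gaps")
  if (length(snr) < 5) stop("incomplete track: fewer than 5 SNR values")
  mean(snr[5:length(snr)])
}

#' Monte-Carlo study of the adaptive procedure
#'
#' Runs many independent adaptive tracks against one simulated listener and
#' summarizes the sampling distribution of the SRT50 estimate: bias and SD
#' relative to the listener's true SRT50, and the mean intelligibility the
#' psychometric function assigns to the estimates (which should be close to
#' 50% for an unbiased procedure).
#'
#' @param listener A [psychometric_listener()].
#' @param n_tracks Number of tracks.
#' @param n_words Fixed sentence length, or `NULL` to sample 5-9 words.
#' @param seed Base seed; track i uses substream `(seed, "srt-study", i)`.
#' @return A list with `estimates` (numeric vector), `bias`, `sd` and
#'   `mean_p_at_estimate`.
#' @export
run_srt_study <- function(listener, n_tracks = 500, n_words = 6, seed = 1L) {
  est <- vapply(seq_len(n_tracks), function(i) {
    with_substream(seed, "srt-study", i, expr = {
      run_track(function(snr) simulate_word_score(listener, snr, n_words))$srt50_db
    })
  }, numeric(1))
  list(estimates = est,
       bias = mean(est) - listener$srt50_db,
       sd = stats::sd(est),
       mean_p_at_estimate = mean(p_correct(listener, est)))
}
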