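# Orchestration: one reproducible run tying simulation -> preprocessing ->
# GLMMs -> intra-individual detection, with CSV/JSON outputs and a manifest.

#' Experiment run configuration
#'
#' @param cohort A [cohort_config()] (or a list of its arguments).
#' @param n_svt_items SVT statements per condition (default 30: 15 true,
#'   15 false).
#' @param n_swirt_lists SWIRT lists per condition (default 5).
#' @param conditions SNR condition offsets in dB above SRT50, strictly
#'   increasing (default `c(4, 8)`).
#' @param training_recall SWIRT training recall score(s), 0-5.
#' @param learning_correction Apply the retest learning-effect correction to
#'   SVT reaction times.
#' @param outlier_removal Exclude trials of flagged outlier items/lists from
#'   model fitting (flags are always computed and reported).
#' @param fit_models Fit the four GLMMs (can be switched off for
#'   simulation-only runs).
#' @param model_random_slopes Include SNR-condition random slopes in the
#'   full models (the full crossed structure; slower to fit).
#' @param seed Explicit RNG seed for everything (no wall-clock defaults).
#' @param out_dir Output directory for CSV/JSON artifacts, or `NULL` to keep
#'   results in memory only.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(), n_svt_items = 30,
                       n_swirt_lists = 5, conditions = c(4, 8),
                       training_recall = 3, learning_correction = TRUE,
                       outlier_removal = TRUE, fit_models = TRUE,
                       model_random_slopes = TRUE, seed = 1L, out_dir = NULL) {
  if (!inherits(cohort, "cohort_config")) cohort <- do.call(cohort_config, as.list(cohort))
  if (length(conditions) != 2 || diff(conditions) <= 0)
    stop("conditions must be two strictly increasing offsets")
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stop("an explicit numeric seed is required")
  structure(list(cohort = cohort, n_svt_items = n_svt_items,
                 n_swirt_lists = n_swirt_lists, conditions = conditions,
                 training_recall = training_recall,
                 learning_correction = isTRUE(learning_correction),
                 outlier_removal = isTRUE(outlier_removal),
                 fit_models = isTRUE(fit_models),
                 model_random_slopes = isTRUE(model_random_slopes),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; top-level keys are [run_config()] arguments, with
#'   `cohort` a mapping of [cohort_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$cohort)) {
    if (!is.null(y$cohort$recall_pos_logit)) y$cohort$recall_pos_logit <- unlist(y$cohort$recall_pos_logit)
    y$cohort <- do.call(cohort_config, y$cohort)
  }
  do.call(run_config, y)
}

.config_hash <- function(x) {
  x <- unclass(x)
  x$out_dir <- NULL  # hash the scientific configuration, not the destination
  s <- paste(deparse(x), collapse = "")
  h <- 17
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
  sprintf("%09d", h)
}

.write_json <- function(x, path)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10, null = "null", pretty = TRUE)

# attach participant covariates and factor codings used by the models
.model_frame <- function(trials, cohort) {
  wsq <- vapply(cohort, function(l) l$word_score_quiet, numeric(1))
  names(wsq) <- vapply(cohort, function(l) l$id, character(1))
  trials$wsq <- wsq[trials$participant_id]
  trials$snr <- factor(trials$snr_condition, levels = c(4, 8), labels = c("p4", "p8"))
  trials$session <- factor(trials$session, levels = c("test", "retest"))
  trials$order <- factor(trials$order)
  trials
}

#' Run a complete simulated experiment
#'
#' Generates a cohort and its trial tables, runs one adaptive SRT50 track
#' per participant, applies the preprocessing steps (validity filtering, RT
#' shifting, item/list outlier detection, learning-effect correction), fits
#' the four GLMMs with AIC backward selection and standardized
#' coefficients, and derives the intra-individual detection thresholds for
#' all four study measures. When `config$out_dir` is set, trial tables are
#' written as CSV and all results as JSON next to a manifest carrying the
#' config hash, seed and package version; re-running the same config
#' reproduces every output byte-identically.
#'
#' @param config A [run_config()].
#' @return A list of class `effort_run` with elements `cohort`, `srt`,
#'   `trials`, `outliers`, `learning`, `models`, `thresholds`, `manifest`.
#' @export
run_experiment <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    if (file.access(config$out_dir, 2) != 0)
      stop(sprintf("output directory '%s' is not writable", config$out_dir))
  }
  cohort <- make_cohort(config$cohort)
  ccfg <- attr(cohort, "config")

  # adaptive SRT50 measurement, one track per participant
  srt <- do.call(rbind, lapply(cohort, function(l) {
    tr <- with_substream(config$seed, "srt", l$id, expr = {
      run_track(function(snr) simulate_word_score(l, snr))
    })
    data.frame(participant_id = l$id, srt50_true_db = l$srt50_db,
               srt50_est_db = tr$srt50_db, stringsAsFactors = FALSE)
  }))

  trials <- simulate_cohort_trials(cohort, config$n_svt_items, config$n_swirt_lists,
                                   config$training_recall, seed = config$seed)
  svt <- shift_rt(validate_svt_responses(trials$svt,
                                         window_hi_s = ccfg$response_window_s),
                  shift_s = ccfg$rt_shift_s)
  swirt <- trials$swirt
  hardest <- config$conditions[1]

  outliers <- list(
    svt_accuracy = detect_item_outliers(svt, "answer_correct", "binary",
                                        unit = "item_id", hardest = hardest),
    svt_rt = detect_item_outliers(svt[svt$valid, ], "rt_shifted_s", "rt",
                                  unit = "item_id", hardest = hardest),
    swirt_repeat = detect_item_outliers(swirt, "repeated_correct", "binary",
                                        unit = "list_id", hardest = hardest),
    swirt_recall = detect_item_outliers(swirt, "recalled_correct", "binary",
                                        unit = "list_id", hardest = hardest)
  )

  learning <- NULL
  svt_rt_data <- svt
  if (config$learning_correction) {
    lc <- correct_learning_effect(svt)
    svt_rt_data <- lc$trials
    learning <- lc$model
  }

  drop_flagged <- function(d, rep, unit) {
    if (!config$outlier_removal) return(d)
    d[!d[[unit]] %in% rep$unit_id[rep$flagged], , drop = FALSE]
  }

  models <- NULL
  if (config$fit_models) {
    svt_m <- .model_frame(svt, cohort)
    svt_rt_m <- .model_frame(svt_rt_data, cohort)
    swirt_m <- .model_frame(swirt, cohort)
    re <- function(g) if (config$model_random_slopes)
      sprintf("(1 + snr | %s)", g) else sprintf("(1 | %s)", g)
    mk <- function(resp, fixed, groups)
      stats::as.formula(paste(resp, "~", paste(c(fixed, vapply(groups, re, "")),
                                               collapse = " + ")), env = globalenv())
    specs <- list(
      svt_rt = list(spec = model_spec(mk("rt_shifted_s",
                      c("snr", "session", "order", "answer_correct", "item_truth", "wsq"),
                      c("participant_id", "item_id")), "gamma"),
                    data = drop_flagged(svt_rt_m[svt_rt_m$valid, ], outliers$svt_rt, "item_id")),
      svt_accuracy = list(spec = model_spec(mk("answer_correct",
                      c("snr", "session", "order", "item_truth", "wsq"),
                      c("participant_id", "item_id")), "binomial"),
                    data = drop_flagged(svt_m, outliers$svt_accuracy, "item_id")),
      swirt_recall = list(spec = model_spec(mk("recalled_correct",
                      c("snr", "session", "order", "position_category", "word_type", "wsq"),
                      c("participant_id", "list_id")), "binomial"),
                    data = drop_flagged(swirt_m, outliers$swirt_recall, "list_id")),
      swirt_repeat = list(spec = model_spec(mk("repeated_correct",
                      c("snr", "session", "order", "wsq"),
                      c("participant_id", "list_id")), "binomial"),
                    data = drop_flagged(swirt_m, outliers$swirt_repeat, "list_id"))
    )
    models <- lapply(names(specs), function(nm) {
      sel <- backward_select_aic(specs[[nm]]$spec, specs[[nm]]$data)
      std <- standardized_coefficients(sel$fit, specs[[nm]]$data)
      list(name = nm, selection = sel, fit = sel$fit, std = std,
           r2 = r2_nakagawa(sel$fit), dispersion = overdispersion_check(sel$fit))
    })
    names(models) <- names(specs)
  }

  trt_diffs <- function(d, value) {
    ok <- !is.na(d[[value]])
    m <- tapply(as.numeric(d[[value]][ok]),
                list(d$participant_id[ok], d$session[ok]), mean)
    m[, "test"] - m[, "retest"]
  }
  measure <- function(d, value, direction) {
    thr <- testretest_threshold(trt_diffs(d, value))
    cd <- participant_condition_diffs(d, value, direction,
                                      easier = config$conditions[2],
                                      harder = config$conditions[1])
    count_detections(cd, thr)
  }
  thresholds <- list(
    svt_rt = measure(svt_rt_data, "rt_shifted_s", "lower"),
    svt_accuracy = measure(svt, "answer_correct", "higher"),
    swirt_recall = measure(swirt, "recalled_correct", "higher"),
    swirt_repeat = measure(swirt, "repeated_correct", "higher")
  )

  manifest <- list(config_hash = .config_hash(config), seed = config$seed,
                   package = "effortbench",
                   version = as.character(utils::packageVersion("effortbench")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."))

  bundle <- structure(list(cohort = cohort, srt = srt,
                           trials = list(svt = svt_rt_data, swirt = swirt),
                           outliers = outliers, learning = learning,
                           models = models, thresholds = thresholds,
                           manifest = manifest, config = config),
                      class = "effort_run")

  if (!is.null(config$out_dir)) {
    out <- config$out_dir
    utils::write.csv(svt_rt_data, file.path(out, "svt_trials.csv"), row.names = FALSE)
    utils::write.csv(swirt, file.path(out, "swirt_trials.csv"), row.names = FALSE)
    utils::write.csv(srt, file.path(out, "srt_tracks.csv"), row.names = FALSE)
    .write_json(lapply(outliers, function(o) as.list(as.data.frame(o))),
                file.path(out, "outliers.json"))
    if (!is.null(learning))
      .write_json(list(intercept_s = learning$intercept_s, slope = learning$slope,
                       r_squared = learning$r_squared,
                       correction_s = as.list(learning$correction_s)),
                  file.path(out, "learning.json"))
    if (!is.null(models))
      .write_json(lapply(models, function(m) list(
        formula = deparse(m$fit$spec$formula), family = m$fit$spec$family,
        aic = m$fit$aic, loglik = m$fit$loglik, converged = m$fit$converged,
        r2_marginal = unname(m$r2["marginal"]), r2_conditional = unname(m$r2["conditional"]),
        dispersion_ratio = m$dispersion$dispersion_ratio,
        coefficients = as.list(as.data.frame(m$std)))),
        file.path(out, "models.json"))
    .write_json(lapply(thresholds, function(t) list(
      mu = if (!is.null(t$fit)) t$fit$mu else NA, sigma = if (!is.null(t$fit)) t$fit$sigma else NA,
      threshold = t$threshold, n_participants = t$n_participants,
      n_significant = t$n_significant, n_correct_direction = t$n_correct_direction,
      max_detection_rate = t$max_detection_rate)),
      file.path(out, "thresholds.json"))
    .write_json(manifest, file.path(out, "manifest.json"))
  }
  bundle
}

#' @export
print.effort_run <- function(x, ...) {
  cat(sprintf("Simulated experiment: %d participants, seed %d (config %s)\n",
              length(x$cohort), x$manifest$seed, x$manifest$config_hash))
  cat(sprintf("  SVT trials: %d, SWIRT trials: %d\n",
              nrow(x$trials$svt), nrow(x$trials$swirt)))
  for (nm in names(x$thresholds)) {
    t <- x$thresholds[[nm]]
    cat(sprintf("  %-13s threshold %.3g, %d/%d significant, max detection rate %.0f%%\n",
                nm, t$threshold, t$n_significant, t$n_participants,
                100 * t$max_detection_rate))
  }
  invisible(x)
}

#' Render a human-readable experiment report
#'
#' Formats the results bundle as markdown: standardized-coefficient tables
#' (term, std. coefficient, 95% CI, p with significance stars), model
#' diagnostics (AIC, R-squared, dispersion), outlier summaries, the
#' learning-effect fit, and the threshold/detection summary per measure.
#' Models that failed to converge are rendered with a warning banner;
#' missing components (e.g. a run with `fit_models = FALSE`) are reported as
#' explicit gaps.
#'
#' @param bundle An [run_experiment()] result.
#' @param path Optional file to write the report to.
#' @return The report lines, invisibly.
#' @export
report <- function(bundle, path = NULL) {
  stopifnot(inherits(bundle, "effort_run"))
  L <- character(0)
  add <- function(...) L <<- c(L, sprintf(...))
  add("# Simulated listening-effort experiment")
  add("")
  add("Participants: %d; seed: %d; config hash: %s", length(bundle$cohort),
      bundle$manifest$seed, bundle$manifest$config_hash)
  add("")
  add("## Model coefficients")
  if (is.null(bundle$models)) {
    add("")
    add("_Gap: models were not fitted in this run._")
  } else {
    for (nm in names(bundle$models)) {
      m <- bundle$models[[nm]]
      add("")
      add("### %s (%s)", nm, m$fit$spec$family)
      if (!m$fit$converged) add("> **WARNING: this fit did not converge.**")
      add("")
      add("AIC %.1f; marginal R2 %.2f; conditional R2 %.2f; dispersion ratio %.2f",
          m$fit$aic, m$r2["marginal"], m$r2["conditional"],
          m$dispersion$dispersion_ratio)
      add("")
      add("| term | std. coefficient | 95%% C.I. | p value |")
      add("|---|---|---|---|")
      for (i in seq_len(nrow(m$std)))
        add("| %s | %.3f | [%.3f, %.3f] | %.4g%s |", m$std$term[i],
            m$std$std_coefficient[i], m$std$ci_lo[i], m$std$ci_hi[i],
            m$std$p[i], m$std$stars[i])
      add("")
      add("*<0.05; **<0.01; ***<0.001")
    }
  }
  add("")
  add("## Learning effect")
  if (is.null(bundle$learning)) {
    add("")
    add("_Gap: learning correction was not applied._")
  } else {
    add("")
    add("retest = %.3f + %.3f x test (R2 = %.2f); corrections added to retest trials.",
        bundle$learning$intercept_s, bundle$learning$slope, bundle$learning$r_squared)
  }
  add("")
  add("## Outliers")
  for (nm in names(bundle$outliers)) {
    o <- bundle$outliers[[nm]]
    add("- %s: %d of %d units flagged (two-sided tail < %g)", nm,
        sum(o$flagged), nrow(o), attr(o, "alpha"))
  }
  add("")
  add("## Intra-individual detection")
  add("")
  add("| measure | threshold | significant | correct direction | max detection rate |")
  add("|---|---|---|---|---|")
  for (nm in names(bundle$thresholds)) {
    t <- bundle$thresholds[[nm]]
    add("| %s | %.3g | %d/%d | %d/%d | %.0f%% |", nm, t$threshold,
        t$n_significant, t$n_participants, t$n_correct_direction,
        t$n_participants, 100 * t$max_detection_rate)
  }
  if (!is.null(path)) writeLines(L, path)
  invisible(L)
}
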