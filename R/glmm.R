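# Generalized linear mixed models with crossed random effects: Gamma
# log-link for shifted reaction times, binomial logit for accuracy,
# repetition and recall. Fitting delegates to lme4 (Laplace approximation);
# this module adds the model-selection, inference and reporting layer.

#' Specify a GLMM
#'
#' A lightweight container pairing an `lme4`-style formula (random terms in
#' `(1 + x | group)` notation, grouping factors crossed) with the response
#' family. Only the two families used for these experiments are supported:
#' binomial with logit link for binary outcomes, and Gamma with log link for
#' strictly positive shifted reaction times.
#'
#' @param formula Model formula, e.g.
#'   `rt_shifted_s ~ snr + session + (1 + snr | participant_id) + (1 | item_id)`.
#' @param family `"binomial"` or `"gamma"`.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(formula, family = c("binomial", "gamma")) {
  family <- match.arg(family)
  stopifnot(inherits(formula, "formula"), length(formula) == 3)
  bars <- lme4::findbars(formula)
  for (b in bars) {
    svars <- setdiff(all.vars(b[[2]]), "1")
    fvars <- all.vars(lme4::nobars(formula)[[3]])
    if (!all(svars %in% fvars))
      stop("every random slope variable must also appear as a fixed term")
  }
  structure(list(formula = formula, family = family), class = "model_spec")
}

.glmm_family <- function(family)
  if (family == "binomial") stats::binomial() else stats::Gamma(link = "log")

#' Fit a GLMM by the Laplace approximation
#'
#' Fits the model with [lme4::glmer()] using the Laplace approximation of
#' the integrated likelihood (the default `nAGQ = 1`). Rows with a missing
#' response or missing covariates are dropped listwise. Formulas without
#' random terms are fitted with [stats::glm()], which the Laplace fit
#' reduces to when every random-effect variance is zero. Non-convergence and
#' singular variance components are flagged on the returned object, never
#' raised as errors.
#'
#' Inference on the coefficients is Wald-z: standard errors from the
#' observed information, two-sided normal p-values and 95% confidence
#' intervals.
#'
#' @param spec A [model_spec()].
#' @param data Trial-level data.frame.
#' @param ... Passed on to [lme4::glmer()] (e.g. `control`).
#' @return An object of class `effort_glmm`: list with the fitted `model`,
#'   the `spec`, a Wald `coefficients` table, `varcomp` (data.frame of
#'   variance components), `loglik`, `df` (number of estimated parameters),
#'   `aic`, `n`, and flags `converged` and `singular`.
#' @export
fit_glmm <- function(spec, data, ...) {
  stopifnot(inherits(spec, "model_spec"), is.data.frame(data))
  vars <- all.vars(spec$formula)
  data <- data[stats::complete.cases(data[, vars, drop = FALSE]), , drop = FALSE]
  resp <- data[[all.vars(spec$formula[[2]])[1]]]
  if (spec$family == "gamma" && any(resp <= 0))
    stop("Gamma log-link requires a strictly positive response (use shifted RTs)")
  has_bars <- !is.null(lme4::findbars(spec$formula))

  if (has_bars) {
    mod <- suppressWarnings(suppressMessages(
      lme4::glmer(spec$formula, data = data, family = .glmm_family(spec$family), ...)))
    conv <- length(mod@optinfo$conv$lme4$messages) == 0 && mod@optinfo$conv$opt == 0
    singular <- lme4::isSingular(mod, tol = 1e-4)
    est <- lme4::fixef(mod)
    vc <- as.data.frame(lme4::VarCorr(mod))
  } else {
    mod <- stats::glm(spec$formula, family = .glmm_family(spec$family), data = data)
    conv <- isTRUE(mod$converged)
    singular <- FALSE
    est <- stats::coef(mod)
    vc <- data.frame()
  }
  se <- sqrt(diag(as.matrix(suppressWarnings(stats::vcov(mod)))))
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  hw <- stats::qnorm(0.975) * se
  ll <- stats::logLik(mod)
  structure(list(
    model = mod, spec = spec,
    coefficients = data.frame(term = names(est), estimate = unname(est),
                              se = unname(se), ci_lo = unname(est - hw),
                              ci_hi = unname(est + hw), z = unname(z),
                              p = unname(p), stringsAsFactors = FALSE),
    varcomp = vc, loglik = as.numeric(ll), df = attr(ll, "df"),
    aic = stats::AIC(mod), n = nrow(data),
    converged = conv, singular = singular
  ), class = "effort_glmm")
}

#' @export
print.effort_glmm <- function(x, ...) {
  cat(sprintf("GLMM (%s, %s): %s\n",
              x$spec$family, if (inherits(x$model, "glmerMod")) "Laplace" else "GLM",
              deparse(x$spec$formula)))
  cat(sprintf("  n = %d, logLik = %.2f (df %d), AIC = %.2f\n", x$n, x$loglik, x$df, x$aic))
  if (!x$converged) cat("  WARNING: fit did not converge\n")
  if (x$singular) cat("  note: singular variance component(s)\n")
  print(x$coefficients, digits = 3, row.names = FALSE)
  invisible(x)
}

# --- formula surgery -------------------------------------------------------

.decompose_formula <- function(f) {
  fixed <- lme4::nobars(f)
  list(resp = deparse(f[[2]]),
       fixed = attr(stats::terms(fixed), "term.labels"),
       bars = lme4::findbars(f))
}

.bar_text <- function(b) paste0("(", deparse(b), ")")

.rebuild_formula <- function(resp, fixed, bars) {
  rhs <- c(fixed, vapply(bars, .bar_text, character(1)))
  if (!length(rhs)) rhs <- "1"
  stats::as.formula(paste(resp, "~", paste(rhs, collapse = " + ")),
                    env = globalenv())
}

.bar_slopes <- function(b) {
  lhs <- stats::reformulate(deparse(b[[2]]))
  attr(stats::terms(lhs), "term.labels")
}

# drop one slope from a bar; NULL if the slope leaves an intercept-only bar
.bar_without_slope <- function(b, slope) {
  keep <- setdiff(.bar_slopes(b), slope)
  lhs <- if (length(keep)) paste(c("1", keep), collapse = " + ") else "1"
  str2lang(paste(lhs, "|", deparse(b[[3]])))
}

#' Backward model selection by AIC
#'
#' Starting from the full model, iteratively removes one fixed or random
#' term at a time, refits, and keeps the single removal with the lowest AIC;
#' selection stops when no removal lowers the AIC. Removable candidates are
#' the droppable fixed terms (respecting marginality, and never while a
#' matching random slope remains), individual random slopes, and
#' intercept-only random terms. When two models tie in AIC the simpler one
#' (fewer parameters) is preferred.
#'
#' If the full model fails to converge, the random-effects structure is
#' first simplified by removing random slopes - item/list slopes before
#' participant slopes - until a converging fit is found.
#'
#' @param spec Full [model_spec()].
#' @param data Trial-level data.frame.
#' @param tie_tol AIC differences within this tolerance count as ties.
#' @param ... Passed to [fit_glmm()].
#' @return A list of class `aic_selection` with `fit` (the selected
#'   [fit_glmm()] object) and `trace`, a data.frame recording every
#'   candidate refit (step, removed term, AIC, convergence, action).
#' @export
backward_select_aic <- function(spec, data, tie_tol = 1e-9, ...) {
  stopifnot(inherits(spec, "model_spec"))
  parts <- .decompose_formula(spec$formula)
  trace <- list()
  note <- function(step, removed, aic, conv, action)
    trace[[length(trace) + 1]] <<- data.frame(step = step, removed = removed,
                                              aic = aic, converged = conv,
                                              action = action, stringsAsFactors = FALSE)

  refit <- function(parts) fit_glmm(model_spec(.rebuild_formula(parts$resp, parts$fixed, parts$bars),
                                               spec$family), data, ...)
  cur_fit <- refit(parts)
  note(0L, "<full model>", cur_fit$aic, cur_fit$converged, "start")

  # convergence fallback: strip random slopes, weakest-identified groups first
  if (!cur_fit$converged) {
    grp_order <- function(b) {
      g <- deparse(b[[3]])
      if (grepl("participant", g, ignore.case = TRUE)) 2 else 1
    }
    repeat {
      slopes <- list()
      for (i in seq_along(parts$bars))
        for (s in .bar_slopes(parts$bars[[i]]))
          slopes[[length(slopes) + 1]] <- list(i = i, s = s, ord = grp_order(parts$bars[[i]]))
      if (!length(slopes) || cur_fit$converged) break
      slopes <- slopes[order(vapply(slopes, `[[`, numeric(1), "ord"))]
      sl <- slopes[[1]]
      parts$bars[[sl$i]] <- .bar_without_slope(parts$bars[[sl$i]], sl$s)
      cur_fit <- refit(parts)
      note(0L, sprintf("slope %s | %s", sl$s, deparse(parts$bars[[sl$i]][[3]])),
           cur_fit$aic, cur_fit$converged, "convergence fallback")
    }
  }

  step <- 0L
  repeat {
    step <- step + 1L
    slope_vars <- unlist(lapply(parts$bars, .bar_slopes))
    cands <- list()
    # fixed terms: droppable under marginality, and not held by a random slope
    droppable <- stats::drop.scope(stats::reformulate(if (length(parts$fixed)) parts$fixed else "1"))
    for (tm in droppable) {
      if (tm %in% slope_vars) next
      p2 <- parts; p2$fixed <- setdiff(p2$fixed, tm)
      cands[[length(cands) + 1]] <- list(label = tm, parts = p2)
    }
    # random slopes
    for (i in seq_along(parts$bars)) {
      for (s in .bar_slopes(parts$bars[[i]])) {
        p2 <- parts
        p2$bars[[i]] <- .bar_without_slope(p2$bars[[i]], s)
        cands[[length(cands) + 1]] <-
          list(label = sprintf("slope %s | %s", s, deparse(parts$bars[[i]][[3]])), parts = p2)
      }
      if (!length(.bar_slopes(parts$bars[[i]]))) {
        p2 <- parts; p2$bars <- p2$bars[-i]
        cands[[length(cands) + 1]] <-
          list(label = sprintf("(1 | %s)", deparse(parts$bars[[i]][[3]])), parts = p2)
      }
    }
    if (!length(cands)) break
    fits <- lapply(cands, function(cd)
      tryCatch(refit(cd$parts), error = function(e) NULL))
    aics <- vapply(fits, function(f) if (is.null(f)) Inf else f$aic, numeric(1))
    dfs <- vapply(fits, function(f) if (is.null(f)) Inf else f$df, numeric(1))
    for (j in seq_along(cands))
      note(step, cands[[j]]$label, aics[j],
           !is.null(fits[[j]]) && fits[[j]]$converged, "candidate")
    # ties (within tie_tol) resolved toward fewer parameters
    best <- order(aics, dfs)[1]
    if (is.finite(aics[best]) && aics[best] < cur_fit$aic + tie_tol) {
      parts <- cands[[best]]$parts
      cur_fit <- fits[[best]]
      note(step, cands[[best]]$label, aics[best], cur_fit$converged, "removed")
    } else break
  }
  structure(list(fit = cur_fit, trace = do.call(rbind, trace)), class = "aic_selection")
}

#' @export
print.aic_selection <- function(x, ...) {
  removed <- x$trace$removed[x$trace$action == "removed"]
  cat(sprintf("AIC backward selection: %d term(s) removed%s\n", length(removed),
              if (length(removed)) paste0(" (", paste(removed, collapse = ", "), ")") else ""))
  print(x$fit)
  invisible(x)
}

#' Likelihood-ratio test for added interaction terms
#'
#' Augments a fitted model with candidate interaction terms among its
#' retained fixed effects, refits on the same data, and compares the two
#' nested fits with a likelihood-ratio chi-square whose degrees of freedom
#' equal the parameter difference. The interaction set is considered a
#' significant improvement when p < 0.05.
#'
#' @param fit Base [fit_glmm()] object.
#' @param candidate_terms Character vector of terms to add, e.g.
#'   `c("snr:session", "snr:order")`; may be empty.
#' @param data The same data used for the base fit.
#' @param ... Passed to [fit_glmm()].
#' @return A list of class `lrt_result` with `fit` (augmented), `chisq`,
#'   `df`, `p` and `kept` (`TRUE` when p < 0.05).
#' @export
add_interactions_lrt <- function(fit, candidate_terms, data, ...) {
  stopifnot(inherits(fit, "effort_glmm"))
  parts <- .decompose_formula(fit$spec$formula)
  if (!length(candidate_terms))
    return(structure(list(fit = fit, chisq = 0, df = 0L, p = 1, kept = FALSE),
                     class = "lrt_result"))
  new_vars <- unique(unlist(strsplit(candidate_terms, ":", fixed = TRUE)))
  if (!all(new_vars %in% unlist(lapply(parts$fixed, function(t) strsplit(t, ":")[[1]]))))
    stop("non-nested comparison: interaction variables must be retained fixed terms")
  p2 <- parts
  p2$fixed <- union(p2$fixed, candidate_terms)
  aug <- fit_glmm(model_spec(.rebuild_formula(p2$resp, p2$fixed, p2$bars), fit$spec$family),
                  data, ...)
  df <- aug$df - fit$df
  if (df < 0) stop("non-nested comparison: augmented model has fewer parameters")
  chisq <- 2 * (aug$loglik - fit$loglik)
  p <- if (df == 0) 1 else stats::pchisq(chisq, df, lower.tail = FALSE)
  structure(list(fit = aug, chisq = chisq, df = df, p = p, kept = p < 0.05),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("Likelihood-ratio test: chi^2 = %.2f, df = %d, p = %.4g -> %s\n",
              x$chisq, x$df, x$p,
              if (x$kept) "interactions kept" else "interactions not kept"))
  invisible(x)
}

#' Standardized coefficients with Wald inference
#'
#' Refits the model after z-scoring every continuous covariate (numeric with
#' more than two distinct values); binary dummies and factors are left
#' unscaled, and for the binomial and Gamma families the response is not
#' transformed (logit/log responses cannot be z-scored). Coefficients are
#' reported with 95% Wald-z confidence intervals, p-values and significance
#' stars.
#'
#' @param fit A converged [fit_glmm()] object.
#' @param data The model data on the original scale.
#' @param ... Passed to [fit_glmm()].
#' @return A data.frame of class `std_coef_table` with columns `term`,
#'   `std_coefficient`, `ci_lo`, `ci_hi`, `p`, `stars`.
#' @export
standardized_coefficients <- function(fit, data, ...) {
  stopifnot(inherits(fit, "effort_glmm"))
  f <- fit$spec$formula
  covs <- setdiff(all.vars(f[[3]]), all.vars(f[[2]]))
  grp_vars <- unlist(lapply(lme4::findbars(f), function(b) all.vars(b[[3]])))
  for (v in setdiff(covs, grp_vars)) {
    x <- data[[v]]
    if (is.numeric(x) && length(unique(x[!is.na(x)])) > 2) {
      s <- stats::sd(x, na.rm = TRUE)
      if (s == 0) {
        warning(sprintf("covariate '%s' has zero variance; left unscaled", v))
      } else data[[v]] <- (x - mean(x, na.rm = TRUE)) / s
    }
  }
  refit <- fit_glmm(fit$spec, data, ...)
  tab <- refit$coefficients
  stars <- ifelse(tab$p < 0.001, "***", ifelse(tab$p < 0.01, "**",
                  ifelse(tab$p < 0.05, "*", "")))
  out <- data.frame(term = tab$term, std_coefficient = tab$estimate,
                    ci_lo = tab$ci_lo, ci_hi = tab$ci_hi, p = tab$p,
                    stars = stars, stringsAsFactors = FALSE)
  class(out) <- c("std_coef_table", "data.frame")
  attr(out, "converged") <- refit$converged
  out
}

#' @export
print.std_coef_table <- function(x, ...) {
  if (!isTRUE(attr(x, "converged"))) cat("WARNING: standardized refit did not converge\n")
  print.data.frame(x, digits = 3, row.names = FALSE)
  cat("*<0.05; **<0.01; ***<0.001\n")
  invisible(x)
}

#' Nakagawa marginal and conditional R-squared
#'
#' Variance explained on the link scale: the marginal R-squared relates the
#' variance of the fixed-effect linear predictor to the total (fixed +
#' random + distribution-specific residual) variance; the conditional
#' R-squared adds the random-effect variances to the numerator. Random-slope
#' variance contributions use the mean row variance of the random-effect
#' design (Johnson's extension). The distribution-specific residual variance
#' is pi^2/3 for the binomial logit and trigamma(shape) for the Gamma log
#' link.
#'
#' @param fit A [fit_glmm()] object.
#' @return Named numeric vector `c(marginal = , conditional = )`.
#' @export
r2_nakagawa <- function(fit) {
  stopifnot(inherits(fit, "effort_glmm"))
  mod <- fit$model
  X <- stats::model.matrix(mod)
  beta <- if (inherits(mod, "glmerMod")) lme4::fixef(mod) else stats::coef(mod)
  var_f <- stats::var(as.numeric(X %*% beta))
  var_re <- 0
  if (inherits(mod, "glmerMod")) {
    vc <- lme4::VarCorr(mod)
    for (g in names(vc)) {
      S <- as.matrix(vc[[g]])
      cols <- rownames(S)
      if (!all(cols %in% colnames(X))) stop("cannot map random slopes onto the design")
      Xr <- X[, cols, drop = FALSE]
      var_re <- var_re + mean(rowSums((Xr %*% S) * Xr))
    }
  }
  var_d <- if (fit$spec$family == "binomial") pi^2 / 3
           else trigamma(1 / stats::sigma(mod)^2)
  tot <- var_f + var_re + var_d
  c(marginal = var_f / tot, conditional = (var_f + var_re) / tot)
}

#' Overdispersion check via the Pearson statistic
#'
#' Ratio of the sum of squared Pearson residuals to the residual degrees of
#' freedom. Values near 1 indicate that the family's variance assumption
#' holds; the fit is flagged when the ratio exceeds `threshold`.
#'
#' @param fit A [fit_glmm()] object.
#' @param threshold Flagging threshold on the ratio (default 1.5).
#' @return A list with `dispersion_ratio`, `pearson_chisq`, `df` and
#'   `overdispersed`.
#' @export
overdispersion_check <- function(fit, threshold = 1.5) {
  stopifnot(inherits(fit, "effort_glmm"))
  r <- stats::residuals(fit$model, type = "pearson")
  df <- stats::df.residual(fit$model)
  ratio <- sum(r^2) / df
  list(dispersion_ratio = ratio, pearson_chisq = sum(r^2), df = df,
       overdispersed = ratio > threshold)
}
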