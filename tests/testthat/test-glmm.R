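test_that("with zero random-effect variance the Laplace fit matches an ordinary GLM", {
  set.seed(30)
  d <- sim_binomial_clusters(15, 20, beta0 = 0.2, beta_x = 0.7, sigma_u = 0)
  fit <- fit_glmm(model_spec(y ~ x + (1 | g), "binomial"), d)
  oracle <- glm(y ~ x, binomial, d)
  expect_equal(fit$coefficients$estimate, unname(coef(oracle)), tolerance = 1e-3)
  expect_true(fit$singular)   # the zero variance component is flagged, not raised
})

test_that("the Laplace log-likelihood agrees with 50-node adaptive quadrature", {
  set.seed(31)
  d <- sim_binomial_clusters(12, 10, beta0 = 0.3, beta_x = 0.6, sigma_u = 0.8,
                             x_binary = FALSE)
  fit <- fit_glmm(model_spec(y ~ x + (1 | g), "binomial"), d)
  beta <- lme4::fixef(fit$model)
  sigma <- attr(lme4::VarCorr(fit$model)$g, "stddev")[["(Intercept)"]]
  ll_oracle <- agq_binomial_loglik(d$y, model.matrix(fit$model), d$g, beta, sigma)
  expect_lt(abs(fit$loglik - ll_oracle), 0.05)
})

test_that("model specs enforce slope-in-fixed and family/response contracts", {
  expect_error(model_spec(y ~ x + (1 + z | g), "binomial"), "random slope")
  d <- data.frame(y = c(-1, 2, 3), x = 1:3, g = factor(c(1, 1, 2)))
  expect_error(fit_glmm(model_spec(y ~ x + (1 | g), "gamma"), d), "positive")
})

test_that("95% Wald intervals cover a nonzero condition effect in at least 90% of refits", {
  set.seed(32)
  beta_true <- 0.8
  covered <- logical(150)
  for (r in seq_along(covered)) {
    d <- sim_binomial_clusters(40, 20, beta0 = 0.2, beta_x = beta_true, sigma_u = 0.5)
    fit <- fit_glmm(model_spec(y ~ x + (1 | g), "binomial"), d)
    ci <- fit$coefficients[fit$coefficients$term == "x", c("ci_lo", "ci_hi")]
    covered[r] <- ci$ci_lo <= beta_true && beta_true <= ci$ci_hi
  }
  expect_gte(mean(covered), 0.90)
})

test_that("AIC backward selection drops pure-noise terms and keeps strong ones", {
  set.seed(33)
  drops <- keeps <- logical(20)
  for (r in seq_along(drops)) {
    d <- sim_binomial_clusters(30, 20, beta0 = 0.1, beta_x = 1.2, sigma_u = 0.4)
    d$noise <- rnorm(nrow(d))
    sel <- backward_select_aic(model_spec(y ~ x + noise + (1 | g), "binomial"), d)
    kept <- attr(terms(lme4::nobars(sel$fit$spec$formula)), "term.labels")
    drops[r] <- !("noise" %in% kept)
    keeps[r] <- "x" %in% kept
  }
  expect_gt(mean(drops), 0.5)    # noise removed in the majority of replicates
  expect_gte(mean(keeps), 0.95)  # strong effect virtually always retained
})

test_that("selection never worsens AIC and random slopes are removable", {
  set.seed(34)
  d <- sim_binomial_clusters(25, 30, beta0 = 0, beta_x = 0.8, sigma_u = 0.5)
  full <- model_spec(y ~ x + (1 + x | g), "binomial")
  full_fit <- fit_glmm(full, d)
  sel <- backward_select_aic(full, d)
  if (full_fit$converged) expect_lte(sel$fit$aic, full_fit$aic + 1e-9)
  expect_true(all(c("step", "removed", "aic", "action") %in% names(sel$trace)))
  expect_gt(sum(sel$trace$action == "candidate"), 0)
})

test_that("the interaction LRT matches its definition and degenerates correctly", {
  set.seed(35)
  d <- sim_binomial_clusters(30, 24, beta0 = 0, beta_x = 0.6, sigma_u = 0.4)
  d$z <- rbinom(nrow(d), 1, 0.5)
  d$y <- rbinom(nrow(d), 1, plogis(0.6 * d$x + 0.3 * d$z + 1.0 * d$x * d$z))
  base <- fit_glmm(model_spec(y ~ x + z + (1 | g), "binomial"), d)
  # empty candidate set: chi-square 0, p = 1
  none <- add_interactions_lrt(base, character(0), d)
  expect_equal(none$chisq, 0)
  expect_equal(none$p, 1)
  res <- add_interactions_lrt(base, "x:z", d)
  expect_equal(res$chisq, 2 * (res$fit$loglik - base$loglik), tolerance = 1e-12)
  expect_equal(res$df, 1L)
  expect_error(add_interactions_lrt(base, "x:unknown", d), "non-nested")
})

test_that("a simulated interaction is detected with high power at this effect size", {
  set.seed(36)
  hits <- logical(25)
  for (r in seq_along(hits)) {
    d <- sim_binomial_clusters(40, 20, beta0 = 0, beta_x = 0.5, sigma_u = 0.4)
    d$z <- rbinom(nrow(d), 1, 0.5)
    u <- rnorm(40, 0, 0.4)
    d$y <- rbinom(nrow(d), 1, plogis(0.5 * d$x + 0.2 * d$z + 1.0 * d$x * d$z +
                                       u[as.integer(d$g)]))
    base <- fit_glmm(model_spec(y ~ x + z + (1 | g), "binomial"), d)
    hits[r] <- add_interactions_lrt(base, "x:z", d)$p < 0.05
  }
  expect_gte(mean(hits), 0.80)
})

test_that("standardized coefficients are scale-invariant and equal beta * SD(x) for one covariate", {
  set.seed(37)
  n <- 20
  d <- data.frame(x = rnorm(n, 5, 2), g = factor(rep(1:4, 5)))
  d$y <- rgamma(n, shape = 8, rate = 8 / exp(0.1 + 0.12 * d$x))
  fit <- fit_glmm(model_spec(y ~ x, "gamma"), d)
  std <- standardized_coefficients(fit, d)
  # closed form under predictors-only standardization
  expect_equal(std$std_coefficient[std$term == "x"],
               fit$coefficients$estimate[fit$coefficients$term == "x"] * sd(d$x),
               tolerance = 1e-6)
  d10 <- d; d10$x <- d10$x * 10
  fit10 <- fit_glmm(model_spec(y ~ x, "gamma"), d10)
  std10 <- standardized_coefficients(fit10, d10)
  expect_equal(std10$std_coefficient, std$std_coefficient, tolerance = 1e-6)
  # binary dummies are left unscaled
  d$b <- rep(c(0, 1), 10)
  fitb <- fit_glmm(model_spec(y ~ x + b, "gamma"), d)
  stdb <- standardized_coefficients(fitb, d)
  expect_equal(stdb$std_coefficient[stdb$term == "b"],
               fitb$coefficients$estimate[fitb$coefficients$term == "b"],
               tolerance = 1e-6)
})

test_that("Nakagawa R-squared obeys its bounds and recovers known variance shares", {
  set.seed(38)
  d <- sim_binomial_clusters(60, 30, beta0 = 0, beta_x = 1, sigma_u = 0.8)
  fit <- fit_glmm(model_spec(y ~ x + (1 | g), "binomial"), d)
  r2 <- r2_nakagawa(fit)
  expect_gte(r2[["conditional"]], r2[["marginal"]])
  expect_gte(r2[["marginal"]], 0)
  # plug-in truth: var_f = beta^2 * var(x) with x ~ Bernoulli(0.5), var_u = 0.64
  vf <- 1^2 * 0.25; vu <- 0.64; vd <- pi^2 / 3
  expect_lt(abs(r2[["marginal"]] - vf / (vf + vu + vd)), 0.02)
  expect_lt(abs(r2[["conditional"]] - (vf + vu) / (vf + vu + vd)), 0.06)
  # intercept-only fixed structure explains nothing marginally
  fit0 <- fit_glmm(model_spec(y ~ 1 + (1 | g), "binomial"), d)
  expect_equal(unname(r2_nakagawa(fit0)[["marginal"]]), 0, tolerance = 1e-10)
})

test_that("the dispersion ratio is near 1 under the model and rises under contamination", {
  set.seed(39)
  d <- sim_binomial_clusters(30, 40, beta0 = 0.2, beta_x = 0.5, sigma_u = 0.4)
  # aggregate to binomial counts per group x covariate level so the Pearson
  # statistic is informative about overdispersion
  agg <- aggregate(y ~ g + x, d, function(v) c(k = sum(v), n = length(v)))
  agg <- data.frame(g = agg$g, x = agg$x, k = agg$y[, "k"], n = agg$y[, "n"])
  fit <- fit_glmm(model_spec(cbind(k, n - k) ~ x + (1 | g), "binomial"), agg)
  chk <- overdispersion_check(fit)
  expect_equal(chk$dispersion_ratio,
               sum(residuals(fit$model, type = "pearson")^2) / df.residual(fit$model),
               tolerance = 1e-12)
  expect_lt(abs(chk$dispersion_ratio - 1), 0.45)
  expect_false(chk$overdispersed)
  # beta-binomial contamination inflates the ratio
  agg$k2 <- rbinom(nrow(agg), agg$n, rbeta(nrow(agg), 2, 2))
  fit2 <- fit_glmm(model_spec(cbind(k2, n - k2) ~ x + (1 | g), "binomial"), agg)
  expect_gt(overdispersion_check(fit2)$dispersion_ratio, 1.5)
})
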