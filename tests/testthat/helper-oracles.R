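# Independent numerical oracles used by the GLMM tests.

# Gauss-Hermite nodes/weights by Golub-Welsch (eigen-decomposition of the
# Jacobi matrix); independent of any quadrature code in the fitting path.
gh_nodes <- function(n) {
  i <- seq_len(n - 1)
  b <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = (e$vectors[1, ])^2 * sqrt(pi))
}

# Marginal log-likelihood of a single-random-intercept binomial-logit GLMM,
# by adaptive Gauss-Hermite quadrature centered on each group's mode.
agq_binomial_loglik <- function(y, X, group, beta, sigma, nq = 50) {
  nodes <- gh_nodes(nq)
  eta0 <- as.numeric(X %*% beta)
  ll <- 0
  for (g in unique(group)) {
    idx <- group == g
    f <- function(u)
      sum(stats::dbinom(y[idx], 1, stats::plogis(eta0[idx] + u), log = TRUE)) +
        stats::dnorm(u, 0, sigma, log = TRUE)
    m <- stats::optimize(function(u) -f(u), c(-15, 15))$minimum
    d2 <- (f(m + 1e-4) - 2 * f(m) + f(m - 1e-4)) / 1e-8
    h <- sqrt(-1 / d2)
    u <- m + sqrt(2) * h * nodes$x
    integrand <- vapply(u, f, numeric(1))
    ll <- ll + f(m) +
      log(sqrt(2) * h * sum(nodes$w * exp(nodes$x^2 + integrand - f(m))))
  }
  ll
}

# simulate a simple clustered binomial dataset
sim_binomial_clusters <- function(n_groups, n_per, beta0, beta_x, sigma_u,
                                  x_binary = TRUE) {
  g <- factor(rep(seq_len(n_groups), each = n_per))
  u <- stats::rnorm(n_groups, 0, sigma_u)
  x <- if (x_binary) stats::rbinom(n_groups * n_per, 1, 0.5)
       else stats::rnorm(n_groups * n_per)
  y <- stats::rbinom(n_groups * n_per, 1, stats::plogis(beta0 + beta_x * x + u[as.integer(g)]))
  data.frame(y = y, x = x, g = g)
}
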