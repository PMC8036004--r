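# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; no stored data files.

# ELBO trace non-decreasing up to a relative tolerance
expect_monotone_trace <- function(trace, rel_tol = 1e-8) {
  if (length(trace) < 2) return(invisible(TRUE))
  prev <- trace[-length(trace)]
  expect_true(all(diff(trace) >= -rel_tol * abs(prev)),
              label = paste0("ELBO trace monotone (min step ",
                             signif(min(diff(trace)), 3), ")"))
}

# Brute-force single-feature oracle: point-mass hyper-parameters tau, gamma,
# pi0. Enumerates s in {0, 1}, integrating b analytically, and returns the
# exact posterior inclusion probability, slab moments and log evidence.
enum_p1 <- function(y, x, tau, gamma, pi0) {
  n <- length(y)
  A <- tau * sum(x^2) + gamma
  sigma2 <- 1 / A
  mu <- sigma2 * tau * sum(x * y)
  log_m0 <- -n / 2 * log(2 * pi) + n / 2 * log(tau) - tau / 2 * sum(y^2)
  log_m1 <- log_m0 + 0.5 * log(gamma * sigma2) + mu^2 / (2 * sigma2)
  log_ev <- log(pi0 * exp(log_m1) + (1 - pi0) * exp(log_m0))
  list(psi = plogis(qlogis(pi0) + log_m1 - log_m0),
       mu = mu, sigma2 = sigma2, log_evidence = log_ev)
}

# Small gaussian dataset + two-group partition used across tests
toy_gaussian <- function(n = 40, p = 10, seed = 7, informative = TRUE) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  beta <- if (informative) c(rep(2, p %/% 2), rep(0, p - p %/% 2)) else rep(0, p)
  y <- as.numeric(X %*% beta) + rnorm(n, sd = 0.5)
  list(data = gs_dataset(X, y),
       partition = build_partition(rep(c("a", "b"), length.out = p)),
       beta = beta)
}

# Minimal variational state for direct calls into the update functions
toy_state <- function(p, G, mu = numeric(p), sigma2 = rep(1, p),
                      psi = rep(0.5, p), fixed = list(),
                      variant = "sparse") {
  list(mu = mu, sigma2 = sigma2, psi = psi,
       gamma_shape = rep(1, G), gamma_rate = rep(1, G),
       pi_a = rep(1, G), pi_b = rep(1, G),
       tau_shape = 1, tau_rate = 1,
       spike_var = rep(1, G), fixed = fixed,
       family = "gaussian", variant = variant,
       elbo_trace = numeric(0), converged = FALSE)
}

# Closed-form ridge solution (independent oracle for dense fits)
ridge_oracle <- function(X, y, lambda) {
  solve(crossprod(X) + diag(lambda, ncol(X)), crossprod(X, y))
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)
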