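# Dense-model engine keeping one joint multivariate Gaussian factor q(beta)
# over all coefficients, so posterior correlations between features survive
# the approximation. Gaussian likelihood only; the spike-and-slab machinery
# is replaced by beta = b, s = 1, pi = 1.

# S = (E[tau] X'X + D)^-1, m = E[tau] S X'y, with D = diag(E[gamma_{g(j)}]).
# For p > n the Woodbury identity
#   S = D^-1 - D^-1 X' (E[tau]^-1 I + X D^-1 X')^-1 X D^-1
# keeps the cost quadratic in max(n, p) and cubic in min(n, p).
update_beta_joint <- function(state, data, partition) {
  X <- data$X; y <- data$y
  Et <- e_tau(state)
  d <- e_gamma(state)[partition$assignment]
  p <- data$p; n <- data$n
  if (p <= n) {
    prec <- Et * crossprod(X) + diag(d, p)
    S <- chol2inv(chol_with_jitter(prec))
  } else {
    dinv <- 1 / d
    Xdi <- sweep(X, 2, dinv, "*")          # X D^-1  (n x p)
    M <- diag(1 / Et, n) + tcrossprod(Xdi, X)   # E[tau]^-1 I + X D^-1 X'
    R <- chol_with_jitter(M)
    W <- backsolve(R, forwardsolve(t(R), Xdi))  # M^-1 X D^-1
    S <- diag(dinv, p) - crossprod(Xdi, W)
  }
  S <- (S + t(S)) / 2
  m <- Et * as.numeric(S %*% crossprod(X, y))
  list(mean = m, cov = S)
}

chol_with_jitter <- function(A) {
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) {
    jitter <- 1e-8 * mean(diag(A))
    R <- tryCatch(chol(A + diag(jitter, nrow(A))), error = function(e) NULL)
    if (is.null(R)) {
      stop("covariance update is numerically non-positive-definite even after jitter.")
    }
  }
  R
}

update_gamma_joint <- function(state, partition, prior) {
  Eb2 <- state$m^2 + diag(state$S)
  list(shape = prior$r_gamma + partition$group_sizes / 2,
       rate = prior$d_gamma +
         0.5 * as.numeric(rowsum(Eb2, partition$assignment, reorder = TRUE)))
}

update_tau_joint <- function(state, data, prior) {
  r <- data$y - as.numeric(data$X %*% state$m)
  trXXS <- sum(crossprod(data$X) * state$S)
  list(shape = prior$r_tau + data$n / 2,
       rate = prior$d_tau + 0.5 * (sum(r^2) + trXXS))
}

compute_elbo_joint <- function(state, data, partition, prior) {
  k <- partition$assignment
  Et <- e_tau(state); Elt <- e_log_tau(state)
  Eg <- e_gamma(state); Elg <- e_log_gamma(state)
  m <- state$m; S <- state$S
  p <- data$p; n <- data$n

  r <- data$y - as.numeric(data$X %*% m)
  erss <- sum(r^2) + sum(crossprod(data$X) * S)
  lik <- 0.5 * n * (Elt - log(2 * pi)) - 0.5 * Et * erss

  Eb2 <- m^2 + diag(S)
  t_b <- sum(0.5 * Elg[k] - 0.5 * log(2 * pi) - 0.5 * Eg[k] * Eb2)

  R <- chol_with_jitter(S)
  h_beta <- 0.5 * p * log(2 * pi * exp(1)) + sum(log(diag(R)))

  t_hyper <- 0
  if (is.null(state$fixed$gamma)) {
    t_hyper <- t_hyper +
      sum(prior$r_gamma * log(prior$d_gamma) - lgamma(prior$r_gamma) +
            (prior$r_gamma - 1) * Elg - prior$d_gamma * Eg) +
      sum(gamma_entropy(state$gamma_shape, state$gamma_rate))
  }
  if (is.null(state$fixed$tau)) {
    t_hyper <- t_hyper +
      prior$r_tau * log(prior$d_tau) - lgamma(prior$r_tau) +
      (prior$r_tau - 1) * Elt - prior$d_tau * Et +
      gamma_entropy(state$tau_shape, state$tau_rate)
  }
  elbo <- lik + t_b + h_beta + t_hyper
  if (!is.finite(elbo)) stop("non-finite ELBO in the joint dense engine.")
  elbo
}

#' Fit the dense model with a joint multivariate coefficient posterior
#'
#' Group-adaptive ridge regression where the variational family keeps a full
#' multivariate Gaussian over all coefficients (factorized only against the
#' slab-precision and noise factors). Captures posterior correlations
#' between features that the fully factorized family discards, which can
#' improve prediction under correlated designs, at quadratic cost in
#' `max(n, p)` and cubic cost in `min(n, p)`.
#'
#' @inheritParams fit_linear
#' @return A `gs_fit` with `inclusion_prob` identically 1 and `pi_hat`
#'   identically 1.
#' @export
#' @examples
#' sim <- simulate_data(default_scenario(nu = 1, n = 60, p = 30, seed = 3))
#' fit <- fit_linear_joint(sim$dataset, sim$partition)
fit_linear_joint <- function(data, partition, prior = prior_config(),
                             options = fit_options(variant = "dense")) {
  stopifnot(inherits(data, "gs_dataset"))
  if (data$family != "gaussian") {
    stop("the joint dense engine supports only the gaussian family.")
  }
  validate_inputs(data, partition)
  prep <- preprocess_gaussian(data, options)
  wdata <- prep$data
  G <- partition$G

  vy <- var(wdata$y); if (!is.finite(vy) || vy <= 0) vy <- 1
  state <- list(
    m = numeric(data$p), S = diag(1, data$p),
    gamma_shape = prior$r_gamma + partition$group_sizes / 2,
    gamma_rate = prior$r_gamma + partition$group_sizes / 2,
    tau_shape = prior$r_tau + data$n / 2,
    tau_rate = (prior$r_tau + data$n / 2) * vy,
    fixed = list(tau = options$fixed_tau,
                 gamma = if (!is.null(options$fixed_gamma))
                   rep_G(options$fixed_gamma, G)),
    family = "gaussian", variant = "dense-joint",
    elbo_trace = numeric(0), converged = FALSE
  )

  elbo_prev <- -Inf
  for (iter in seq_len(options$max_iter)) {
    bu <- update_beta_joint(state, wdata, partition)
    state$m <- bu$mean; state$S <- bu$cov
    if (is.null(state$fixed$gamma)) {
      g <- update_gamma_joint(state, partition, prior)
      state$gamma_shape <- g$shape; state$gamma_rate <- g$rate
    }
    if (is.null(state$fixed$tau)) {
      tt <- update_tau_joint(state, wdata, prior)
      state$tau_shape <- tt$shape; state$tau_rate <- tt$rate
    }
    elbo <- compute_elbo_joint(state, wdata, partition, prior)
    state$elbo_trace <- c(state$elbo_trace, elbo)
    if (is.finite(elbo_prev) &&
        abs(elbo - elbo_prev) <= options$elbo_rel_tol * abs(elbo_prev)) {
      state$converged <- TRUE
      break
    }
    elbo_prev <- elbo
  }

  # adapt the joint state to the common summary shape
  sstate <- list(
    mu = state$m, sigma2 = diag(state$S), psi = rep(1, data$p),
    gamma_shape = state$gamma_shape, gamma_rate = state$gamma_rate,
    pi_a = rep(1, G), pi_b = rep(1, G),
    tau_shape = state$tau_shape, tau_rate = state$tau_rate,
    fixed = list(tau = state$fixed$tau, gamma = state$fixed$gamma,
                 pi = rep(1, G)),
    family = "gaussian", variant = "dense-joint",
    elbo_trace = state$elbo_trace, converged = state$converged
  )
  fit <- finalize_fit(sstate, partition, prep, data, options)
  fit$cov <- state$S
  fit$variant <- "dense-joint"
  fit
}
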