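# Binary-response engine: Bernoulli likelihood with logistic link, handled
# through the Jaakkola-Jordan quadratic lower bound on the logistic
# function with one variational tightness parameter xi_i per sample. The
# bound restores a quadratic form in the coefficients, so all spike-and-slab
# updates carry over from the linear engine with bound-weighted curvature in
# place of E[tau] ||X_j||^2.

#' Jaakkola-Jordan curvature function
#'
#' `eta(xi) = (sigma(xi) - 1/2) / (2 xi)`, the curvature weight of the
#' quadratic lower bound on the logistic function. Even in `xi`; the
#' removable singularity at 0 is evaluated by its series expansion
#' (`eta(0) = 1/8`).
#'
#' @param xi Numeric vector.
#' @return `eta(xi)`, same length as `xi`.
#' @export
#' @examples
#' jj_eta(0)      # 1/8
#' jj_eta(1)      # (sigma(1) - 0.5) / 2
jj_eta <- function(xi) {
  xi <- abs(xi)
  out <- numeric(length(xi))
  small <- xi < 1e-4
  # series: eta(x) = 1/8 - x^2/96 + O(x^4)
  out[small] <- 1 / 8 - xi[small]^2 / 96
  xl <- xi[!small]
  out[!small] <- (plogis(xl) - 0.5) / (2 * xl)
  out
}

#' Jaakkola-Jordan lower bound on the logistic function
#'
#' `sigma(xi) * exp((z - xi)/2 - eta(xi) (z^2 - xi^2))`, which is `<=
#' sigma(z)` for every real `z`, with equality when `|z| = |xi|`.
#'
#' @param z Numeric vector of linear-predictor values.
#' @param xi Numeric vector (recycled) of tightness parameters.
#' @return The bound values.
#' @export
#' @examples
#' jj_bound(1.3, 1.3) - plogis(1.3)   # 0: tight at z == xi
jj_bound <- function(z, xi) {
  plogis(xi) * exp(0.5 * (z - xi) - jj_eta(xi) * (z^2 - xi^2))
}

# xi_i = sqrt(E[(x_i' beta + beta_0)^2]) -- the optimal tightness value for
# the current coefficient moments.
update_xi <- function(state, data) {
  Ebeta <- state$psi * state$mu
  varbeta <- state$psi * (state$mu^2 + state$sigma2) - Ebeta^2
  zbar <- state$intercept_mean + as.numeric(data$X %*% Ebeta)
  ez2 <- zbar^2 + state$intercept_var +
    as.numeric(data$X^2 %*% varbeta)
  sqrt(pmax(ez2, 0))
}

# Bound objective: E_q of the quadratic lower bound on log p(y|beta) plus
# all prior and entropy terms shared with the linear engine (no tau factor;
# flat improper prior on the intercept contributes only its entropy).
compute_bound_elbo <- function(state, data, partition, prior) {
  k <- partition$assignment
  Eg <- e_gamma(state); Elg <- e_log_gamma(state)
  Elp <- e_log_pi(state); El1p <- e_log_1mpi(state)
  psi <- state$psi
  v <- state$spike_var[k]
  xi <- state$xi
  eta <- jj_eta(xi)

  Ebeta <- psi * state$mu
  varbeta <- psi * (state$mu^2 + state$sigma2) - Ebeta^2
  zbar <- state$intercept_mean + as.numeric(data$X %*% Ebeta)
  ez2 <- zbar^2 + state$intercept_var + as.numeric(data$X^2 %*% varbeta)

  lik <- sum(0.5 * (2 * data$y - 1) * zbar - eta * ez2 +
               log(plogis(xi)) - 0.5 * xi + eta * xi^2)

  Eb2 <- e_b2(state, partition)
  t_b <- sum(0.5 * Elg[k] - 0.5 * log(2 * pi) - 0.5 * Eg[k] * Eb2)
  t_s <- sum(wmult(psi, Elp[k]) + wmult(1 - psi, El1p[k]))
  h_bs <- sum(wmult(psi, 0.5 * log(2 * pi * exp(1) * state$sigma2)) +
                wmult(1 - psi, 0.5 * log(2 * pi * exp(1) * v)) +
                binary_entropy(psi))
  h_int <- if (state$intercept_var > 0) {
    0.5 * log(2 * pi * exp(1) * state$intercept_var)
  } else 0

  t_hyper <- 0
  if (is.null(state$fixed$gamma)) {
    t_hyper <- t_hyper +
      sum(prior$r_gamma * log(prior$d_gamma) - lgamma(prior$r_gamma) +
            (prior$r_gamma - 1) * Elg - prior$d_gamma * Eg) +
      sum(gamma_entropy(state$gamma_shape, state$gamma_rate))
  }
  if (is.null(state$fixed$pi)) {
    t_hyper <- t_hyper +
      sum((prior$d_pi - 1) * Elp + (prior$r_pi - 1) * El1p -
            lbeta(prior$d_pi, prior$r_pi)) +
      sum(beta_entropy(state$pi_a, state$pi_b))
  }
  elbo <- lik + t_b + t_s + h_bs + h_int + t_hyper
  if (!is.finite(elbo)) stop("non-finite bound objective in the logistic engine.")
  elbo
}

#' Fit the group-adaptive spike-and-slab logistic model
#'
#' Variational inference for a binary response through the Jaakkola-Jordan
#' quadratic bound. Per sweep: the (flat-prior) intercept and every
#' coefficient factor are updated with bound-weighted curvature
#' `h_j = 2 sum_i eta(xi_i) x_ij^2`, then the group slab precisions and
#' mixing proportions, then the per-sample tightness parameters `xi_i`.
#' The monitored objective is the bound-ELBO (a lower bound on the ELBO),
#' which is non-decreasing across sweeps.
#'
#' @inheritParams fit_linear
#' @param data A [gs_dataset()] with `family = "bernoulli"`. A response
#'   that is all zeros or all ones is rejected.
#' @return A `gs_fit`; `tau_hat` is `NA` (no noise precision in the
#'   Bernoulli model).
#' @export
#' @examples
#' sim <- simulate_data(default_scenario(nu = 0.2, n = 120, p = 60, seed = 2,
#'                                       family = "bernoulli"))
#' fit <- fit_logistic(sim$dataset, sim$partition)
fit_logistic <- function(data, partition, prior = prior_config(),
                         options = fit_options()) {
  stopifnot(inherits(data, "gs_dataset"))
  if (data$family != "bernoulli") {
    stop("fit_logistic requires a bernoulli-family dataset.")
  }
  if (all(data$y == 1) || all(data$y == 0)) {
    stop("response is constant (all ", data$y[1], "): no signal to fit and ",
         "complete separation is guaranteed.")
  }
  validate_inputs(data, partition)
  if (options$variant == "dense") {
    options$fixed_pi <- options$fixed_pi %||% 1
  }

  X <- data$X
  sdx <- rep(1, data$p)
  if (options$standardize) {
    sdx <- apply(X, 2, sd)
    X <- sweep(X, 2, sdx, "/")
  }
  X2 <- X^2
  y <- data$y
  n <- data$n; p <- data$p
  k_of <- partition$assignment
  G <- partition$G
  dense <- options$variant == "dense"

  state <- init_state_linear(
    structure(list(X = X, y = y, n = n, p = p, family = "bernoulli"),
              class = "gs_dataset"),
    partition, prior, options)
  state$family <- "bernoulli"
  state$tau_shape <- NULL; state$tau_rate <- NULL
  state$xi <- rep(1, n)
  state$intercept_mean <- 0
  state$intercept_var <- if (options$intercept) 1 else 0
  wdata <- structure(list(X = X, y = y, n = n, p = p, family = "bernoulli"),
                     class = "gs_dataset")

  yc <- y - 0.5
  elbo_prev <- -Inf
  for (iter in seq_len(options$max_iter)) {
    eta <- jj_eta(state$xi)
    Eg <- e_gamma(state)
    Elogitpi <- e_logit_pi(state)
    state$spike_var <- 1 / Eg

    beta_bar <- state$psi * state$mu
    zbar <- state$intercept_mean + as.numeric(X %*% beta_bar)

    if (options$intercept) {
      h0 <- 2 * sum(eta)
      lin0 <- sum(yc) - 2 * sum(eta * (zbar - state$intercept_mean))
      m0 <- lin0 / h0
      zbar <- zbar + (m0 - state$intercept_mean)
      state$intercept_mean <- m0
      state$intercept_var <- 1 / h0
    }

    hj <- 2 * as.numeric(crossprod(X2, eta))
    for (j in seq_len(p)) {
      xj <- X[, j]
      b_old <- beta_bar[j]
      # linear term of the bound for feature j, excluding j's own contribution
      lin <- sum(yc * xj) - 2 * sum(eta * xj * (zbar - xj * b_old))
      terms <- coef_update_terms(hj[j], lin, Eg[k_of[j]], Elogitpi[k_of[j]])
      psi_j <- if (dense) 1 else plogis(terms$logit)
      state$mu[j] <- terms$mu
      state$sigma2[j] <- terms$sigma2
      state$psi[j] <- psi_j
      b_new <- psi_j * terms$mu
      beta_bar[j] <- b_new
      if (b_new != b_old) zbar <- zbar + xj * (b_new - b_old)
    }

    if (is.null(state$fixed$gamma)) {
      g <- update_gamma(state, partition, prior)
      state$gamma_shape <- g$shape; state$gamma_rate <- g$rate
    }
    if (!dense && is.null(state$fixed$pi)) {
      pp <- update_pi(state, partition, prior)
      state$pi_a <- pp$a; state$pi_b <- pp$b
    }
    state$xi <- update_xi(state, wdata)

    elbo <- compute_bound_elbo(state, wdata, partition, prior)
    state$elbo_trace <- c(state$elbo_trace, elbo)
    if (is.finite(elbo_prev) &&
        abs(elbo - elbo_prev) <= options$elbo_rel_tol * abs(elbo_prev)) {
      state$converged <- TRUE
      break
    }
    elbo_prev <- elbo
  }

  fit <- summarize_posterior(state, partition,
                             intercept = state$intercept_mean)
  fit$beta_hat <- fit$beta_hat / sdx
  names(fit$beta_hat) <- data$feature_ids
  names(fit$inclusion_prob) <- data$feature_ids
  fit$tau_hat <- NA_real_
  fit$options <- options
  fit$state <- state
  fit
}

#' Predict class probabilities from a logistic fit
#'
#' @param fit A `gs_fit` from [fit_logistic()].
#' @param X_new Matrix with the training feature columns.
#' @return Probabilities `sigma(intercept + X_new %*% beta_hat)` in (0, 1).
#' @export
predict_logistic <- function(fit, X_new) {
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(fit$beta_hat)) {
    stop("X_new has ", ncol(X_new), " columns but the fit has ",
         length(fit$beta_hat), " coefficients.")
  }
  plogis(as.numeric(fit$intercept + X_new %*% fit$beta_hat))
}
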