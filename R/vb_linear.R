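# Coordinate-ascent variational inference for the Gaussian-likelihood model
# with the factorized mean-field family: per-feature joint factors
# q(b_j, s_j), per-group Gamma factors for the slab precisions gamma_k,
# per-group Beta factors for the mixing proportions pi_k, and a Gamma factor
# for the noise precision tau.

#' Fitting options
#'
#' @param max_iter Maximum number of full update sweeps.
#' @param elbo_rel_tol Convergence threshold on the relative change of the
#'   evidence lower bound between sweeps.
#' @param variant `"sparse"` uses the spike-and-slab prior; `"dense"` fixes
#'   every inclusion probability at 1 (group-adaptive ridge).
#' @param intercept Include an (unpenalized) intercept. For the gaussian
#'   family this centers `y` and the columns of `X`; for the bernoulli
#'   family an explicit flat-prior coefficient is used.
#' @param standardize Scale the feature columns to unit standard deviation
#'   before fitting (coefficients are reported on the original scale).
#'   Off by default: whether scale differences between features are signal
#'   or nuisance is an analysis decision, so it is never applied implicitly.
#' @param seed Optional integer recorded with the fit (the optimization
#'   itself is deterministic).
#' @param fixed_tau,fixed_gamma,fixed_pi Optional point-mass values that
#'   replace the corresponding variational factor (then not updated); used
#'   mainly for validation against closed-form posteriors. `fixed_gamma`
#'   and `fixed_pi` may be scalars or length-G vectors.
#' @return An object of class `gs_options`.
#' @export
fit_options <- function(max_iter = 1000, elbo_rel_tol = 1e-5,
                        variant = c("sparse", "dense"),
                        intercept = TRUE, standardize = FALSE, seed = NULL,
                        fixed_tau = NULL, fixed_gamma = NULL,
                        fixed_pi = NULL) {
  variant <- match.arg(variant)
  stopifnot(max_iter >= 1, elbo_rel_tol > 0)
  structure(
    list(max_iter = as.integer(max_iter), elbo_rel_tol = elbo_rel_tol,
         variant = variant, intercept = isTRUE(intercept),
         standardize = isTRUE(standardize), seed = seed,
         fixed_tau = fixed_tau, fixed_gamma = fixed_gamma,
         fixed_pi = fixed_pi),
    class = "gs_options"
  )
}

# ---- expectation helpers (honor point-mass overrides) -----------------------

e_tau <- function(state) {
  if (!is.null(state$fixed$tau)) state$fixed$tau else state$tau_shape / state$tau_rate
}
e_log_tau <- function(state) {
  if (!is.null(state$fixed$tau)) log(state$fixed$tau)
  else digamma(state$tau_shape) - log(state$tau_rate)
}
e_gamma <- function(state) {
  if (!is.null(state$fixed$gamma)) state$fixed$gamma else state$gamma_shape / state$gamma_rate
}
e_log_gamma <- function(state) {
  if (!is.null(state$fixed$gamma)) log(state$fixed$gamma)
  else digamma(state$gamma_shape) - log(state$gamma_rate)
}
e_logit_pi <- function(state) {
  if (!is.null(state$fixed$pi)) qlogis(state$fixed$pi)
  else digamma(state$pi_a) - digamma(state$pi_b)
}
e_log_pi <- function(state) {
  if (!is.null(state$fixed$pi)) log(state$fixed$pi)
  else digamma(state$pi_a) - digamma(state$pi_a + state$pi_b)
}
e_log_1mpi <- function(state) {
  if (!is.null(state$fixed$pi)) log(1 - state$fixed$pi)
  else digamma(state$pi_b) - digamma(state$pi_a + state$pi_b)
}

rep_G <- function(x, G) if (length(x) == 1) rep(x, G) else x

# ---- single-coefficient update ---------------------------------------------

# Shared closed form for one q(b_j, s_j) update. `prec` is the likelihood
# curvature for feature j (E[tau]*||X_j||^2 for gaussian, 2*sum eta*x^2 for
# logistic), `lin` the likelihood linear term. The inclusion log-odds use
# log E[gamma_k] (spike factor N(0, 1/E[gamma_k])), which is the exact
# coordinate-ascent step for this family; see the methods vignette.
coef_update_terms <- function(prec, lin, Egamma_k, Elogitpi_k) {
  sigma2 <- 1 / (prec + Egamma_k)
  mu <- sigma2 * lin
  logit <- Elogitpi_k + 0.5 * log(Egamma_k) + 0.5 * log(sigma2) +
    mu^2 / (2 * sigma2)
  list(mu = mu, sigma2 = sigma2, logit = logit)
}

# Single-feature update against an explicit residual vector (the residual
# excludes feature j's current contribution on entry in the fit loop; here
# it is the full residual and j's contribution is added back first).
update_coefficient <- function(j, state, data, partition, residual) {
  k <- partition$assignment[j]
  xj <- data$X[, j]
  cn2 <- sum(xj^2)
  if (cn2 == 0) stop("feature ", j, " has zero norm; exclude it before fitting.")
  rj <- residual + xj * (state$psi[j] * state$mu[j])
  Et <- e_tau(state)
  terms <- coef_update_terms(Et * cn2, Et * sum(xj * rj),
                             e_gamma(state)[k], e_logit_pi(state)[k])
  psi <- if (state$variant == "dense") 1 else plogis(terms$logit)
  list(mu = terms$mu, sigma2 = terms$sigma2, psi = psi,
       residual = rj - xj * (psi * terms$mu))
}

# ---- block updates ----------------------------------------------------------

# E[b_j^2] under q: slab branch psi*(mu^2+sigma2); spike branch keeps the
# prior at the slab precision seen by the last coefficient sweep
# (spike_var_k = 1/E[gamma_k] at that point).
e_b2 <- function(state, partition) {
  v <- state$spike_var[partition$assignment]
  state$psi * (state$mu^2 + state$sigma2) + (1 - state$psi) * v
}

update_gamma <- function(state, partition, prior) {
  Eb2 <- e_b2(state, partition)
  shape <- prior$r_gamma + partition$group_sizes / 2
  rate <- prior$d_gamma +
    0.5 * as.numeric(rowsum(Eb2, partition$assignment, reorder = TRUE))
  list(shape = shape, rate = rate)
}

update_pi <- function(state, partition, prior) {
  spsi <- as.numeric(rowsum(state$psi, partition$assignment, reorder = TRUE))
  list(a = prior$d_pi + spsi, b = prior$r_pi + partition$group_sizes - spsi)
}

# E||y - X beta||^2 under q (factorized coefficients)
expected_rss <- function(state, data) {
  Ebeta <- state$psi * state$mu
  Ebeta2 <- state$psi * (state$mu^2 + state$sigma2)
  cn2 <- colSums(data$X^2)
  sum((data$y - as.numeric(data$X %*% Ebeta))^2) +
    sum(cn2 * (Ebeta2 - Ebeta^2))
}

update_tau <- function(state, data, partition, prior) {
  list(shape = prior$r_tau + data$n / 2,
       rate = prior$d_tau + 0.5 * expected_rss(state, data))
}

# ---- ELBO -------------------------------------------------------------------

clip01 <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

# w * x with the 0 * log 0 := 0 convention (x may be -Inf when w == 0)
wmult <- function(w, x) ifelse(w == 0, 0, w * x)

binary_entropy <- function(p) {
  p <- clip01(p)
  -(p * log(p) + (1 - p) * log(1 - p))
}

gamma_entropy <- function(shape, rate) {
  shape - log(rate) + lgamma(shape) + (1 - shape) * digamma(shape)
}

beta_entropy <- function(a, b) {
  lbeta(a, b) - (a - 1) * digamma(a) - (b - 1) * digamma(b) +
    (a + b - 2) * digamma(a + b)
}

#' Evidence lower bound of a variational state
#'
#' Computes the ELBO `E_q[log p(y, theta)] + H(q)` in closed form for the
#' Gaussian-likelihood model, on the data exactly as used by the update
#' sweeps (i.e. already centered/scaled when the fit used an intercept or
#' standardization). Point-mass (fixed) hyper-parameters contribute neither
#' prior nor entropy terms.
#'
#' @param state A variational state (as stored in `gs_fit$state` or built by
#'   the internal engines).
#' @param data The [gs_dataset()] seen by the updates.
#' @param partition The feature partition.
#' @param prior The [prior_config()].
#' @return A finite scalar; non-finite intermediates raise an error.
#' @export
compute_elbo <- function(state, data, partition, prior) {
  k <- partition$assignment
  Et <- e_tau(state); Elt <- e_log_tau(state)
  Eg <- e_gamma(state); Elg <- e_log_gamma(state)
  Elp <- e_log_pi(state); El1p <- e_log_1mpi(state)
  psi <- state$psi
  v <- state$spike_var[k]

  lik <- 0.5 * data$n * (Elt - log(2 * pi)) -
    0.5 * Et * expected_rss(state, data)

  Eb2 <- e_b2(state, partition)
  t_b <- sum(0.5 * Elg[k] - 0.5 * log(2 * pi) - 0.5 * Eg[k] * Eb2)
  t_s <- sum(wmult(psi, Elp[k]) + wmult(1 - psi, El1p[k]))

  h_bs <- sum(wmult(psi, 0.5 * log(2 * pi * exp(1) * state$sigma2)) +
                wmult(1 - psi, 0.5 * log(2 * pi * exp(1) * v)) +
                binary_entropy(psi))

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
  if (is.null(state$fixed$tau)) {
    t_hyper <- t_hyper +
      prior$r_tau * log(prior$d_tau) - lgamma(prior$r_tau) +
      (prior$r_tau - 1) * Elt - prior$d_tau * Et +
      gamma_entropy(state$tau_shape, state$tau_rate)
  }

  elbo <- lik + t_b + t_s + h_bs + t_hyper
  if (!is.finite(elbo)) {
    stop("non-finite ELBO: a numerical fault occurred during inference.")
  }
  elbo
}

# ---- initialization ---------------------------------------------------------

init_state_linear <- function(data, partition, prior, options) {
  p <- data$p; G <- partition$G
  fixed <- list(tau = options$fixed_tau,
                gamma = if (!is.null(options$fixed_gamma))
                  rep_G(options$fixed_gamma, G),
                pi = if (!is.null(options$fixed_pi))
                  rep_G(options$fixed_pi, G))
  if (options$variant == "dense" && is.null(fixed$pi)) fixed$pi <- rep(1, G)
  vy <- var(data$y)
  if (!is.finite(vy) || vy <= 0) vy <- 1
  state <- list(
    mu = numeric(p),
    sigma2 = rep(1, p),
    psi = if (options$variant == "dense") rep(1, p) else rep(0.5, p),
    gamma_shape = prior$r_gamma + partition$group_sizes / 2,
    gamma_rate = prior$r_gamma + partition$group_sizes / 2,  # E[gamma] = 1
    pi_a = rep(prior$d_pi, G), pi_b = rep(prior$r_pi, G),
    tau_shape = prior$r_tau + data$n / 2,
    tau_rate = (prior$r_tau + data$n / 2) * vy,               # E[tau] = 1/var(y)
    spike_var = rep(1, G),
    fixed = fixed,
    family = "gaussian",
    variant = options$variant,
    elbo_trace = numeric(0),
    converged = FALSE
  )
  state
}

# ---- main fitting routine ---------------------------------------------------

#' Fit the group-adaptive spike-and-slab linear model
#'
#' Coordinate-ascent variational inference for a Gaussian response. Each
#' sweep updates every coefficient factor in ascending index order, then the
#' group slab precisions, the group mixing proportions (sparse variant), the
#' noise precision, and finally records the ELBO. Iteration stops when the
#' relative ELBO change falls below `elbo_rel_tol` or `max_iter` is reached;
#' non-convergence is reported through the `converged` flag, not an error.
#'
#' @param data A [gs_dataset()] with `family = "gaussian"`.
#' @param partition A [gs_partition][build_partition()] over the features.
#' @param prior A [prior_config()].
#' @param options A [fit_options()].
#' @return A `gs_fit` with posterior means `beta_hat` (`psi * mu`),
#'   `inclusion_prob`, per-group `gamma_hat` and `pi_hat`, `tau_hat`,
#'   `intercept`, the ELBO trace and convergence diagnostics.
#' @seealso [predict_linear()], [fit_linear_joint()], [fit_logistic()]
#' @export
#' @examples
#' sim <- simulate_data(default_scenario(nu = 0.2, n = 80, p = 60, seed = 1))
#' fit <- fit_linear(sim$dataset, sim$partition)
#' fit$gamma_hat
fit_linear <- function(data, partition, prior = prior_config(),
                       options = fit_options()) {
  stopifnot(inherits(data, "gs_dataset"))
  if (data$family != "gaussian") {
    stop("fit_linear requires a gaussian-family dataset; use fit_logistic for bernoulli.")
  }
  validate_inputs(data, partition)

  prep <- preprocess_gaussian(data, options)
  wdata <- prep$data
  X <- wdata$X; y <- wdata$y
  cn2 <- colSums(X^2)
  p <- wdata$p

  state <- init_state_linear(wdata, partition, prior, options)
  k_of <- partition$assignment
  dense <- options$variant == "dense"

  elbo_prev <- -Inf
  for (iter in seq_len(options$max_iter)) {
    Et <- e_tau(state)
    Eg <- e_gamma(state)
    Elogitpi <- e_logit_pi(state)
    state$spike_var <- 1 / Eg

    beta_bar <- state$psi * state$mu
    residual <- y - as.numeric(X %*% beta_bar)
    for (j in seq_len(p)) {
      xj <- X[, j]
      b_old <- beta_bar[j]
      lin <- Et * (sum(xj * residual) + cn2[j] * b_old)
      terms <- coef_update_terms(Et * cn2[j], lin, Eg[k_of[j]],
                                 Elogitpi[k_of[j]])
      psi_j <- if (dense) 1 else plogis(terms$logit)
      state$mu[j] <- terms$mu
      state$sigma2[j] <- terms$sigma2
      state$psi[j] <- psi_j
      b_new <- psi_j * terms$mu
      beta_bar[j] <- b_new
      if (b_new != b_old) residual <- residual - xj * (b_new - b_old)
    }

    if (is.null(state$fixed$gamma)) {
      g <- update_gamma(state, partition, prior)
      state$gamma_shape <- g$shape; state$gamma_rate <- g$rate
    }
    if (!dense && is.null(state$fixed$pi)) {
      pp <- update_pi(state, partition, prior)
      state$pi_a <- pp$a; state$pi_b <- pp$b
    }
    if (is.null(state$fixed$tau)) {
      tt <- update_tau(state, wdata, partition, prior)
      state$tau_shape <- tt$shape; state$tau_rate <- tt$rate
    }

    elbo <- compute_elbo(state, wdata, partition, prior)
    state$elbo_trace <- c(state$elbo_trace, elbo)
    if (is.finite(elbo_prev) &&
        abs(elbo - elbo_prev) <= options$elbo_rel_tol * abs(elbo_prev)) {
      state$converged <- TRUE
      break
    }
    elbo_prev <- elbo
  }

  finalize_fit(state, partition, prep, data, options)
}

# Center/scale per the options; returns the working dataset plus the
# transforms needed to map coefficients back to the original scale.
preprocess_gaussian <- function(data, options) {
  X <- data$X; y <- data$y
  sdx <- rep(1, data$p)
  if (options$standardize) {
    sdx <- apply(X, 2, sd)
    if (any(sdx == 0)) stop("cannot standardize zero-variance columns.")
    X <- sweep(X, 2, sdx, "/")
  }
  xbar <- rep(0, data$p); ybar <- 0
  if (options$intercept) {
    xbar <- colMeans(X)
    ybar <- mean(y)
    X <- sweep(X, 2, xbar, "-")
    y <- y - ybar
  }
  wdata <- structure(
    list(X = X, y = y, sample_ids = data$sample_ids,
         feature_ids = data$feature_ids, family = data$family,
         n = data$n, p = data$p),
    class = "gs_dataset"
  )
  list(data = wdata, sdx = sdx, xbar = xbar, ybar = ybar)
}

finalize_fit <- function(state, partition, prep, data, options) {
  fit <- summarize_posterior(state, partition)
  # map back to the original feature scale
  beta_scaled <- fit$beta_hat
  fit$beta_hat <- beta_scaled / prep$sdx
  fit$intercept <- if (options$intercept) {
    prep$ybar - sum(prep$xbar * beta_scaled)
  } else 0
  names(fit$beta_hat) <- data$feature_ids
  names(fit$inclusion_prob) <- data$feature_ids
  fit$options <- options
  fit$state <- state
  fit
}

#' Predict from a linear fit
#'
#' @param fit A `gs_fit` from [fit_linear()] or [fit_linear_joint()].
#' @param X_new Matrix with the same feature columns as the training data.
#' @return `intercept + X_new %*% beta_hat` as a numeric vector.
#' @export
predict_linear <- function(fit, X_new) {
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(fit$beta_hat)) {
    stop("X_new has ", ncol(X_new), " columns but the fit has ",
         length(fit$beta_hat), " coefficients.")
  }
  as.numeric(fit$intercept + X_new %*% fit$beta_hat)
}
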