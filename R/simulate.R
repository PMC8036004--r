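# Synthetic-data generator: multivariate-normal designs with Toeplitz
# (AR(1)) correlation, spike-and-slab coefficients with group-specific slab
# precision and mixing proportion, Gaussian or Bernoulli responses, plus
# recovery/prediction metrics. This is the benchmark bed for every
# inference engine.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' Simulation configuration
#'
#' Describes one synthetic scenario: sample and feature counts, number of
#' equal-size feature groups, AR(1) design correlation `rho` (so the design
#' covariance is `Sigma_ij = rho^|i-j|`), noise precision `tau`, and the
#' true per-group slab precisions `gamma_true` and mixing proportions
#' `pi_true`.
#'
#' @param n,p Sample and feature counts; `p` must be divisible by `G`.
#' @param G Number of equal-size feature groups.
#' @param rho Toeplitz correlation in `[0, 1)`.
#' @param tau Noise precision (gaussian family).
#' @param gamma_true,pi_true Length-`G` truth vectors.
#' @param family Response family.
#' @param seed Integer seed; all draws are deterministic given it.
#' @return An object of class `gs_sim_config`.
#' @export
simulation_config <- function(n, p, G, rho = 0, tau = 10,
                              gamma_true, pi_true,
                              family = c("gaussian", "bernoulli"),
                              seed = 1) {
  family <- match.arg(family)
  stopifnot(n >= 1, p >= 1, G >= 1, p %% G == 0,
            rho >= 0, rho < 1, tau > 0,
            length(gamma_true) == G, all(gamma_true > 0),
            length(pi_true) == G, all(pi_true >= 0), all(pi_true <= 1))
  structure(
    list(n = as.integer(n), p = as.integer(p), G = as.integer(G), rho = rho,
         tau = tau, gamma_true = gamma_true, pi_true = pi_true,
         family = family, seed = as.integer(seed)),
    class = "gs_sim_config"
  )
}

#' Benchmark scenario with six groups at three effect-size levels
#'
#' The standard evaluation design: `G = 6` equal groups with slab precisions
#' `(0.01, 0.01, 1, 1, 100, 100)` (high-, medium- and low-amplitude pairs)
#' and, for each pair sharing a precision level, mixing proportions
#' `nu` (odd group of the pair) and `min(1, 1.5 nu)` (even group). Defaults
#' `n = 100`, `p = 300`; `rho = 0`, `tau = 10` and `nu = 0.2` are this
#' package's defaults for the remaining free knobs.
#'
#' @param nu Sparsity level in `(0, 1]`.
#' @param ... Overrides passed to [simulation_config()] (`n`, `p`, `rho`,
#'   `tau`, `family`, `seed`).
#' @return A `gs_sim_config`.
#' @export
#' @examples
#' default_scenario(nu = 0.2)$pi_true   # 0.2 0.3 0.2 0.3 0.2 0.3
default_scenario <- function(nu = 0.2, ...) {
  if (!is.numeric(nu) || length(nu) != 1 || nu <= 0 || nu > 1) {
    stop("nu must be a single value in (0, 1].")
  }
  args <- list(n = 100, p = 300, G = 6L, rho = 0, tau = 10,
               gamma_true = c(0.01, 0.01, 1, 1, 100, 100),
               pi_true = rep(c(nu, min(1, 1.5 * nu)), 3),
               seed = 1)
  do.call(simulation_config, modifyList(args, list(...)))
}

#' Draw a Toeplitz-correlated Gaussian design matrix
#'
#' Rows are i.i.d. mean-zero multivariate normal with covariance
#' `Sigma_ij = rho^|i-j|`, generated by the AR(1) recursion
#' `x_j = rho x_{j-1} + sqrt(1 - rho^2) e_j`, which is exact for this
#' covariance and costs O(np).
#'
#' @param n,p Dimensions.
#' @param rho Correlation decay in `[0, 1)`.
#' @param seed Optional seed.
#' @return An `n x p` numeric matrix.
#' @export
make_design <- function(n, p, rho = 0, seed = NULL) {
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1).")
  with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    if (rho > 0 && p > 1) {
      a <- sqrt(1 - rho^2)
      for (j in 2:p) X[, j] <- rho * X[, j - 1] + a * X[, j]
    }
    X
  })
}

#' Draw coefficients from the group-wise spike-and-slab prior
#'
#' `s_j ~ Bernoulli(pi_true[g(j)])`, `b_j ~ N(0, 1/gamma_true[g(j)])`,
#' `beta_j = s_j b_j`.
#'
#' @param p Feature count.
#' @param partition Feature partition.
#' @param gamma_true,pi_true Length-`G` truth vectors.
#' @param seed Optional seed.
#' @return `list(beta_true, s_true, b_true)`.
#' @export
make_coefficients <- function(p, partition, gamma_true, pi_true,
                              seed = NULL) {
  k <- partition$assignment
  stopifnot(length(k) == p, length(gamma_true) == partition$G,
            length(pi_true) == partition$G)
  with_seed(seed, {
    s <- rbinom(p, 1, pi_true[k])
    b <- rnorm(p, 0, 1 / sqrt(gamma_true[k]))
    list(beta_true = s * b, s_true = s, b_true = b)
  })
}

#' Draw a response from the linear or logistic model
#'
#' Gaussian: `y = X beta + e`, `e ~ N(0, 1/tau)`. Bernoulli:
#' `y_i ~ Ber(sigma(x_i' beta))`.
#'
#' @param X Design matrix.
#' @param beta_true Coefficient vector.
#' @param tau Noise precision (gaussian only).
#' @param family Response family.
#' @param seed Optional seed.
#' @return Numeric response vector.
#' @export
make_response <- function(X, beta_true, tau = 10,
                          family = c("gaussian", "bernoulli"),
                          seed = NULL) {
  family <- match.arg(family)
  stopifnot(ncol(X) == length(beta_true))
  eta <- as.numeric(X %*% beta_true)
  with_seed(seed, {
    if (family == "gaussian") {
      stopifnot(tau > 0)
      eta + rnorm(nrow(X), 0, 1 / sqrt(tau))
    } else {
      as.numeric(rbinom(nrow(X), 1, plogis(eta)))
    }
  })
}

#' Simulate a complete dataset from a configuration
#'
#' Builds the equal-size group partition, draws the design, the
#' coefficients and the response, all deterministically from
#' `config$seed` (sub-seeds are derived for each stage).
#'
#' @param config A [simulation_config()] / [default_scenario()].
#' @return A `gs_sim_data` list: `dataset` ([gs_dataset()]), `partition`,
#'   `beta_true`, `s_true`, `config`.
#' @export
simulate_data <- function(config) {
  stopifnot(inherits(config, "gs_sim_config"))
  gsize <- config$p / config$G
  partition <- new_partition(rep(seq_len(config$G), each = gsize))
  X <- make_design(config$n, config$p, config$rho, seed = config$seed)
  coefs <- make_coefficients(config$p, partition, config$gamma_true,
                             config$pi_true, seed = config$seed + 1L)
  y <- make_response(X, coefs$beta_true, config$tau, config$family,
                     seed = config$seed + 2L)
  structure(
    list(dataset = gs_dataset(X, y, family = config$family),
         partition = partition,
         beta_true = coefs$beta_true, s_true = coefs$s_true,
         config = config),
    class = "gs_sim_data"
  )
}

#' Independent test set for a simulated scenario
#'
#' Draws `n_test` fresh samples from the same design distribution and the
#' same true coefficients, using a seed offset of 10^6 from the training
#' seed.
#'
#' @param sim A `gs_sim_data` from [simulate_data()].
#' @param n_test Test-set size.
#' @return `list(X, y)`.
#' @export
make_test_set <- function(sim, n_test = 1000) {
  cfg <- sim$config
  seed <- cfg$seed + 1000000L
  X <- make_design(n_test, cfg$p, cfg$rho, seed = seed)
  y <- make_response(X, sim$beta_true, cfg$tau, cfg$family,
                     seed = seed + 1L)
  list(X = X, y = y)
}

#' Recovery and prediction metrics against simulation truth
#'
#' @param fit A `gs_fit`.
#' @param truth The `gs_sim_data` the fit was trained on.
#' @param X_test,y_test Independent test set (e.g. from [make_test_set()]).
#' @return A list with `rmse_y` (test-set prediction RMSE), `rmse_beta`,
#'   `gamma_log_ratio` (`log(gamma_hat/gamma_true)` per group), `pi_error`
#'   (`pi_hat - pi_true` per group) and `sign_agreement` (share of truly
#'   active features whose estimated coefficient sign matches the truth).
#' @export
recovery_metrics <- function(fit, truth, X_test, y_test) {
  stopifnot(inherits(truth, "gs_sim_data"))
  if (ncol(X_test) != length(fit$beta_hat) ||
      length(y_test) != nrow(X_test)) {
    stop("test-set dimensions do not match the fit.")
  }
  yhat <- predict(fit, X_test)
  active <- truth$s_true == 1 & truth$beta_true != 0
  list(
    rmse_y = sqrt(mean((yhat - y_test)^2)),
    rmse_beta = sqrt(mean((fit$beta_hat - truth$beta_true)^2)),
    gamma_log_ratio = log(fit$gamma_hat / truth$config$gamma_true),
    pi_error = fit$pi_hat - truth$config$pi_true,
    sign_agreement = if (any(active)) {
      mean(sign(fit$beta_hat[active]) == sign(truth$beta_true[active]))
    } else NA_real_
  )
}
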