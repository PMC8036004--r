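# Core data containers: dataset, feature-group partition, prior
# configuration, and posterior summaries shared by all inference engines.

#' Construct a regression dataset
#'
#' Bundles the design matrix, response and identifiers together with the
#' response family. The bernoulli family requires a 0/1 response.
#'
#' @param X Numeric matrix, samples in rows and features in columns. All
#'   entries must be finite.
#' @param y Numeric response vector of length `nrow(X)`; for
#'   `family = "bernoulli"` every entry must be 0 or 1.
#' @param family Either `"gaussian"` or `"bernoulli"`.
#' @param sample_ids,feature_ids Optional character identifiers; defaults are
#'   taken from `dimnames(X)` or generated.
#'
#' @return An object of class `gs_dataset` with elements `X`, `y`,
#'   `sample_ids`, `feature_ids`, `family`, `n`, `p`.
#' @export
#' @examples
#' X <- matrix(rnorm(20), 5, 4)
#' d <- gs_dataset(X, rnorm(5))
#' d$p
gs_dataset <- function(X, y, family = c("gaussian", "bernoulli"),
                       sample_ids = NULL, feature_ids = NULL) {
  family <- match.arg(family)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (!all(is.finite(X))) {
    stop("X contains non-finite entries; impute or remove them before fitting.")
  }
  if (length(y) != nrow(X)) {
    stop("length(y) [", length(y), "] does not match nrow(X) [", nrow(X), "].")
  }
  if (!all(is.finite(y))) stop("y contains non-finite entries.")
  if (family == "bernoulli" && !all(y %in% c(0, 1))) {
    stop("bernoulli family requires a 0/1 response.")
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(X) %||% paste0("sample", seq_len(nrow(X)))
  }
  if (is.null(feature_ids)) {
    feature_ids <- colnames(X) %||% paste0("feature", seq_len(ncol(X)))
  }
  if (anyDuplicated(sample_ids)) stop("duplicate sample identifiers.")
  if (anyDuplicated(feature_ids)) stop("duplicate feature identifiers.")
  structure(
    list(X = X, y = y, sample_ids = as.character(sample_ids),
         feature_ids = as.character(feature_ids), family = family,
         n = nrow(X), p = ncol(X)),
    class = "gs_dataset"
  )
}

#' @export
print.gs_dataset <- function(x, ...) {
  cat("<gs_dataset> ", x$n, " samples x ", x$p, " features, family: ",
      x$family, "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a feature-group partition from an external covariate
#'
#' Maps a per-feature covariate (e.g. assay type, chromosomal region,
#' per-feature variance) to groups `1..G`. Categorical covariates map each
#' distinct level to one group, ordered by first appearance. Continuous
#' covariates are binned by quantiles (equal-count bins); the default is 5
#' bins when no binning is specified.
#'
#' @param covariate Vector with one value per feature: character, factor or
#'   logical input is treated as categorical; numeric input as continuous
#'   unless `breaks` is given.
#' @param n_bins Number of quantile bins for a continuous covariate.
#' @param breaks Optional explicit breakpoints for a continuous covariate
#'   (interior breakpoints; outermost bounds are -Inf/Inf).
#'
#' @return An object of class `gs_partition` with `assignment` (integer in
#'   `1..G`), `G`, `group_sizes`, `group_labels` and the raw
#'   `covariate_values`.
#' @export
#' @examples
#' build_partition(c("drug", "rna", "meth", "rna"))
#' build_partition(c(0.1, 0.2, 0.9, 1.0), n_bins = 2)
build_partition <- function(covariate, n_bins = NULL, breaks = NULL) {
  if (length(covariate) == 0) stop("empty covariate: one value per feature is required.")
  categorical <- is.character(covariate) || is.factor(covariate) ||
    is.logical(covariate)
  if (categorical) {
    lev <- unique(as.character(covariate))
    assignment <- match(as.character(covariate), lev)
    labels <- lev
  } else {
    zeta <- as.numeric(covariate)
    if (!all(is.finite(zeta))) stop("continuous covariate contains non-finite values.")
    if (is.null(breaks)) {
      if (is.null(n_bins)) n_bins <- 5L
      n_bins <- as.integer(n_bins)
      n_distinct <- length(unique(zeta))
      if (n_bins > n_distinct) {
        stop("degenerate binning: requested ", n_bins, " bins but the covariate has only ",
             n_distinct, " distinct values.")
      }
      if (n_bins == n_distinct) {
        breaks <- sort(unique(zeta))[-1] - .Machine$double.eps^0.5
      } else {
        breaks <- unique(quantile(zeta, probs = seq_len(n_bins - 1) / n_bins,
                                  names = FALSE, type = 7))
      }
    }
    assignment <- findInterval(zeta, sort(breaks), left.open = TRUE) + 1L
    # re-index so bins are 1..G in ascending order and every group non-empty
    used <- sort(unique(assignment))
    assignment <- match(assignment, used)
    labels <- paste0("bin", seq_along(used))
  }
  new_partition(as.integer(assignment), labels = labels,
                covariate_values = covariate)
}

new_partition <- function(assignment, labels = NULL, covariate_values = NULL) {
  G <- max(assignment)
  sizes <- tabulate(assignment, nbins = G)
  if (any(sizes < 1)) stop("every group must contain at least one feature.")
  structure(
    list(assignment = assignment, G = G, group_sizes = sizes,
         group_labels = labels %||% paste0("group", seq_len(G)),
         covariate_values = covariate_values),
    class = "gs_partition"
  )
}

#' @export
print.gs_partition <- function(x, ...) {
  cat("<gs_partition> ", length(x$assignment), " features in ", x$G,
      " groups (sizes: ", paste(x$group_sizes, collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

#' Hyper-prior configuration
#'
#' Gamma hyper-priors on the noise precision tau and the per-group slab
#' precisions gamma_k, and a Beta hyper-prior on the per-group mixing
#' proportions pi_k. The defaults are vague: Gamma(0.001, 0.001) and
#' Beta(1, 1).
#'
#' @param r_tau,d_tau Shape and rate of the Gamma prior on tau.
#' @param r_gamma,d_gamma Shape and rate of the Gamma prior on each gamma_k.
#' @param d_pi,r_pi First and second Beta parameters of the prior on each
#'   pi_k.
#' @return An object of class `gs_prior`.
#' @export
prior_config <- function(r_tau = 0.001, d_tau = 0.001,
                         r_gamma = 0.001, d_gamma = 0.001,
                         d_pi = 1, r_pi = 1) {
  vals <- c(r_tau = r_tau, d_tau = d_tau, r_gamma = r_gamma,
            d_gamma = d_gamma, d_pi = d_pi, r_pi = r_pi)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all hyper-prior parameters must be strictly positive.")
  }
  structure(as.list(vals), class = "gs_prior")
}

#' Validate a dataset / partition pair
#'
#' Checks dimensional agreement, rejects constant (zero-variance) feature
#' columns by name, and warns when any group holds fewer than 10 features
#' (group-level hyper-parameters are poorly estimable from very small
#' groups).
#'
#' @param data A [gs_dataset()].
#' @param partition A [gs_partition][build_partition()].
#' @return Invisibly, `list(data, partition)` unchanged.
#' @export
validate_inputs <- function(data, partition) {
  stopifnot(inherits(data, "gs_dataset"), inherits(partition, "gs_partition"))
  if (length(partition$assignment) != data$p) {
    stop("partition length [", length(partition$assignment),
         "] does not match the number of features [", data$p, "].")
  }
  v <- apply(data$X, 2, function(col) max(col) - min(col))
  if (any(v == 0)) {
    bad <- data$feature_ids[v == 0]
    stop("constant (zero-variance) feature column(s): ",
         paste(head(bad, 10), collapse = ", "),
         if (length(bad) > 10) ", ..." else "",
         ". Remove them before fitting; silent dropping would break coefficient indexing.")
  }
  if (any(partition$group_sizes < 10)) {
    small <- which(partition$group_sizes < 10)
    warning("group(s) ", paste(small, collapse = ", "),
            " contain fewer than 10 features; group-wise hyper-parameter ",
            "estimates will be unstable.", call. = FALSE)
  }
  invisible(list(data = data, partition = partition))
}

#' Summarize a variational state into posterior point estimates
#'
#' Converts the variational factors into the posterior means used for
#' estimation and prediction: `beta_hat[j] = psi[j] * mu[j]`,
#' `gamma_hat[k] = gamma_shape[k]/gamma_rate[k]`,
#' `pi_hat[k] = pi_a[k]/(pi_a[k]+pi_b[k])` and
#' `tau_hat = tau_shape/tau_rate`.
#'
#' @param state A variational state as produced by the fitting engines.
#' @param partition The [gs_partition][build_partition()] used in the fit.
#' @param intercept Intercept value to store (default 0).
#' @return An object of class `gs_fit`; see [fit_linear()] for the fields.
#' @export
summarize_posterior <- function(state, partition, intercept = 0) {
  num <- unlist(state[c("mu", "sigma2", "psi", "gamma_shape", "gamma_rate",
                        "pi_a", "pi_b")], use.names = FALSE)
  if (!all(is.finite(num))) stop("non-finite entries in the variational state.")
  fixed <- state$fixed %||% list()
  gamma_hat <- fixed$gamma %||% (state$gamma_shape / state$gamma_rate)
  pi_hat <- fixed$pi %||% (state$pi_a / (state$pi_a + state$pi_b))
  tau_hat <- fixed$tau %||%
    (if (!is.null(state$tau_shape)) state$tau_shape / state$tau_rate else NA_real_)
  structure(
    list(beta_hat = state$psi * state$mu,
         inclusion_prob = state$psi,
         mu = state$mu, sigma2 = state$sigma2,
         gamma_hat = gamma_hat, pi_hat = pi_hat, tau_hat = tau_hat,
         intercept = intercept,
         n_iter = length(state$elbo_trace),
         converged = isTRUE(state$converged),
         elbo_trace = state$elbo_trace,
         partition = partition,
         family = state$family %||% "gaussian",
         variant = state$variant %||% "sparse"),
    class = "gs_fit"
  )
}

#' @export
print.gs_fit <- function(x, ...) {
  cat("<gs_fit> family: ", x$family, ", variant: ", x$variant, "\n", sep = "")
  cat("  ", length(x$beta_hat), " coefficients, ", length(x$gamma_hat),
      " groups\n", sep = "")
  cat("  gamma_hat: ", paste(signif(x$gamma_hat, 3), collapse = ", "), "\n",
      sep = "")
  cat("  pi_hat:    ", paste(signif(x$pi_hat, 3), collapse = ", "), "\n",
      sep = "")
  cat("  ", x$n_iter, " sweeps, converged: ", x$converged, "\n", sep = "")
  invisible(x)
}

#' @export
coef.gs_fit <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$beta_hat)
}

#' Predict from a fitted model
#'
#' @param object A `gs_fit`.
#' @param newdata Matrix of new samples (columns must match the training
#'   features).
#' @param ... Unused.
#' @return Numeric vector: fitted values (gaussian) or class-1 probabilities
#'   (bernoulli).
#' @export
predict.gs_fit <- function(object, newdata, ...) {
  if (object$family == "bernoulli") predict_logistic(object, newdata)
  else predict_linear(object, newdata)
}
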