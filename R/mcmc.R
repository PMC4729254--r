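# Data log-likelihood and its gradient wrt the signal, by response kind.
# bernoulli: sum(y*S - log(1 + e^S)); poisson: sum(y*S - e^S - log y!);
# gaussian (test-only conjugate variant): sum(-(y - S)^2 / (2 v)).
data_loglik <- function(signal, y, kind, noise_var = 1) {
  switch(kind,
    bernoulli = sum(y * signal - (pmax(signal, 0) + log1p(exp(-abs(signal))))),
    poisson   = sum(y * signal - exp(signal) - lgamma(y + 1)),
    gaussian  = -sum((y - signal)^2) / (2 * noise_var),
    stop("unknown likelihood kind: ", kind, call. = FALSE))
}

data_grad <- function(signal, y, kind, noise_var = 1) {
  switch(kind,
    bernoulli = y - stats::plogis(signal),
    poisson   = y - exp(signal),
    gaussian  = (y - signal) / noise_var)
}

#' Log-posterior of the latent signal and its exact gradient
#'
#' Evaluates \eqn{\log p(y \mid S) + \log N(S; X\beta, C)} up to an additive
#' constant, together with its gradient in \eqn{S}: the data-term gradient
#' (e.g. \eqn{y - e^S} for Poisson counts) minus \eqn{C^{-1}(S - X\beta)}.
#' This is the target density of the conditional-simulation sampler.
#'
#' @param signal Numeric vector, current signal values at the data locations.
#' @param y Observed counts (Poisson), presence indicators (Bernoulli), or
#'   Gaussian responses (test variant).
#' @param params A [glsm_params] object (trend + variogram).
#' @param covariates Data frame of covariates at the data locations.
#' @param coords Matrix/data frame of (x, y) coordinates.
#' @param likelihood \code{"poisson"}, \code{"bernoulli"} or
#'   \code{"gaussian"}.
#' @param noise_var Gaussian response variance (test variant only).
#' @return List with \code{logp} (scalar, up to a constant) and \code{grad}.
#' @export
log_posterior_gradient <- function(signal, y, params, covariates, coords,
                                   likelihood = c("poisson", "bernoulli",
                                                  "gaussian"),
                                   noise_var = 1) {
  likelihood <- match.arg(likelihood)
  if (any(!is.finite(signal))) stop("non-finite signal", call. = FALSE)
  X <- trend_matrix(covariates, params$beta)
  m <- drop(X %*% params$beta)
  C <- covariance_matrix(coords, params)
  U <- chol(C)
  r <- signal - m
  Cinv_r <- backsolve(U, forwardsolve(t(U), r))
  logp <- data_loglik(signal, y, likelihood, noise_var) -
    0.5 * sum(r * Cinv_r)
  grad <- data_grad(signal, y, likelihood, noise_var) - Cinv_r
  list(logp = logp, grad = grad)
}

#' Langevin-Hastings (MALA) simulation of the latent signal
#'
#' Samples the signal \eqn{S} at the data locations conditional on the
#' observations and fixed parameters \eqn{\theta}, using Metropolis-adjusted
#' Langevin proposals on a whitened parameterization: with \eqn{C = A A'}
#' (Cholesky), the chain runs on \eqn{z = A^{-1}(S - X\beta)}, whose prior is
#' standard normal, so one scalar step size serves all locations. The step
#' size is tuned during burn-in by stochastic approximation toward a target
#' acceptance rate (default 0.55, close to the optimal rate for
#' Langevin-Hastings samplers) and frozen afterwards, preserving detailed
#' balance for the retained draws.
#'
#' @inheritParams log_posterior_gradient
#' @param n_iter Total iterations. Defaults used for full-scale calibration
#'   are 100,000 (Poisson) and 50,000 (Bernoulli).
#' @param burn_in Iterations discarded (and used for step-size adaptation);
#'   default 100.
#' @param thin Keep every \code{thin}-th post-burn-in iteration; default 100.
#' @param seed Integer seed; identical seeds give identical draws.
#' @param target_acceptance Acceptance rate the adaptation aims for.
#' @return An object of class \code{"signal_sample"}: retained draws (matrix,
#'   iterations x locations), realized post-burn-in \code{acceptance_rate},
#'   frozen \code{step_size}, and the run settings. \code{\link{run_report}}
#'   summarizes convergence evidence.
#' @export
mala_sample <- function(y, params, covariates, coords,
                        likelihood = c("poisson", "bernoulli", "gaussian"),
                        n_iter = 10000L, burn_in = 100L, thin = 100L,
                        seed = 1L, target_acceptance = 0.55, noise_var = 1) {
  likelihood <- match.arg(likelihood)
  if (n_iter <= burn_in) stop("'n_iter' must exceed 'burn_in'", call. = FALSE)
  if (thin < 1L) stop("'thin' must be >= 1", call. = FALSE)
  X <- trend_matrix(covariates, params$beta)
  m <- drop(X %*% params$beta)
  n <- length(y)
  C <- covariance_matrix(coords, params)
  U <- chol(C)                       # C = U'U ; S = m + U'z

  logf <- function(z, S) {
    data_loglik(S, y, likelihood, noise_var) - 0.5 * sum(z * z)
  }
  gradf <- function(z, S) {
    drop(U %*% data_grad(S, y, likelihood, noise_var)) - z
  }

  n_keep <- floor((n_iter - burn_in) / thin)
  draws <- matrix(NA_real_, n_keep, n)
  h <- 2.4^2 / n^(1/3)               # optimal-scaling style initial step
  acc_post <- 0L; n_post <- 0L

  with_seed(seed, {
    z <- stats::rnorm(n) * 0.1
    S <- m + drop(crossprod(U, z))
    lp <- logf(z, S); g <- gradf(z, S)
    kept <- 0L
    for (t in seq_len(n_iter)) {
      eps <- stats::rnorm(n)
      z_star <- z + (h / 2) * g + sqrt(h) * eps
      S_star <- m + drop(crossprod(U, z_star))
      lp_star <- logf(z_star, S_star)
      g_star <- gradf(z_star, S_star)
      # proposal correction: q(z | z*) / q(z* | z)
      fwd <- z_star - z - (h / 2) * g
      bwd <- z - z_star - (h / 2) * g_star
      log_alpha <- lp_star - lp + (sum(fwd^2) - sum(bwd^2)) / (2 * h)
      accept <- is.finite(log_alpha) && log(stats::runif(1)) < log_alpha
      if (accept) { z <- z_star; S <- S_star; lp <- lp_star; g <- g_star }
      if (t <= burn_in) {
        a_prob <- if (is.finite(log_alpha)) min(1, exp(log_alpha)) else 0
        h <- h * exp(t^(-0.6) * (a_prob - target_acceptance))
      } else {
        n_post <- n_post + 1L
        if (accept) acc_post <- acc_post + 1L
        if ((t - burn_in) %% thin == 0L) {
          kept <- kept + 1L
          draws[kept, ] <- S
        }
      }
    }
  })

  rate <- acc_post / n_post
  warn <- NULL
  if (rate < 0.05 || rate > 0.95) {
    warn <- sprintf(
      "post-adaptation acceptance rate %.2f collapsed toward %d", rate,
      as.integer(rate > 0.5))
    warning(warn, call. = FALSE)
  }
  structure(list(
    draws = draws, acceptance_rate = rate, step_size = h,
    n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
    thin = as.integer(thin), likelihood_kind = likelihood,
    target_acceptance = target_acceptance, seed = as.integer(seed),
    convergence_warning = warn),
    class = "signal_sample")
}

#' @export
print.signal_sample <- function(x, ...) {
  cat("Signal sample (", x$likelihood_kind, "): ", nrow(x$draws),
      " retained draws at ", ncol(x$draws), " locations; acceptance ",
      sprintf("%.1f%%", 100 * x$acceptance_rate),
      ", step size ", format(x$step_size, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Geweke convergence diagnostic
#'
#' Compares the mean of an early window of the chain with that of a late
#' window, \eqn{z = (\bar x_A - \bar x_B) / \sqrt{\hat s_A/n_A + \hat
#' s_B/n_B}}, where \eqn{\hat s} is the spectral density at frequency zero
#' (estimated by an AR model fitted with AIC order selection), so
#' autocorrelation within each window is accounted for. |z| well above 2
#' flags a drifting chain.
#'
#' @param chain Numeric vector (length >= 100).
#' @param first_frac,last_frac Fractions of the chain used for the early and
#'   late windows (defaults 0.1 and 0.5); they must not overlap.
#' @return The z-score (scalar).
#' @export
geweke_diagnostic <- function(chain, first_frac = 0.1, last_frac = 0.5) {
  n <- length(chain)
  if (n < 100L) stop("chain too short for the diagnostic (need >= 100)",
                     call. = FALSE)
  if (first_frac <= 0 || last_frac <= 0 || first_frac + last_frac > 1)
    stop("window fractions must be positive and non-overlapping",
         call. = FALSE)
  if (stats::sd(chain) == 0)
    stop("constant chain: spectral variance undefined", call. = FALSE)
  a <- chain[seq_len(floor(first_frac * n))]
  b <- chain[seq.int(n - floor(last_frac * n) + 1L, n)]
  (mean(a) - mean(b)) / sqrt(spectrum0_ar(a) / length(a) +
                             spectrum0_ar(b) / length(b))
}

# Spectral density at frequency zero from an AIC-selected AR fit:
# var_pred / (1 - sum(ar coefficients))^2. A white-noise window (order 0)
# reduces to the sample variance.
spectrum0_ar <- function(x) {
  v <- stats::var(x)
  if (v == 0) return(0)
  fit <- tryCatch(
    stats::ar(x, aic = TRUE, order.max = min(length(x) - 1L,
                                             floor(10 * log10(length(x))))),
    error = function(e) NULL)
  if (is.null(fit) || fit$order == 0) return(v)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Machine-readable convergence report for a signal sample
#'
#' Summarizes the evidence a practitioner would read off trace/autocorrelation
#' /Geweke plots: realized acceptance rate, frozen step size, lag-1
#' autocorrelation of the retained draws, and Geweke z-scores for a random
#' subset of locations.
#'
#' @param sample A [mala_sample] result.
#' @param n_locations How many locations to diagnose (sampled w/o
#'   replacement).
#' @param seed Seed for the location subset.
#' @return A list (serializable as JSON) with the fields above.
#' @export
run_report <- function(sample, n_locations = 10L, seed = 1L) {
  stopifnot(inherits(sample, "signal_sample"))
  d <- sample$draws
  idx <- with_seed(seed, sample.int(ncol(d), min(n_locations, ncol(d))))
  lag1 <- vapply(idx, function(j) {
    x <- d[, j]
    if (stats::sd(x) == 0) return(NA_real_)
    stats::cor(x[-1], x[-length(x)])
  }, numeric(1))
  gz <- vapply(idx, function(j) {
    tryCatch(geweke_diagnostic(d[, j]), error = function(e) NA_real_)
  }, numeric(1))
  list(likelihood = sample$likelihood_kind,
       n_retained = nrow(d),
       acceptance_rate = sample$acceptance_rate,
       target_acceptance = sample$target_acceptance,
       step_size = sample$step_size,
       locations = idx,
       lag1_autocorrelation = lag1,
       geweke_z = gz,
       convergence_warning = sample$convergence_warning)
}
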