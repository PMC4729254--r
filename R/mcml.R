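#' Exact multivariate-normal log-density of a signal vector
#'
#' \eqn{\log f(S \mid \theta)} with mean \eqn{X\beta} and covariance from
#' [covariance_matrix]; the numerator and denominator of the Monte Carlo
#' likelihood ratio.
#'
#' @param signal Numeric vector of signal values at the data locations.
#' @param params A [glsm_params] object.
#' @param covariates Covariate data frame at the data locations.
#' @param coords Coordinates (x, y) of the data locations.
#' @return Scalar log-density (normalizing constant included).
#' @export
signal_logdensity <- function(signal, params, covariates, coords) {
  X <- trend_matrix(covariates, params$beta)
  m <- drop(X %*% params$beta)
  C <- covariance_matrix(coords, params)
  U <- tryCatch(chol(C), error = function(e)
    stop("covariance factorization failed: ", conditionMessage(e),
         call. = FALSE))
  r <- signal - m
  w <- forwardsolve(t(U), r)
  -0.5 * length(r) * log(2 * pi) - sum(log(diag(U))) - 0.5 * sum(w * w)
}

# Per-draw log-densities for a draws matrix (J x n), sharing one
# factorization of C(theta). Used by mc_loglik/maximize_mcml.
signal_logdensity_draws <- function(draws, params, covariates, coords) {
  X <- trend_matrix(covariates, params$beta)
  m <- drop(X %*% params$beta)
  C <- covariance_matrix(coords, params)
  U <- chol(C)
  Rm <- t(draws) - m                      # n x J residuals
  W <- forwardsolve(t(U), Rm)
  -0.5 * ncol(draws) * log(2 * pi) - sum(log(diag(U))) - 0.5 * colSums(W * W)
}

#' Monte Carlo log-likelihood (likelihood-ratio approximation)
#'
#' The likelihood of \eqn{\theta} relative to the simulation parameters
#' \eqn{\theta_0} is approximated by the average density ratio over MCMC
#' draws of the signal,
#' \eqn{L_m(\theta) \approx J^{-1} \sum_j f(S_j \mid \theta) / f(S_j \mid
#' \theta_0)}, evaluated stably through log-sum-exp. At \eqn{\theta =
#' \theta_0} every ratio is 1 and the value is exactly 0.
#'
#' @param theta Candidate [glsm_params].
#' @param draws A [mala_sample] result (draws generated under
#'   \code{theta0}), or a numeric matrix of draws (J x n).
#' @param theta0 The [glsm_params] the draws were simulated under.
#' @param covariates,coords Data-location covariates and coordinates.
#' @return Scalar \eqn{\log L_m(\theta)} (0 at \eqn{\theta_0}); attribute
#'   \code{"ess"} carries the effective number of draws, with a warning when
#'   the importance weights have degenerated (ESS < 5).
#' @export
mc_loglik <- function(theta, draws, theta0, covariates, coords) {
  d <- if (inherits(draws, "signal_sample")) draws$draws else as.matrix(draws)
  if (nrow(d) < 1L) stop("no draws", call. = FALSE)
  ld1 <- signal_logdensity_draws(d, theta, covariates, coords)
  ld0 <- signal_logdensity_draws(d, theta0, covariates, coords)
  lr <- ld1 - ld0
  mx <- max(lr)
  if (!is.finite(mx)) return(structure(-Inf, ess = 0))
  w <- exp(lr - mx)
  ess <- sum(w)^2 / sum(w^2)
  if (nrow(d) >= 5 && ess < 5)
    warning("importance weights degenerate (ESS = ",
                       format(ess, digits = 3), ")", call. = FALSE)
  structure(mx + log(mean(w)), ess = ess)
}

#' Maximize the Monte Carlo likelihood over the GLSM parameters
#'
#' Optimizes [mc_loglik] over the trend coefficients and the log-transformed
#' variogram parameters \eqn{(\log\sigma^2, \log\tau^2, \log\phi)} (the
#' correlation family stays fixed), by quasi-Newton iteration with a
#' Nelder-Mead restart if that fails to improve.
#'
#' @param draws A [mala_sample] result generated under \code{theta0}.
#' @param theta0 [glsm_params] used to generate the draws (also the starting
#'   point).
#' @param covariates,coords Data-location covariates and coordinates.
#' @param maxit Iteration cap handed to the optimizer.
#' @return An object of class \code{"mcml_result"}: \code{theta_hat},
#'   \code{mc_loglik_at_max}, \code{n_draws_used}, optimizer trace info.
#' @export
maximize_mcml <- function(draws, theta0, covariates, coords, maxit = 300L) {
  d <- if (inherits(draws, "signal_sample")) draws$draws else as.matrix(draws)
  J <- nrow(d)
  if (J < 2L) stop("need at least 2 draws", call. = FALSE)
  X <- trend_matrix(covariates, theta0$beta)
  cmat <- as_coord_matrix(coords)
  p <- length(theta0$beta)
  ld0 <- signal_logdensity_draws(d, theta0, covariates, coords)

  unpack <- function(par) {
    glsm_params(stats::setNames(par[seq_len(p)], names(theta0$beta)),
                sigma2 = exp(par[p + 1]), tau2 = exp(par[p + 2]),
                phi = exp(par[p + 3]), family = theta0$family)
  }
  negobj <- function(par) {
    th <- tryCatch(unpack(par), error = function(e) NULL)
    if (is.null(th)) return(1e10)
    ld1 <- tryCatch(
      signal_logdensity_draws(d, th, covariates, coords),
      error = function(e) NULL)
    if (is.null(ld1) || any(!is.finite(ld1))) return(1e10)
    lr <- ld1 - ld0
    mx <- max(lr)
    -(mx + log(mean(exp(lr - mx))))
  }
  start <- c(theta0$beta, log(max(theta0$sigma2, 1e-8)),
             log(max(theta0$tau2, 1e-8)), log(theta0$phi))

  opt <- suppressWarnings(
    stats::optim(start, negobj, method = "BFGS",
                 control = list(maxit = maxit, reltol = 1e-10)))
  opt2 <- suppressWarnings(
    stats::optim(opt$par, negobj, method = "Nelder-Mead",
                 control = list(maxit = 5L * maxit)))
  if (opt2$value < opt$value) opt <- opt2
  if (!is.finite(opt$value) || opt$value >= 1e10)
    stop("MCML optimization failed to find a valid parameter point",
         call. = FALSE)

  theta_hat <- unpack(opt$par)
  structure(list(
    theta_hat = theta_hat,
    mc_loglik_at_max = -opt$value,
    mc_loglik_at_start = -negobj(start),
    n_draws_used = J,
    convergence = opt$convergence,
    counts = opt$counts),
    class = "mcml_result")
}

#' @export
print.mcml_result <- function(x, ...) {
  cat("MCML estimate (J =", x$n_draws_used, "draws, log LR at max =",
      sprintf("%.3f", x$mc_loglik_at_max), ")\n")
  print(x$theta_hat)
  invisible(x)
}

#' Calibrate one GLSM submodel by iterated MCMC + MCML
#'
#' Alternates conditional simulation of the signal ([mala_sample] at the
#' current parameter values) with Monte Carlo maximum likelihood
#' ([maximize_mcml]); repeating the pair stabilizes the estimates because
#' each cycle re-centers the importance distribution at the latest
#' \eqn{\hat\theta}. Three cycles are the default.
#'
#' @param y Response vector: presence indicators (Bernoulli submodel) or
#'   counts on the Poisson subset.
#' @param covariates,coords Covariates and coordinates of the same locations.
#' @param theta_init Starting [glsm_params] (e.g. from
#'   [initial_spatial_params]).
#' @param likelihood \code{"poisson"} or \code{"bernoulli"}.
#' @param n_cycles Number of MCMC+MCML cycles (default 3).
#' @param n_iter,burn_in,thin,target_acceptance MCMC settings, passed to
#'   [mala_sample]. Full-scale defaults are 100,000 iterations for the
#'   Poisson process and 50,000 for the Bernoulli, burn-in 100, thinning 100;
#'   desk-scale runs override them.
#' @param seed Integer seed (cycle c uses seed + c - 1).
#' @param maxit Optimizer iteration cap per cycle.
#' @return A list of class \code{"submodel_calibration"}: final
#'   \code{result} ([maximize_mcml] output), \code{theta_hat}, per-cycle
#'   parameter sets \code{cycle_thetas}, and the final cycle's
#'   \code{sample} (used downstream for prediction).
#' @export
calibrate_submodel <- function(y, covariates, coords, theta_init,
                               likelihood = c("poisson", "bernoulli"),
                               n_cycles = 3L,
                               n_iter = if (match.arg(likelihood) == "poisson")
                                 100000L else 50000L,
                               burn_in = 100L, thin = 100L,
                               target_acceptance = 0.55, seed = 1L,
                               maxit = 300L) {
  likelihood <- match.arg(likelihood)
  if (n_cycles < 1L) stop("'n_cycles' must be >= 1", call. = FALSE)
  theta <- theta_init
  cycle_thetas <- vector("list", n_cycles)
  res <- NULL; samp <- NULL
  for (cyc in seq_len(n_cycles)) {
    samp <- mala_sample(y, theta, covariates, coords, likelihood,
                        n_iter = n_iter, burn_in = burn_in, thin = thin,
                        seed = seed + cyc - 1L,
                        target_acceptance = target_acceptance)
    res <- maximize_mcml(samp, theta, covariates, coords, maxit = maxit)
    res$cycle_index <- cyc
    theta <- res$theta_hat
    cycle_thetas[[cyc]] <- theta
  }
  structure(list(result = res, theta_hat = theta,
                 cycle_thetas = cycle_thetas, sample = samp,
                 likelihood = likelihood),
            class = "submodel_calibration")
}

#' @export
print.submodel_calibration <- function(x, ...) {
  cat("Calibrated", x$likelihood, "submodel after",
      length(x$cycle_thetas), "MCMC+MCML cycle(s)\n")
  print(x$theta_hat)
  invisible(x)
}

#' Starting values for the spatial calibration
#'
#' Trend coefficients are taken from the nonspatial fit; the signal variance
#' is split evenly between partial sill and nugget at half the
#' deviance-residual variance of a nonspatial GLM, and the range starts at a
#' quarter of the domain diameter.
#'
#' @param y Response vector (indicators or counts).
#' @param covariates,coords Covariates and coordinates.
#' @param beta Named starting trend coefficients (from [fit_zip_ml]).
#' @param likelihood \code{"poisson"} or \code{"bernoulli"}.
#' @param family Correlation family for the calibration.
#' @return A [glsm_params] object.
#' @export
initial_spatial_params <- function(y, covariates, coords, beta,
                                   likelihood = c("poisson", "bernoulli"),
                                   family = "spherical") {
  likelihood <- match.arg(likelihood)
  X <- trend_matrix(covariates, beta)
  fam <- if (likelihood == "poisson") stats::poisson() else stats::binomial()
  g <- suppressWarnings(stats::glm.fit(X, y, family = fam))
  mu <- g$fitted.values
  dev_res <- sign(y - mu) * sqrt(pmax(fam$dev.resids(y, mu, rep(1, length(y))), 0))
  v <- max(stats::var(dev_res) / 2, 0.02)
  cmat <- as_coord_matrix(coords)
  diam <- sqrt(diff(range(cmat[, 1]))^2 + diff(range(cmat[, 2]))^2)
  glsm_params(beta, sigma2 = v, tau2 = v, phi = diam / 4, family = family)
}

#' Critical value for comparing nested submodels
#'
#' One half of the \eqn{(1-\alpha)} quantile of the \eqn{\chi^2}
#' distribution: a difference in twice the log-likelihood between a larger
#' and a smaller covariate set exceeding this value prefers the larger model.
#'
#' @param alpha Significance level (default 0.05).
#' @param df Degrees of freedom = number of extra covariates.
#' @return Scalar threshold, e.g. 5.5 for \code{alpha = 0.05, df = 5}.
#' @export
model_comparison_threshold <- function(alpha = 0.05, df) {
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0,1)", call. = FALSE)
  if (df < 1) stop("'df' must be a positive integer", call. = FALSE)
  stats::qchisq(1 - alpha, df = df) / 2
}
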