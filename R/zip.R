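#' Zero-inflated Poisson probability mass function
#'
#' Mixture of a point mass at zero and a Poisson component. With prevalence
#' \eqn{\pi} (probability that the Bernoulli process yields presence) the
#' structural-zero weight is \eqn{\omega = 1 - \pi} and
#' \deqn{P(Y = 0) = \omega + (1-\omega) e^{-\mu}, \quad
#'       P(Y = y) = (1-\omega) e^{-\mu} \mu^y / y! \;\; (y \ge 1).}
#'
#' @param y Non-negative integer count(s).
#' @param prevalence \eqn{\pi \in [0, 1]}; the boundary values give the pure
#'   Poisson (\eqn{\pi = 1}) and all-structural-zero (\eqn{\pi = 0}) limits.
#' @param intensity Poisson mean \eqn{\mu > 0}, conditional on presence.
#' @param log Return log-probabilities?
#' @return Probabilities (or log-probabilities), vectorized over \code{y}.
#' @examples
#' dzip(0:3, prevalence = 0.8, intensity = 1.5)
#' @export
dzip <- function(y, prevalence, intensity, log = FALSE) {
  if (any(y < 0) || any(y != floor(y)))
    stop("'y' must contain non-negative integers", call. = FALSE)
  if (any(prevalence < 0 | prevalence > 1))
    stop("'prevalence' must lie in [0, 1]", call. = FALSE)
  if (any(intensity <= 0)) stop("'intensity' must be positive", call. = FALSE)
  omega <- 1 - prevalence
  p <- (1 - omega) * stats::dpois(y, intensity)
  p <- ifelse(y == 0, omega + p, p)
  if (log) base::log(p) else p
}

#' Probability that an observed zero is a structural (Bernoulli) zero
#'
#' The ratio of the probability of a structural zero to the total probability
#' of a zero, \eqn{\omega / (\omega + (1-\omega) e^{-\mu})} with
#' \eqn{\omega = 1 - \pi}. Increasing in \eqn{\mu} (a zero under a large
#' Poisson mean is implausible) and in \eqn{\omega}.
#'
#' @inheritParams dzip
#' @return Value(s) in \[0, 1\].
#' @export
bernoulli_zero_ratio <- function(prevalence, intensity) {
  if (any(prevalence < 0 | prevalence > 1))
    stop("'prevalence' must lie in [0, 1]", call. = FALSE)
  if (any(intensity <= 0)) stop("'intensity' must be positive", call. = FALSE)
  omega <- 1 - prevalence
  omega / (omega + (1 - omega) * exp(-intensity))
}

#' Maximum-likelihood fit of the nonspatial zero-inflated Poisson mixture
#'
#' Calibration step 1: both error terms are treated as spatially independent
#' and the mixture likelihood is maximized over the logit-prevalence and
#' log-intensity regression coefficients jointly by quasi-Newton iteration.
#' Starting values come from a logistic regression of the positive-count
#' indicator and a Poisson regression on the positive counts.
#'
#' @param data Data frame with a \code{count} column and covariate columns
#'   (the schema written by [simulate_survey] / [read_survey]).
#' @param formula_B,formula_P Character vectors of covariate column names for
#'   the prevalence (logit) and intensity (log) parts; the intercept is always
#'   included.
#' @return An object of class \code{"zip_fit"} with named coefficient vectors
#'   \code{beta_B}, \code{beta_P}, fitted per-location \code{prevalence} and
#'   \code{intensity}, the maximized \code{loglik}, and convergence info.
#' @export
fit_zip_ml <- function(data, formula_B = character(0), formula_P = formula_B) {
  y <- data$count
  if (is.null(y)) stop("'data' must have a 'count' column", call. = FALSE)
  if (any(y < 0) || any(y != floor(y)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (all(y > 0)) stop("all counts are positive: the zero-inflation weight ",
                       "is at its boundary (omega = 0); fit a plain Poisson ",
                       "regression instead", call. = FALSE)
  if (all(y == 0)) stop("all counts are zero: intensity is not identifiable",
                        call. = FALSE)
  design_mat <- function(cols) {
    if (length(cols) == 0L)
      return(matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)")))
    missing <- setdiff(cols, names(data))
    if (length(missing))
      stop("covariate column(s) not found: ", paste(missing, collapse = ", "),
           call. = FALSE)
    stats::model.matrix(~ ., data = data[, cols, drop = FALSE])
  }
  X_B <- design_mat(formula_B)
  X_P <- design_mat(formula_P)
  if (qr(X_B)$rank < ncol(X_B) || qr(X_P)$rank < ncol(X_P))
    stop("design matrix is rank deficient", call. = FALSE)
  p_B <- ncol(X_B); p_P <- ncol(X_P)

  # initialization: logistic fit of presence, Poisson fit on positives
  pres <- as.integer(y > 0)
  b0 <- stats::coef(suppressWarnings(
    stats::glm.fit(X_B, pres, family = stats::binomial())))
  g0 <- stats::coef(suppressWarnings(
    stats::glm.fit(X_P[pres == 1L, , drop = FALSE], y[pres == 1L],
                   family = stats::poisson())))
  start <- c(b0, g0)

  negll <- function(par) {
    pi_i <- stats::plogis(drop(X_B %*% par[seq_len(p_B)]))
    mu_i <- exp(drop(X_P %*% par[p_B + seq_len(p_P)]))
    om <- 1 - pi_i
    ll0 <- log(om + (1 - om) * exp(-mu_i))
    llp <- log1p(-om) + stats::dpois(y, mu_i, log = TRUE)
    -sum(ifelse(y == 0, ll0, llp))
  }
  grad <- function(par) {
    eta_B <- drop(X_B %*% par[seq_len(p_B)])
    eta_P <- drop(X_P %*% par[p_B + seq_len(p_P)])
    pi_i <- stats::plogis(eta_B); mu_i <- exp(eta_P)
    om <- 1 - pi_i
    p0 <- om + (1 - om) * exp(-mu_i)
    # d/d eta_B: zeros: pi(1-pi)(exp(-mu)-1)/p0 ; positives: 1 - pi
    d_B <- ifelse(y == 0, pi_i * (1 - pi_i) * (exp(-mu_i) - 1) / p0, 1 - pi_i)
    # d/d eta_P: zeros: -(1-om) exp(-mu) mu / p0 ; positives: y - mu
    d_P <- ifelse(y == 0, -(1 - om) * exp(-mu_i) * mu_i / p0, y - mu_i)
    -c(drop(crossprod(X_B, d_B)), drop(crossprod(X_P, d_P)))
  }

  opt <- stats::optim(start, negll, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  if (opt$convergence != 0)
    stop("ZIP likelihood maximization did not converge (code ",
         opt$convergence, "): ", opt$message, call. = FALSE)
  beta_B <- stats::setNames(opt$par[seq_len(p_B)], colnames(X_B))
  beta_P <- stats::setNames(opt$par[p_B + seq_len(p_P)], colnames(X_P))
  structure(list(
    beta_B = beta_B, beta_P = beta_P,
    prevalence = stats::plogis(drop(X_B %*% beta_B)),
    intensity = exp(drop(X_P %*% beta_P)),
    loglik = -opt$value, loglik_start = -negll(start),
    n = length(y), convergence = opt$convergence,
    formula_B = formula_B, formula_P = formula_P),
    class = "zip_fit")
}

#' @export
print.zip_fit <- function(x, ...) {
  cat("Nonspatial ZIP mixture fit (n =", x$n, ", logLik =",
      sprintf("%.2f", x$loglik), ")\n")
  cat("  logit(prevalence):\n"); print(round(x$beta_B, 4))
  cat("  log(intensity):\n"); print(round(x$beta_P, 4))
  invisible(x)
}

#' Stochastic classification of zero counts (calibration step 2)
#'
#' Each zero count is independently classified as a structural (Bernoulli)
#' zero with probability equal to [bernoulli_zero_ratio] evaluated at the
#' fitted prevalence and intensity at that location, and otherwise as a
#' Poisson zero. This splits the survey into the Bernoulli data set (a
#' presence indicator at every location: Poisson zeros count as presence) and
#' the smaller Poisson data set (locations with indicator 1, counts kept).
#'
#' @param data Survey data frame with a \code{count} column.
#' @param fit A [fit_zip_ml] result supplying fitted prevalence/intensity at
#'   every location.
#' @param seed Integer classification seed.
#' @return An object of class \code{"classified_data"}: list with integer
#'   vector \code{indicator} (1 = presence / Poisson membership), index
#'   vector \code{poisson_subset}, and the \code{seed}.
#' @export
classify_zeros <- function(data, fit, seed = 1L) {
  y <- data$count
  if (is.null(fit$prevalence) || is.null(fit$intensity) ||
      length(fit$prevalence) != length(y))
    stop("'fit' must provide fitted prevalence and intensity at every location",
         call. = FALSE)
  ratio <- bernoulli_zero_ratio(fit$prevalence, fit$intensity)
  indicator <- rep(1L, length(y))
  zero <- which(y == 0)
  with_seed(seed, {
    structural <- stats::runif(length(zero)) < ratio[zero]
    indicator[zero[structural]] <- 0L
  })
  structure(list(indicator = indicator,
                 poisson_subset = which(indicator == 1L),
                 seed = as.integer(seed)),
            class = "classified_data")
}

#' @export
print.classified_data <- function(x, ...) {
  n <- length(x$indicator)
  cat("Zero classification (seed ", x$seed, "): Bernoulli data set n = ", n,
      ", Poisson data set n = ", length(x$poisson_subset), "\n", sep = "")
  invisible(x)
}
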