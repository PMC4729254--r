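#' Parameter set for a generalized linear spatial model
#'
#' Bundles the trend coefficients and variogram parameters of one submodel
#' (Bernoulli prevalence on the logit scale, or Poisson intensity on the log
#' scale). The latent signal at location \eqn{s} is
#' \eqn{S(s) = x(s)'\beta + \eta(s)} with \eqn{\eta} a stationary Gaussian
#' process whose covariance at lag \eqn{h} is
#' \eqn{C(h) = \sigma^2 \rho(h; \phi) + \tau^2 1(h = 0)}.
#'
#' @param beta Numeric vector of trend (regression) coefficients. Names, if
#'   present, identify covariate columns; the first is taken to be the
#'   intercept when named \code{"(Intercept)"} or unnamed.
#' @param sigma2 Partial sill \eqn{\sigma^2 > 0}: variance of the spatially
#'   structured component.
#' @param tau2 Nugget \eqn{\tau^2 \ge 0}: spatially uncorrelated micro-scale
#'   variance of the latent signal.
#' @param phi Range parameter \eqn{\phi > 0} in meters. For the spherical
#'   family, correlation is exactly zero beyond \eqn{\phi}.
#' @param family Correlation family, \code{"spherical"} or
#'   \code{"exponential"}.
#'
#' @return An object of class \code{"glsm_params"}.
#' @examples
#' glsm_params(c(0.485, 0.587), sigma2 = 0.429, tau2 = 0.417, phi = 3414)
#' @export
glsm_params <- function(beta, sigma2, tau2, phi, family = "spherical") {
  beta <- as.numeric_named(beta)
  if (!is.numeric(sigma2) || length(sigma2) != 1L || !is.finite(sigma2) || sigma2 < 0)
    stop("'sigma2' (partial sill) must be a single positive number", call. = FALSE)
  # sigma2 = 0 is tolerated as a degenerate simulation-only case (signal = trend
  # + nugget noise); estimation always works on the log scale, sigma2 > 0.
  if (!is.numeric(tau2) || length(tau2) != 1L || !is.finite(tau2) || tau2 < 0)
    stop("'tau2' (nugget) must be a single non-negative number", call. = FALSE)
  if (!is.numeric(phi) || length(phi) != 1L || !is.finite(phi) || phi <= 0)
    stop("'phi' (range) must be a single positive number", call. = FALSE)
  family <- match.arg(family, c("spherical", "exponential"))
  structure(
    list(beta = beta, sigma2 = unname(sigma2), tau2 = unname(tau2),
         phi = unname(phi), family = family),
    class = "glsm_params")
}

as.numeric_named <- function(x) {
  if (!is.numeric(x) || length(x) < 1L || any(!is.finite(x)))
    stop("'beta' must be a finite numeric vector", call. = FALSE)
  storage.mode(x) <- "double"
  x
}

#' @export
print.glsm_params <- function(x, ...) {
  cat("GLSM parameters (", x$family, " correlation)\n", sep = "")
  cat("  beta  :", paste(formatC(x$beta, digits = 4, format = "g"), collapse = ", "), "\n")
  cat(sprintf("  sigma2: %.4g  tau2: %.4g  phi: %.4g m\n", x$sigma2, x$tau2, x$phi))
  invisible(x)
}

#' Spatial correlation function
#'
#' Isotropic correlation at lag \code{h}. The spherical model is
#' \eqn{1 - 1.5 (h/\phi) + 0.5 (h/\phi)^3} for \eqn{h \le \phi} and 0 beyond;
#' the exponential model is \eqn{\exp(-h/\phi)}.
#'
#' @param h Non-negative lag distance(s), meters (vectorized).
#' @param phi Range parameter, meters.
#' @param family \code{"spherical"} or \code{"exponential"}.
#' @return Correlation value(s) in \[0, 1\]; \code{rho(0) = 1}.
#' @examples
#' spatial_correlation(c(0, 1707, 3414), phi = 3414)
#' @export
spatial_correlation <- function(h, phi, family = c("spherical", "exponential")) {
  family <- match.arg(family)
  if (any(h < 0)) stop("lag distances 'h' must be non-negative", call. = FALSE)
  if (phi <= 0) stop("'phi' must be positive", call. = FALSE)
  u <- h / phi
  switch(family,
    spherical   = ifelse(u >= 1, 0, 1 - 1.5 * u + 0.5 * u^3),
    exponential = exp(-u))
}

#' Covariance matrix of the latent signal at a set of locations
#'
#' Builds \eqn{C_{ij} = \sigma^2 \rho(h_{ij}; \phi)} off the diagonal and
#' \eqn{\sigma^2 + \tau^2} on it: the nugget acts only at lag zero. The two
#' submodel error processes are independent, so each process gets its own
#' matrix and the joint covariance is block diagonal by construction.
#'
#' @param coords Two-column matrix or data frame of (x, y) coordinates in
#'   meters; duplicate coordinates are rejected (they make kriging systems
#'   singular).
#' @param params A [glsm_params] object.
#' @return A symmetric n x n covariance matrix, positive definite whenever
#'   \code{tau2 > 0}.
#' @export
covariance_matrix <- function(coords, params) {
  stopifnot(inherits(params, "glsm_params"))
  coords <- as_coord_matrix(coords)
  n <- nrow(coords)
  if (n < 1L) stop("need at least one location", call. = FALSE)
  if (anyDuplicated(coords) > 0L)
    stop("duplicate coordinates are not allowed (singular covariance)", call. = FALSE)
  d <- as.matrix(stats::dist(coords))
  C <- params$sigma2 * spatial_correlation(d, params$phi, params$family)
  diag(C) <- params$sigma2 + params$tau2
  dimnames(C) <- NULL
  C
}

as_coord_matrix <- function(coords) {
  if (is.data.frame(coords)) {
    cn <- intersect(c("x", "y"), names(coords))
    coords <- if (length(cn) == 2L) as.matrix(coords[, c("x", "y")]) else as.matrix(coords)
  }
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L) stop("'coords' must have two columns (x, y)", call. = FALSE)
  storage.mode(coords) <- "double"
  unname(coords)
}

# Cross-covariance between prediction points and data points.
# Nugget contributes only where a prediction point coincides with a datum.
cross_covariance <- function(pred_coords, data_coords, params) {
  pred_coords <- as_coord_matrix(pred_coords)
  data_coords <- as_coord_matrix(data_coords)
  d <- euclid_cross(pred_coords, data_coords)
  C <- params$sigma2 * spatial_correlation(d, params$phi, params$family)
  C[d == 0] <- params$sigma2 + params$tau2
  C
}

euclid_cross <- function(a, b) {
  # pairwise distances, rows of a vs rows of b
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}
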