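# Shared fixtures, all built in code.

# Variogram/trend values of the published small-covariate-set calibration,
# used as realistic generating parameters for synthetic surveys.
theta_small_bernoulli <- function() {
  glsm_params(c("(Intercept)" = -0.765, silt = 0.819, altitude = 0.551,
                silt2 = -0.523),
              sigma2 = 0.145, tau2 = 0.164, phi = 21121, family = "spherical")
}
theta_small_poisson <- function() {
  glsm_params(c("(Intercept)" = 0.485, silt = 0.587, altitude = 0.280,
                silt2 = -0.222),
              sigma2 = 0.429, tau2 = 0.417, phi = 3414, family = "spherical")
}

# n random locations in a square domain (meters), no duplicates.
random_coords <- function(n, extent = 8000, seed = 1) {
  zipmap:::with_seed(seed, data.frame(x = stats::runif(n, 0, extent),
                                      y = stats::runif(n, 0, extent)))
}

# Intercept-only ZIP counts: structural-zero weight omega, Poisson mean mu.
sim_zip_counts <- function(n, omega, mu, seed = 1) {
  zipmap:::with_seed(seed, {
    present <- stats::rbinom(n, 1, 1 - omega)
    ifelse(present == 1, stats::rpois(n, mu), 0L)
  })
}

# Poisson GLSM survey at random locations with an intercept + one covariate.
sim_poisson_glsm <- function(n = 300, theta = NULL, extent = 8000, seed = 1) {
  if (is.null(theta))
    theta <- glsm_params(c("(Intercept)" = 0.5, z = 0.7),
                         sigma2 = 0.4, tau2 = 0.4, phi = 3000)
  xy <- random_coords(n, extent, seed)
  covs <- zipmap:::with_seed(seed + 500, data.frame(z = stats::rnorm(n)))
  m <- drop(zipmap:::trend_matrix(covs, theta$beta) %*% theta$beta)
  S <- zipmap:::with_seed(seed + 1000,
                          zipmap:::draw_mvn(m, as.matrix(xy), theta))
  y <- zipmap:::with_seed(seed + 1500, stats::rpois(n, exp(S)))
  list(y = y, coords = xy, covariates = covs, signal = S, theta = theta)
}
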