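test_that("signal log-density equals the exact multivariate normal", {
  # single standard-normal location
  p1 <- glsm_params(0, sigma2 = 0.6, tau2 = 0.4, phi = 1000)
  expect_equal(signal_logdensity(0, p1, data.frame(d = 0), rbind(c(0, 0))),
               log(1 / sqrt(2 * pi)), tolerance = 1e-9)
  # dense-inverse oracle on n = 6
  set.seed(201)
  xy <- random_coords(6, seed = 9)
  covs <- data.frame(z = rnorm(6))
  p <- glsm_params(c("(Intercept)" = 0.4, z = 0.7), sigma2 = 0.5,
                   tau2 = 0.3, phi = 2500)
  S <- rnorm(6)
  C <- covariance_matrix(xy, p)
  m <- drop(cbind(1, covs$z) %*% p$beta)
  oracle <- -3 * log(2 * pi) - 0.5 * log(det(C)) -
    0.5 * drop(t(S - m) %*% solve(C) %*% (S - m))
  expect_equal(signal_logdensity(S, p, covs, xy), oracle, tolerance = 1e-8)
})

test_that("the signal density integrates to one (bivariate importance check)", {
  set.seed(202)
  xy <- rbind(c(0, 0), c(1500, 800))
  covs <- data.frame(d = c(0, 0))
  p <- glsm_params(c("(Intercept)" = 0.3, d = 0), sigma2 = 0.5, tau2 = 0.2,
                   phi = 3000)
  # proposal: independent N(0.3, 2^2) per coordinate (known density)
  J <- 200000
  z <- matrix(rnorm(2 * J, mean = 0.3, sd = 2), J, 2)
  logf <- vapply(seq_len(J), function(j)
    signal_logdensity(z[j, ], p, covs, xy), numeric(1))
  logg <- rowSums(dnorm(z, 0.3, 2, log = TRUE))
  expect_equal(mean(exp(logf - logg)), 1, tolerance = 0.02)
})

test_that("the Monte Carlo likelihood ratio is exactly zero at theta0", {
  set.seed(203)
  xy <- random_coords(8, seed = 10)
  covs <- data.frame(z = rnorm(8))
  p0 <- glsm_params(c("(Intercept)" = 0.2, z = 0.5), sigma2 = 0.4,
                    tau2 = 0.4, phi = 3000)
  draws <- matrix(rnorm(40 * 8), 40, 8)
  expect_identical(as.numeric(mc_loglik(p0, draws, p0, covs, xy)), 0)
  # J = 1: the log ratio of the single draw, no averaging
  p1 <- glsm_params(c("(Intercept)" = 0.3, z = 0.5), sigma2 = 0.4,
                    tau2 = 0.4, phi = 3000)
  one <- draws[1, , drop = FALSE]
  expect_equal(as.numeric(mc_loglik(p1, one, p0, covs, xy)),
               signal_logdensity(one[1, ], p1, covs, xy) -
               signal_logdensity(one[1, ], p0, covs, xy), tolerance = 1e-12)
})

test_that("MC log-likelihood differences match the closed-form Gaussian likelihood", {
  # Gaussian responses: marginal likelihood of y is N(X beta, C + vI), and
  # the posterior of S is exactly MVN, so we can draw from it directly
  set.seed(204)
  n <- 20; v <- 0.4
  xy <- random_coords(n, seed = 11)
  covs <- data.frame(z = rnorm(n))
  X <- cbind(1, covs$z)
  p0 <- glsm_params(c("(Intercept)" = 0.5, z = 0.7), sigma2 = 0.5,
                    tau2 = 0.3, phi = 3000)
  m <- drop(X %*% p0$beta)
  C0 <- covariance_matrix(xy, p0)
  y <- drop(m + crossprod(chol(C0 + v * diag(n)), rnorm(n)))

  marginal_ll <- function(p) {
    C <- covariance_matrix(xy, p) + v * diag(n)
    mm <- drop(X %*% p$beta)
    -0.5 * n * log(2 * pi) - 0.5 * log(det(C)) -
      0.5 * drop(t(y - mm) %*% solve(C) %*% (y - mm))
  }
  # exact posterior draws of S under theta0
  post_cov <- C0 - C0 %*% solve(C0 + v * diag(n)) %*% C0
  post_mean <- m + drop(C0 %*% solve(C0 + v * diag(n), y - m))
  J <- 4000
  L <- chol(post_cov + 1e-10 * diag(n))
  draws <- matrix(rep(post_mean, each = J), J, n) +
    matrix(rnorm(J * n), J, n) %*% L

  for (p1 in list(
    glsm_params(c("(Intercept)" = 0.65, z = 0.7), 0.5, 0.3, 3000),
    glsm_params(c("(Intercept)" = 0.5, z = 0.7), 0.65, 0.3, 3000),
    glsm_params(c("(Intercept)" = 0.5, z = 0.7), 0.5, 0.3, 3600))) {
    got <- mc_loglik(p1, draws, p0, covs, xy)
    want <- marginal_ll(p1) - marginal_ll(p0)
    # MC standard error of the log of a mean of ratios (delta method)
    ld1 <- zipmap:::signal_logdensity_draws(draws, p1, covs, xy)
    ld0 <- zipmap:::signal_logdensity_draws(draws, p0, covs, xy)
    w <- exp(ld1 - ld0 - max(ld1 - ld0))
    se <- sd(w) / (mean(w) * sqrt(J))
    expect_lt(abs(as.numeric(got) - want), 3 * se + 0.01)
  }
})

test_that("the MC likelihood surface converges to the exact Gaussian surface in J", {
  set.seed(205)
  n <- 15; v <- 0.3
  xy <- random_coords(n, seed = 12)
  covs <- data.frame(z = rnorm(n))
  p0 <- glsm_params(c("(Intercept)" = 0.4, z = 0.6), sigma2 = 0.5,
                    tau2 = 0.3, phi = 3000)
  m <- drop(cbind(1, covs$z) %*% p0$beta)
  C0 <- covariance_matrix(xy, p0)
  y <- drop(m + crossprod(chol(C0 + v * diag(n)), rnorm(n)))
  post_cov <- C0 - C0 %*% solve(C0 + v * diag(n)) %*% C0
  post_mean <- m + drop(C0 %*% solve(C0 + v * diag(n), y - m))
  L <- chol(post_cov + 1e-10 * diag(n))
  mk_draws <- function(J) matrix(rep(post_mean, each = J), J, n) +
    matrix(rnorm(J * n), J, n) %*% L
  marg <- function(p) {
    C <- covariance_matrix(xy, p) + v * diag(n)
    mm <- drop(cbind(1, covs$z) %*% p$beta)
    -0.5 * log(det(C)) - 0.5 * drop(t(y - mm) %*% solve(C) %*% (y - mm))
  }
  # candidate parameter points around theta0
  cands <- list(
    glsm_params(c("(Intercept)" = 0.55, z = 0.6), 0.5, 0.3, 3000),
    glsm_params(c("(Intercept)" = 0.4, z = 0.75), 0.5, 0.3, 3000),
    glsm_params(c("(Intercept)" = 0.4, z = 0.6), 0.65, 0.3, 3000),
    glsm_params(c("(Intercept)" = 0.4, z = 0.6), 0.5, 0.4, 3000),
    glsm_params(c("(Intercept)" = 0.4, z = 0.6), 0.5, 0.3, 3700))
  rms <- vapply(c(50, 500), function(J) {
    # averaged over replicate draw sets to measure the Monte Carlo error
    errs <- vapply(1:5, function(rep) {
      d <- mk_draws(J)
      mean(vapply(cands, function(p1)
        (as.numeric(mc_loglik(p1, d, p0, covs, xy)) -
         (marg(p1) - marg(p0)))^2, numeric(1)))
    }, numeric(1))
    sqrt(mean(errs))
  }, numeric(1))
  expect_lt(rms[2], rms[1])    # 10x draws must shrink the surface error
})

test_that("MCML recovers Poisson GLSM parameters across seeds", {
  truth <- glsm_params(c("(Intercept)" = 0.5, z = 0.7), sigma2 = 0.4,
                       tau2 = 0.4, phi = 3000)
  ok <- logical(10)
  for (s in 1:10) {
    sim <- sim_poisson_glsm(300, theta = truth, seed = s)
    draws <- mala_sample(sim$y, truth, sim$covariates, sim$coords, "poisson",
                         n_iter = 3000, burn_in = 500, thin = 5,
                         seed = s + 100)
    r <- maximize_mcml(draws, truth, sim$covariates, sim$coords, maxit = 100)
    th <- r$theta_hat
    ok[s] <- all(abs(th$beta - truth$beta) < 0.3) &&
      th$sigma2 > 0.2 && th$sigma2 < 0.8 &&
      th$tau2 > 0.2 && th$tau2 < 0.8 &&
      th$phi > 1500 && th$phi < 6000
    expect_gte(r$mc_loglik_at_max, 0)
  }
  expect_gte(sum(ok), 8)
})

test_that("iterated calibration stabilizes the estimates", {
  truth <- glsm_params(c("(Intercept)" = 0.5, z = 0.7), sigma2 = 0.4,
                       tau2 = 0.4, phi = 3000)
  # single-cycle call is a plain MCMC+MCML pass
  sim1 <- sim_poisson_glsm(80, theta = truth, seed = 31)
  one <- calibrate_submodel(sim1$y, sim1$covariates, sim1$coords, truth,
                            "poisson", n_cycles = 1, n_iter = 1200,
                            burn_in = 300, thin = 6, seed = 1, maxit = 60)
  expect_length(one$cycle_thetas, 1)
  expect_identical(one$theta_hat, one$result$theta_hat)

  param_dist <- function(a, b)
    sqrt(sum((a$beta - b$beta)^2) + (log(a$sigma2) - log(b$sigma2))^2 +
         (log(a$tau2) - log(b$tau2))^2 + (log(a$phi) - log(b$phi))^2)
  d01 <- d12 <- d23 <- numeric(10)
  for (s in 1:10) {
    sim <- sim_poisson_glsm(150, theta = truth, seed = 40 + s)
    # start well away from the generating values: the first cycle has to
    # travel, later cycles only refine around the estimate
    start <- glsm_params(c("(Intercept)" = -0.5, z = 0), sigma2 = 0.05,
                         tau2 = 0.05, phi = 12000)
    cal <- suppressWarnings(
      calibrate_submodel(sim$y, sim$covariates, sim$coords, start,
                         "poisson", n_cycles = 3, n_iter = 3000,
                         burn_in = 300, thin = 6, seed = s, maxit = 100))
    d01[s] <- param_dist(start, cal$cycle_thetas[[1]])
    d12[s] <- param_dist(cal$cycle_thetas[[1]], cal$cycle_thetas[[2]])
    d23[s] <- param_dist(cal$cycle_thetas[[2]], cal$cycle_thetas[[3]])
  }
  # the first cycle moves the most in (nearly) every replicate, and the
  # average cycle-to-cycle change keeps shrinking afterwards
  expect_gte(sum(d12 < d01), 9)
  expect_lt(mean(d23), mean(d12))
})

test_that("model-comparison threshold is half a chi-squared quantile", {
  expect_equal(round(model_comparison_threshold(0.05, 5), 1), 5.5)
  expect_equal(round(model_comparison_threshold(0.05, 1), 1), 1.9)
  thr <- vapply(1:10, function(df) model_comparison_threshold(0.05, df),
                numeric(1))
  expect_true(all(diff(thr) > 0))
  expect_error(model_comparison_threshold(1.5, 5), "alpha")
})
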