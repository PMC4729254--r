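test_that("inverse distance weighting interpolates as defined", {
  pts <- data.frame(x = c(0, 1000, 2000), y = c(0, 0, 0),
                    value = c(1, 5, 9))
  # exactness at a data point
  expect_equal(idw_interpolate(pts, data.frame(x = 1000, y = 0)), 5)
  # symmetry: node equidistant from values 0 and 1
  pts2 <- data.frame(x = c(0, 1000), y = c(0, 0), value = c(0, 1))
  expect_equal(idw_interpolate(pts2, data.frame(x = 500, y = 0)), 0.5)
  # hand evaluation: distances (1, 2, 2), values (3, 0, 0), power 2
  pts3 <- data.frame(x = c(1, 2, -2), y = 0, value = c(3, 0, 0))
  expect_equal(idw_interpolate(pts3, data.frame(x = 0, y = 0), power = 2),
               3 / 1.5)
  # k limits the neighbourhood
  expect_equal(idw_interpolate(pts3, data.frame(x = 0, y = 0),
                               k_neighbors = 1), 3)
  expect_error(idw_interpolate(pts3[0, ], data.frame(x = 0, y = 0)), "empty")
})

test_that("kriging is exact at data points with zero nugget", {
  set.seed(301)
  xy <- random_coords(6, seed = 13)
  covs <- data.frame(z = rnorm(6))
  p <- glsm_params(c("(Intercept)" = 0.3, z = 0.6), sigma2 = 0.5, tau2 = 0,
                   phi = 4000)
  S <- drop(cbind(1, covs$z) %*% p$beta) +
    crossprod(chol(covariance_matrix(xy, p) + 1e-12 * diag(6)), rnorm(6))
  kr <- simple_krige_external_drift(S, p, covs, xy, covs, xy)
  expect_equal(kr$prediction, as.numeric(S), tolerance = 1e-6)
  expect_equal(kr$variance, rep(0, 6), tolerance = 1e-6)
})

test_that("beyond the spherical range prediction falls back to the drift", {
  covs <- data.frame(z = c(0.5, -0.2, 1))
  xy <- data.frame(x = c(0, 400, 800), y = c(0, 0, 0))
  p <- glsm_params(c("(Intercept)" = 0.3, z = 0.6), sigma2 = 0.5,
                   tau2 = 0.2, phi = 1000)
  far <- data.frame(x = 50000, y = 50000)
  farc <- data.frame(z = 2)
  kr <- simple_krige_external_drift(c(1, 0, -1), p, covs, xy, farc, far)
  expect_equal(kr$prediction, 0.3 + 0.6 * 2)
  expect_equal(kr$variance, 0.7)
})

test_that("kriging matches a brute-force dense-algebra oracle", {
  set.seed(302)
  xy <- random_coords(4, seed = 14)
  covs <- data.frame(z = rnorm(4))
  p <- glsm_params(c("(Intercept)" = 0.2, z = 0.5), sigma2 = 0.6,
                   tau2 = 0.3, phi = 3500)
  S <- rnorm(4)
  tc <- data.frame(x = 3000, y = 2500); tcv <- data.frame(z = 0.4)
  kr <- simple_krige_external_drift(S, p, covs, xy, tcv, tc)
  # oracle: explicit inverse, element-wise covariances
  C <- covariance_matrix(xy, p)
  h <- sqrt((xy$x - 3000)^2 + (xy$y - 2500)^2)
  cc <- p$sigma2 * spatial_correlation(h, p$phi, p$family)
  m <- drop(cbind(1, covs$z) %*% p$beta)
  m0 <- 0.2 + 0.5 * 0.4
  expect_equal(kr$prediction, m0 + drop(t(cc) %*% solve(C) %*% (S - m)),
               tolerance = 1e-10)
  expect_equal(kr$variance, 0.9 - drop(t(cc) %*% solve(C) %*% cc),
               tolerance = 1e-10)
  # variance bounded by the total signal variance
  expect_true(all(kr$variance >= 0 & kr$variance <= p$sigma2 + p$tau2))
})

test_that("the Taylor backtransform corrects for curvature", {
  # zero variance reduces to the plain inverse link
  expect_equal(taylor_backtransform(0, 0, "log"), 1)
  expect_equal(taylor_backtransform(0.7, 0, "logit"), plogis(0.7))
  # symmetry point of the logistic: second derivative vanishes
  expect_equal(taylor_backtransform(0, 0.5, "logit"), 0.5)
  # log link: e^S (1 + v/2)
  expect_equal(taylor_backtransform(0, 0.5, "log"), 1.25)
  expect_equal(taylor_backtransform(1, 0.8, "log"), exp(1) * 1.4)
  # logit output stays within [0, 1]
  out <- taylor_backtransform(seq(-6, 6, 0.2), 4, "logit")
  expect_true(all(out >= 0 & out <= 1))
  expect_error(taylor_backtransform(0, -1, "log"), "non-negative")
})

test_that("map stacks summarize realizations consistently", {
  set.seed(303)
  d <- generate_design(6, 6, 500, 0, seed = 15)
  g <- prediction_grid(d, spacing_m = 500)
  cv <- simulate_covariates(d, g, seed = 16)
  p_B <- glsm_params(c("(Intercept)" = -0.3, silt = 0.8), sigma2 = 0.15,
                     tau2 = 0.16, phi = 3000)
  p_P <- glsm_params(c("(Intercept)" = 0.4, silt = 0.6), sigma2 = 0.4,
                     tau2 = 0.4, phi = 3000)
  n <- 36
  draws_B <- matrix(rnorm(5 * n, 0, 0.3), 5, n)
  draws_P <- matrix(rnorm(5 * n, 0.4, 0.3), 5, n)
  xy <- d$all_locations
  maps <- build_maps(draws_B, draws_P, p_B, p_P,
                     cv$design_covariates, xy, cv$design_covariates, xy,
                     cv$grid, n_realizations = 5)
  s <- maps$summary
  expect_equal(s$prevalence, colMeans(maps$prevalence))
  expect_equal(s$intensity, colMeans(maps$intensity))
  expect_equal(s$unconditional, s$prevalence * s$intensity)
  expect_true(all(s$prevalence >= 0 & s$prevalence <= 1))
  expect_true(all(s$intensity > 0))
  expect_true(all(s$cv >= 0))

  # single realization: summaries equal it, CV identically zero
  m1 <- build_maps(draws_B[1, , drop = FALSE], draws_P[1, , drop = FALSE],
                   p_B, p_P, cv$design_covariates, xy, cv$design_covariates,
                   xy, cv$grid, n_realizations = 1)
  expect_equal(m1$summary$prevalence, as.numeric(m1$prevalence[1, ]))
  expect_equal(m1$summary$cv, rep(0, n))
  expect_equal(m1$summary$unconditional,
               m1$summary$unconditional_mean_of_products)

  # identical realizations: CV zero, product exact
  same_B <- draws_B[rep(1, 3), ]; same_P <- draws_P[rep(1, 3), ]
  m3 <- build_maps(same_B, same_P, p_B, p_P, cv$design_covariates, xy,
                   cv$design_covariates, xy, cv$grid, n_realizations = 3)
  expect_equal(max(m3$summary$cv), 0, tolerance = 1e-12)
  expect_equal(m3$summary$unconditional,
               m3$summary$prevalence * m3$summary$intensity)

  expect_error(build_maps(draws_B, draws_P, p_B, p_P, cv$design_covariates,
                          xy, cv$design_covariates, xy, cv$grid,
                          n_realizations = 50), "fewer")
})

test_that("kriged unconditional-intensity maps track the true surface", {
  # synthetic end-to-end: krige conditional draws of both true signals
  # to the grid and compare the mean product map with the truth
  ok <- logical(10)
  for (s in 1:10) {
    d <- generate_design(10, 20, 500, 0, seed = s)
    g <- prediction_grid(d, spacing_m = 700)
    cv <- simulate_covariates(d, g, seed = s + 50)
    p_B <- glsm_params(c("(Intercept)" = -0.3, silt = 0.9, altitude = 0.5),
                       sigma2 = 0.15, tau2 = 0.16, phi = 4000)
    p_P <- glsm_params(c("(Intercept)" = 0.5, silt = 0.6, altitude = 0.3),
                       sigma2 = 0.4, tau2 = 0.4, phi = 3400)
    sv <- simulate_survey(d, cv$design_covariates, p_B, p_P, seed = s + 100,
                          grid = cv$grid)
    xy <- d$all_locations
    # conditional draws of the signals given counts/presence
    s_B <- mala_sample(as.integer(sv$data$count > 0), p_B,
                       cv$design_covariates, xy, "bernoulli",
                       n_iter = 1200, burn_in = 300, thin = 40,
                       seed = s + 200)
    s_P <- mala_sample(sv$data$count, p_P, cv$design_covariates, xy,
                       "poisson", n_iter = 1200, burn_in = 300, thin = 40,
                       seed = s + 300)
    maps <- build_maps(s_B, s_P, p_B, p_P, cv$design_covariates, xy,
                       cv$design_covariates, xy, cv$grid,
                       n_realizations = 20)
    ok[s] <- cor(maps$summary$unconditional,
                 sv$truth_grid$unconditional) > 0.5
  }
  expect_gte(sum(ok), 8)
})
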