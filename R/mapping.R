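#' Inverse distance weighted interpolation
#'
#' Interpolates point values to grid nodes as
#' \eqn{\hat v(s_0) = \sum w_i v_i / \sum w_i} with weights
#' \eqn{w_i = d_i^{-p}} over the \code{k} nearest points; a node coinciding
#' with a data point returns that point's value exactly. Used to carry
#' point-measured covariates (e.g. sediment texture) onto the prediction
#' grid.
#'
#' @param points Data frame with columns x, y and \code{value}.
#' @param targets Data frame/matrix of target coordinates (x, y), or a
#'   [prediction_grid].
#' @param power Weighting exponent (default 2).
#' @param k_neighbors Number of nearest points used (default 12).
#' @return Numeric vector of interpolated values, one per target.
#' @export
idw_interpolate <- function(points, targets, power = 2, k_neighbors = 12L) {
  if (NROW(points) < 1L) stop("empty point set", call. = FALSE)
  if (k_neighbors < 1L) stop("'k_neighbors' must be >= 1", call. = FALSE)
  if (inherits(targets, "prediction_grid")) targets <- targets$nodes
  pxy <- as_coord_matrix(points[, c("x", "y")])
  v <- points$value
  txy <- as_coord_matrix(targets[, c("x", "y"), drop = FALSE])
  D <- euclid_cross(txy, pxy)
  k <- min(k_neighbors, nrow(pxy))
  apply_rows <- function(i) {
    d <- D[i, ]
    nn <- order(d)[seq_len(k)]
    dn <- d[nn]
    if (dn[1] == 0) return(v[nn[1]])
    w <- dn^(-power)
    sum(w * v[nn]) / sum(w)
  }
  vapply(seq_len(nrow(txy)), apply_rows, numeric(1))
}

#' Simple kriging with an external drift
#'
#' Predicts the latent signal at target locations from one realization of the
#' signal at the data locations. The drift \eqn{m(s) = x(s)'\hat\beta} is
#' treated as known (plug-in trend), and the residual is kriged:
#' \deqn{\hat S(s_0) = m(s_0) + c' C^{-1} (S - m), \qquad
#'       v(s_0) = \sigma^2 + \tau^2 - c' C^{-1} c,}
#' with \eqn{C} the data covariance and \eqn{c} the cross-covariances
#' \eqn{\sigma^2 \rho(h)} (plus nugget at lag zero). With zero nugget the
#' predictor is exact at data locations; beyond the spherical range the
#' prediction falls back to the drift with variance \eqn{\sigma^2 + \tau^2}.
#'
#' @param signal Numeric vector: one signal realization at the data
#'   locations.
#' @param params [glsm_params] (supplies \eqn{\beta}, \eqn{\sigma^2},
#'   \eqn{\tau^2}, \eqn{\phi}, family).
#' @param data_covariates,data_coords Covariates and coordinates of the data
#'   locations.
#' @param target_covariates,target_coords Covariates and coordinates of the
#'   prediction targets.
#' @return List with \code{prediction} and \code{variance}, one value per
#'   target.
#' @export
simple_krige_external_drift <- function(signal, params, data_covariates,
                                        data_coords, target_covariates,
                                        target_coords) {
  X_d <- trend_matrix(data_covariates, params$beta)
  X_t <- trend_matrix(target_covariates, params$beta)
  m_d <- drop(X_d %*% params$beta)
  m_t <- drop(X_t %*% params$beta)
  C <- covariance_matrix(data_coords, params)
  U <- tryCatch(chol(C), error = function(e)
    stop("singular kriging system: ", conditionMessage(e), call. = FALSE))
  cc <- cross_covariance(target_coords, data_coords, params)  # n_t x n_d
  # C^{-1} c' and C^{-1} (S - m) via one factorization
  A <- backsolve(U, forwardsolve(t(U), t(cc)))                # n_d x n_t
  pred <- unname(m_t + drop(crossprod(A, signal - m_d)))
  v <- params$sigma2 + params$tau2 - colSums(t(cc) * A)
  list(prediction = pred, variance = unname(pmax(v, 0)))
}

#' Second-order Taylor backtransform of a kriged signal
#'
#' Converts a predicted signal and its kriging variance to the parameter
#' scale, correcting for the curvature of the inverse link:
#' \eqn{g^{-1}(\hat S) + \frac{1}{2} (g^{-1})''(\hat S) v}. For the log link
#' this is \eqn{e^{\hat S}(1 + v/2)}; for the logit link,
#' \eqn{p + p(1-p)(1-2p) v/2} with \eqn{p = \mathrm{logistic}(\hat S)},
#' clamped to \[0, 1\].
#'
#' @param prediction Predicted signal(s).
#' @param variance Kriging variance(s), >= 0.
#' @param link \code{"log"} (intensity) or \code{"logit"} (prevalence).
#' @return Backtransformed value(s) on the parameter scale.
#' @export
taylor_backtransform <- function(prediction, variance, link = c("log", "logit")) {
  link <- match.arg(link)
  if (any(variance < 0)) stop("'variance' must be non-negative", call. = FALSE)
  if (link == "log") {
    exp(prediction) * (1 + variance / 2)
  } else {
    p <- stats::plogis(prediction)
    pmin(pmax(p + p * (1 - p) * (1 - 2 * p) * variance / 2, 0), 1)
  }
}

#' Krige realizations of both processes to a grid and assemble maps
#'
#' Takes the retained MCMC draws of the Bernoulli and Poisson signals at the
#' data locations, kriges the first \code{n_realizations} of each to the
#' prediction grid ([simple_krige_external_drift]) and backtransforms them
#' ([taylor_backtransform]). Summaries: the prevalence and intensity maps are
#' pixel-wise means over realizations; the unconditional-intensity map is the
#' pixel-wise product of those two mean maps; the coefficient-of-variation
#' map is the per-pixel SD/mean of the per-realization prevalence x intensity
#' products (the mean of those products is stored too).
#'
#' @param sample_B,sample_P [mala_sample] results for the Bernoulli process
#'   (all survey locations) and Poisson process (Poisson subset).
#' @param params_B,params_P Final [glsm_params] of the two submodels.
#' @param covariates_B,coords_B,covariates_P,coords_P Covariates/coordinates
#'   backing each sample's locations.
#' @param grid A [prediction_grid] carrying the model covariates at its
#'   nodes.
#' @param n_realizations Number of realizations kriged per process
#'   (default 100).
#' @return An object of class \code{"map_stack"}: per-realization matrices
#'   \code{prevalence}, \code{intensity} (n_realizations x nodes) and a
#'   \code{summary} data frame with x, y, \code{prevalence},
#'   \code{intensity}, \code{unconditional} (product of means),
#'   \code{unconditional_mean_of_products} and \code{cv}.
#' @export
build_maps <- function(sample_B, sample_P, params_B, params_P,
                       covariates_B, coords_B, covariates_P, coords_P,
                       grid, n_realizations = 100L) {
  d_B <- if (inherits(sample_B, "signal_sample")) sample_B$draws else sample_B
  d_P <- if (inherits(sample_P, "signal_sample")) sample_P$draws else sample_P
  if (nrow(d_B) < n_realizations || nrow(d_P) < n_realizations)
    stop("fewer retained draws than 'n_realizations'", call. = FALSE)
  nodes <- grid$nodes
  n_g <- nrow(nodes)

  krige_stack <- function(draws, params, covs, coords, link) {
    X_d <- trend_matrix(covs, params$beta)
    m_d <- drop(X_d %*% params$beta)
    m_t <- drop(trend_matrix(nodes, params$beta) %*% params$beta)
    C <- covariance_matrix(coords, params)
    U <- chol(C)
    cc <- cross_covariance(nodes[, c("x", "y")], coords, params)
    A <- backsolve(U, forwardsolve(t(U), t(cc)))
    v <- pmax(params$sigma2 + params$tau2 - colSums(t(cc) * A), 0)
    out <- matrix(NA_real_, n_realizations, n_g)
    for (j in seq_len(n_realizations)) {
      pred <- m_t + drop(crossprod(A, draws[j, ] - m_d))
      out[j, ] <- taylor_backtransform(pred, v, link)
    }
    out
  }

  prev <- krige_stack(d_B, params_B, covariates_B, coords_B, "logit")
  inten <- krige_stack(d_P, params_P, covariates_P, coords_P, "log")

  prev_mean <- colMeans(prev)
  inten_mean <- colMeans(inten)
  prod_real <- prev * inten                   # per-realization pi x mu
  prod_mean <- colMeans(prod_real)
  prod_sd <- apply(prod_real, 2, stats::sd)
  cv <- ifelse(prod_mean > 0, prod_sd / prod_mean, 0)
  if (n_realizations == 1L) cv <- rep(0, n_g)

  summary <- data.frame(
    x = nodes$x, y = nodes$y,
    prevalence = prev_mean, intensity = inten_mean,
    unconditional = prev_mean * inten_mean,
    unconditional_mean_of_products = prod_mean,
    cv = cv)
  structure(list(prevalence = prev, intensity = inten, summary = summary,
                 n_realizations = as.integer(n_realizations)),
            class = "map_stack")
}

#' @export
print.map_stack <- function(x, ...) {
  s <- x$summary
  cat("Map stack:", nrow(s), "grid nodes,", x$n_realizations,
      "realizations\n")
  cat(sprintf("  prevalence %.3f-%.3f (mean %.3f); intensity %.2f-%.2f (mean %.2f)\n",
              min(s$prevalence), max(s$prevalence), mean(s$prevalence),
              min(s$intensity), max(s$intensity), mean(s$intensity)))
  cat(sprintf("  unconditional intensity mean %.2f; CV mean %.2f\n",
              mean(s$unconditional), mean(s$cv)))
  invisible(x)
}
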