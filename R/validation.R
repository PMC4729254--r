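#' Leave-one-out kriging predictions at the data locations
#'
#' For each data location \eqn{i}, the signal there is held back and kriged
#' (simple kriging with external drift, the same engine as the mapping step)
#' from the remaining \eqn{n - 1} locations. Computed through the precision
#' matrix: with \eqn{Q = C^{-1}} and residual \eqn{r = S - X\beta}, the
#' held-out prediction is \eqn{m_i + r_i - (Qr)_i / Q_{ii}} with variance
#' \eqn{1 / Q_{ii}}, identical to re-solving each reduced kriging system.
#'
#' @param signal Signal values at the data locations (the per-location
#'   posterior-mean signal is the reproducible choice).
#' @param params [glsm_params] of the submodel.
#' @param covariates,coords Covariates and coordinates of the data locations.
#' @return List with \code{prediction} and \code{variance} per location.
#' @export
loo_predict <- function(signal, params, covariates, coords) {
  cmat <- as_coord_matrix(coords)
  n <- nrow(cmat)
  if (n < 3L) stop("need at least 3 locations for leave-one-out",
                   call. = FALSE)
  X <- trend_matrix(covariates, params$beta)
  m <- drop(X %*% params$beta)
  if (params$sigma2 == 0) {
    # pure-nugget limit: no information from neighbours, prediction = drift
    return(list(prediction = m, variance = rep(params$tau2, n)))
  }
  C <- covariance_matrix(cmat, params)
  Q <- tryCatch(chol2inv(chol(C)), error = function(e)
    stop("singular leave-one-out system: ", conditionMessage(e),
         call. = FALSE))
  r <- signal - m
  u <- drop(Q %*% r)
  qd <- diag(Q)
  list(prediction = m + r - u / qd, variance = 1 / qd)
}

#' Confusion matrix and accuracy measures for a binary prevalence map
#'
#' Thresholds predicted prevalence at \code{threshold} (default 0.5) and
#' cross-tabulates against the observed class. With cells a (pred 1, obs 1),
#' b (pred 1, obs 0), c (pred 0, obs 1), d (pred 0, obs 0):
#' overall accuracy (a+d)/n; user's accuracies a/(a+b) and d/(c+d) (rows =
#' predictions); producer's accuracies a/(a+c) and d/(b+d) (columns =
#' observations). Empty denominators yield \code{NA} and a flag, never 0.
#'
#' @param predicted_prevalence Predicted prevalence per location, in \[0,1\].
#' @param observed_binary Observed class per location (0/1 or logical).
#' @param threshold Classification threshold in (0,1).
#' @return List of class \code{"confusion_metrics"} with the
#'   \code{confusion} cells (a, b, c, d) and the five accuracies.
#' @export
confusion_metrics <- function(predicted_prevalence, observed_binary,
                              threshold = 0.5) {
  if (length(predicted_prevalence) != length(observed_binary))
    stop("inputs must have equal length", call. = FALSE)
  if (threshold <= 0 || threshold >= 1)
    stop("'threshold' must be in (0,1)", call. = FALSE)
  pred <- as.integer(predicted_prevalence >= threshold)
  obs <- as.integer(observed_binary != 0)
  a <- sum(pred == 1 & obs == 1)
  b <- sum(pred == 1 & obs == 0)
  c_ <- sum(pred == 0 & obs == 1)
  d <- sum(pred == 0 & obs == 0)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- list(
    confusion = c(a = a, b = b, c = c_, d = d),
    overall_accuracy = (a + d) / (a + b + c_ + d),
    users_accuracy_1 = safe_div(a, a + b),
    users_accuracy_0 = safe_div(d, c_ + d),
    producers_accuracy_1 = safe_div(a, a + c_),
    producers_accuracy_0 = safe_div(d, b + d),
    threshold = threshold)
  out$undefined <- names(which(vapply(out[2:6], is.na, logical(1))))
  class(out) <- "confusion_metrics"
  out
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cm <- x$confusion
  cat("Confusion matrix (rows = prediction, columns = observation):\n")
  m <- matrix(cm[c("a", "b", "c", "d")], 2, 2, byrow = TRUE,
              dimnames = list(pred = c("1", "0"), obs = c("1", "0")))
  print(m)
  cat(sprintf("overall %.3f; user's (1) %.3f, (0) %.3f; producer's (1) %.3f, (0) %.3f\n",
              x$overall_accuracy, x$users_accuracy_1, x$users_accuracy_0,
              x$producers_accuracy_1, x$producers_accuracy_0))
  invisible(x)
}

#' Mean error and mean squared error
#'
#' \code{ME = mean(pred - obs)} (signed bias) and
#' \code{MSE = mean((pred - obs)^2)}.
#'
#' @param predicted,observed Equal-length numeric vectors.
#' @return Named list with \code{me} and \code{mse}.
#' @export
error_metrics <- function(predicted, observed) {
  if (length(predicted) == 0L || length(predicted) != length(observed))
    stop("inputs must be non-empty and of equal length", call. = FALSE)
  e <- predicted - observed
  list(me = mean(e), mse = mean(e^2))
}

#' Stability of maps across replicate zero-classification seeds
#'
#' Repeating the whole calibration + prediction with different random
#' classifications of the zeros should leave the maps essentially unchanged.
#' Given two or more [build_maps] results on the same grid, computes pairwise
#' Pearson correlations per map quantity (prevalence, intensity,
#' unconditional intensity) and the mean per-pixel within-replicate variance.
#'
#' @param replicates List of >= 2 \code{map_stack} objects sharing a grid.
#' @return List of class \code{"replication_stability"}: per quantity, the
#'   min/max/mean pairwise correlation and the mean per-pixel variance across
#'   replicates.
#' @export
replication_stability <- function(replicates) {
  if (length(replicates) < 2L) stop("need >= 2 replicates", call. = FALSE)
  sums <- lapply(replicates, function(r)
    if (inherits(r, "map_stack")) r$summary else r)
  n <- nrow(sums[[1]])
  if (!all(vapply(sums, nrow, integer(1)) == n) ||
      !all(vapply(sums, function(s)
        isTRUE(all.equal(s$x, sums[[1]]$x)) &&
        isTRUE(all.equal(s$y, sums[[1]]$y)), logical(1))))
    stop("replicates must share the same grid", call. = FALSE)
  quantities <- c(prevalence = "prevalence", intensity = "intensity",
                  unconditional = "unconditional")
  out <- lapply(quantities, function(q) {
    M <- vapply(sums, function(s) s[[q]], numeric(n))  # pixels x replicates
    flagged <- any(apply(M, 2, stats::sd) == 0)
    pairs <- utils::combn(ncol(M), 2)
    cors <- apply(pairs, 2, function(ij) {
      if (stats::sd(M[, ij[1]]) == 0 || stats::sd(M[, ij[2]]) == 0)
        return(NA_real_)
      stats::cor(M[, ij[1]], M[, ij[2]])
    })
    list(min_correlation = min(cors), max_correlation = max(cors),
         mean_correlation = mean(cors),
         mean_within_variance = mean(apply(M, 1, stats::var)),
         constant_map_flagged = flagged)
  })
  structure(out, class = "replication_stability")
}

#' @export
print.replication_stability <- function(x, ...) {
  for (q in names(x)) {
    cat(sprintf("%-13s correlation %.3f-%.3f (mean %.3f); within-variance %.3g\n",
                q, x[[q]]$min_correlation, x[[q]]$max_correlation,
                x[[q]]$mean_correlation, x[[q]]$mean_within_variance))
  }
  invisible(x)
}

#' Leave-one-out validation report for a calibrated model
#'
#' Runs [loo_predict] for both submodels on their posterior-mean signals,
#' backtransforms the held-out predictions, and assembles the map-quality
#' measures: the prevalence confusion matrix and accuracies (observed class =
#' raw presence, \code{count > 0}, by default; the stochastic classification
#' indicator behind \code{observed = "indicator"}), ME/MSE of intensity
#' against counts on the Poisson subset, and ME/MSE of the unconditional
#' intensity against raw counts at all locations.
#'
#' @param data Survey data frame (x, y, count, covariates).
#' @param classified [classify_zeros] result.
#' @param calib_B,calib_P [calibrate_submodel] results for the two submodels.
#' @param threshold Prevalence classification threshold (default 0.5).
#' @param observed Observed class for the confusion matrix:
#'   \code{"presence"} (count > 0) or \code{"indicator"} (stochastic
#'   classification).
#' @return List of class \code{"validation_report"}: \code{prevalence}
#'   ([confusion_metrics]), \code{intensity} and \code{unconditional}
#'   (ME/MSE), plus the held-out predictions.
#' @export
validate_loo <- function(data, classified, calib_B, calib_P, threshold = 0.5,
                         observed = c("presence", "indicator")) {
  observed <- match.arg(observed)
  coords <- data[, c("x", "y")]
  sub <- classified$poisson_subset

  s_B <- colMeans(calib_B$sample$draws)
  s_P <- colMeans(calib_P$sample$draws)
  loo_B <- loo_predict(s_B, calib_B$theta_hat, data, coords)
  loo_P <- loo_predict(s_P, calib_P$theta_hat, data[sub, , drop = FALSE],
                       coords[sub, , drop = FALSE])
  prev_hat <- taylor_backtransform(loo_B$prediction, loo_B$variance, "logit")
  inten_hat <- taylor_backtransform(loo_P$prediction, loo_P$variance, "log")

  obs_bin <- if (observed == "presence") as.integer(data$count > 0)
             else classified$indicator
  cm <- confusion_metrics(prev_hat, obs_bin, threshold)
  em_int <- error_metrics(inten_hat, data$count[sub])
  # unconditional intensity at every location: held-out prevalence times the
  # full-data intensity surface (intensity LOO exists only on the subset)
  full_int <- rep(NA_real_, nrow(data))
  full_int[sub] <- inten_hat
  outside <- setdiff(seq_len(nrow(data)), sub)
  if (length(outside)) {
    kr <- simple_krige_external_drift(
      s_P, calib_P$theta_hat, data[sub, , drop = FALSE],
      coords[sub, , drop = FALSE], data[outside, , drop = FALSE],
      coords[outside, , drop = FALSE])
    full_int[outside] <- taylor_backtransform(kr$prediction, kr$variance, "log")
  }
  uncond <- prev_hat * full_int
  em_unc <- error_metrics(uncond, data$count)

  structure(list(
    prevalence = cm,
    intensity = em_int,
    unconditional = em_unc,
    loo = list(prevalence = prev_hat, intensity = inten_hat,
               unconditional = uncond),
    observed_class = observed),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Leave-one-out validation (observed class:", x$observed_class, ")\n")
  print(x$prevalence)
  cat(sprintf("intensity      ME %+.3f  MSE %.3f\n",
              x$intensity$me, x$intensity$mse))
  cat(sprintf("unconditional  ME %+.3f  MSE %.3f\n",
              x$unconditional$me, x$unconditional$mse))
  invisible(x)
}
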