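# Trend design matrix for a GLSM: intercept column plus the covariate
# columns named by beta. An unnamed length-1 beta means intercept only.
trend_matrix <- function(covariates, beta) {
  nm <- names(beta)
  if (is.null(nm)) {
    if (length(beta) == 1L) return(matrix(1, nrow = max(1L, NROW(covariates)),
                                          dimnames = list(NULL, "(Intercept)")))
    stop("'beta' must be named (except for a single intercept)", call. = FALSE)
  }
  covs <- setdiff(nm, "(Intercept)")
  missing <- setdiff(covs, colnames(covariates))
  if (length(missing))
    stop("covariate column(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  X <- cbind(1, as.matrix(covariates[, covs, drop = FALSE]))
  colnames(X) <- c("(Intercept)", covs)
  if (!identical(nm[1], "(Intercept)"))
    stop("the first element of 'beta' must be the intercept '(Intercept)'",
         call. = FALSE)
  X
}

#' Simulate a zero-inflated Poisson survey with spatially correlated signals
#'
#' Generates ground-truth data under the full model: two independent latent
#' Gaussian signals are drawn at all design locations,
#' \eqn{S_B \sim N(X_B \beta_B, C_B)} (logit scale) and
#' \eqn{S_P \sim N(X_P \beta_P, C_P)} (log scale), each covariance built from
#' the partial sill, nugget and range of its parameter set. Presence is
#' Bernoulli with prevalence \eqn{\pi = \mathrm{logistic}(S_B)}; counts are 0
#' where the species is absent and Poisson with intensity
#' \eqn{\mu = \exp(S_P)} where present. Structural (true) zeros are therefore
#' a subset of all observed zeros.
#'
#' @param design A [generate_design] result.
#' @param covariates Data frame of covariate values at the design locations
#'   (e.g. \code{design_covariates} from [simulate_covariates]).
#' @param theta_B,theta_P [glsm_params] for the Bernoulli (prevalence) and
#'   Poisson (intensity) processes. \code{beta} entries are matched to
#'   covariate columns by name; the prevalence convention is used throughout:
#'   \code{logistic(S_B)} is the probability of presence.
#' @param seed Integer seed.
#' @param grid Optional [prediction_grid] whose nodes carry the covariates
#'   named by both parameter sets: the latent fields are then simulated
#'   jointly at design locations and grid nodes, so the ground-truth
#'   prevalence/intensity surface at the nodes is returned too (for
#'   map-recovery checks).
#' @return A list of class \code{"zip_survey"} with elements
#'   \describe{
#'     \item{data}{the observed survey: data frame with x, y, count and the
#'       covariate columns (what a real survey would provide);}
#'     \item{truth}{the generative state: signals \code{signal_B},
#'       \code{signal_P}, \code{prevalence}, \code{intensity},
#'       \code{presence}, and the two parameter sets;}
#'     \item{truth_grid}{(only with \code{grid}) the true \code{prevalence},
#'       \code{intensity} and \code{unconditional} surface at the grid
#'       nodes.}
#'   }
#' @export
simulate_survey <- function(design, covariates, theta_B, theta_P, seed = 1L,
                            grid = NULL) {
  stopifnot(inherits(theta_B, "glsm_params"), inherits(theta_P, "glsm_params"))
  loc <- design$all_locations
  n <- nrow(loc)
  if (n != nrow(covariates))
    stop("covariate table does not match the design size", call. = FALSE)

  all_cov <- covariates
  all_xy <- loc
  if (!is.null(grid)) {
    gnodes <- grid$nodes
    all_cov <- rbind(covariates[, names(covariates), drop = FALSE],
                     gnodes[, names(covariates), drop = FALSE])
    all_xy <- rbind(loc, gnodes[, c("x", "y")])
  }
  # grid nodes may coincide with design locations: simulate each unique
  # coordinate once and share the value
  key <- paste(all_xy$x, all_xy$y, sep = "_")
  uniq <- !duplicated(key)
  idx <- match(key, key[uniq])
  coords <- as_coord_matrix(all_xy[uniq, ])
  ucov <- all_cov[uniq, , drop = FALSE]

  X_B <- trend_matrix(ucov, theta_B$beta)
  X_P <- trend_matrix(ucov, theta_P$beta)

  sim <- with_seed(seed, {
    S_B <- draw_mvn(drop(X_B %*% theta_B$beta), coords, theta_B)[idx]
    S_P <- draw_mvn(drop(X_P %*% theta_P$beta), coords, theta_P)[idx]
    presence <- stats::rbinom(n, 1L, stats::plogis(S_B[seq_len(n)]))
    counts <- integer(n)
    on <- presence == 1L
    counts[on] <- stats::rpois(sum(on), exp(S_P[seq_len(n)][on]))
    list(S_B = S_B, S_P = S_P, presence = presence, counts = counts)
  })

  data <- cbind(loc, count = sim$counts, covariates)
  rownames(data) <- NULL
  out <- list(
    data = data,
    truth = list(signal_B = sim$S_B[seq_len(n)],
                 signal_P = sim$S_P[seq_len(n)],
                 prevalence = stats::plogis(sim$S_B[seq_len(n)]),
                 intensity = exp(sim$S_P[seq_len(n)]),
                 presence = sim$presence,
                 theta_B = theta_B, theta_P = theta_P))
  if (!is.null(grid)) {
    gi <- seq.int(n + 1L, nrow(all_xy))
    prev <- stats::plogis(sim$S_B[gi])
    inten <- exp(sim$S_P[gi])
    out$truth_grid <- data.frame(
      x = all_xy$x[gi], y = all_xy$y[gi],
      prevalence = prev, intensity = inten,
      unconditional = prev * inten)
  }
  structure(out, class = "zip_survey")
}

#' @export
print.zip_survey <- function(x, ...) {
  n <- nrow(x$data)
  cat("Simulated ZIP survey:", n, "locations;",
      sprintf("%.1f%% zeros;", 100 * mean(x$data$count == 0)),
      "mean count", sprintf("%.2f", mean(x$data$count)), "\n")
  invisible(x)
}

# Exact MVN draw: mean + L' z with C = L'L (upper-triangular chol).
draw_mvn <- function(mean, coords, params) {
  if (params$sigma2 + params$tau2 == 0) return(mean)  # degenerate: trend only
  if (params$sigma2 == 0)                             # pure nugget
    return(mean + stats::rnorm(nrow(coords), sd = sqrt(params$tau2)))
  C <- covariance_matrix(coords, params)
  L <- tryCatch(chol(C), error = function(e)
    stop("covariance matrix is not positive definite (sigma2 = ",
         params$sigma2, ", tau2 = ", params$tau2, ", phi = ", params$phi,
         "): ", conditionMessage(e), call. = FALSE))
  drop(mean + crossprod(L, stats::rnorm(nrow(C))))
}
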