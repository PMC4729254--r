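#' Generate a survey design: square grid plus supplementary points
#'
#' Emulates a benthic monitoring design: sampling locations on the nodes of a
#' square grid of given spacing, supplemented by points placed at a fixed
#' offset distance from randomly chosen grid nodes. Parent nodes are drawn by
#' simple random sampling without replacement and each supplementary point is
#' offset in one of the four grid directions (+x, -x, +y, -y), chosen
#' uniformly. A direction that would collide with an existing location is
#' re-drawn, so all coordinates are unique.
#'
#' @param n_rows,n_cols Grid dimensions (numbers of rows and columns of nodes).
#' @param spacing_m Grid spacing in meters (e.g. 500).
#' @param n_supplementary Number of supplementary points (must not exceed the
#'   number of grid nodes).
#' @param offset_m Offset distance in meters from the parent node (e.g. 250);
#'   must be smaller than the spacing.
#' @param seed Integer seed; the design is reproducible under it.
#'
#' @return An object of class \code{"survey_design"}: a list with data frames
#'   \code{grid_nodes} (x, y), \code{supplementary} (x, y, parent index,
#'   direction) and \code{all_locations} (x, y), the concatenation of both.
#' @examples
#' d <- generate_design(10, 10, 500, n_supplementary = 20, offset_m = 250, seed = 1)
#' nrow(d$all_locations)  # 120
#' @export
generate_design <- function(n_rows, n_cols, spacing_m, n_supplementary = 0L,
                            offset_m = spacing_m / 2, seed = 1L) {
  if (spacing_m <= 0) stop("'spacing_m' must be positive", call. = FALSE)
  if (offset_m <= 0 || offset_m >= spacing_m)
    stop("'offset_m' must be in (0, spacing_m)", call. = FALSE)
  n_nodes <- as.integer(n_rows) * as.integer(n_cols)
  if (n_supplementary > n_nodes)
    stop("'n_supplementary' exceeds the number of grid nodes", call. = FALSE)

  nodes <- expand.grid(
    x = seq_len(n_cols) * spacing_m - spacing_m,
    y = seq_len(n_rows) * spacing_m - spacing_m,
    KEEP.OUT.ATTRS = FALSE)
  nodes <- nodes[order(nodes$y, nodes$x), , drop = FALSE]
  rownames(nodes) <- NULL

  supp <- data.frame(x = numeric(0), y = numeric(0),
                     parent = integer(0), direction = character(0),
                     stringsAsFactors = FALSE)
  if (n_supplementary > 0L) {
    with_seed(seed, {
      parents <- sample.int(n_nodes, n_supplementary, replace = FALSE)
      dirs <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
      dir_names <- c("+x", "-x", "+y", "-y")
      taken <- nodes
      xs <- ys <- numeric(n_supplementary)
      dn <- character(n_supplementary)
      for (k in seq_len(n_supplementary)) {
        g <- as.numeric(nodes[parents[k], ])
        repeat {
          j <- sample.int(4L, 1L)
          p <- g + offset_m * dirs[j, ]
          clash <- any(taken$x == p[1] & taken$y == p[2])
          if (!clash) break
        }
        xs[k] <- p[1]; ys[k] <- p[2]; dn[k] <- dir_names[j]
        taken <- rbind(taken, data.frame(x = p[1], y = p[2]))
      }
      supp <- data.frame(x = xs, y = ys, parent = parents, direction = dn,
                          stringsAsFactors = FALSE)
    })
  }

  all_loc <- rbind(nodes, supp[, c("x", "y")])
  rownames(all_loc) <- NULL
  structure(
    list(grid_nodes = nodes, supplementary = supp, all_locations = all_loc,
         spacing_m = spacing_m, offset_m = offset_m),
    class = "survey_design")
}

#' @export
print.survey_design <- function(x, ...) {
  cat("Survey design:", nrow(x$grid_nodes), "grid nodes at", x$spacing_m,
      "m spacing +", nrow(x$supplementary), "supplementary points at",
      x$offset_m, "m offset\n")
  invisible(x)
}

# Run expr under a local RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

#' Build a square prediction grid over a design's bounding box
#'
#' @param design A [generate_design] result (or any object with an
#'   \code{all_locations} data frame).
#' @param spacing_m Node spacing of the prediction grid in meters
#'   (default 100).
#' @param expand_m Margin added around the design bounding box, meters.
#' @return An object of class \code{"prediction_grid"}: data frame of node
#'   coordinates plus the spacing; covariate columns are attached by
#'   [simulate_covariates] or by the user.
#' @export
prediction_grid <- function(design, spacing_m = 100, expand_m = 0) {
  if (spacing_m <= 0) stop("'spacing_m' must be positive", call. = FALSE)
  loc <- design$all_locations
  nodes <- expand.grid(
    x = seq(min(loc$x) - expand_m, max(loc$x) + expand_m, by = spacing_m),
    y = seq(min(loc$y) - expand_m, max(loc$y) + expand_m, by = spacing_m),
    KEEP.OUT.ATTRS = FALSE)
  structure(list(nodes = nodes, spacing_m = spacing_m),
            class = "prediction_grid")
}

#' @export
print.prediction_grid <- function(x, ...) {
  cat("Prediction grid:", nrow(x$nodes), "nodes at", x$spacing_m, "m spacing;",
      length(setdiff(names(x$nodes), c("x", "y"))), "covariate columns\n")
  invisible(x)
}

#' Simulate smooth covariate fields over a design and prediction grid
#'
#' Stands in for measured environmental covariates (e.g. silt content, median
#' grain size, tidal-flat altitude): each covariate is one realization of a
#' stationary Gaussian random field, drawn jointly at all design locations and
#' grid nodes by covariance-matrix factorization (exact at desk scale).
#' Covariates are scaled -- demeaned and divided by the standard deviation
#' computed over the design locations -- and squared terms plus standardized
#' coordinates (\code{east}, \code{north}) are added, so quadratic trend
#' models can be fitted directly.
#'
#' @param design A [generate_design] result.
#' @param grid Optional [prediction_grid]; covariate values are simulated at
#'   its nodes from the same field realization.
#' @param field_params Named list; one entry per covariate, each a list with
#'   elements \code{range} (meters, > 0), \code{variance} (> 0) and optional
#'   \code{family} (default \code{"exponential"}).
#' @param seed Integer seed.
#' @return A list with data frames \code{design_covariates} (one row per
#'   design location) and, if a grid was given, \code{grid_covariates}. Each
#'   has the named covariates, their squared terms (suffix \code{"2"}), and
#'   scaled \code{east}/\code{north} coordinates; all columns have mean 0 and
#'   SD 1 over the design locations. If \code{grid} is supplied it is also
#'   returned with covariates attached.
#' @export
simulate_covariates <- function(design, grid = NULL,
                                field_params = list(
                                  silt = list(range = 5000, variance = 1),
                                  mgs = list(range = 5000, variance = 1),
                                  altitude = list(range = 8000, variance = 1)),
                                seed = 1L) {
  loc <- design$all_locations
  if (is.null(loc) || nrow(loc) == 0L) stop("empty design", call. = FALSE)
  n_d <- nrow(loc)
  all_xy <- loc
  if (!is.null(grid)) all_xy <- rbind(loc, grid$nodes[, c("x", "y")])
  # Duplicates between design points and grid nodes are fine for field
  # simulation (same value at same place); collapse to unique coords.
  key <- paste(all_xy$x, all_xy$y, sep = "_")
  uniq <- !duplicated(key)
  uxy <- as_coord_matrix(all_xy[uniq, ])
  idx <- match(key, key[uniq])

  raw <- with_seed(seed, {
    vapply(names(field_params), function(nm) {
      fp <- field_params[[nm]]
      if (is.null(fp$range) || fp$range <= 0 || is.null(fp$variance) || fp$variance <= 0)
        stop("field_params for '", nm, "' need positive range and variance",
             call. = FALSE)
      fam <- if (is.null(fp$family)) "exponential" else fp$family
      p <- glsm_params(0, sigma2 = fp$variance, tau2 = 1e-8 * fp$variance,
                       phi = fp$range, family = fam)
      C <- covariance_matrix(uxy, p)
      z <- drop(crossprod(chol(C), stats::rnorm(nrow(uxy))))
      z[idx]
    }, numeric(nrow(all_xy)))
  })

  tab <- as.data.frame(raw)
  for (nm in names(field_params)) tab[[paste0(nm, "2")]] <- tab[[nm]]^2
  tab$east <- all_xy$x
  tab$north <- all_xy$y
  # scale every column by design-location mean/SD
  for (nm in names(tab)) {
    m <- mean(tab[[nm]][seq_len(n_d)])
    s <- stats::sd(tab[[nm]][seq_len(n_d)])
    if (s == 0) stop("covariate '", nm, "' is constant over the design", call. = FALSE)
    tab[[nm]] <- (tab[[nm]] - m) / s
  }

  out <- list(design_covariates = tab[seq_len(n_d), , drop = FALSE])
  rownames(out$design_covariates) <- NULL
  if (!is.null(grid)) {
    gc <- tab[-seq_len(n_d), , drop = FALSE]
    rownames(gc) <- NULL
    out$grid_covariates <- gc
    grid$nodes <- cbind(grid$nodes, gc)
    out$grid <- grid
  }
  out
}
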