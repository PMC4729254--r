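#' Read a survey table from delimited text
#'
#' Expects a CSV with header and columns \code{x}, \code{y}, \code{count}
#' plus covariate columns; coordinates in planar meters. Rows with malformed
#' or negative counts are rejected with their line numbers.
#'
#' @param path CSV file path.
#' @param required_covariates Covariate column names that must be present.
#' @return Validated data frame.
#' @export
read_survey <- function(path, required_covariates = character(0)) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("x", "y", "count")) {
    if (!col %in% names(tab))
      stop("survey file is missing column '", col, "'", call. = FALSE)
    if (!is.numeric(tab[[col]]))
      stop("column '", col, "' is not numeric", call. = FALSE)
  }
  bad <- which(tab$count < 0 | tab$count != floor(tab$count))
  if (length(bad))
    stop("invalid count at data line(s) ", paste(utils::head(bad, 5) + 1L,
         collapse = ", "), " of ", path, call. = FALSE)
  missing <- setdiff(required_covariates, names(tab))
  if (length(missing))
    stop("covariate column(s) named in the configuration are missing from ",
         path, ": ", paste(missing, collapse = ", "), call. = FALSE)
  tab$count <- as.integer(tab$count)
  tab
}

#' Write a survey table or map summary as CSV
#'
#' @param tab Data frame (e.g. a \code{map_stack} summary or survey data).
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_maps <- function(tab, path) {
  if (inherits(tab, "map_stack")) tab <- tab$summary
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects everything one end-to-end run needs. Two covariate sets mirror
#' the small/large model idea: a minimum set (e.g. silt, silt squared,
#' altitude) and a larger set adding more terms; model comparison between
#' them uses [model_comparison_threshold]. Profiles: \code{"fast"}
#' (desk-scale MCMC, suitable for tests and exploration) and \code{"full"}
#' (full-scale settings: 100,000 / 50,000 iterations, 100 realizations; runs
#' for hours on survey-sized data).
#'
#' @param covariates_small,covariates_large Character vectors of covariate
#'   column names (intercept implied). \code{covariates_large = NULL} skips
#'   the model comparison.
#' @param profile \code{"fast"} or \code{"full"}.
#' @param grid_spacing_m Prediction-grid spacing, meters (default 100).
#' @param n_realizations Realizations kriged per process.
#' @param n_cycles MCMC+MCML cycles per submodel.
#' @param mcmc Named list of MCMC settings per process, each with
#'   \code{n_iter}, \code{burn_in}, \code{thin}.
#' @param seeds Named list with integer \code{classification}, \code{mcmc},
#'   \code{prediction} seeds: all randomness flows from these three.
#' @param family Correlation family.
#' @param maxit MCML optimizer cap per cycle.
#' @return List of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(covariates_small,
                            covariates_large = NULL,
                            profile = c("fast", "full"),
                            grid_spacing_m = 100,
                            n_realizations = NULL,
                            n_cycles = 3L,
                            mcmc = NULL,
                            seeds = list(classification = 1L, mcmc = 2L,
                                         prediction = 3L),
                            family = "spherical",
                            maxit = NULL) {
  profile <- match.arg(profile)
  defaults <- if (profile == "full") {
    list(n_realizations = 100L, maxit = 300L,
         mcmc = list(poisson = list(n_iter = 100000L, burn_in = 100L, thin = 100L),
                     bernoulli = list(n_iter = 50000L, burn_in = 100L, thin = 100L)))
  } else {
    list(n_realizations = 20L, maxit = 120L,
         mcmc = list(poisson = list(n_iter = 2000L, burn_in = 400L, thin = 10L),
                     bernoulli = list(n_iter = 2000L, burn_in = 400L, thin = 10L)))
  }
  structure(list(
    covariates_small = covariates_small,
    covariates_large = covariates_large,
    profile = profile,
    grid_spacing_m = grid_spacing_m,
    n_realizations = if (is.null(n_realizations)) defaults$n_realizations
                     else as.integer(n_realizations),
    n_cycles = as.integer(n_cycles),
    mcmc = if (is.null(mcmc)) defaults$mcmc else mcmc,
    seeds = lapply(seeds, as.integer),
    family = family,
    maxit = if (is.null(maxit)) defaults$maxit else as.integer(maxit)),
    class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the [pipeline_config] arguments.
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(pipeline_config)))]
  if (is.null(args$covariates_small))
    stop("configuration must name 'covariates_small'", call. = FALSE)
  do.call(pipeline_config, args)
}

# Calibrate both submodels for one covariate set; shared by run_pipeline.
calibrate_model <- function(data, classified, covariate_set, config) {
  coords <- data[, c("x", "y")]
  fit <- fit_zip_ml(data, covariate_set, covariate_set)
  pres <- classified$indicator
  sub <- classified$poisson_subset
  th0_B <- initial_spatial_params(pres, data, coords, fit$beta_B,
                                  "bernoulli", config$family)
  th0_P <- initial_spatial_params(data$count[sub], data[sub, , drop = FALSE],
                                  coords[sub, , drop = FALSE], fit$beta_P,
                                  "poisson", config$family)
  mc <- config$mcmc
  calib_B <- calibrate_submodel(
    pres, data, coords, th0_B, "bernoulli", n_cycles = config$n_cycles,
    n_iter = mc$bernoulli$n_iter, burn_in = mc$bernoulli$burn_in,
    thin = mc$bernoulli$thin, seed = config$seeds$mcmc,
    maxit = config$maxit)
  calib_P <- calibrate_submodel(
    data$count[sub], data[sub, , drop = FALSE], coords[sub, , drop = FALSE],
    th0_P, "poisson", n_cycles = config$n_cycles,
    n_iter = mc$poisson$n_iter, burn_in = mc$poisson$burn_in,
    thin = mc$poisson$thin, seed = config$seeds$mcmc + 1000L,
    maxit = config$maxit)
  list(zip_fit = fit, calib_B = calib_B, calib_P = calib_P)
}

#' Run the full mapping pipeline
#'
#' Executes the whole procedure on one survey: nonspatial ZIP fit, stochastic
#' zero classification, iterated MCMC + MCML calibration of the Bernoulli and
#' Poisson submodels, conditional signal simulation, kriging of
#' \code{n_realizations} signal realizations per process to the grid with
#' backtransform, map summaries, leave-one-out validation, and (when a large
#' covariate set is configured) a small-vs-large model comparison against the
#' half-chi-squared threshold. Every stage's outputs and the three seeds are
#' written under \code{out_dir} when given.
#'
#' @param data Survey data frame (from [read_survey] or [simulate_survey]).
#' @param grid A [prediction_grid] carrying all configured covariates at its
#'   nodes.
#' @param config A [pipeline_config].
#' @param out_dir Optional run directory; created if missing. Maps and
#'   tables go there as CSV, reports as JSON, a log as text.
#' @return List of class \code{"pipeline_run"} with the classified data,
#'   the small-model calibrations, \code{maps} ([build_maps] result),
#'   \code{validation} ([validate_loo] result) and, if configured,
#'   \code{comparison} (twice-log-likelihood differences vs the threshold).
#' @export
run_pipeline <- function(data, grid, config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  covs_all <- unique(c(config$covariates_small, config$covariates_large))
  missing <- setdiff(covs_all, names(data))
  if (length(missing))
    stop("configured covariate(s) missing from the survey: ",
         paste(missing, collapse = ", "), call. = FALSE)
  missing_g <- setdiff(covs_all, names(grid$nodes))
  if (length(missing_g))
    stop("configured covariate(s) missing from the grid: ",
         paste(missing_g, collapse = ", "), call. = FALSE)
  log_lines <- character(0)
  say <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  say("ZIP fit + zero classification (model 'small', %d locations)", nrow(data))
  fit_small <- stage("fit-zip", fit_zip_ml(data, config$covariates_small,
                                           config$covariates_small))
  classified <- stage("classify", classify_zeros(data, fit_small,
                                                 config$seeds$classification))
  say("Bernoulli data set n = %d; Poisson data set n = %d",
      length(classified$indicator), length(classified$poisson_subset))

  say("calibrating submodels ('small', %d cycle(s), profile '%s')",
      config$n_cycles, config$profile)
  small <- stage("calibrate", calibrate_model(data, classified,
                                              config$covariates_small, config))

  say("kriging %d realizations per process to %d grid nodes",
      config$n_realizations, nrow(grid$nodes))
  sub <- classified$poisson_subset
  coords <- data[, c("x", "y")]
  maps <- stage("predict", build_maps(
    small$calib_B$sample, small$calib_P$sample,
    small$calib_B$theta_hat, small$calib_P$theta_hat,
    data, coords, data[sub, , drop = FALSE], coords[sub, , drop = FALSE],
    grid, n_realizations = config$n_realizations))

  say("leave-one-out validation")
  validation <- stage("validate", validate_loo(data, classified,
                                               small$calib_B, small$calib_P))

  comparison <- NULL
  if (!is.null(config$covariates_large)) {
    say("calibrating submodels ('large') for model comparison")
    large <- stage("calibrate-large", calibrate_model(
      data, classified, config$covariates_large, config))
    df <- length(setdiff(config$covariates_large, config$covariates_small))
    thr <- model_comparison_threshold(0.05, df)
    # twice-log-likelihood differences from the nonspatial mixture fits
    # (shared data) and the MC likelihood-ratio maxima of each submodel
    comparison <- list(
      df = df, threshold = thr,
      d2ll_zip = 2 * (large$zip_fit$loglik - small$zip_fit$loglik),
      d2ll_bernoulli = 2 * (large$calib_B$result$mc_loglik_at_max -
                            small$calib_B$result$mc_loglik_at_max),
      d2ll_poisson = 2 * (large$calib_P$result$mc_loglik_at_max -
                          small$calib_P$result$mc_loglik_at_max),
      prefer_large_zip = 2 * (large$zip_fit$loglik - small$zip_fit$loglik) > thr)
    comparison$large <- large
  }

  run <- structure(list(
    config = config, zip_fit = fit_small, classified = classified,
    calib_B = small$calib_B, calib_P = small$calib_P,
    maps = maps, validation = validation, comparison = comparison,
    log = log_lines),
    class = "pipeline_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_maps(maps, file.path(out_dir, "maps.csv"))
    utils::write.csv(
      data.frame(x = data$x, y = data$y, count = data$count,
                 indicator = classified$indicator),
      file.path(out_dir, "classification.csv"), row.names = FALSE)
    jsonlite::write_json(serialize_params(small$calib_B$theta_hat),
                         file.path(out_dir, "theta_bernoulli.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(serialize_params(small$calib_P$theta_hat),
                         file.path(out_dir, "theta_poisson.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(list(
      seeds = config$seeds,
      mcmc_bernoulli = run_report(small$calib_B$sample),
      mcmc_poisson = run_report(small$calib_P$sample)),
      file.path(out_dir, "mcmc_report.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(validation_json(validation),
                         file.path(out_dir, "validation.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(comparison))
      jsonlite::write_json(comparison[c("df", "threshold", "d2ll_zip",
                                        "d2ll_bernoulli", "d2ll_poisson",
                                        "prefer_large_zip")],
                           file.path(out_dir, "model_comparison.json"),
                           auto_unbox = TRUE, digits = NA)
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("Pipeline run (profile '", x$config$profile, "')\n", sep = "")
  print(x$maps)
  print(x$validation)
  if (!is.null(x$comparison))
    cat(sprintf("model comparison: 2*dlogLik (mixture) = %.2f vs threshold %.2f\n",
                x$comparison$d2ll_zip, x$comparison$threshold))
  invisible(x)
}

# Lossless JSON round-trip form of glsm_params.
serialize_params <- function(p) {
  list(beta = as.list(stats::setNames(as.numeric(p$beta), names(p$beta))),
       sigma2 = p$sigma2, tau2 = p$tau2, phi = p$phi, family = p$family)
}

#' @rdname serialize_params
#' @noRd
deserialize_params <- function(x) {
  glsm_params(unlist(x$beta), sigma2 = x$sigma2, tau2 = x$tau2, phi = x$phi,
              family = x$family)
}

validation_json <- function(v) {
  list(observed_class = v$observed_class,
       confusion = as.list(v$prevalence$confusion),
       overall_accuracy = v$prevalence$overall_accuracy,
       users_accuracy_1 = v$prevalence$users_accuracy_1,
       users_accuracy_0 = v$prevalence$users_accuracy_0,
       producers_accuracy_1 = v$prevalence$producers_accuracy_1,
       producers_accuracy_0 = v$prevalence$producers_accuracy_0,
       me_intensity = v$intensity$me, mse_intensity = v$intensity$mse,
       me_unconditional = v$unconditional$me,
       mse_unconditional = v$unconditional$mse)
}
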