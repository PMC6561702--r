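#' Configuration for the end-to-end landing analysis pipeline
#'
#' Collects every setting the pipeline needs: either a path to an
#' observation CSV or a [simulation_config()] to generate one; the
#' probabilistic-model settings (turbulence intensity, sea-to-cliff scaling
#' ratio, at-sea wind speeds, maximum tabulated attempts, covariate
#' profile); energetic constants; optional bearings; and the master seed.
#'
#' @param observations_path Optional CSV of landing attempts; when `NULL`
#'   the table is simulated from `sim`.
#' @param sim A [simulation_config()] used when no file is given (its seed
#'   is overridden by `seed`).
#' @param profile Covariate profile for the headline curves; defaults to a
#'   guillemot approaching a long-narrow ledge in the third height band.
#' @param turbulence_intensity Cliff turbulence intensity for the
#'   at-sea curves (default 0.2).
#' @param scaling_ratio Sea-to-cliff wind scaling constant (default 0.5,
#'   the ratio of typical near-cliff to open-water median winds).
#' @param sea_winds At-sea mean wind speeds to tabulate (m s^-1).
#' @param n_max Largest attempt number tabulated (default 20).
#' @param flight_power_w,loop_duration_s,prey_energy_kj Energetic
#'   constants: level-flight power (W), loop duration (s) and prey
#'   calorific value (kJ).
#' @param bearings_path Optional CSV of colony bearings; when `NULL`,
#'   bearings are simulated (11 colonies, uniform).
#' @param seed Master integer seed; stage seeds derive from it via
#'   [split_seed()].
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(observations_path = NULL,
                            sim = simulation_config(),
                            profile = list(ledge = "long_narrow",
                                           species = "guillemot",
                                           height = "h3"),
                            turbulence_intensity = 0.2,
                            scaling_ratio = 0.5,
                            sea_winds = 1:16,
                            n_max = 20,
                            flight_power_w = 144.1,
                            loop_duration_s = 34,
                            prey_energy_kj = 29.4,
                            bearings_path = NULL,
                            seed = 1L) {
  stopifnot(inherits(sim, "simulation_config"),
            is.numeric(seed), length(seed) == 1L)
  if (!is.null(observations_path) && !file.exists(observations_path))
    stop("observations_path does not exist: ", observations_path)
  if (!is.null(bearings_path) && !file.exists(bearings_path))
    stop("bearings_path does not exist: ", bearings_path)
  if (scaling_ratio <= 0) stop("scaling_ratio must be > 0")
  if (turbulence_intensity < 0) stop("turbulence_intensity must be >= 0")
  if (any(c(flight_power_w, loop_duration_s, prey_energy_kj) <= 0))
    stop("energetic constants must be > 0")
  structure(list(observations_path = observations_path, sim = sim,
                 profile = profile,
                 turbulence_intensity = turbulence_intensity,
                 scaling_ratio = scaling_ratio, sea_winds = sea_winds,
                 n_max = n_max, flight_power_w = flight_power_w,
                 loop_duration_s = loop_duration_s,
                 prey_energy_kj = prey_energy_kj,
                 bearings_path = bearings_path, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full landing analysis
#'
#' Executes the stages in order — obtain observations (simulate or read),
#' fit the landing mixed model, run the preference chi-squared tests and
#' deviance decomposition, collapse the fit to a logistic wind curve for
#' the configured profile, propagate it to the at-sea attempt curves,
#' convert attempts to energetic costs, and summarise colony orientation —
#' and optionally writes every stage output as CSV plus a run log. The same
#' seed and inputs give identical numerical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory for CSV outputs and the run log;
#'   created if needed. `NULL` skips writing.
#' @return List with `observations`, `fit`, `r2`, `anodev`, `ledge_chisq`,
#'   `height_chisq`, `logistic`, `curves`, `energetics`, `orientation`,
#'   `seed`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- split_seed(config$seed, 3)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE))
  }

  obs <- stage("observations", {
    if (is.null(config$observations_path)) {
      sim <- config$sim
      sim$seed <- seeds[1]
      generate_observations(sim)
    } else read_observations(config$observations_path)
  })
  fit <- stage("fit", fit_landing_glmm(obs))
  r2 <- stage("fit", r2_nakagawa(fit))
  an <- stage("anodev", anodev_table(obs))
  ledge_chisq <- stage("preference",
                       chi_square_preference(table(obs$species, obs$ledge)))
  height_chisq <- stage("preference",
                        chi_square_preference(table(obs$species, obs$height)))
  logistic <- stage("collapse", logistic_from_glmm(fit, config$profile))
  curves <- stage("attempt-curves",
                  landing_curve_at_sea(logistic,
                                       TI = config$turbulence_intensity,
                                       scaling = config$scaling_ratio,
                                       sea_winds = config$sea_winds,
                                       n_max = config$n_max))
  energetics <- stage("energetics", {
    cost <- cost_per_attempt(config$flight_power_w, config$loop_duration_s)
    mid <- curves[which.min(abs(curves$sea_wind -
                                  stats::median(config$sea_winds))), ]
    list(cost_per_attempt_kj = cost,
         attempts_per_prey_item =
           attempts_per_prey_item(config$prey_energy_kj, cost),
         bout_at_median_wind =
           expected_bout_cost(cost, attempt_distribution(mid$P)))
  })
  orientation <- stage("orientation", {
    bearings <- if (is.null(config$bearings_path))
      generate_orientations(11, concentration = 0, seed = seeds[2])
    else read_bearings(config$bearings_path)$bearing
    c(circular_summary(bearings), unclass(rayleigh_test(bearings)))
  })

  res <- list(observations = obs, fit = fit, r2 = r2, anodev = an,
              ledge_chisq = ledge_chisq, height_chisq = height_chisq,
              logistic = logistic, curves = curves, energetics = energetics,
              orientation = orientation, seed = config$seed)
  if (!is.null(out_dir)) write_pipeline_outputs(res, config, out_dir)
  res
}

write_pipeline_outputs <- function(res, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  write_observations(res$observations, file.path(out_dir, "observations.csv"))
  coef_tab <- data.frame(term = names(res$fit$coefficients),
                         estimate = unname(res$fit$coefficients),
                         se = unname(res$fit$se))
  utils::write.csv(coef_tab, file.path(out_dir, "fit_coefficients.csv"),
                   row.names = FALSE)
  utils::write.csv(res$anodev, file.path(out_dir, "anodev.csv"),
                   row.names = FALSE)
  utils::write.csv(res$curves, file.path(out_dir, "attempt_curves.csv"),
                   row.names = FALSE)
  log_path <- file.path(out_dir, "run_log.txt")
  writeLines(c(
    sprintf("cliffwind %s | R %s.%s | lme4 %s",
            as.character(utils::packageVersion("cliffwind")),
            R.version$major, R.version$minor,
            as.character(utils::packageVersion("lme4"))),
    sprintf("seed: %d", config$seed),
    sprintf("n observations: %d", nrow(res$observations)),
    sprintf("AIC: %.2f | marginal R2: %.3f | conditional R2: %.3f",
            res$fit$aic, res$r2[["marginal"]], res$r2[["conditional"]]),
    sprintf("elapsed writing outputs: %.2f s",
            as.numeric(difftime(Sys.time(), t0, units = "secs")))
  ), log_path)
  invisible(out_dir)
}
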