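#' Validate and type a table of landing attempts
#'
#' Checks the per-attempt schema used throughout the package: `colony`,
#' `day`, `species` (guillemot/razorbill), `ledge` (large/long_narrow/small),
#' `height` (h1..h4, bottom to top), `wind` (m s^-1, >= 0), `turbulence`
#' (>= 0) and binary `success`. Offending rows are reported by row number.
#'
#' @param table A data frame of landing attempts.
#' @return The validated table, with factor-like columns as characters.
#' @keywords internal
validate_observations <- function(table) {
  stopifnot(is.data.frame(table))
  need <- c("colony", "day", "species", "ledge", "height",
            "wind", "turbulence", "success")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols))
    stop("observation table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(table) == 0L) return(table)
  bad_rows <- function(ok, what) {
    if (!all(ok))
      stop("invalid ", what, " at row(s): ",
           paste(utils::head(which(!ok), 10), collapse = ", "))
  }
  bad_rows(table$species %in% species_levels(), "species level")
  bad_rows(table$ledge %in% ledge_levels(), "ledge level")
  bad_rows(table$height %in% height_levels(), "height band")
  bad_rows(is.finite(table$wind) & table$wind >= 0, "wind speed (must be >= 0)")
  bad_rows(is.finite(table$turbulence) & table$turbulence >= 0,
           "turbulence intensity (must be >= 0)")
  bad_rows(table$success %in% c(0L, 1L), "success flag (must be 0/1)")
  table
}

#' Centre the continuous predictors of an observation table
#'
#' Wind speed and turbulence are centred before fitting so that their main
#' effects remain interpretable alongside the wind-by-ledge and
#' turbulence-by-ledge interactions (centring removes the collinearity
#' between a predictor and its interaction terms). The original columns are
#' retained; `wind_c` and `turbulence_c` are appended.
#'
#' @param table An observation table (see [validate_observations()]).
#' @return List with `table` (centred columns appended) and `means`, the
#'   named centring constants needed to predict from raw wind speeds later.
#' @export
center_predictors <- function(table) {
  table <- validate_observations(table)
  if (nrow(table) == 0L) stop("cannot centre an empty observation table")
  means <- c(wind = mean(table$wind), turbulence = mean(table$turbulence))
  for (v in c("wind", "turbulence")) {
    if (stats::sd(table[[v]]) == 0)
      warning("`", v, "` has no variation; its centred column is all zero ",
              "and the term will be inestimable")
    table[[paste0(v, "_c")]] <- table[[v]] - means[[v]]
  }
  list(table = table, means = means)
}

obs_factors <- function(table) {
  # baselines: large ledge, guillemot, top height band
  table$ledge <- factor(table$ledge, levels = ledge_levels())
  table$species <- factor(table$species, levels = species_levels())
  table$height <- factor(table$height, levels = c("h4", "h1", "h2", "h3"))
  table$day_colony <- factor(paste(table$day, table$colony, sep = ":"))
  table
}

#' Fit the binomial mixed model of landing success
#'
#' Fits, by Laplace-approximated maximum likelihood with the bobyqa
#' optimiser, the logistic mixed model
#' `success ~ wind_c * ledge + turbulence_c * ledge + species + height +
#' (1 | day:colony)`:
#' centred wind and turbulence with their ledge interactions, species and
#' height main effects, and a random intercept for each (day, colony)
#' combination to absorb the shared conditions of one site on one day.
#' Baselines are large ledges, guillemots and the top height band.
#'
#' @param table An observation table.
#' @param formula Optional alternative fixed/random formula using columns of
#'   the centred table (`wind_c`, `turbulence_c`, `ledge`, `species`,
#'   `height`, `day_colony`).
#' @return An object of class `landing_fit`: the `lme4` model plus the
#'   centring means, coefficient table, random-intercept SD, AIC and a
#'   convergence flag. Non-convergence or complete separation is signalled
#'   with a warning and `converged = FALSE`.
#' @export
fit_landing_glmm <- function(table, formula = NULL) {
  cen <- center_predictors(table)
  dat <- obs_factors(cen$table)
  if (nlevels(droplevels(dat$day_colony)) < 2L)
    stop("need at least two (day, colony) groups to fit a random intercept")
  for (v in c("ledge", "species", "height"))
    if (nlevels(droplevels(dat[[v]])) < 2L)
      stop("factor `", v, "` has fewer than 2 observed levels")
  formula <- formula %||% (success ~ wind_c * ledge + turbulence_c * ledge +
                             species + height + (1 | day_colony))
  model <- lme4::glmer(formula, data = dat, family = stats::binomial(),
                       control = lme4::glmerControl(optimizer = "bobyqa"))
  msgs <- unlist(model@optinfo$conv$lme4$messages)
  converged <- model@optinfo$conv$opt == 0 && is.null(msgs)
  sm <- summary(model)$coefficients
  separation <- any(abs(sm[, "Estimate"]) > 15) || any(sm[, "Std. Error"] > 25)
  if (!converged)
    warning("landing model did not converge cleanly: ",
            paste(msgs, collapse = "; "))
  if (separation)
    warning("possible complete separation: extreme coefficient or ",
            "standard error detected")
  fit <- structure(
    list(model = model,
         centering = cen$means,
         coefficients = sm[, "Estimate"],
         se = sm[, "Std. Error"],
         random_intercept_sd =
           sqrt(as.numeric(lme4::VarCorr(model)$day_colony[1, 1])),
         logLik = as.numeric(stats::logLik(model)),
         aic = stats::AIC(model),
         n = nrow(dat),
         converged = converged && !separation,
         formula = formula),
    class = "landing_fit"
  )
  fit
}

#' @export
print.landing_fit <- function(x, ...) {
  cat("Binomial mixed model of landing success (logit link)\n")
  cat(sprintf("  n = %d attempts, %d (day, colony) groups\n", x$n,
              nlevels(x$model@frame$day_colony)))
  cat(sprintf("  AIC = %.1f, logLik = %.1f, random-intercept SD = %.3f\n",
              x$aic, x$logLik, x$random_intercept_sd))
  cat(sprintf("  centring: wind %.3f m/s, turbulence %.4f\n",
              x$centering[["wind"]], x$centering[["turbulence"]]))
  if (!x$converged) cat("  WARNING: fit flagged as not converged\n")
  tab <- cbind(Estimate = x$coefficients, `Std. Error` = x$se)
  print(round(tab, 3))
  invisible(x)
}

new_profile_data <- function(fit, profile, wind, turbulence = NULL) {
  profile <- as.list(profile)
  lv <- list(ledge = ledge_levels(), species = species_levels(),
             height = height_levels())
  for (v in names(lv)) {
    if (is.null(profile[[v]]))
      stop("covariate profile must include `", v, "`")
    if (!profile[[v]] %in% lv[[v]])
      stop("unknown ", v, " level `", profile[[v]], "`; expected one of: ",
           paste(lv[[v]], collapse = ", "))
  }
  tc <- if (is.null(turbulence)) 0
        else turbulence - fit$centering[["turbulence"]]
  nd <- data.frame(
    wind_c = wind - fit$centering[["wind"]],
    turbulence_c = tc,
    ledge = factor(profile$ledge, levels = ledge_levels()),
    species = factor(profile$species, levels = species_levels()),
    height = factor(profile$height, levels = c("h4", "h1", "h2", "h3"))
  )
  nd
}

#' Predict the landing probability for a covariate profile
#'
#' Evaluates the fitted model at raw (uncentred) wind speeds for a given
#' ledge class, species and height band. Turbulence defaults to its sample
#' mean (i.e. a centred value of zero). Predictions are population-level
#' (random intercept set to 0) unless `marginal = TRUE`, in which case the
#' success probability is averaged over the Normal random-intercept
#' distribution by quadrature.
#'
#' @param fit A [fit_landing_glmm()] result.
#' @param profile Named list with `ledge`, `species` and `height`.
#' @param wind Raw wind speed(s), m s^-1, >= 0.
#' @param turbulence Optional raw turbulence intensity (default: the
#'   centring mean).
#' @param marginal Average over the random-intercept distribution?
#' @return Predicted success probabilities, one per element of `wind`.
#' @export
predict_success <- function(fit, profile, wind, turbulence = NULL,
                            marginal = FALSE) {
  stopifnot(inherits(fit, "landing_fit"))
  if (any(wind < 0)) stop("wind speed must be >= 0")
  nd <- new_profile_data(fit, profile, wind, turbulence)
  eta <- stats::predict(fit$model, newdata = nd, re.form = NA, type = "link")
  if (!marginal) return(unname(stats::plogis(eta)))
  sdre <- fit$random_intercept_sd
  if (sdre == 0) return(unname(stats::plogis(eta)))
  vapply(eta, function(e)
    stats::integrate(function(b) stats::plogis(e + b) * stats::dnorm(b, 0, sdre),
                     -Inf, Inf, rel.tol = 1e-10)$value,
    numeric(1))
}

#' Collapse a fitted model to a logistic curve in wind speed
#'
#' For a fixed covariate profile (and turbulence held at a fixed value,
#' defaulting to its sample mean) the fitted linear predictor is linear in
#' raw wind speed, so the success probability is exactly
#' `p(W) = a/(a + exp(bW))` with `b` the negated total wind slope (main
#' effect plus the ledge interaction for the profile's ledge) and
#' `log a` the linear predictor at `W = 0`. The returned curve reproduces
#' [predict_success()] identically.
#'
#' @inheritParams predict_success
#' @return A [logistic_landing()] object.
#' @export
logistic_from_glmm <- function(fit, profile, turbulence = NULL) {
  stopifnot(inherits(fit, "landing_fit"))
  nd <- new_profile_data(fit, profile, wind = c(0, 1), turbulence)
  eta <- stats::predict(fit$model, newdata = nd, re.form = NA, type = "link")
  slope <- eta[2] - eta[1]
  logistic_landing(a = exp(unname(eta[1])), b = -unname(slope))
}

#' Sequential analysis-of-deviance table
#'
#' Decomposes the explanatory power of the landing model by adding terms in
#' the fixed reporting order (wind, ledge, turbulence, species, height,
#' wind-by-ledge, turbulence-by-ledge) to the null model (intercept plus
#' the day-colony random intercept) and recording, for each term, the drop
#' in deviance per degree of freedom (an F-like statistic), the
#' likelihood-ratio p-value, and the percentage of the null model's deviance
#' explained.
#'
#' @param table An observation table.
#' @return Data frame with columns `term`, `df`, `F_value`, `p`,
#'   `deviance_explained_pct`.
#' @export
anodev_table <- function(table) {
  cen <- center_predictors(table)
  dat <- obs_factors(cen$table)
  terms <- c("wind_c", "ledge", "turbulence_c", "species", "height",
             "wind_c:ledge", "turbulence_c:ledge")
  labels <- c("wind", "ledge", "turbulence", "species", "height",
              "wind:ledge", "turbulence:ledge")
  fit_dev <- function(rhs) {
    f <- stats::as.formula(paste("success ~", rhs, "+ (1 | day_colony)"))
    m <- lme4::glmer(f, data = dat, family = stats::binomial(),
                     control = lme4::glmerControl(optimizer = "bobyqa"))
    c(dev = -2 * as.numeric(stats::logLik(m)),
      df = length(lme4::fixef(m)))
  }
  null <- fit_dev("1")
  out <- vector("list", length(terms))
  prev <- null
  rhs <- "1"
  for (i in seq_along(terms)) {
    rhs <- paste(rhs, "+", terms[i])
    cur <- tryCatch(fit_dev(rhs), error = function(e) NULL)
    if (is.null(cur)) {
      out[[i]] <- data.frame(term = labels[i], df = NA, F_value = NA,
                             p = NA, deviance_explained_pct = NA)
      next
    }
    ddev <- prev[["dev"]] - cur[["dev"]]
    ddf <- cur[["df"]] - prev[["df"]]
    out[[i]] <- data.frame(
      term = labels[i], df = ddf,
      F_value = ddev / ddf,
      p = stats::pchisq(ddev, ddf, lower.tail = FALSE),
      deviance_explained_pct = 100 * ddev / null[["dev"]])
    prev <- cur
  }
  do.call(rbind, out)
}

#' Marginal and conditional R-squared for the landing model
#'
#' Variance-partition R-squared for a logit mixed model: with `vf` the
#' variance of the fixed-effects linear predictor over the data, `vr` the
#' random-intercept variance and `pi^2/3` the latent logistic residual
#' variance,
#' marginal R2 = vf / (vf + vr + pi^2/3) (fixed effects only) and
#' conditional R2 = (vf + vr) / (vf + vr + pi^2/3) (fixed plus random).
#'
#' @param fit A [fit_landing_glmm()] result.
#' @return Named numeric vector `c(marginal = , conditional = )`.
#' @export
r2_nakagawa <- function(fit) {
  stopifnot(inherits(fit, "landing_fit"))
  X <- lme4::getME(fit$model, "X")
  vf <- stats::var(as.numeric(X %*% lme4::fixef(fit$model)))
  vr <- fit$random_intercept_sd^2
  tot <- vf + vr + pi^2 / 3
  c(marginal = vf / tot, conditional = (vf + vr) / tot)
}

#' Pearson chi-squared test of ledge or height preference
#'
#' Tests whether two species distribute their landing attempts identically
#' over ledge classes (or height bands) with the Pearson statistic
#' `sum((O - E)^2 / E)` on the species-by-category contingency table,
#' without continuity correction.
#'
#' @param counts A matrix of nonnegative integer counts (species in rows,
#'   categories in columns), with every row and column sum positive.
#' @return An object of class `chi_square_result` with `statistic`, `df`,
#'   `p` and `n`.
#' @export
chi_square_preference <- function(counts) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-8))
    stop("`counts` must be nonnegative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("every row and column of `counts` must have a positive total")
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("`counts` must be at least 2 x 2")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  structure(list(statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p = ct$p.value, n = sum(counts)),
            class = "chi_square_result")
}

#' @export
print.chi_square_result <- function(x, ...) {
  cat(sprintf("Pearson chi-squared: X2 = %.4g, df = %d, p = %.3g, n = %d\n",
              x$statistic, x$df, x$p, x$n))
  invisible(x)
}

#' Simulation-based residual uniformity check
#'
#' A basic simulated-residual diagnostic: responses are simulated from the
#' fitted model (new random intercepts each time), each observation's
#' probability-integral-transform residual is computed against its simulated
#' distribution (randomised for the discrete response), and the residuals
#' are tested for uniformity with a Kolmogorov-Smirnov test. Under a
#' well-specified model the p-values are approximately uniform, so the test
#' rejects at about its nominal rate.
#'
#' @param fit A [fit_landing_glmm()] result.
#' @param n_sim Number of simulated response sets (default 250).
#' @param seed Optional integer seed.
#' @return List with `residuals` (in (0, 1)) and `p` (KS uniformity
#'   p-value).
#' @export
residual_uniformity <- function(fit, n_sim = 250, seed = NULL) {
  stopifnot(inherits(fit, "landing_fit"), n_sim >= 10)
  if (!is.null(seed)) set.seed(seed)
  sims <- stats::simulate(fit$model, nsim = n_sim,
                          re.form = NA, allow.new.levels = TRUE)
  simmat <- vapply(sims, function(s)
    if (is.data.frame(s)) s[[1]] else as.numeric(s), numeric(fit$n))
  obs <- lme4::getME(fit$model, "y")
  p_less <- rowMeans(simmat < obs)
  p_eq <- rowMeans(simmat == obs)
  resid <- p_less + stats::runif(fit$n) * p_eq
  ks <- suppressWarnings(stats::ks.test(resid, "punif"))
  list(residuals = resid, p = ks$p.value)
}

#' Summary analysis of a deposited landing-observation table
#'
#' Runs the full observational analysis on a raw landing table read from
#' disk: record counts and the species split, the species-by-ledge and
#' species-by-height preference chi-squared tests, the mixed-model fit with
#' its wind coefficient, the sequential deviance decomposition, and the
#' predicted success for a guillemot on a long-narrow ledge at 8 m s^-1.
#'
#' @param path CSV file of landing attempts in the package schema (see
#'   [read_observations()], which is used to load it); a column-mapping may
#'   be supplied for files with different headers.
#' @param column_map Optional named character vector mapping package column
#'   names to the file's column names.
#' @return List with `n`, `species_counts`, `ledge_chisq`, `height_chisq`,
#'   `fit`, `wind_coefficient`, `anodev`, `wind_deviance_explained_pct`,
#'   and `pred_success_8ms`.
#' @export
analyse_deposited_observations <- function(path, column_map = NULL) {
  tab <- read_observations(path, column_map = column_map)
  fit <- fit_landing_glmm(tab)
  an <- anodev_table(tab)
  list(
    n = nrow(tab),
    species_counts = table(tab$species),
    ledge_chisq = chi_square_preference(table(tab$species, tab$ledge)),
    height_chisq = chi_square_preference(table(tab$species, tab$height)),
    fit = fit,
    wind_coefficient = unname(fit$coefficients[["wind_c"]]),
    anodev = an,
    wind_deviance_explained_pct =
      an$deviance_explained_pct[an$term == "wind"],
    pred_success_8ms = predict_success(
      fit, list(ledge = "long_narrow", species = "guillemot", height = "h3"),
      wind = 8)
  )
}
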