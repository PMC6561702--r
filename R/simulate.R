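#' Configuration for the synthetic landing-observation generator
#'
#' Bundles everything the generator needs to emulate a season of landing
#' observations at a cliff-nesting auk colony complex: the number of
#' attempts, the logit-scale coefficients of the data-generating landing
#' model, the between-(day, colony) heterogeneity, the wind climate, and the
#' behavioural frequencies (which ledge classes and height bands each species
#' uses, and the species mix).
#'
#' Coefficients act on predictors centred at their climate values
#' (`mean_wind` for wind, `turbulence_intensity` for turbulence), mirroring
#' the centring used when the model is fitted. Factor baselines are: ledge =
#' `large`, species = `guillemot`, height = `h4` (top band); offsets are
#' named for the non-reference level they move.
#'
#' @param n_attempts Number of landing attempts to simulate.
#' @param true_coefficients Named numeric vector of logit-scale effects. Any
#'   subset of the default names may be supplied; the rest keep their
#'   defaults. Defaults follow the fitted field model: wind -0.62 per m s^-1,
#'   long-narrow ledge -1.21, small ledge -2.48, turbulence -0.81, razorbill
#'   +1.10, lowest height band -0.58, wind x long-narrow +0.03, wind x small
#'   +0.22, turbulence x long-narrow +0.95, turbulence x small +0.07. The
#'   intercept (2.8) and the unreported middle height bands (-0.3, -0.1) are
#'   chosen so success is near-certain in still air on large ledges and drops
#'   below 20% at 8 m s^-1 on long-narrow ledges.
#' @param random_intercept_sd SD (logit units) of the Normal random intercept
#'   shared by all attempts at one (day, colony) combination. Default 0.5.
#' @param colonies,days Numbers of colonies and observation days.
#' @param mean_wind Climate mean of the per-minute wind speed (m s^-1).
#' @param turbulence_intensity Climate mean turbulence intensity.
#' @param ledge_frequencies Named list with elements `guillemot` and
#'   `razorbill`, each a probability vector over ledge classes
#'   (large, long_narrow, small). Defaults put long-narrow ledges near 47%
#'   overall and bias razorbills toward the smallest ledges.
#' @param height_frequencies Same structure over height bands h1..h4
#'   (bottom to top); razorbills sit higher by default.
#' @param species_mix Probability that an attempt is by a guillemot.
#' @param seed Integer seed governing all draws for this configuration.
#' @return An object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(n_attempts = 6000,
                              true_coefficients = NULL,
                              random_intercept_sd = 0.5,
                              colonies = 5,
                              days = 26,
                              mean_wind = 3,
                              turbulence_intensity = 0.2,
                              ledge_frequencies = NULL,
                              height_frequencies = NULL,
                              species_mix = 0.69,
                              seed = 1L) {
  coefs <- c(
    intercept = 2.8,
    wind = -0.62,
    turbulence = -0.81,
    ledge_long_narrow = -1.21,
    ledge_small = -2.48,
    species_razorbill = 1.10,
    height_h1 = -0.58,
    height_h2 = -0.30,
    height_h3 = -0.10,
    wind_x_ledge_long_narrow = 0.03,
    wind_x_ledge_small = 0.22,
    turb_x_ledge_long_narrow = 0.95,
    turb_x_ledge_small = 0.07
  )
  if (!is.null(true_coefficients)) {
    bad <- setdiff(names(true_coefficients), names(coefs))
    if (length(bad))
      stop("unknown coefficient name(s): ", paste(bad, collapse = ", "))
    coefs[names(true_coefficients)] <- true_coefficients
  }
  ledge_frequencies <- ledge_frequencies %||% list(
    guillemot = c(large = 0.37, long_narrow = 0.47, small = 0.16),
    razorbill = c(large = 0.18, long_narrow = 0.42, small = 0.40)
  )
  height_frequencies <- height_frequencies %||% list(
    guillemot = c(h1 = 0.25, h2 = 0.30, h3 = 0.28, h4 = 0.17),
    razorbill = c(h1 = 0.12, h2 = 0.22, h3 = 0.33, h4 = 0.33)
  )
  cfg <- structure(
    list(n_attempts = as.integer(n_attempts),
         true_coefficients = coefs,
         random_intercept_sd = random_intercept_sd,
         colonies = as.integer(colonies),
         days = as.integer(days),
         mean_wind = mean_wind,
         turbulence_intensity = turbulence_intensity,
         ledge_frequencies = ledge_frequencies,
         height_frequencies = height_frequencies,
         species_mix = species_mix,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
  validate_simulation_config(cfg)
}

validate_simulation_config <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (cfg$n_attempts < 0) stop("n_attempts must be >= 0")
  if (cfg$mean_wind < 0) stop("mean_wind must be >= 0")
  if (cfg$turbulence_intensity < 0) stop("turbulence_intensity must be >= 0")
  if (cfg$random_intercept_sd < 0) stop("random_intercept_sd must be >= 0")
  if (cfg$species_mix < 0 || cfg$species_mix > 1)
    stop("species_mix must be a probability in [0, 1]")
  if (cfg$colonies < 1 || cfg$days < 1) stop("need >= 1 colony and >= 1 day")
  chk_prob <- function(p, what, levels) {
    if (!identical(sort(names(p)), sort(levels)))
      stop(what, " must be named over: ", paste(levels, collapse = ", "))
    if (any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-8)
      stop(what, " must be probabilities in [0, 1] summing to 1")
  }
  for (sp in c("guillemot", "razorbill")) {
    chk_prob(cfg$ledge_frequencies[[sp]], paste(sp, "ledge frequencies"),
             ledge_levels())
    chk_prob(cfg$height_frequencies[[sp]], paste(sp, "height frequencies"),
             height_levels())
  }
  cfg
}

ledge_levels <- function() c("large", "long_narrow", "small")
height_levels <- function() c("h1", "h2", "h3", "h4")
species_levels <- function() c("guillemot", "razorbill")

#' @export
print.simulation_config <- function(x, ...) {
  cat("Synthetic landing-observation configuration\n")
  cat(sprintf("  %d attempts over %d colonies x %d days, seed %d\n",
              x$n_attempts, x$colonies, x$days, x$seed))
  cat(sprintf("  wind climate: mean %.2f m/s, turbulence intensity %.2f\n",
              x$mean_wind, x$turbulence_intensity))
  cat(sprintf("  random intercept SD %.2f; P(guillemot) = %.2f\n",
              x$random_intercept_sd, x$species_mix))
  invisible(x)
}

#' Simulate a per-minute wind-speed series
#'
#' Draws `n` independent log-normal wind speeds whose mean is `mean_wind`
#' and whose standard deviation is `turbulence_intensity * mean_wind`,
#' the model used for instantaneous cliff winds throughout the package.
#' A zero intensity returns the constant series.
#'
#' @param mean_wind Mean wind speed (m s^-1), > 0.
#' @param turbulence_intensity Ratio of the SD of fluctuations to the mean,
#'   >= 0.
#' @param n Number of per-minute readings.
#' @param seed Optional integer seed.
#' @return Numeric vector of `n` strictly positive wind speeds.
#' @export
generate_wind_series <- function(mean_wind, turbulence_intensity, n,
                                 seed = NULL) {
  if (!is.numeric(mean_wind) || mean_wind <= 0)
    stop("mean_wind must be > 0")
  if (turbulence_intensity < 0) stop("turbulence_intensity must be >= 0")
  stopifnot(n >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (turbulence_intensity == 0) return(rep(mean_wind, n))
  wd <- lognormal_from_moments(mean_wind, turbulence_intensity * mean_wind)
  stats::rlnorm(n, meanlog = wd$m, sdlog = wd$s)
}

#' Simulate a table of landing attempts
#'
#' Generates per-attempt records (colony, date, species, ledge class, height
#' band, per-minute wind speed, turbulence intensity, success flag) by
#' inverting the binomial-logit mixed model the analysis fits: the success
#' probability is the inverse logit of the configured linear predictor on
#' centred wind and turbulence, plus a Normal random intercept shared by all
#' attempts at the same (day, colony).
#'
#' Wind is drawn hierarchically: each (day, colony) gets a log-normal daily
#' mean around the climate mean (CV 0.5), and per-minute readings fluctuate
#' around that daily mean with the configured turbulence intensity. The
#' turbulence covariate is a (day, colony)-level log-normal draw around the
#' climate intensity (CV 0.5), as turbulence at a site is set by that day's
#' wind direction, not by the minute.
#'
#' @param config A [simulation_config()].
#' @return A data frame with columns `colony`, `day` (ISO-8601 date string),
#'   `species`, `ledge`, `height`, `wind`, `turbulence`, `success`, carrying
#'   the generating truth in `attr(, "truth")` (coefficients, centring
#'   values, random-intercept SD, and the realised per-group intercepts).
#' @export
generate_observations <- function(config) {
  config <- validate_simulation_config(config)
  set.seed(config$seed)
  n <- config$n_attempts
  cols <- c("colony", "day", "species", "ledge", "height",
            "wind", "turbulence", "success")
  truth <- list(coefficients = config$true_coefficients,
                wind_center = config$mean_wind,
                turbulence_center = config$turbulence_intensity,
                random_intercept_sd = config$random_intercept_sd)
  if (n == 0L) {
    out <- data.frame(colony = character(), day = character(),
                      species = character(), ledge = character(),
                      height = character(), wind = numeric(),
                      turbulence = numeric(), success = integer())
    attr(out, "truth") <- truth
    return(out)
  }

  colony_ids <- sprintf("colony_%02d", seq_len(config$colonies))
  day_ids <- format(as.Date("2016-04-28") + seq_len(config$days) - 1L,
                    "%Y-%m-%d")

  colony <- sample(colony_ids, n, replace = TRUE)
  day <- sample(day_ids, n, replace = TRUE)
  species <- ifelse(stats::runif(n) < config$species_mix,
                    "guillemot", "razorbill")
  ledge <- character(n)
  height <- character(n)
  for (sp in species_levels()) {
    idx <- which(species == sp)
    if (!length(idx)) next
    lf <- config$ledge_frequencies[[sp]][ledge_levels()]
    hf <- config$height_frequencies[[sp]][height_levels()]
    ledge[idx] <- sample(ledge_levels(), length(idx), replace = TRUE, prob = lf)
    height[idx] <- sample(height_levels(), length(idx), replace = TRUE, prob = hf)
  }

  # (day, colony)-level structure: daily mean wind, site turbulence, and the
  # shared random intercept
  grp <- paste(day, colony, sep = ":")
  grp_levels <- sort(unique(grp))
  gi <- match(grp, grp_levels)
  ng <- length(grp_levels)
  day_mean <- draw_lognormal(ng, config$mean_wind, 0.5 * config$mean_wind)
  site_turb <- if (config$turbulence_intensity > 0)
    draw_lognormal(ng, config$turbulence_intensity,
                   0.5 * config$turbulence_intensity)
  else rep(0, ng)
  ranef <- stats::rnorm(ng, 0, config$random_intercept_sd)

  ti <- config$turbulence_intensity
  wind <- if (ti > 0) {
    m <- day_mean[gi]
    draw_lognormal(n, m, ti * m)
  } else day_mean[gi]
  turbulence <- site_turb[gi]

  b <- config$true_coefficients
  wc <- wind - config$mean_wind
  tc <- turbulence - config$turbulence_intensity
  ln <- ledge == "long_narrow"
  sm <- ledge == "small"
  lp <- b[["intercept"]] +
    b[["wind"]] * wc +
    b[["turbulence"]] * tc +
    b[["ledge_long_narrow"]] * ln +
    b[["ledge_small"]] * sm +
    b[["species_razorbill"]] * (species == "razorbill") +
    b[["height_h1"]] * (height == "h1") +
    b[["height_h2"]] * (height == "h2") +
    b[["height_h3"]] * (height == "h3") +
    b[["wind_x_ledge_long_narrow"]] * wc * ln +
    b[["wind_x_ledge_small"]] * wc * sm +
    b[["turb_x_ledge_long_narrow"]] * tc * ln +
    b[["turb_x_ledge_small"]] * tc * sm +
    ranef[gi]
  success <- as.integer(stats::runif(n) < stats::plogis(lp))

  out <- data.frame(colony = colony, day = day, species = species,
                    ledge = ledge, height = height, wind = wind,
                    turbulence = turbulence, success = success)
  out <- out[cols]
  truth$random_intercepts <- stats::setNames(ranef, grp_levels)
  attr(out, "truth") <- truth
  out
}

# log-normal draws parameterised by arithmetic mean and SD (vectorised)
draw_lognormal <- function(n, mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Simulate colony bearings on the circle
#'
#' Draws `n` bearings from a von Mises distribution with the given modal
#' direction and concentration; a concentration of zero gives the uniform
#' distribution on the circle. Sampling uses the Best-Fisher (1979)
#' wrapped-Cauchy rejection envelope.
#'
#' @param n Number of bearings.
#' @param mode Modal direction in degrees.
#' @param concentration Von Mises concentration (kappa), >= 0.
#' @param seed Optional integer seed.
#' @return Bearings in degrees, in `[0, 360)`.
#' @export
generate_orientations <- function(n, mode = 0, concentration = 0,
                                  seed = NULL) {
  stopifnot(n >= 1, concentration >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (concentration == 0) return(stats::runif(n, 0, 360))
  kappa <- concentration
  a <- 1 + sqrt(1 + 4 * kappa^2)
  bb <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + bb^2) / (2 * bb)
  theta <- numeric(n)
  got <- 0L
  while (got < n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      got <- got + 1L
      theta[got] <- sign(u3 - 0.5) * acos(f)
    }
  }
  (mode + theta * 180 / pi) %% 360
}

#' Simulate a gridded wind field
#'
#' Builds an `nx` by `ny` grid of (mean wind speed `U`, turbulent kinetic
#' energy `k`) samples with the statistical signature of flow around
#' topography: `U` varies smoothly and averages `mean_wind`, while the
#' magnitude of the turbulent fluctuations varies only mildly, so the
#' derived turbulence intensity is largest where the mean wind is weakest
#' (sheltered, leeward areas). This is a statistical fixture, not a flow
#' solution.
#'
#' @param nx,ny Grid dimensions, >= 1.
#' @param mean_wind Spatial mean of `U` (m s^-1).
#' @param seed Optional integer seed.
#' @param spacing Grid spacing (m) used for the `x`, `y` coordinates.
#' @return Data frame with columns `x`, `y`, `U`, `k`.
#' @export
generate_wind_grid <- function(nx, ny, mean_wind, seed = NULL, spacing = 25) {
  stopifnot(nx >= 1, ny >= 1, mean_wind >= 0)
  if (!is.null(seed)) set.seed(seed)
  g <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  smooth_field <- function(ix, iy) {
    f <- 0
    for (mode in 1:4) {
      amp <- stats::runif(1, 0.3, 1)
      px <- stats::runif(1, 0.5, 2) / max(nx, 2)
      py <- stats::runif(1, 0.5, 2) / max(ny, 2)
      ph <- stats::runif(1, 0, 2 * pi)
      f <- f + amp * sin(2 * pi * (px * ix + py * iy) + ph)
    }
    if (diff(range(f)) < 1e-12) return(rep(0.5, length(f)))
    (f - min(f)) / diff(range(f))
  }
  fU <- smooth_field(g$ix, g$iy)
  U_raw <- 0.25 + 0.75 * fU
  U <- if (mean(U_raw) > 0) mean_wind * U_raw / mean(U_raw) else U_raw * 0
  # near-uniform fluctuation magnitude: intensity u/U peaks where U is low
  fu <- smooth_field(g$ix, g$iy)
  u <- 0.12 * mean_wind * (0.8 + 0.4 * fu)
  data.frame(x = (g$ix - 1) * spacing, y = (g$iy - 1) * spacing,
             U = U, k = 1.5 * u^2)
}

#' Simulate landing-loop durations
#'
#' After an aborted attempt a bird flies a loop before re-approaching the
#' cliff. Durations are log-normal around a median of 34 s, truncated by
#' rejection to the observed 11-58 s range.
#'
#' @param n Number of loops.
#' @param median_s Median duration (s).
#' @param range_s Length-2 vector of admissible durations (s).
#' @param sdlog Log-scale SD of the untruncated distribution.
#' @param seed Optional integer seed.
#' @return Durations in seconds within `range_s`.
#' @export
generate_loop_durations <- function(n, median_s = 34, range_s = c(11, 58),
                                    sdlog = 0.3, seed = NULL) {
  stopifnot(n >= 0, median_s > 0, length(range_s) == 2L,
            range_s[1] > 0, range_s[2] > range_s[1])
  if (!is.null(seed)) set.seed(seed)
  out <- numeric(0)
  while (length(out) < n) {
    d <- stats::rlnorm(max(n, 16L), meanlog = log(median_s), sdlog = sdlog)
    out <- c(out, d[d >= range_s[1] & d <= range_s[2]])
  }
  out[seq_len(n)]
}

#' Derive per-stage seeds from one master seed
#'
#' The pipeline draws from several independent generators; each stage gets
#' its own seed through the fixed rule `seed + 10007 * stage_index`, reduced
#' modulo 2^31 - 1 so the result is always a valid integer seed.
#'
#' @param seed Master integer seed.
#' @param n Number of substream seeds required.
#' @return Integer vector of `n` seeds.
#' @export
split_seed <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1)
  as.integer((as.double(seed) + 10007 * seq_len(n)) %% (2^31 - 1))
}
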