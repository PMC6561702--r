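#' Typical velocity perturbation from turbulent kinetic energy
#'
#' Converts turbulent kinetic energy `k` into a "typical" velocity
#' perturbation `u` under the assumption of isotropic turbulence, i.e. that
#' the fluctuations about the mean in the three velocity components are
#' similar in magnitude. Then \eqn{u = \sqrt{(2/3)\,k/\rho}}.
#'
#' @param k Turbulent kinetic energy (J m^-3). Vectorised; must be >= 0.
#' @param rho Air density (kg m^-3), default 1 so that density can be
#'   neglected when working with normalised CFD output.
#' @return Velocity perturbation in m s^-1, same length as `k`.
#' @examples
#' velocity_perturbation(1.5)   # 1
#' velocity_perturbation(0.015) # 0.1
#' @export
velocity_perturbation <- function(k, rho = 1) {
  stopifnot(is.numeric(k), is.numeric(rho), length(rho) == 1L)
  if (any(k < 0, na.rm = TRUE)) stop("turbulent kinetic energy `k` must be >= 0")
  if (!is.finite(rho) || rho <= 0) stop("air density `rho` must be > 0")
  sqrt((2 / 3) * k / rho)
}

#' Non-dimensional turbulence intensity
#'
#' Ratio of the typical velocity perturbation to the mean wind speed,
#' \eqn{I = u/U}. Typical values near the ground are ~0.1; values near 1
#' indicate winds whose fluctuations are as large as the mean.
#'
#' @param u Velocity perturbation (m s^-1), >= 0. Vectorised.
#' @param U Mean wind speed (m s^-1), must be strictly positive: the
#'   intensity is undefined in still air and a zero `U` is rejected rather
#'   than silently returned as infinite.
#' @return Turbulence intensity (dimensionless).
#' @export
turbulence_intensity <- function(u, U) {
  stopifnot(is.numeric(u), is.numeric(U))
  if (any(u < 0, na.rm = TRUE)) stop("velocity perturbation `u` must be >= 0")
  if (any(U <= 0, na.rm = TRUE))
    stop("turbulence intensity is undefined for mean wind U <= 0")
  u / U
}

#' Adjust a wind speed between heights with the logarithmic profile
#'
#' Under a neutral logarithmic boundary-layer profile with roughness length
#' `z0`, the speed measured at height `z1` is translated to height `z2` by
#' \eqn{U_2 = U_1 \ln(z_2/z_0) / \ln(z_1/z_0)}. Used e.g. to reduce wave-buoy
#' anemometer records from 3.5 m to the 2 m above-surface level at which
#' near-cliff conditions are assessed.
#'
#' @param U1 Wind speed at height `z1` (m s^-1). Vectorised.
#' @param z1,z2 Measurement and target heights (m); both must exceed `z0`.
#' @param z0 Roughness length (m), > 0. Over open sea a small value such as
#'   0.001 m is appropriate; over land the airflow model uses 0.1 m.
#' @return Wind speed at height `z2` (m s^-1).
#' @examples
#' adjust_wind_to_height(10, z1 = 3.5, z2 = 2, z0 = 0.001) # ~9.31
#' @export
adjust_wind_to_height <- function(U1, z1, z2, z0 = 0.001) {
  stopifnot(is.numeric(U1), is.numeric(z1), is.numeric(z2), is.numeric(z0))
  if (!is.finite(z0) || z0 <= 0) stop("roughness length `z0` must be > 0")
  if (z1 <= z0 || z2 <= z0)
    stop("heights must lie strictly above the roughness length `z0`")
  U1 * log(z2 / z0) / log(z1 / z0)
}

#' Sea-to-cliff wind scaling constant
#'
#' Cliffs shelter their immediate airspace: the wind an approaching bird
#' meets at the cliff is systematically weaker than the open-water wind.
#' This computes the scaling constant linking the two as the mean over wind
#' directions of the per-direction ratio (cliff speed / at-sea speed) —
#' mean-of-ratios, matching per-direction normalisation by an upwind
#' reference speed.
#'
#' @param cliff Wind speeds adjacent to the cliff (m s^-1), one per direction.
#' @param sea Matching open-water speeds (m s^-1), all > 0.
#' @param directions Optional labels for the directions averaged over.
#' @return An object of class `scaling_constant` with elements `ratio`,
#'   `per_direction` and `directions`.
#' @examples
#' sea_to_cliff_ratio(c(5, 6), c(10, 10))$ratio # 0.55
#' @export
sea_to_cliff_ratio <- function(cliff, sea, directions = NULL) {
  stopifnot(is.numeric(cliff), is.numeric(sea))
  if (length(cliff) == 0L) stop("at least one (cliff, sea) pair is required")
  if (length(cliff) != length(sea))
    stop("`cliff` and `sea` must have the same length")
  if (any(!is.finite(sea)) || any(sea <= 0))
    stop("all at-sea wind speeds must be positive")
  if (any(cliff < 0)) stop("cliff wind speeds must be >= 0")
  r <- cliff / sea
  structure(
    list(ratio = mean(r), per_direction = r,
         directions = directions %||% seq_along(r)),
    class = "scaling_constant"
  )
}

#' @export
print.scaling_constant <- function(x, ...) {
  cat("Sea-to-cliff wind scaling\n")
  cat(sprintf("  mean ratio (cliff / at-sea): %.4f over %d direction(s)\n",
              x$ratio, length(x$per_direction)))
  invisible(x)
}

#' Derive perturbation and turbulence intensity for a gridded wind field
#'
#' Adds columns `u` (typical velocity perturbation) and `I` (turbulence
#' intensity) to a data frame of wind-field samples holding mean speed `U`
#' and turbulent kinetic energy `k`, as extracted from an airflow model.
#' Points with `U = 0` get `I = NA` with a warning rather than an infinite
#' intensity.
#'
#' @param grid Data frame with numeric columns `U` and `k` (and optionally
#'   coordinates); other columns are passed through.
#' @param rho Air density (kg m^-3), default 1.
#' @return The input data frame with `u` and `I` appended.
#' @export
derive_turbulence <- function(grid, rho = 1) {
  stopifnot(is.data.frame(grid))
  need <- setdiff(c("U", "k"), names(grid))
  if (length(need))
    stop("wind grid is missing column(s): ", paste(need, collapse = ", "))
  grid$u <- velocity_perturbation(grid$k, rho)
  grid$I <- ifelse(grid$U > 0, grid$u / grid$U, NA_real_)
  if (anyNA(grid$I))
    warning("turbulence intensity undefined (U = 0) at ",
            sum(is.na(grid$I)), " grid point(s); set to NA")
  grid
}

`%||%` <- function(a, b) if (is.null(a)) b else a
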