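#' Logistic landing-probability curve
#'
#' For a fixed situation (ledge class, height band, species, turbulence
#' level), the probability that a single landing attempt succeeds is modelled
#' as a logistic function of the instantaneous wind speed `W`:
#' \deqn{p(W) = a / (a + e^{bW})}
#' with `a > 0` setting the still-air odds (p(0) = a/(a+1)) and `b` the
#' logit slope per m s^-1; `b > 0` means success declines with wind.
#'
#' @param a Positive dimensionless constant.
#' @param b Logit slope per m s^-1 (positive when wind impedes landing).
#' @return An object of class `logistic_landing`.
#' @seealso [logistic_from_glmm()] to derive (a, b) from a fitted
#'   mixed model, [landing_prob_given_wind()] to evaluate the curve.
#' @export
logistic_landing <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == 1L, length(b) == 1L)
  if (!is.finite(a) || a <= 0) stop("`a` must be a positive constant")
  if (!is.finite(b)) stop("`b` must be finite")
  structure(list(a = a, b = b), class = "logistic_landing")
}

#' @export
print.logistic_landing <- function(x, ...) {
  cat(sprintf("Logistic landing curve p(W) = a/(a + exp(bW)); a = %.6g, b = %.6g\n",
              x$a, x$b))
  cat(sprintf("  p(0) = %.4f; success %s with wind\n", x$a / (x$a + 1),
              if (x$b > 0) "declines" else if (x$b < 0) "increases"
              else "does not change"))
  invisible(x)
}

#' Landing probability at a given instantaneous wind speed
#'
#' @param model A [logistic_landing()] curve.
#' @param W Instantaneous wind speed(s), m s^-1, >= 0.
#' @return Probabilities in (0, 1), same length as `W`.
#' @examples
#' landing_prob_given_wind(logistic_landing(1, 0.62), 10) # ~0.00202
#' @export
landing_prob_given_wind <- function(model, W) {
  stopifnot(inherits(model, "logistic_landing"), is.numeric(W))
  if (any(W < 0)) stop("wind speed W must be >= 0")
  # evaluated as plogis(log a - bW) for numerical stability at large bW
  if (model$b == 0) return(rep(stats::plogis(log(model$a)), length(W)))
  stats::plogis(log(model$a) - model$b * W)
}

#' Log-normal wind distribution matched to mean and fluctuation SD
#'
#' A bird attempting to land repeatedly samples instantaneous cliff winds
#' W ~ LogNormal(m, s^2). The log-scale parameters are chosen by moment
#' matching so that W has arithmetic mean `U` (mean cliff wind) and standard
#' deviation `u` (root-mean-square turbulent fluctuation):
#' \deqn{s^2 = \ln(1 + u^2/U^2), \quad m = \ln U - s^2/2.}
#' With `u = 0` the distribution is the point mass at `U` (s = 0).
#'
#' @param U Mean wind speed (m s^-1), > 0.
#' @param u SD of the fluctuations (m s^-1), >= 0. Equal to
#'   `turbulence_intensity * U`.
#' @return An object of class `wind_distribution` with fields `U`, `u`,
#'   `m`, `s`.
#' @export
lognormal_from_moments <- function(U, u) {
  stopifnot(is.numeric(U), is.numeric(u), length(U) == 1L, length(u) == 1L)
  if (!is.finite(U) || U <= 0) stop("mean wind U must be > 0")
  if (!is.finite(u) || u < 0) stop("fluctuation SD u must be >= 0")
  s2 <- log(1 + (u / U)^2)
  structure(list(U = U, u = u, m = log(U) - s2 / 2, s = sqrt(s2)),
            class = "wind_distribution")
}

#' @export
print.wind_distribution <- function(x, ...) {
  cat(sprintf(
    "LogNormal cliff-wind model: mean U = %.4g m/s, SD u = %.4g m/s (m = %.6g, s = %.6g)\n",
    x$U, x$u, x$m, x$s))
  invisible(x)
}

#' Mean landing probability over the wind distribution
#'
#' The per-attempt success probability when each attempt meets an
#' independent instantaneous wind `W ~ LogNormal(m, s^2)`:
#' \deqn{P = E[p(W)] = \int_0^\infty p(W)\, f_{LN}(W; m, s)\, dW.}
#' The integral is evaluated on the standardised log scale,
#' `z = (ln W - m)/s`, where the integrand is the bounded smooth function
#' `p(exp(m + s z)) phi(z)`; adaptive quadrature is run on the +/- 12
#' standardised range with absolute tolerance 1e-10, the truncated Gaussian
#' tail (< 4e-33, below the tolerance) bounding the truncation error. A
#' degenerate distribution (`u = 0`) returns `p(U)` exactly.
#'
#' @param model A [logistic_landing()] curve.
#' @param wind A [lognormal_from_moments()] wind distribution.
#' @param abs_tol Absolute quadrature tolerance.
#' @return The per-attempt success probability `P` in (0, 1).
#' @seealso [mean_landing_prob_mc()] for the Monte-Carlo estimate of the
#'   same quantity.
#' @export
mean_landing_prob <- function(model, wind, abs_tol = 1e-10) {
  stopifnot(inherits(model, "logistic_landing"),
            inherits(wind, "wind_distribution"))
  if (wind$s == 0)
    return(landing_prob_given_wind(model, wind$U))
  integrand <- function(z)
    landing_prob_given_wind(model, exp(wind$m + wind$s * z)) * stats::dnorm(z)
  q <- stats::integrate(integrand, -12, 12, abs.tol = abs_tol,
                        rel.tol = abs_tol, stop.on.error = FALSE)
  if (q$message != "OK")
    stop("quadrature for the mean landing probability did not converge: ",
         q$message)
  min(max(q$value, 0), 1)
}

#' Monte-Carlo estimate of the mean landing probability
#'
#' Brute-force companion to [mean_landing_prob()]: averages `p(W)` over
#' independent log-normal draws of the instantaneous wind.
#'
#' @inheritParams mean_landing_prob
#' @param n_draws Number of draws, >= 1.
#' @param seed Optional integer seed.
#' @return List with `P` (the estimate), `se` (its standard error) and
#'   `n_draws`.
#' @export
mean_landing_prob_mc <- function(model, wind, n_draws = 1e6, seed = NULL) {
  stopifnot(inherits(model, "logistic_landing"),
            inherits(wind, "wind_distribution"), n_draws >= 1)
  if (!is.null(seed)) set.seed(seed)
  W <- if (wind$s == 0) rep(wind$U, n_draws)
       else stats::rlnorm(n_draws, wind$m, wind$s)
  p <- landing_prob_given_wind(model, W)
  list(P = mean(p), se = stats::sd(p) / sqrt(n_draws), n_draws = n_draws)
}

#' Geometric distribution of the number of attempts to land
#'
#' When every attempt independently succeeds with probability `P`, the
#' number of attempts `S` up to and including the first success is
#' geometric: `P(S = n) = (1 - P)^(n-1) P`, `P(S <= n) = 1 - (1 - P)^n`,
#' and the expected number of attempts is `1/P`.
#'
#' @param P Per-attempt success probability in (0, 1].
#' @return An object of class `attempt_distribution` with fields `P` and
#'   `expected_attempts`, plus pmf/cdf/quantile accessors
#'   ([attempt_pmf()], [attempt_cdf()], [attempt_quantile()]).
#' @export
attempt_distribution <- function(P) {
  stopifnot(is.numeric(P), length(P) == 1L)
  if (!is.finite(P) || P <= 0 || P > 1)
    stop("per-attempt success probability P must lie in (0, 1]")
  structure(list(P = P, expected_attempts = 1 / P),
            class = "attempt_distribution")
}

#' @rdname attempt_distribution
#' @param dist An `attempt_distribution`.
#' @param n Attempt number(s), integer >= 1.
#' @export
attempt_pmf <- function(dist, n) {
  stopifnot(inherits(dist, "attempt_distribution"), all(n >= 1))
  (1 - dist$P)^(n - 1) * dist$P
}

#' @rdname attempt_distribution
#' @export
attempt_cdf <- function(dist, n) {
  stopifnot(inherits(dist, "attempt_distribution"), all(n >= 0))
  1 - (1 - dist$P)^n
}

#' @rdname attempt_distribution
#' @param q Probability level(s) in (0, 1).
#' @export
attempt_quantile <- function(dist, q) {
  stopifnot(inherits(dist, "attempt_distribution"), all(q > 0), all(q < 1))
  if (dist$P == 1) return(rep(1, length(q)))
  ceiling(log1p(-q) / log1p(-dist$P))
}

#' @export
print.attempt_distribution <- function(x, ...) {
  cat(sprintf(
    "Geometric attempt distribution: P = %.4f per attempt, expected attempts = %.2f\n",
    x$P, x$expected_attempts))
  cat(sprintf("  P(landed within 6 attempts)  = %.3f\n", attempt_cdf(x, 6)))
  cat(sprintf("  P(landed within 20 attempts) = %.3f\n", attempt_cdf(x, 20)))
  invisible(x)
}

#' Landing curves as a function of the at-sea wind speed
#'
#' Wind records over seasons come from open-water buoys, while birds meet
#' the (weaker) wind adjacent to the cliff. For each at-sea speed `w` this
#' translates to the cliff via the scaling constant (`U = ratio * w`), sets
#' the fluctuation SD from the fixed turbulence intensity (`u = TI * U`),
#' matches the log-normal wind model, integrates to the per-attempt success
#' probability `P`, and tabulates the geometric cumulative landing
#' probabilities for attempts 1..`n_max`.
#'
#' @param model A [logistic_landing()] curve for the chosen situation.
#' @param TI Turbulence intensity at the cliff, >= 0 (default 0.2).
#' @param scaling A [sea_to_cliff_ratio()] result, or a bare positive number.
#' @param sea_winds At-sea mean wind speeds (m s^-1), > 0.
#' @param n_max Largest attempt number tabulated (default 20, the most a
#'   guillemot is predicted to need near the seasonal maximum wind).
#' @return Data frame with one row per sea wind: `sea_wind`, `cliff_wind`,
#'   `P`, `expected_attempts`, and `cum_1` ... `cum_<n_max>` cumulative
#'   landing probabilities.
#' @export
landing_curve_at_sea <- function(model, TI = 0.2, scaling = 1, sea_winds,
                                 n_max = 20) {
  stopifnot(inherits(model, "logistic_landing"), is.numeric(sea_winds),
            n_max >= 1)
  ratio <- if (inherits(scaling, "scaling_constant")) scaling$ratio
           else as.numeric(scaling)
  if (!is.finite(ratio) || ratio <= 0) stop("scaling ratio must be > 0")
  if (TI < 0) stop("turbulence intensity must be >= 0")
  if (any(sea_winds <= 0)) stop("sea wind speeds must be > 0")
  rows <- lapply(sea_winds, function(w) {
    U <- ratio * w
    P <- mean_landing_prob(model, lognormal_from_moments(U, TI * U))
    dist <- attempt_distribution(P)
    c(sea_wind = w, cliff_wind = U, P = P,
      expected_attempts = dist$expected_attempts,
      stats::setNames(attempt_cdf(dist, seq_len(n_max)),
                      paste0("cum_", seq_len(n_max))))
  })
  as.data.frame(do.call(rbind, rows))
}
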