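#' Energetic cost of one landing attempt
#'
#' Each aborted approach costs a full landing loop flown at level-flight
#' power. The cost is `flight_power * loop_duration / 1000` kilojoules.
#'
#' @param flight_power Metabolic power of level flight (W), from the
#'   literature for the species at hand.
#' @param loop_duration Duration of one landing loop (s); the observed
#'   median is 34 s (range 11-58 s).
#' @return Cost per attempt in kJ.
#' @examples
#' cost_per_attempt(144.1, 34) # ~4.9 kJ
#' @export
cost_per_attempt <- function(flight_power, loop_duration = 34) {
  stopifnot(is.numeric(flight_power), is.numeric(loop_duration))
  if (any(flight_power <= 0) || any(loop_duration <= 0))
    stop("flight power and loop duration must be > 0")
  flight_power * loop_duration / 1000
}

#' Expected energetic cost of a landing bout
#'
#' A bout is the sequence of attempts up to the first success; with
#' geometric attempts the expected cost is `cost / P` and the cost
#' quantiles follow the geometric quantiles.
#'
#' @param cost Cost of one attempt (kJ), > 0.
#' @param attempts An [attempt_distribution()].
#' @param probs Quantile levels for the cost distribution.
#' @return List with `expected_kj` and `quantiles_kj` (named by level).
#' @export
expected_bout_cost <- function(cost, attempts, probs = c(0.5, 0.9, 0.95)) {
  stopifnot(is.numeric(cost), length(cost) == 1L, cost > 0,
            inherits(attempts, "attempt_distribution"))
  list(expected_kj = cost * attempts$expected_attempts,
       quantiles_kj = stats::setNames(cost * attempt_quantile(attempts, probs),
                                      paste0("q", probs * 100)))
}

#' Landing attempts bought by one prey item
#'
#' Number of landing loops whose summed cost equals the calorific value of
#' one prey item (e.g. a lesser sandeel), i.e.
#' `prey_energy / cost_per_attempt`.
#'
#' @param prey_energy Gross calorific value of the prey item (kJ), > 0.
#' @param cost Cost of one attempt (kJ), > 0.
#' @return Real-valued attempt count.
#' @examples
#' attempts_per_prey_item(29.4, 4.9) # 6
#' @export
attempts_per_prey_item <- function(prey_energy, cost) {
  stopifnot(is.numeric(prey_energy), is.numeric(cost))
  if (any(prey_energy <= 0) || any(cost <= 0))
    stop("prey energy and attempt cost must be > 0")
  prey_energy / cost
}
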