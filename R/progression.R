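#' Convert a median time to progression to an exponential hazard rate
#'
#' The progression model is exponential throughout: a drug population with
#' true median time to progression (TTP) `m` months progresses with constant
#' hazard `log(2) / m` per month. The two parameterisations are exact
#' inverses of one another.
#'
#' @param median_ttp Median TTP in months; must be a single positive number.
#' @return The hazard rate per month, `log(2) / median_ttp`.
#' @seealso [hazard_to_median()], [epd_probability()]
#' @examples
#' median_to_hazard(3)            # 0.2310
#' hazard_to_median(median_to_hazard(6))  # 6
#' @export
median_to_hazard <- function(median_ttp) {
  check_number(median_ttp, "median_ttp", lower = 0, strict_lower = TRUE)
  log(2) / median_ttp
}

#' @rdname median_to_hazard
#' @param hazard Hazard rate per month; must be a single positive number.
#' @export
hazard_to_median <- function(hazard) {
  check_number(hazard, "hazard", lower = 0, strict_lower = TRUE)
  log(2) / hazard
}

#' Probability of early progressive disease under exponential progression
#'
#' Early progressive disease (EPD) is progression detected at the first
#' post-baseline tumour measurement, taken `t_first` months after treatment
#' start. Under an exponential TTP distribution with median `median_ttp`,
#'
#' \deqn{P(\mathrm{EPD}) = 1 - 2^{-t_{first}/m} = 1 - e^{-\lambda t_{first}},}
#'
#' with \eqn{\lambda = \log(2)/m}. The probability is strictly decreasing in
#' the median and strictly increasing in the scan time, and equals 0.5
#' exactly when `t_first == median_ttp` (the definition of the median).
#'
#' @param median_ttp True median TTP in months (> 0).
#' @param t_first Time of first tumour measurement in months (> 0).
#' @return A probability in (0, 1).
#' @examples
#' epd_probability(3, 1.5)   # 1 - 2^(-1/2) = 0.2929
#' epd_probability(6, 1.5)   # 0.1591
#' @export
epd_probability <- function(median_ttp, t_first) {
  check_number(median_ttp, "median_ttp", lower = 0, strict_lower = TRUE)
  check_number(t_first, "t_first", lower = 0, strict_lower = TRUE)
  -expm1(-median_to_hazard(median_ttp) * t_first)
}

#' Draw exponential times to progression
#'
#' Simple seeded wrapper around [stats::rexp()] used by the trial simulator;
#' the empirical median of a large sample converges to `log(2) / hazard`.
#'
#' @param n Number of draws.
#' @param hazard Hazard rate per month (> 0).
#' @return Numeric vector of `n` progression times in months.
#' @export
sample_ttp <- function(n, hazard) {
  check_count(n, "n", lower = 0L)
  check_number(hazard, "hazard", lower = 0, strict_lower = TRUE)
  stats::rexp(n, rate = hazard)
}
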