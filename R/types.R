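#' Null and alternative hypotheses for a combination stopping rule design
#'
#' The design tests drug inactivity against activity on two endpoints at
#' once. The null hypothesis (drug uninteresting) is `r <= r_nul` AND
#' `ttp <= ttp_nul`; the alternative (drug interesting) is `r >= r_alt` OR
#' `ttp >= ttp_alt`, where `r` is the true response rate and `ttp` the true
#' median time to progression in months. At stage I the TTP component is
#' carried by its earliest observable surrogate, early progressive disease:
#' the null and alternative EPD rates are derived from the TTP hypotheses by
#' [epd_probability()] at the time of first tumour measurement.
#'
#' @param r_nul,r_alt Uninteresting and interesting response rates,
#'   `0 <= r_nul < r_alt <= 1`.
#' @param ttp_nul,ttp_alt Uninteresting and interesting median TTP in
#'   months, `0 < ttp_nul < ttp_alt`.
#' @param t_first Time of first tumour measurement in months (default 1.5,
#'   a standard six-week restaging interval); used to derive the EPD rates.
#' @return An object of class `"csr_hypotheses"`: a list with the four
#'   inputs plus the derived `epd_nul` and `epd_alt`.
#' @examples
#' csr_hypotheses(0.05, 0.20, 3, 6)
#' @export
csr_hypotheses <- function(r_nul, r_alt, ttp_nul, ttp_alt, t_first = 1.5) {
  check_number(r_nul, "r_nul", lower = 0, upper = 1)
  check_number(r_alt, "r_alt", lower = 0, upper = 1)
  check_number(ttp_nul, "ttp_nul", lower = 0, strict_lower = TRUE)
  check_number(ttp_alt, "ttp_alt", lower = 0, strict_lower = TRUE)
  check_number(t_first, "t_first", lower = 0, strict_lower = TRUE)
  if (r_nul >= r_alt)
    stop_invalid(sprintf("need r_nul < r_alt, got r_nul = %g, r_alt = %g",
                         r_nul, r_alt))
  if (ttp_nul >= ttp_alt)
    stop_invalid(sprintf("need ttp_nul < ttp_alt, got ttp_nul = %g, ttp_alt = %g",
                         ttp_nul, ttp_alt))
  structure(list(
    r_nul = r_nul, r_alt = r_alt,
    ttp_nul = ttp_nul, ttp_alt = ttp_alt,
    t_first = t_first,
    epd_nul = epd_probability(ttp_nul, t_first),
    epd_alt = epd_probability(ttp_alt, t_first)
  ), class = "csr_hypotheses")
}

#' @export
print.csr_hypotheses <- function(x, ...) {
  cat("Combination stopping rule hypotheses\n")
  cat(sprintf("  H_nul: RR <= %.3g and median TTP <= %.3g mo (EPD >= %.3f)\n",
              x$r_nul, x$ttp_nul, x$epd_nul))
  cat(sprintf("  H_alt: RR >= %.3g or  median TTP >= %.3g mo (EPD <= %.3f)\n",
              x$r_alt, x$ttp_alt, x$epd_alt))
  cat(sprintf("  first tumour measurement at %.3g mo\n", x$t_first))
  invisible(x)
}

#' Trial and simulation configuration
#'
#' Bundles the per-trial mechanics (stage sizes, censoring, scan time) with
#' the search settings (error limits, replication count, TTP grid step,
#' seed) used by the Monte-Carlo engine.
#'
#' @param n1,n2 Stage I and stage II sample sizes (patients); `n1 >= 1`,
#'   `n2 >= 0`.
#' @param t_first Time of first tumour measurement in months (default 1.5).
#' @param censor_prob Per-patient probability of censoring for the TTP
#'   endpoint (default 0.05). Patients censored before `t_first` are
#'   replaced, mirroring trial practice of replacing early unevaluable
#'   patients.
#' @param min_median_ttp Absolute floor on a clinically conceivable median
#'   TTP, in months (default 1); lower bound of the mixture draw for the
#'   alternative scenario and of nothing else.
#' @param alpha_max Maximum tolerated type I error (default 0.05).
#' @param power_min Minimum required power (default 0.80).
#' @param n_sim Number of simulated trials per Monte-Carlo evaluation
#'   (default 100000; a warning is issued below 1000).
#' @param ttp_grid_step Grid step for candidate median-TTP thresholds in
#'   months (fixed at 0.25 by the search; changing it changes the
#'   threshold resolution).
#' @param seed Integer seed making every downstream simulation
#'   reproducible; `NULL` leaves the RNG state alone.
#' @return An object of class `"csr_config"`.
#' @examples
#' csr_config(n1 = 15, n2 = 15, seed = 1)
#' @export
csr_config <- function(n1, n2, t_first = 1.5, censor_prob = 0.05,
                       min_median_ttp = 1, alpha_max = 0.05,
                       power_min = 0.80, n_sim = 100000L,
                       ttp_grid_step = 0.25, seed = NULL) {
  n1 <- check_count(n1, "n1", lower = 1L)
  n2 <- check_count(n2, "n2", lower = 0L)
  check_number(t_first, "t_first", lower = 0, strict_lower = TRUE)
  check_number(censor_prob, "censor_prob", lower = 0, upper = 1,
               strict_upper = TRUE)
  check_number(min_median_ttp, "min_median_ttp", lower = 0,
               strict_lower = TRUE)
  check_number(alpha_max, "alpha_max", lower = 0, upper = 1)
  check_number(power_min, "power_min", lower = 0, upper = 1)
  n_sim <- check_count(n_sim, "n_sim", lower = 1L)
  if (n_sim < 1000L)
    warning("n_sim < 1000: Monte-Carlo error will dominate the estimates")
  check_number(ttp_grid_step, "ttp_grid_step", lower = 0, strict_lower = TRUE)
  if (!is.null(seed)) seed <- check_count(seed, "seed")
  structure(list(
    n1 = n1, n2 = n2, t_first = t_first, censor_prob = censor_prob,
    min_median_ttp = min_median_ttp, alpha_max = alpha_max,
    power_min = power_min, n_sim = n_sim, ttp_grid_step = ttp_grid_step,
    seed = seed
  ), class = "csr_config")
}

#' @export
print.csr_config <- function(x, ...) {
  cat("CSR trial configuration\n")
  cat(sprintf("  stage sizes n1 = %d, n2 = %d; first scan %.3g mo; censoring %.3g\n",
              x$n1, x$n2, x$t_first, x$censor_prob))
  cat(sprintf("  limits: alpha <= %.3g, power >= %.3g; min median TTP %.3g mo\n",
              x$alpha_max, x$power_min, x$min_median_ttp))
  cat(sprintf("  n_sim = %d, TTP grid step %.3g mo, seed %s\n",
              x$n_sim, x$ttp_grid_step,
              if (is.null(x$seed)) "unset" else format(x$seed)))
  invisible(x)
}

#' Stopping rules for a combination two-stage design
#'
#' The four thresholds that define the decision procedure. At the end of
#' stage I the trial stops and accepts the null (futility) if the stage-I
#' response count is `<= r1_stop` AND the stage-I EPD count is
#' `>= epd_stop`; early rejection of the null is never permitted. At the
#' end of stage II the null is rejected if the cumulative response count is
#' `>= r2_reject` OR the Kaplan-Meier median TTP is `>= ttp2_reject`
#' months (a median not reached by the data counts as exceeding any
#' threshold).
#'
#' `r1_stop = -1` or `epd_stop = n1 + 1` are sentinel values meaning the
#' stage-I stop state is unreachable: the trial always proceeds to stage II.
#'
#' @param r1_stop Stage-I response threshold (integer, `-1` allowed).
#' @param epd_stop Stage-I EPD threshold (integer, `n1 + 1` allowed).
#' @param r2_reject Final response threshold (integer >= 1).
#' @param ttp2_reject Final median-TTP threshold in months.
#' @param n1 Optional stage-I size used to validate reachability of the
#'   stage-I stop state.
#' @return An object of class `"csr_rules"`.
#' @examples
#' csr_rules(r1_stop = 0, epd_stop = 5, r2_reject = 5, ttp2_reject = 5.25)
#' @export
csr_rules <- function(r1_stop, epd_stop, r2_reject, ttp2_reject, n1 = NULL) {
  r1_stop <- check_count(r1_stop, "r1_stop", lower = -1L)
  epd_stop <- check_count(epd_stop, "epd_stop", lower = 0L)
  r2_reject <- check_count(r2_reject, "r2_reject", lower = 1L)
  check_number(ttp2_reject, "ttp2_reject", lower = 0, strict_lower = TRUE)
  if (r1_stop >= r2_reject)
    stop_invalid("r1_stop must be smaller than r2_reject")
  if (!is.null(n1)) {
    n1 <- check_count(n1, "n1", lower = 1L)
    if (epd_stop > n1 + 1L)
      stop_invalid(sprintf("epd_stop = %d exceeds n1 + 1 = %d",
                           epd_stop, n1 + 1L))
    if (r1_stop >= 0L && epd_stop <= n1 && r1_stop + epd_stop > n1 + 1L)
      stop_invalid("stage-I stop state unreachable: r1_stop + epd_stop > n1 + 1")
  }
  structure(list(r1_stop = r1_stop, epd_stop = epd_stop,
                 r2_reject = r2_reject, ttp2_reject = ttp2_reject),
            class = "csr_rules")
}

#' @export
print.csr_rules <- function(x, ...) {
  cat("CSR stopping rules\n")
  if (x$r1_stop < 0L)
    cat("  stage I : never stop (sentinel thresholds)\n")
  else
    cat(sprintf("  stage I : accept H_nul if responses <= %d and EPD >= %d\n",
                x$r1_stop, x$epd_stop))
  cat(sprintf("  stage II: reject H_nul if responses >= %d or KM median TTP >= %.2f mo\n",
              x$r2_reject, x$ttp2_reject))
  invisible(x)
}
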