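#' Kaplan-Meier median of a right-censored sample
#'
#' Computes the product-limit survivor estimate and returns the smallest
#' observed event time `t` at which `S(t)` falls strictly below 0.5. Tied
#' event and censoring times are resolved events-first, the usual
#' Kaplan-Meier convention. A step that lands exactly on `S = 0.5` does
#' not define the median -- half the sample is still progression-free
#' there, so for an uncensored sample of even size `n` the median is the
#' `(n/2 + 1)`-th order statistic. (This differs from the `S(t) <= 0.5`
#' rule used by [survival::survfit()], which would take the `n/2`-th; the
#' two agree whenever the survivor estimate does not step exactly onto
#' 0.5.) If the estimate never falls below 0.5 (heavy censoring, or all
#' observations censored) the median is not reached and `Inf` is returned,
#' so comparisons such as `km_median(...) >= threshold` behave naturally.
#'
#' @param times Non-negative observed times (event or censoring), months.
#' @param events Event indicators, 1 = progression observed, 0 = censored;
#'   same length as `times`.
#' @return The median in months, or `Inf` if not reached.
#' @examples
#' km_median(1:5, rep(1, 5))            # 3: S(3) = 0.4
#' km_median(1:4, rep(1, 4))            # 3: S(2) = 0.5 exactly, not below
#' km_median(1:3, c(1, 0, 0))           # Inf: S stays at 2/3
#' @export
km_median <- function(times, events) {
  if (length(times) == 0L || length(times) != length(events))
    stop_invalid("'times' and 'events' must be nonempty and of equal length")
  if (any(!is.finite(times)) || any(times < 0))
    stop_invalid("'times' must be finite and non-negative")
  events <- as.integer(events != 0)
  o <- order(times, -events)
  tt <- times[o]; ee <- events[o]
  n <- length(tt)
  s <- cumprod(1 - ee / (n - seq_len(n) + 1))
  hit <- which(ee == 1L & s < 0.5 - 1e-12)
  if (length(hit) == 0L) Inf else tt[hit[1L]]
}

# Row-wise Kaplan-Meier medians for a bank of simulated trials.
# times, events: n_sim x n_pat matrices. Fully vectorised: one global sort
# keyed by (row, time, event-first), then a cumulative product swept over
# the patient columns. Returns a length-n_sim vector (Inf = not reached).
km_median_rows <- function(times, events) {
  ns <- nrow(times); np <- ncol(times)
  o <- order(row(times), times, -events)
  ts <- matrix(times[o], ns, np, byrow = TRUE)
  es <- matrix(events[o], ns, np, byrow = TRUE)
  med <- rep(Inf, ns)
  open <- rep(TRUE, ns)
  logs <- numeric(ns)
  for (j in seq_len(np)) {
    logs <- logs + log1p(-es[, j] / (np - j + 1))
    # strictly below 0.5; the margin excludes steps landing exactly on 0.5
    # (accumulated log error ~1e-14, next distinct S level >= ~1/n lower)
    hit <- open & es[, j] == 1 & logs < log(0.5) - 1e-9
    if (any(hit)) {
      med[hit] <- ts[hit, j]
      open[hit] <- FALSE
    }
  }
  med
}

# Draw one n_sim x n_pat block of patient outcomes, with replacement of
# patients censored before the first tumour measurement. rr and rate are
# length-n_sim vectors (per-trial true parameters); matrices are filled
# column-major so the vectors recycle correctly across patients.
# Returns response/ttp/observed/event matrices plus per-trial replacement
# counts split at patient column n1 (stage I vs stage II slots).
draw_patients <- function(n_sim, n_pat, n1, rr, rate, censor_prob, t_first) {
  m <- n_sim * n_pat
  resp <- matrix(stats::rbinom(m, 1L, rr), n_sim, n_pat)
  ttp <- matrix(stats::rexp(m, rate), n_sim, n_pat)
  cens <- matrix(stats::rbinom(m, 1L, censor_prob) == 1L, n_sim, n_pat)
  ctime <- matrix(stats::runif(m), n_sim, n_pat) * ttp
  extra1 <- integer(n_sim)
  extra2 <- integer(n_sim)
  redo <- which(cens & ctime < t_first)
  iter <- 0L
  while (length(redo) > 0L) {
    iter <- iter + 1L
    if (iter > 10000L)
      stop_invalid("patient replacement loop exceeded 10000 iterations; censoring configuration is degenerate")
    k <- length(redo)
    row_i <- (redo - 1L) %% n_sim + 1L
    col_i <- (redo - 1L) %/% n_sim + 1L
    in1 <- col_i <= n1
    extra1 <- extra1 + tabulate(row_i[in1], n_sim)
    extra2 <- extra2 + tabulate(row_i[!in1], n_sim)
    resp[redo] <- stats::rbinom(k, 1L, rr[row_i])
    t_new <- stats::rexp(k, rate[row_i])
    ttp[redo] <- t_new
    c_new <- stats::rbinom(k, 1L, censor_prob) == 1L
    cens[redo] <- c_new
    ct_new <- stats::runif(k) * t_new
    ctime[redo] <- ct_new
    redo <- redo[c_new & ct_new < t_first]
  }
  observed <- ifelse(cens, ctime, ttp)
  event <- !cens
  list(resp = resp, ttp = ttp, observed = observed, event = event,
       extra1 = extra1, extra2 = extra2)
}

#' Simulate a bank of two-stage trials
#'
#' Simulates `n_sim` independent trials of `n1 + n2` patients each and
#' returns the per-trial summaries on which every stopping rule operates:
#' stage-I response and EPD counts, the cumulative response count, and the
#' Kaplan-Meier median TTP over all retained patients. No stopping rule is
#' applied here -- thresholds are pure functions of these summaries, so a
#' single bank can be re-thresholded many times (this is what makes the
#' design search cheap).
#'
#' Each patient responds with probability `true_rr`, independently of a
#' latent exponential progression time with median `true_median_ttp`
#' months. With probability `censor_prob` the patient is censored at a time
#' drawn uniformly between 0 and the progression time; a patient censored
#' before the first tumour measurement is replaced by a fresh draw
#' (replacements are counted in `n_extra1`/`n_extra2` but excluded from all
#' decision summaries). A patient has EPD if progression is observed at or
#' before `t_first` and the patient is not a responder -- response and EPD
#' are mutually exclusive readings of the same first scan. A responder's
#' latent progression time still enters the Kaplan-Meier estimate
#' unchanged.
#'
#' @param n_sim Number of trials to simulate.
#' @param true_rr True response rate; scalar or length-`n_sim` vector
#'   (per-trial truths, used by the alternative-mixture evaluation).
#' @param true_median_ttp True median TTP in months; scalar or
#'   length-`n_sim` vector.
#' @param config A [csr_config()]; its `seed` is applied if set.
#' @return A `data.frame` with one row per trial: `r1`, `epd1`, `r_total`,
#'   `km_median` (months, `Inf` = not reached), `n_extra1`, `n_extra2`
#'   (replaced patients by stage). Stage sizes are attached as attributes.
#' @examples
#' cfg <- csr_config(n1 = 15, n2 = 15, n_sim = 2000, seed = 7)
#' bank <- simulate_trials(2000, 0.05, 3, cfg)
#' colMeans(bank[, c("r1", "epd1")])
#' @export
simulate_trials <- function(n_sim, true_rr, true_median_ttp, config) {
  stopifnot(inherits(config, "csr_config"))
  n_sim <- check_count(n_sim, "n_sim", lower = 1L)
  if (any(true_rr < 0 | true_rr > 1))
    stop_invalid("'true_rr' must lie in [0, 1]")
  if (any(true_median_ttp <= 0))
    stop_invalid("'true_median_ttp' must be positive")
  rr <- rep_len(as.numeric(true_rr), n_sim)
  rate <- log(2) / rep_len(as.numeric(true_median_ttp), n_sim)
  with_seed(config$seed, {
    n1 <- config$n1; n2 <- config$n2
    d <- draw_patients(n_sim, n1 + n2, n1, rr, rate, config$censor_prob,
                       config$t_first)
    s1 <- seq_len(n1)
    epd <- d$event & d$ttp <= config$t_first & d$resp == 0L
    r1 <- as.integer(rowSums(d$resp[, s1, drop = FALSE]))
    epd1 <- as.integer(rowSums(epd[, s1, drop = FALSE]))
    r_total <- as.integer(rowSums(d$resp))
    km <- km_median_rows(d$observed, d$event + 0)
    out <- data.frame(r1 = r1, epd1 = epd1, r_total = r_total,
                      km_median = km,
                      n_extra1 = d$extra1, n_extra2 = d$extra2)
    attr(out, "n1") <- n1
    attr(out, "n2") <- n2
    out
  })
}

# Apply stopping rules to a simulated bank. Returns logical vectors:
# stop1 (accept H_nul at stage I) and reject (reject H_nul at stage II).
# A not-reached KM median (Inf) exceeds any TTP threshold.
apply_rules <- function(bank, rules) {
  stop1 <- bank$r1 <= rules$r1_stop & bank$epd1 >= rules$epd_stop
  rej2 <- bank$r_total >= rules$r2_reject |
    bank$km_median >= rules$ttp2_reject - 1e-9
  list(stop1 = stop1, reject = !stop1 & rej2)
}

#' Simulate a single two-stage trial under given stopping rules
#'
#' Runs one trial through the full decision procedure: enrol `n1` patients,
#' stop for futility if responses `<= r1_stop` and EPD `>= epd_stop`,
#' otherwise enrol `n2` more and reject inactivity if cumulative responses
#' `>= r2_reject` or the Kaplan-Meier median TTP `>= ttp2_reject`. Early
#' rejection of the null at stage I is never permitted.
#'
#' @inheritParams simulate_trials
#' @param rules A [csr_rules()] object.
#' @return A list of class `"csr_trial_result"`: `r1`, `epd1`,
#'   `stopped_stage1`, `r_total`, `km_median` (`NA` if the trial stopped at
#'   stage I, `Inf` if not reached), `reject_null`, and `n_enrolled`
#'   (including replaced patients).
#' @examples
#' cfg <- csr_config(n1 = 15, n2 = 15, seed = 11)
#' rl <- csr_rules(0, 5, 5, 5.25)
#' simulate_trial(0.05, 3, rl, cfg)
#' @export
simulate_trial <- function(true_rr, true_median_ttp, rules, config) {
  stopifnot(inherits(rules, "csr_rules"), inherits(config, "csr_config"))
  check_number(true_rr, "true_rr", lower = 0, upper = 1)
  check_number(true_median_ttp, "true_median_ttp", lower = 0,
               strict_lower = TRUE)
  bank <- simulate_trials(1L, true_rr, true_median_ttp, config)
  dec <- apply_rules(bank, rules)
  stopped <- dec$stop1[1L]
  structure(list(
    r1 = bank$r1[1L],
    epd1 = bank$epd1[1L],
    stopped_stage1 = stopped,
    r_total = if (stopped) bank$r1[1L] else bank$r_total[1L],
    km_median = if (stopped) NA_real_ else bank$km_median[1L],
    reject_null = dec$reject[1L],
    n_enrolled = (if (stopped) config$n1 else config$n1 + config$n2) +
      bank$n_extra1[1L] + bank$n_extra2[1L]
  ), class = "csr_trial_result")
}

#' @export
print.csr_trial_result <- function(x, ...) {
  cat(sprintf("Trial: r1 = %d, epd1 = %d, %s\n", x$r1, x$epd1,
              if (x$stopped_stage1) "stopped at stage I (H_nul accepted)"
              else sprintf("continued; r_total = %d, KM median = %s mo, H_nul %s",
                           x$r_total,
                           if (is.infinite(x$km_median)) "not reached"
                           else sprintf("%.2f", x$km_median),
                           if (x$reject_null) "rejected" else "accepted")))
  cat(sprintf("  patients enrolled (incl. replacements): %d\n", x$n_enrolled))
  invisible(x)
}
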