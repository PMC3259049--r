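# Seeds for the independent Monte-Carlo streams derived from one top-level
# seed; fixed offsets keep every stream stable when new ones are added.
derive_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) + stream * 1000003) %% 2147483647)
}

bank_fixed <- function(n_sim, true_rr, true_median_ttp, config, stream = 0L) {
  cfg <- config
  cfg$seed <- derive_seed(config$seed, stream)
  simulate_trials(n_sim, true_rr, true_median_ttp, cfg)
}

# Bank under the alternative-scenario mixture: half the trials have
# RR = r_alt with median TTP ~ Uniform(min_median_ttp, ttp_alt), half have
# median TTP = ttp_alt with RR ~ Uniform(0, r_alt).
bank_mixture <- function(n_sim, hyps, config, stream = 1L) {
  if (config$min_median_ttp >= hyps$ttp_alt)
    stop_invalid("min_median_ttp must be below ttp_alt for the alternative mixture")
  with_seed(derive_seed(config$seed, stream), {
    n_a <- n_sim %/% 2L
    n_b <- n_sim - n_a
    rr <- c(rep(hyps$r_alt, n_a), stats::runif(n_b, 0, hyps$r_alt))
    med <- c(stats::runif(n_a, config$min_median_ttp, hyps$ttp_alt),
             rep(hyps$ttp_alt, n_b))
    cfg <- config
    cfg$seed <- NULL  # continue the stream the mixture draws started
    simulate_trials(n_sim, rr, med, cfg)
  })
}

check_t_first <- function(hyps, config) {
  if (abs(hyps$t_first - config$t_first) > 1e-9)
    stop_invalid(sprintf(
      "t_first differs between hypotheses (%g) and configuration (%g)",
      hyps$t_first, config$t_first))
  invisible(TRUE)
}

binom_se <- function(p, n) sqrt(pmax(p * (1 - p), 0) / n)

#' Rejection and early-stopping probability of fixed rules at one scenario
#'
#' Monte-Carlo estimate of the probability that a trial run under the given
#' stopping rules rejects the null hypothesis, and of the probability that
#' it stops at stage I, when the true response rate and true median TTP are
#' as specified. Evaluating at `(r_nul, ttp_nul)` gives the design's type I
#' error.
#'
#' @param rules A [csr_rules()] object.
#' @param true_rr True response rate.
#' @param true_median_ttp True median TTP, months.
#' @param config A [csr_config()]; `n_sim` trials are simulated under its
#'   seed (stream 0).
#' @return A list: `reject_prob`, `stop_prob`, their Monte-Carlo standard
#'   errors `mc_se_reject` and `mc_se_stop`, and `n_sim`.
#' @examples
#' cfg <- csr_config(15, 15, n_sim = 5000, seed = 3)
#' rejection_probability(csr_rules(0, 5, 5, 5.25), 0.05, 3, cfg)
#' @export
rejection_probability <- function(rules, true_rr, true_median_ttp, config) {
  stopifnot(inherits(rules, "csr_rules"), inherits(config, "csr_config"))
  bank <- bank_fixed(config$n_sim, true_rr, true_median_ttp, config)
  dec <- apply_rules(bank, rules)
  rp <- mean(dec$reject)
  sp <- mean(dec$stop1)
  list(reject_prob = rp, stop_prob = sp,
       mc_se_reject = binom_se(rp, config$n_sim),
       mc_se_stop = binom_se(sp, config$n_sim),
       n_sim = config$n_sim)
}

#' Power of fixed rules under the 50/50 alternative mixture
#'
#' The design's power is defined against a composite alternative: the drug
#' is interesting if either endpoint is good. Half the simulated trials are
#' run with `RR = r_alt` and true median TTP drawn uniformly between
#' `min_median_ttp` and `ttp_alt`; the other half with median TTP =
#' `ttp_alt` and RR drawn uniformly between 0 and `r_alt`. Power is the
#' overall fraction of those trials that reject the null.
#'
#' @param rules A [csr_rules()] object.
#' @param hyps A [csr_hypotheses()] object.
#' @param config A [csr_config()]; `n_sim` mixture trials are simulated
#'   under its seed (stream 1).
#' @return The estimated power, with Monte-Carlo standard error and stage-I
#'   stop fraction attached as attributes `"mc_se"` and `"stop_prob"`.
#' @export
alt_mixture_power <- function(rules, hyps, config) {
  stopifnot(inherits(rules, "csr_rules"), inherits(hyps, "csr_hypotheses"),
            inherits(config, "csr_config"))
  check_t_first(hyps, config)
  bank <- bank_mixture(config$n_sim, hyps, config)
  dec <- apply_rules(bank, rules)
  p <- mean(dec$reject)
  structure(p, mc_se = binom_se(p, config$n_sim),
            stop_prob = mean(dec$stop1))
}

oc_from_banks <- function(rules, bank_nul, bank_mix, config) {
  dec_n <- apply_rules(bank_nul, rules)
  dec_a <- apply_rules(bank_mix, rules)
  n_n <- nrow(bank_nul); n_a <- nrow(bank_mix)
  alpha <- mean(dec_n$reject)
  power <- mean(dec_a$reject)
  pes_nul <- mean(dec_n$stop1)
  pes_alt <- mean(dec_a$stop1)
  n1 <- config$n1; n2 <- config$n2
  structure(list(
    power = power, alpha = alpha,
    pes_nul = pes_nul, pes_alt = pes_alt,
    en_nul = n1 + (1 - pes_nul) * n2,
    en_alt = n1 + (1 - pes_alt) * n2,
    mc_se_power = binom_se(power, n_a),
    mc_se_alpha = binom_se(alpha, n_n),
    mc_se_pes_nul = binom_se(pes_nul, n_n),
    # mean patients actually enrolled, counting replaced patients
    mean_enrolled_nul = mean(n1 + bank_nul$n_extra1 +
                               (!dec_n$stop1) * (n2 + bank_nul$n_extra2)),
    mean_enrolled_alt = mean(n1 + bank_mix$n_extra1 +
                               (!dec_a$stop1) * (n2 + bank_mix$n_extra2)),
    n_sim = c(null = n_n, mixture = n_a)
  ), class = "csr_oc")
}

#' Operating characteristics of a fixed design
#'
#' Estimates all the summary quantities a design report carries: the type I
#' error (rejection probability at the null scenario `RR = r_nul`, median
#' TTP = `ttp_nul`), the power under the 50/50 alternative mixture, the
#' stage-I early-stopping probabilities under both, and the expected sample
#' sizes through the identity `EN = n1 + (1 - PES) * n2` (replaced patients
#' are excluded from EN and reported separately as `mean_enrolled_*`).
#'
#' @inheritParams alt_mixture_power
#' @return An object of class `"csr_oc"` with fields `power`, `alpha`,
#'   `pes_nul`, `pes_alt`, `en_nul`, `en_alt`, Monte-Carlo standard errors,
#'   and mean enrolment including replacements.
#' @examples
#' hyp <- csr_hypotheses(0.05, 0.2, 3, 6)
#' cfg <- csr_config(15, 15, n_sim = 5000, seed = 3)
#' operating_characteristics(csr_rules(0, 5, 5, 5.25), hyp, cfg)
#' @export
operating_characteristics <- function(rules, hyps, config) {
  stopifnot(inherits(rules, "csr_rules"), inherits(hyps, "csr_hypotheses"),
            inherits(config, "csr_config"))
  check_t_first(hyps, config)
  bank_nul <- bank_fixed(config$n_sim, hyps$r_nul, hyps$ttp_nul, config)
  bank_mix <- bank_mixture(config$n_sim, hyps, config)
  oc_from_banks(rules, bank_nul, bank_mix, config)
}

#' @export
print.csr_oc <- function(x, ...) {
  cat("Operating characteristics (Monte-Carlo)\n")
  cat(sprintf("  power      %.3f (MC SE %.4f)\n", x$power, x$mc_se_power))
  cat(sprintf("  alpha      %.3f (MC SE %.4f)\n", x$alpha, x$mc_se_alpha))
  cat(sprintf("  null:      EN %.1f, PES %.3f\n", x$en_nul, x$pes_nul))
  cat(sprintf("  alt:       EN %.1f, PES %.3f\n", x$en_alt, x$pes_alt))
  cat(sprintf("  mean enrolled incl. replacements: null %.1f, alt %.1f\n",
              x$mean_enrolled_nul, x$mean_enrolled_alt))
  invisible(x)
}
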