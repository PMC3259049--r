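# Shared fixtures and independent oracles used across the test files.

hyp_t1r1 <- function() csr_hypotheses(0.05, 0.2, 3, 6)

cfg_small <- function(n_sim = 5000, seed = 101, ...)
  csr_config(n1 = 15, n2 = 15, n_sim = n_sim, seed = seed, ...)

rules_t1r1 <- function() csr_rules(0, 5, 5, 5.25)

# Exhaustive trinomial oracle for the stage-I stop probability with no
# censoring: per patient P(response) = rr, P(EPD) = (1 - rr) * p_epd,
# P(neither) = rest; responders and EPD are mutually exclusive.
# Stop iff responders <= r1_stop and EPD count >= epd_stop.
trinomial_stop_prob <- function(n1, rr, median_ttp, t_first,
                                r1_stop, epd_stop) {
  if (r1_stop < 0 || epd_stop > n1) return(0)
  p_epd <- (1 - rr) * (1 - 2^(-t_first / median_ttp))
  total <- 0
  for (r in 0:min(r1_stop, n1)) {
    pr <- dbinom(r, n1, rr)
    # EPD among the n1 - r non-responders, rate p_epd / (1 - rr)
    pe <- p_epd / (1 - rr)
    for (e in epd_stop:(n1 - r)) {
      if (e < 0) next
      total <- total + pr * dbinom(e, n1 - r, pe)
    }
  }
  total
}

# exact rejection probability of a futility-only two-stage binomial design
# (independent of the package's internal two_stage_reject_prob)
oracle_two_stage_reject <- function(p, n1, n2, a1, r) {
  tot <- 0
  for (k in 0:n1) {
    if (k <= a1) next
    need <- r - k
    p2 <- if (need <= 0) 1 else if (need > n2) 0 else
      sum(dbinom(need:n2, n2, p))
    tot <- tot + dbinom(k, n1, p) * p2
  }
  tot
}

run_cli <- function(args) {
  script <- system.file("cli", "csr.R", package = "csrdesign")
  rscript <- file.path(R.home("bin"), "Rscript")
  # stderr carries progress/timing messages that legitimately vary run to
  # run; determinism is asserted on the stdout payload only
  out <- suppressWarnings(system2(rscript, c(script, args),
                                  stdout = TRUE, stderr = FALSE))
  list(stdout = out, status = attr(out, "status") %||% 0L)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

strip_timestamp <- function(lines) lines[!grepl("timestamp", lines)]
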