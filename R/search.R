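# --- shared-bank grid machinery -------------------------------------------
#
# Thresholds are pure functions of per-trial summaries, so one simulated
# bank serves the whole search: for every candidate (r2, ttp2) pair the
# rejection fraction is a counting exercise, which makes the grid sweep
# orders of magnitude cheaper than re-simulating per candidate and keeps
# every candidate internally consistent (same trials, same noise).

ttp_grid <- function(hyps, config) {
  # candidate TTP thresholds: ttp_nul up to ttp_alt + 2 months in
  # quarter-month steps (values above ttp_alt are allowed but flagged)
  seq(hyps$ttp_nul, hyps$ttp_alt + 2, by = config$ttp_grid_step)
}

# rejection fraction P(r_total >= r2 | km >= ttp2), ignoring stage I, for
# all r2 in 1..n_pat x all ttp2 in ttp_vals. Returns a matrix [r2, ttp2].
reject_grid <- function(bank, ttp_vals, n_pat) {
  n <- nrow(bank)
  out <- matrix(NA_real_, n_pat, length(ttp_vals))
  for (j in seq_along(ttp_vals)) {
    km_ge <- bank$km_median >= ttp_vals[j] - 1e-9
    n_km <- sum(km_ge)
    tb <- tabulate(bank$r_total[!km_ge] + 1L, nbins = n_pat + 1L)
    ge <- rev(cumsum(rev(tb)))            # ge[k + 1] = #(r_total >= k)
    out[, j] <- (n_km + ge[seq_len(n_pat) + 1L]) / n
  }
  out
}

# C[a + 2, b + 1] = #(r1 <= a & epd1 >= b) for a in -1..n1, b in 0..n1+1,
# counted over the trials selected by `keep`. Rows a = -1 and column
# b = n1 + 1 are identically zero (unreachable stop states).
stop_count_grid <- function(r1, epd1, n1, keep = TRUE) {
  r1 <- r1[keep]; epd1 <- epd1[keep]
  tab <- matrix(tabulate(epd1 * (n1 + 1L) + r1 + 1L, nbins = (n1 + 1L)^2),
                n1 + 1L, n1 + 1L)              # tab[r + 1, e + 1]
  le <- apply(tab, 2, cumsum)                  # #(r1 <= r, epd == e)
  ge <- t(apply(le, 1, function(x) rev(cumsum(rev(x)))))  # #(r1 <= r, epd >= e)
  C <- matrix(0, n1 + 2L, n1 + 2L)             # [a + 2, b + 1]
  C[2L:(n1 + 2L), 1L:(n1 + 1L)] <- ge
  C
}

# --- stage II search -------------------------------------------------------

stage2_from_banks <- function(bank_nul, bank_mix, hyps, config) {
  n_pat <- config$n1 + config$n2
  tv <- ttp_grid(hyps, config)
  alpha <- reject_grid(bank_nul, tv, n_pat)
  power <- reject_grid(bank_mix, tv, n_pat)
  # power admissibility allows 2 Monte-Carlo standard errors so a hard cut
  # on a noisy estimate does not bias selection toward lucky candidates
  pow_ok <- power >= config$power_min - 2 * binom_se(power, nrow(bank_mix))
  pick <- NULL
  # preferred rule: for each response threshold the paired TTP threshold
  # sits at the power boundary -- the largest grid value still meeting the
  # power floor (tightening TTP further would sacrifice the floor; this is
  # also the minimum-alpha choice among power-admissible TTP values).
  # Select the largest response threshold whose boundary pair also meets
  # the alpha limit.
  for (r2 in rev(seq_len(n_pat))) {
    j <- which(pow_ok[r2, ])
    if (length(j) == 0L) next
    j <- j[length(j)]
    if (alpha[r2, j] <= config$alpha_max) {
      pick <- c(r2, j); feasible <- TRUE
      break
    }
  }
  if (is.null(pick)) {
    # no pair meets both limits: fall back to the minimum-alpha pair among
    # those meeting the power floor (reported designs then carry an
    # inflated type I error, as the small-sample rows of a design table do)
    if (!any(pow_ok))
      stop_infeasible("no stage-II threshold pair reaches the required power; increase n1/n2 or relax the hypotheses")
    a <- alpha; a[!pow_ok] <- Inf
    idx <- which(a == min(a), arr.ind = TRUE)
    idx <- idx[order(-idx[, 1L], -idx[, 2L]), , drop = FALSE]
    pick <- idx[1L, ]
    feasible <- FALSE
  }
  r2 <- as.integer(pick[1L]); j <- pick[2L]
  list(r2_reject = r2, ttp2_reject = tv[j],
       alpha = alpha[r2, j], power = power[r2, j],
       feasible = feasible,
       above_ttp_alt = tv[j] > hyps$ttp_alt + 1e-9,
       ttp_grid = tv, alpha_grid = alpha, power_grid = power)
}

#' Search stage-II thresholds for a combination stopping rule
#'
#' Enumerates candidate final decision rules -- reject inactivity if the
#' cumulative response count is `>= r2` or the Kaplan-Meier median TTP is
#' `>= ttp2` -- over all response counts `1..(n1+n2)` and a quarter-month
#' TTP grid from `ttp_nul` to `ttp_alt + 2`. For each pair the type I error
#' is estimated at the null scenario and the power under the alternative
#' mixture, both ignoring stage-I stopping (stage-I rules do not exist
#' yet). For each response threshold the paired TTP threshold is placed at
#' the power boundary: the largest grid value whose power estimate still
#' meets the floor (within two Monte-Carlo standard errors), which is also
#' the minimum-alpha choice among power-admissible TTP values. The
#' selected pair is the largest response threshold whose boundary pair
#' also meets the alpha limit; if none does, the minimum-alpha pair among
#' those meeting the power floor is returned with `feasible = FALSE` and a
#' warning.
#'
#' @inheritParams alt_mixture_power
#' @return A list: `r2_reject`, `ttp2_reject`, `alpha`, `power`,
#'   `feasible`, and `above_ttp_alt` (TRUE if the TTP threshold exceeds
#'   `ttp_alt`).
#' @examples
#' hyp <- csr_hypotheses(0.05, 0.2, 3, 6)
#' cfg <- csr_config(15, 15, n_sim = 5000, seed = 9)
#' search_stage2(hyp, cfg)[c("r2_reject", "ttp2_reject")]
#' @export
search_stage2 <- function(hyps, config) {
  stopifnot(inherits(hyps, "csr_hypotheses"), inherits(config, "csr_config"))
  check_t_first(hyps, config)
  bank_nul <- bank_fixed(config$n_sim, hyps$r_nul, hyps$ttp_nul, config)
  bank_mix <- bank_mixture(config$n_sim, hyps, config)
  res <- stage2_from_banks(bank_nul, bank_mix, hyps, config)
  if (!res$feasible)
    warning(sprintf("no stage-II pair meets alpha <= %g at power >= %g; returning the minimum-alpha pair (alpha = %.3f)",
                    config$alpha_max, config$power_min, res$alpha))
  res[c("r2_reject", "ttp2_reject", "alpha", "power", "feasible",
        "above_ttp_alt")]
}

# --- stage I search --------------------------------------------------------

stage1_from_banks <- function(stage2, bank_nul, bank_mix, config) {
  n1 <- config$n1
  r2 <- stage2$r2_reject
  ttp2 <- stage2$ttp2_reject
  rej2_mix <- bank_mix$r_total >= r2 | bank_mix$km_median >= ttp2 - 1e-9
  n_n <- nrow(bank_nul); n_a <- nrow(bank_mix)

  # when even stage II could not meet the alpha limit there is no error
  # budget left to trade: stage-I stopping would only sacrifice power, so
  # the design keeps the never-stop sentinel (cf. the sentinel rows of a
  # small-sample design table)
  if (isFALSE(stage2$feasible)) {
    rules <- csr_rules(-1L, n1 + 1L, r2, ttp2, n1 = n1)
    dec_n <- apply_rules(bank_nul, rules)
    return(list(rules = rules, pes_nul = mean(dec_n$stop1),
                power = mean(apply_rules(bank_mix, rules)$reject),
                alpha = mean(dec_n$reject)))
  }

  C_nul <- stop_count_grid(bank_nul$r1, bank_nul$epd1, n1)
  C_loss <- stop_count_grid(bank_mix$r1, bank_mix$epd1, n1, keep = rej2_mix)
  power_base <- mean(rej2_mix)

  a_vals <- -1L:min(r2 - 1L, n1)
  b_vals <- 0L:(n1 + 1L)
  PES <- C_nul[a_vals + 2L, b_vals + 1L, drop = FALSE] / n_n
  PWR <- power_base - C_loss[a_vals + 2L, b_vals + 1L, drop = FALSE] / n_a

  adm <- outer(a_vals, b_vals, function(a, b)
    (a < 0L & b == n1 + 1L) |                       # canonical never-stop
      (a >= 0L & b <= n1 & a + b <= n1 + 1L))       # reachable stop state
  ok <- adm & PWR >= config$power_min - 2 * binom_se(PWR, n_a)
  best <- max(PES[ok])
  if (best <= 0) {
    a <- -1L; b <- n1 + 1L                          # no-stop sentinel
  } else {
    cand <- which(ok & abs(PES - best) < 1e-15, arr.ind = TRUE)
    cand <- cand[order(cand[, 2L], -cand[, 1L]), , drop = FALSE]
    a <- a_vals[cand[1L, 1L]]
    b <- b_vals[cand[1L, 2L]]
  }
  rules <- csr_rules(a, b, r2, ttp2, n1 = n1)
  dec_n <- apply_rules(bank_nul, rules)
  list(rules = rules,
       pes_nul = mean(dec_n$stop1),
       power = mean(apply_rules(bank_mix, rules)$reject),
       alpha = mean(dec_n$reject))
}

#' Search stage-I futility thresholds given stage-II rules
#'
#' Given selected stage-II thresholds, enumerates stage-I futility pairs --
#' stop and accept inactivity if stage-I responses `<= r1` and stage-I EPD
#' count `>= epd` -- over all reachable pairs, and selects the one
#' maximising the probability of early stopping under the null subject to
#' the overall mixture power (now including the power lost to stage-I
#' stopping) staying at or above the power floor, within two Monte-Carlo
#' standard errors. If the supplied stage-II pair carries
#' `feasible = FALSE` (the alpha limit was unattainable) the never-stop
#' sentinel is returned directly: with the type I error already above its
#' limit, early stopping would only sacrifice power. The overall type I error
#' is re-estimated with the stage-I rule in force; stage-I stopping can
#' only lower it. Ties in early-stopping probability prefer the smaller
#' EPD threshold, then the larger response threshold. If no pair with
#' positive early-stopping probability survives the power constraint the
#' never-stop sentinel `(-1, n1 + 1)` is returned.
#'
#' @param stage2 A list with `r2_reject` and `ttp2_reject`, as returned by
#'   [search_stage2()].
#' @inheritParams alt_mixture_power
#' @return A list: `rules` (a [csr_rules()]), `pes_nul`, `power`, `alpha`.
#' @export
search_stage1 <- function(stage2, hyps, config) {
  stopifnot(inherits(hyps, "csr_hypotheses"), inherits(config, "csr_config"))
  check_t_first(hyps, config)
  bank_nul <- bank_fixed(config$n_sim, hyps$r_nul, hyps$ttp_nul, config)
  bank_mix <- bank_mixture(config$n_sim, hyps, config)
  stage1_from_banks(stage2, bank_nul, bank_mix, config)
}

# --- full design search ----------------------------------------------------

#' Derive a combination stopping rule design
#'
#' The full design search: first the stage-II thresholds (response count
#' and Kaplan-Meier median TTP) meeting the error limits, then the stage-I
#' futility thresholds (response and EPD counts) maximising early stopping
#' under the null without dropping the overall power below its floor. If
#' the stage-II limits were met but no stage-I rule with positive
#' early-stopping probability survives the power constraint, one relaxation
#' round loosens stage II by a single grid step (either the TTP threshold
#' down a quarter month or the response threshold down one patient),
#' trading increased type I error for the ability to stop early; if that
#' also fails, the design keeps the never-stop sentinel.
#'
#' All Monte-Carlo estimates in the returned design -- including the final
#' operating characteristics -- are computed from one pair of simulation
#' banks (null and mixture), so the whole report is internally consistent
#' and exactly reproducible from `config$seed`.
#'
#' @inheritParams alt_mixture_power
#' @return An object of class `"csr_design"`: `hypotheses`, `config`,
#'   `rules`, `oc` (a `"csr_oc"`), `stage2` diagnostics (`feasible`,
#'   `above_ttp_alt`), and `relaxed` (TRUE if the relaxation round fired).
#' @examples
#' hyp <- csr_hypotheses(0.05, 0.2, 3, 6)
#' cfg <- csr_config(15, 15, n_sim = 5000, seed = 42)
#' design_csr(hyp, cfg)
#' @export
design_csr <- function(hyps, config) {
  stopifnot(inherits(hyps, "csr_hypotheses"), inherits(config, "csr_config"))
  check_t_first(hyps, config)
  bank_nul <- bank_fixed(config$n_sim, hyps$r_nul, hyps$ttp_nul, config)
  bank_mix <- bank_mixture(config$n_sim, hyps, config)

  s2 <- stage2_from_banks(bank_nul, bank_mix, hyps, config)
  if (!s2$feasible)
    warning(sprintf("alpha <= %g unattainable at power >= %g; using minimum-alpha stage-II pair (alpha = %.3f)",
                    config$alpha_max, config$power_min, s2$alpha))
  s1 <- stage1_from_banks(s2, bank_nul, bank_mix, config)

  relaxed <- FALSE
  if (s2$feasible && s1$pes_nul <= 0) {
    # one relaxation round: loosen stage II a single grid step and retry
    cands <- list()
    if (s2$ttp2_reject - config$ttp_grid_step >= hyps$ttp_nul - 1e-9)
      cands <- c(cands, list(list(r2_reject = s2$r2_reject,
                                  ttp2_reject = s2$ttp2_reject - config$ttp_grid_step)))
    if (s2$r2_reject > 1L)
      cands <- c(cands, list(list(r2_reject = s2$r2_reject - 1L,
                                  ttp2_reject = s2$ttp2_reject)))
    trials <- lapply(cands, stage1_from_banks, bank_nul, bank_mix, config)
    pes <- vapply(trials, `[[`, numeric(1), "pes_nul")
    if (length(pes) > 0 && max(pes) > 0) {
      k <- which.max(pes)
      s2$r2_reject <- cands[[k]]$r2_reject
      s2$ttp2_reject <- cands[[k]]$ttp2_reject
      s1 <- trials[[k]]
      relaxed <- TRUE
    }
  }

  oc <- oc_from_banks(s1$rules, bank_nul, bank_mix, config)
  structure(list(
    hypotheses = hyps, config = config, rules = s1$rules, oc = oc,
    stage2 = list(feasible = s2$feasible, above_ttp_alt = s2$above_ttp_alt,
                  alpha_prestage1 = s2$alpha, power_prestage1 = s2$power),
    relaxed = relaxed
  ), class = "csr_design")
}

#' @export
print.csr_design <- function(x, ...) {
  cat("Combination stopping rule design\n\n")
  print(x$hypotheses)
  cat("\n")
  print(x$rules)
  cat("\n")
  print(x$oc)
  if (!x$stage2$feasible)
    cat("note: the alpha limit could not be met at the required power; this is the minimum-alpha design at that power\n")
  if (x$relaxed)
    cat("note: stage II was relaxed one grid step to admit a stage-I stopping rule\n")
  invisible(x)
}
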