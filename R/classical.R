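#' Exact cumulative binomial probability
#'
#' Validated wrapper over [stats::pbinom()]; the exact-arithmetic backbone
#' of the classical design calculations.
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials.
#' @param p Success probability.
#' @return `P(X <= k)` for `X ~ Binomial(n, p)`.
#' @examples
#' binom_cdf(0, 10, 0.05)  # 0.95^10 = 0.5987
#' @export
binom_cdf <- function(k, n, p) {
  n <- check_count(n, "n", lower = 0L)
  k <- check_count(k, "k", lower = 0L, upper = n)
  check_number(p, "p", lower = 0, upper = 1)
  stats::pbinom(k, n, p)
}

# exact alpha/power of a two-stage binomial design: continue past stage I
# iff X1 > r1_futility, reject at the end iff total responses >= r_reject.
# (An early-rejection bound at or above r_reject leaves this unchanged.)
two_stage_reject_prob <- function(p, n1, n2, r1_futility, r_reject) {
  k <- seq.int(max(r1_futility + 1L, 0L), n1)
  if (length(k) == 0L || k[1L] > n1) return(0)
  need <- r_reject - k
  tail2 <- ifelse(need <= 0L, 1, 1 - stats::pbinom(pmin(need, n2 + 1L) - 1L, n2, p))
  tail2[need > n2] <- 0
  sum(stats::dbinom(k, n1, p) * tail2)
}

new_classical_design <- function(label, n1, r1_futility, n_total, r_reject,
                                 p0, p1) {
  pes <- if (r1_futility < 0L) 0 else stats::pbinom(r1_futility, n1, p0)
  n2 <- n_total - n1
  structure(list(
    design = label,
    n1 = n1, r1_futility = r1_futility,
    n_total = n_total, r_reject = r_reject,
    p0 = p0, p1 = p1,
    alpha = two_stage_reject_prob(p0, n1, n2, r1_futility, r_reject),
    power = two_stage_reject_prob(p1, n1, n2, r1_futility, r_reject),
    pes_null = pes,
    en_null = n1 + (1 - pes) * n2
  ), class = "csr_classical_design")
}

#' @export
print.csr_classical_design <- function(x, ...) {
  cat(sprintf("%s two-stage design (p0 = %g, p1 = %g)\n", x$design, x$p0, x$p1))
  cat(sprintf("  stage I : n1 = %d, stop for futility if responses <= %d\n",
              x$n1, x$r1_futility))
  cat(sprintf("  final   : n = %d, reject H0 if responses >= %d\n",
              x$n_total, x$r_reject))
  cat(sprintf("  alpha = %.4f, power = %.4f, PES(null) = %.3f, EN(null) = %.2f\n",
              x$alpha, x$power, x$pes_null, x$en_null))
  invisible(x)
}

#' Simon's optimal two-stage design
#'
#' Exhaustive exact-binomial search for the two-stage single-arm design
#' minimising the expected sample size under the null (Simon 1989, the
#' "optimal" criterion) subject to exact `alpha <= alpha_max` and power
#' `>= 1 - beta_max` for response rates `p0` (uninteresting) versus `p1`
#' (interesting). Ties in expected null sample size are broken by smaller
#' total size, then smaller stage-I size.
#'
#' @param p0,p1 Null and alternative response rates, `p0 < p1`.
#' @param alpha_max Type I error limit (default 0.05).
#' @param beta_max Type II error limit (default 0.20).
#' @param n_max Largest total sample size searched (default 100).
#' @return A `"csr_classical_design"` with the stage sizes, bounds and
#'   exact operating characteristics. `r_reject` is the smallest final
#'   response count that rejects the null (Simon's tabulated `r` plus one).
#' @examples
#' simon_optimal(0.05, 0.20)   # n1 = 10, n = 29, PES = 0.599
#' @export
simon_optimal <- function(p0, p1, alpha_max = 0.05, beta_max = 0.20,
                          n_max = 100L) {
  check_number(p0, "p0", lower = 0, upper = 1)
  check_number(p1, "p1", lower = 0, upper = 1)
  if (p0 >= p1) stop_invalid("need p0 < p1")
  check_number(alpha_max, "alpha_max", lower = 0, upper = 1)
  check_number(beta_max, "beta_max", lower = 0, upper = 1)
  n_max <- check_count(n_max, "n_max", lower = 2L)
  power_min <- 1 - beta_max
  best <- NULL
  best_en <- Inf
  for (n in 2:n_max) {
    for (n1 in 1:(n - 1L)) {
      if (n1 >= best_en) break               # EN >= n1: hopeless
      n2 <- n - n1
      for (r1 in 0:n1) {
        # quick bounds before the exact sums
        if (1 - stats::pbinom(r1, n1, p1) < power_min) break  # power ceiling
        pet <- stats::pbinom(r1, n1, p0)
        en <- n1 + (1 - pet) * n2
        if (en >= best_en) next
        # smallest final threshold with exact alpha within the limit
        r <- r1 + 1L
        repeat {
          a <- two_stage_reject_prob(p0, n1, n2, r1, r)
          if (a <= alpha_max || r > n) break
          r <- r + 1L
        }
        if (r > n && a > alpha_max) next
        if (two_stage_reject_prob(p1, n1, n2, r1, r) < power_min) next
        best_en <- en
        best <- c(n1 = n1, r1 = r1, n = n, r = r)
      }
    }
  }
  if (is.null(best))
    stop_infeasible(sprintf("no Simon design with n <= %d meets alpha <= %g and power >= %g",
                            n_max, alpha_max, power_min))
  new_classical_design("Simon optimal", best[["n1"]], best[["r1"]],
                       best[["n"]], best[["r"]], p0, p1)
}

#' Fleming's two-stage design
#'
#' Group-sequential single-arm binomial design with boundaries built from
#' the single-stage normal-approximation critical value partitioned by
#' stage (Fleming 1982): with `N = n1 + n2` and `z` the upper `1 - alpha`
#' normal quantile, the stage-`g` rejection bound is
#' `floor(m_g p0 + z sqrt(N p0 q0)) + 1` and the acceptance (futility)
#' bound `floor(m_g p1 - z sqrt(N p1 q1)) + 1`, `m_g` the cumulative sample
#' size. Bounds are mapped to integers conservatively: the stage-I
#' rejection bound is clamped to at least the final critical value, so
#' early efficacy stopping never inflates the exact type I error. All
#' reported operating characteristics are exact binomial sums.
#'
#' @param p0,p1 Null and alternative response rates, `p0 < p1`.
#' @param n1,n2 Stage sizes; `n2 = 0` reduces to the single-stage test.
#' @param alpha_nominal Nominal one-sided level of the construction
#'   (default 0.05); the exact alpha attained may differ and is reported.
#' @return A `"csr_classical_design"`; `r1_futility` is the stage-I
#'   acceptance bound (`-1` if stage-I acceptance is impossible) and
#'   `r_reject` the final rejection bound.
#' @examples
#' fleming_two_stage(0.05, 0.20, 15, 15)  # PES = 0.463, alpha = 0.058
#' @export
fleming_two_stage <- function(p0, p1, n1, n2, alpha_nominal = 0.05) {
  check_number(p0, "p0", lower = 0, upper = 1, strict_lower = TRUE,
               strict_upper = TRUE)
  check_number(p1, "p1", lower = 0, upper = 1, strict_lower = TRUE,
               strict_upper = TRUE)
  if (p0 >= p1) stop_invalid("need p0 < p1")
  n1 <- check_count(n1, "n1", lower = 1L)
  n2 <- check_count(n2, "n2", lower = 0L)
  check_number(alpha_nominal, "alpha_nominal", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  N <- n1 + n2
  z <- stats::qnorm(1 - alpha_nominal)
  r_final <- floor(N * p0 + z * sqrt(N * p0 * (1 - p0))) + 1
  a1 <- floor(n1 * p1 - z * sqrt(N * p1 * (1 - p1))) + 1
  if (!is.finite(r_final) || r_final < 1 || r_final > N)
    stop_invalid("Fleming boundary construction failed at these parameters")
  if (n2 == 0L) a1 <- r_final - 1           # single stage: accept iff not reject
  a1 <- max(min(a1, n1), -1)
  if (a1 >= r_final) a1 <- r_final - 1      # bounds must not cross
  new_classical_design("Fleming", n1, as.integer(a1), N,
                       as.integer(r_final), p0, p1)
}
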