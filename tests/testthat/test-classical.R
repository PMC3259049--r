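test_that("binomial CDF wrapper is exact and validates its range", {
  expect_equal(binom_cdf(0, 10, 0.05), 0.95^10)
  expect_equal(binom_cdf(0, 15, 0.05), 0.95^15)
  expect_equal(binom_cdf(7, 7, 0.3), 1)
  expect_error(binom_cdf(11, 10, 0.05), class = "csr_invalid_parameter")
  expect_error(binom_cdf(2, 10, 1.5), class = "csr_invalid_parameter")
})

test_that("Simon optimal search reproduces the published designs", {
  s <- simon_optimal(0.05, 0.20, 0.05, 0.20)
  expect_identical(s$n1, 10L)
  expect_identical(s$r1_futility, 0L)
  expect_identical(s$n_total, 29L)
  expect_identical(s$r_reject, 4L)          # Simon's r = 3 of 29
  expect_equal(s$pes_null, 0.95^10)
  expect_equal(s$en_null, 10 + (1 - 0.95^10) * 19)
  expect_lte(s$alpha, 0.05)
  expect_gte(s$power, 0.80)

  s2 <- simon_optimal(0.10, 0.30)           # published: 1/10, 5/29, EN 15.0
  expect_identical(s2$n1, 10L)
  expect_identical(s2$r1_futility, 1L)
  expect_identical(s2$n_total, 29L)
  expect_identical(s2$r_reject, 6L)
  expect_equal(s2$en_null, 15.0, tolerance = 0.01)
})

test_that("Simon search operating characteristics agree with an independent exact oracle", {
  for (pars in list(c(0.05, 0.20), c(0.2, 0.4))) {
    s <- simon_optimal(pars[1], pars[2])
    n2 <- s$n_total - s$n1
    expect_equal(s$alpha, oracle_two_stage_reject(pars[1], s$n1, n2,
                                                  s$r1_futility, s$r_reject))
    expect_equal(s$power, oracle_two_stage_reject(pars[2], s$n1, n2,
                                                  s$r1_futility, s$r_reject))
    expect_equal(s$pes_null, pbinom(s$r1_futility, s$n1, pars[1]))
  }
})

test_that("Simon search is truly optimal against brute-force enumeration at small n", {
  # independent exhaustive enumeration with direct binomial sums
  p0 <- 0.1; p1 <- 0.5; amax <- 0.10; pmin <- 0.80; nmax <- 18
  best_en <- Inf; best <- NULL
  for (n in 2:nmax) for (n1 in 1:(n - 1)) for (r1 in 0:n1) {
    for (r in (r1 + 1):n) {
      if (oracle_two_stage_reject(p0, n1, n - n1, r1, r) > amax) next
      if (oracle_two_stage_reject(p1, n1, n - n1, r1, r) < pmin) break
      en <- n1 + (1 - pbinom(r1, n1, p0)) * (n - n1)
      if (en < best_en) { best_en <- en; best <- c(n1, r1, n, r) }
      break
    }
  }
  s <- simon_optimal(p0, p1, amax, 1 - pmin, n_max = nmax)
  expect_equal(s$en_null, best_en)
  expect_identical(c(s$n1, s$r1_futility, s$n_total, s$r_reject),
                   as.integer(best))
})

test_that("Fleming design reproduces the reference two-stage comparison", {
  f <- fleming_two_stage(0.05, 0.20, 15, 15)
  expect_identical(f$r1_futility, 0L)
  expect_identical(f$r_reject, 4L)
  expect_equal(round(f$pes_null, 3), 0.463)
  expect_equal(round(f$alpha, 3), 0.058)
  expect_gte(f$power, 0.80)
  expect_equal(f$en_null, 15 + (1 - pbinom(0, 15, 0.05)) * 15)
})

test_that("Fleming design with no second stage reduces to the single-stage exact test", {
  f <- fleming_two_stage(0.05, 0.20, 15, 0)
  expect_identical(f$n_total, 15L)
  expect_equal(f$alpha, 1 - pbinom(f$r_reject - 1, 15, 0.05))
  expect_equal(f$pes_null, pbinom(f$r_reject - 1, 15, 0.05))
})

test_that("closed-form error rates agree with large-scale simulation", {
  f <- fleming_two_stage(0.05, 0.20, 15, 15)
  set.seed(61)
  nrep <- 400000
  x1 <- rbinom(nrep, 15, 0.05)
  x2 <- rbinom(nrep, 15, 0.05)
  rej <- x1 > f$r1_futility & x1 + x2 >= f$r_reject
  se <- sqrt(f$alpha * (1 - f$alpha) / nrep)
  expect_lt(abs(mean(rej) - f$alpha), 3 * se)
  x1a <- rbinom(nrep, 15, 0.20)
  x2a <- rbinom(nrep, 15, 0.20)
  reja <- x1a > f$r1_futility & x1a + x2a >= f$r_reject
  sea <- sqrt(f$power * (1 - f$power) / nrep)
  expect_lt(abs(mean(reja) - f$power), 3 * sea)
})

test_that("degenerate classical inputs are rejected", {
  expect_error(simon_optimal(0.3, 0.2), class = "csr_invalid_parameter")
  expect_error(fleming_two_stage(0.2, 0.2, 15, 15),
               class = "csr_invalid_parameter")
  expect_error(simon_optimal(0.05, 0.06, 0.01, 0.01, n_max = 15),
               class = "csr_design_infeasible")
})
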