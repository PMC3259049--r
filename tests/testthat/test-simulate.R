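test_that("trial banks respect count invariants and mutual exclusivity", {
  cfg <- cfg_small(n_sim = 3000, seed = 3)
  bank <- simulate_trials(3000, 0.3, 4, cfg)
  expect_true(all(bank$r1 >= 0 & bank$r1 <= 15))
  expect_true(all(bank$r1 + bank$epd1 <= 15))
  expect_true(all(bank$r_total >= bank$r1))
  expect_true(all(bank$r_total <= 30))
  expect_true(all(bank$km_median > 0))

  # a universally responding drug leaves no room for EPD
  b1 <- simulate_trials(1000, 1, 4, cfg_small(n_sim = 1000, seed = 4))
  expect_true(all(b1$r1 == 15L))
  expect_true(all(b1$epd1 == 0L))

  # vanishing TTP with no responses: every patient has EPD
  b0 <- simulate_trials(1000, 0, 0.01,
                        cfg_small(n_sim = 1000, seed = 5, censor_prob = 0))
  expect_true(all(b0$epd1 == 15L))
})

test_that("no censoring means no replacements", {
  cfg <- cfg_small(n_sim = 1000, seed = 6, censor_prob = 0)
  bank <- simulate_trials(1000, 0.2, 3, cfg)
  expect_true(all(bank$n_extra1 == 0L & bank$n_extra2 == 0L))
  res <- simulate_trial(0.2, 3, rules_t1r1(), cfg)
  expect_true(res$n_enrolled %in% c(15L, 30L))
})

test_that("heavy early censoring triggers the replacement loop", {
  cfg <- cfg_small(n_sim = 1000, seed = 8, censor_prob = 0.4)
  bank <- simulate_trials(1000, 0.1, 3, cfg)
  expect_gt(sum(bank$n_extra1 + bank$n_extra2), 0)
})

test_that("stage-I response counts are exactly binomial without censoring", {
  cfg <- cfg_small(n_sim = 20000, seed = 9, censor_prob = 0)
  bank <- simulate_trials(20000, 0.2, 3, cfg)
  obs <- tabulate(bank$r1 + 1L, nbins = 16)
  p <- dbinom(0:15, 15, 0.2)
  # pool sparse upper tail for a valid chi-square comparison
  cut <- max(which(20000 * p > 5))
  obs2 <- c(obs[1:cut], sum(obs[-(1:cut)]))
  p2 <- c(p[1:cut], 1 - sum(p[1:cut]))
  gof <- suppressWarnings(chisq.test(obs2, p = p2))
  expect_gt(gof$p.value, 0.001)
})

test_that("EPD fraction among simulated patients matches the closed form", {
  cfg <- cfg_small(n_sim = 20000, seed = 10, censor_prob = 0)
  rr <- 0.2
  bank <- simulate_trials(20000, rr, 3, cfg)
  p_epd <- (1 - rr) * epd_probability(3, cfg$t_first)
  est <- mean(bank$epd1) / 15
  se <- sqrt(p_epd * (1 - p_epd) / (20000 * 15))
  expect_lt(abs(est - p_epd), 3 * se)
})

test_that("stage-I stop probability matches the exhaustive trinomial oracle", {
  cases <- list(c(rr = 0.05, med = 3, a = 0, b = 5),
                c(rr = 0.10, med = 4, a = 1, b = 4),
                c(rr = 0.20, med = 5, a = 3, b = 3))
  for (cs in cases) {
    cfg <- cfg_small(n_sim = 40000, seed = 11 + cs[["a"]], censor_prob = 0)
    bank <- simulate_trials(40000, cs[["rr"]], cs[["med"]], cfg)
    est <- mean(bank$r1 <= cs[["a"]] & bank$epd1 >= cs[["b"]])
    truth <- trinomial_stop_prob(15, cs[["rr"]], cs[["med"]], cfg$t_first,
                                 cs[["a"]], cs[["b"]])
    se <- sqrt(truth * (1 - truth) / 40000)
    expect_lt(abs(est - truth), 3 * se)
  }
})

test_that("trial simulation is seed-deterministic", {
  cfg <- cfg_small(n_sim = 1000, seed = 12)
  b1 <- simulate_trials(1000, 0.2, 4, cfg)
  b2 <- simulate_trials(1000, 0.2, 4, cfg)
  expect_identical(b1, b2)
  r1 <- simulate_trial(0.1, 3, rules_t1r1(), cfg)
  r2 <- simulate_trial(0.1, 3, rules_t1r1(), cfg)
  expect_identical(r1, r2)
  b3 <- simulate_trials(1000, 0.2, 4, cfg_small(n_sim = 1000, seed = 13))
  expect_false(identical(b1$r1, b3$r1))
})

test_that("single-trial decisions follow the two-stage rule structure", {
  cfg <- cfg_small(n_sim = 1000, seed = 14)
  for (i in 1:40) {
    cfg$seed <- 1000L + i
    res <- simulate_trial(0.05, 2, csr_rules(2, 2, 5, 5), cfg)
    expect_true(res$r1 >= 0 && res$r1 <= 15)
    expect_true(res$r1 + res$epd1 <= 15)
    if (res$stopped_stage1) {
      expect_identical(res$r_total, res$r1)
      expect_false(res$reject_null)       # no stage-I rejection, ever
      expect_true(is.na(res$km_median))
    } else {
      expect_identical(res$reject_null,
                       res$r_total >= 5 || res$km_median >= 5)
    }
  }
})

test_that("sentinel thresholds disable stage-I stopping", {
  cfg <- cfg_small(n_sim = 2000, seed = 15)
  bank <- simulate_trials(2000, 0.05, 3, cfg)
  dec <- csrdesign:::apply_rules(bank, csr_rules(-1, 16, 5, 5.25))
  expect_false(any(dec$stop1))
  dec2 <- csrdesign:::apply_rules(bank, csr_rules(0, 16, 5, 5.25))
  expect_false(any(dec2$stop1))
})
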