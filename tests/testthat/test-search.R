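test_that("stage-I search matches a brute-force enumeration oracle at small n1", {
  cfg <- csr_config(8, 4, n_sim = 4000, seed = 31)
  hyp <- csr_hypotheses(0.1, 0.4, 2, 5)
  bank_nul <- csrdesign:::bank_fixed(4000, 0.1, 2, cfg)
  bank_mix <- csrdesign:::bank_mixture(4000, hyp, cfg)
  stage2 <- list(r2_reject = 3L, ttp2_reject = 3.5, feasible = TRUE)
  got <- csrdesign:::stage1_from_banks(stage2, bank_nul, bank_mix, cfg)

  # independent exhaustive enumeration over all reachable pairs
  rej2 <- bank_mix$r_total >= 3 | bank_mix$km_median >= 3.5 - 1e-9
  best <- 0
  for (a in -1:2) for (b in 0:9) {
    if (!((a < 0 && b == 9) || (a >= 0 && b <= 8 && a + b <= 9))) next
    pwr <- mean(rej2 & !(bank_mix$r1 <= a & bank_mix$epd1 >= b))
    if (pwr < cfg$power_min - 2 * sqrt(pwr * (1 - pwr) / 4000)) next
    best <- max(best, mean(bank_nul$r1 <= a & bank_nul$epd1 >= b))
  }
  expect_equal(got$pes_nul, best)
})

test_that("an unconstrained stage-I search stops as often as possible", {
  cfg <- csr_config(10, 5, n_sim = 3000, seed = 32, power_min = 0)
  hyp <- csr_hypotheses(0.1, 0.4, 2, 5)
  bank_nul <- csrdesign:::bank_fixed(3000, 0.1, 2, cfg)
  bank_mix <- csrdesign:::bank_mixture(3000, hyp, cfg)
  got <- csrdesign:::stage1_from_banks(
    list(r2_reject = 4L, ttp2_reject = 3.5, feasible = TRUE),
    bank_nul, bank_mix, cfg)
  expect_identical(got$rules$r1_stop, 3L)
  expect_identical(got$rules$epd_stop, 0L)
})

test_that("full design search is deterministic and satisfies its own constraints", {
  hyp <- hyp_t1r1()
  cfg <- cfg_small(n_sim = 8000, seed = 33)
  d1 <- design_csr(hyp, cfg)
  d2 <- design_csr(hyp, cfg)
  expect_identical(unclass(d1$rules), unclass(d2$rules))
  expect_identical(unclass(d1$oc), unclass(d2$oc))
  expect_true(d1$stage2$feasible)
  # estimated power of a successful search stays within 2 MC SEs of the floor
  expect_gte(d1$oc$power, cfg$power_min - 2 * d1$oc$mc_se_power)
  expect_lte(d1$stage2$alpha_prestage1, cfg$alpha_max)
  expect_true(d1$rules$r1_stop < d1$rules$r2_reject)
})

test_that("an obviously active drug profile yields a feasible high-power design", {
  hyp <- csr_hypotheses(0.05, 0.9, 1, 12)
  cfg <- csr_config(8, 4, n_sim = 4000, seed = 34)
  d <- design_csr(hyp, cfg)
  expect_true(d$stage2$feasible)
  expect_gte(d$oc$power, 0.8 - 2 * d$oc$mc_se_power)
})

test_that("a hopeless configuration raises the design-infeasible condition", {
  # a near-inactive alternative in a tiny trial: even the loosest stage-II
  # rule cannot reach 80% power
  hyp <- csr_hypotheses(0.01, 0.02, 1.0, 1.2)
  cfg <- csr_config(3, 2, n_sim = 2000, seed = 35, min_median_ttp = 0.5)
  expect_error(design_csr(hyp, cfg), class = "csr_design_infeasible")
})

test_that("more stage-II patients never worsen the attainable alpha at fixed power", {
  hyp <- csr_hypotheses(0.05, 0.3, 3, 7)
  min_alpha <- function(n2, seed) {
    cfg <- csr_config(15, n2, n_sim = 6000, seed = seed)
    bn <- csrdesign:::bank_fixed(6000, 0.05, 3, cfg)
    bm <- csrdesign:::bank_mixture(6000, hyp, cfg)
    s2 <- csrdesign:::stage2_from_banks(bn, bm, hyp, cfg)
    ok <- s2$power_grid >=
      cfg$power_min - 2 * sqrt(s2$power_grid * (1 - s2$power_grid) / 6000)
    min(s2$alpha_grid[ok])
  }
  expect_lte(min_alpha(25, 36), min_alpha(10, 36) + 0.02)
})

test_that("the search honours the quarter-month TTP grid", {
  hyp <- hyp_t1r1()
  d <- design_csr(hyp, cfg_small(n_sim = 8000, seed = 37))
  expect_equal(d$rules$ttp2_reject %% 0.25, 0)
  expect_gte(d$rules$ttp2_reject, 3)
  expect_lte(d$rules$ttp2_reject, 8)
})
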