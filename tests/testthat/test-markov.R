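test_that("discount factors follow the annual-rate convention", {
  expect_equal(discount_factor(0), 1)
  expect_equal(discount_factor(12, 0.03), 1 / 1.03)
  expect_equal(discount_factor(24, 0.03), 1.03^-2)
  expect_error(discount_factor(-1), ">= 0")
})

test_that("cohort trace partitions the cohort according to the two curves", {
  os <- surv_dist("weibull", 1, 20); pfs <- surv_dist("weibull", 1, 8)
  tr <- build_trace(os, pfs, horizon_years = 20)
  expect_equal(unlist(tr[1, c("pfs", "pd", "death")]),
               c(pfs = 1, pd = 0, death = 0))
  # closed-form occupancies at an arbitrary cycle boundary
  i <- 12; t <- tr$time[i]
  expect_equal(tr$pfs[i], exp(-t / 8))
  expect_equal(tr$death[i], 1 - exp(-t / 20))
  expect_equal(tr$pd[i], exp(-t / 20) - exp(-t / 8))
  # identical curves leave no progressed state
  tr2 <- build_trace(os, os)
  expect_equal(max(tr2$pd), 0)
})

test_that("occupancies conserve mass and death is absorbing", {
  set.seed(61)
  for (i in 1:10) {
    os <- random_dist()
    pfs <- surv_dist(os$family, os$shape, os$scale * runif(1, 0.3, 1))
    tr <- quiet(build_trace(os, pfs, horizon_years = 15))
    expect_equal(tr$pfs + tr$pd + tr$death, rep(1, nrow(tr)), tolerance = 1e-9)
    expect_true(all(diff(tr$death) >= -1e-12))
    expect_true(all(tr$pfs >= 0 & tr$pd >= 0))
  }
})

test_that("PFS above OS is clamped and counted", {
  os <- surv_dist("weibull", 1, 5); pfs <- surv_dist("weibull", 1, 10)
  tr <- quiet(build_trace(os, pfs, horizon_years = 10))
  expect_gt(attr(tr, "n_clamped"), 0)
  expect_true(all(tr$pd >= 0))
  expect_equal(tr$pfs + tr$pd, 1 - tr$death, tolerance = 1e-12)
})

test_that("accrual arithmetic matches hand sums and bounds", {
  # two-cycle toy: (1.0 + 0.5) * 0.8 * 0.5y = 0.6 QALY
  tr <- toy_trace(pfs = c(1, 0.5), pd = c(0, 0), death = c(0, 0.5),
                  cycle_length = 6)
  out <- accrue_outcomes(tr, utilities = list(pfs = 0.8, pd = 0.5), rate = 0)
  expect_equal(out$qaly, 0.6)
  expect_equal(out$cost, 0)
  # nobody dies, full utility, no discounting: one QALY per year
  # (and the convergence check flags the still-alive cohort at horizon)
  expect_warning(
    tr2 <- build_trace(surv_dist("weibull", 1, 1e6), surv_dist("weibull", 1, 1e6),
                       horizon_years = 1),
    "still alive")
  out2 <- accrue_outcomes(tr2, utilities = list(pfs = 1, pd = 1), rate = 0)
  expect_equal(out2$qaly, 1, tolerance = cycle_length_months() / 12)
  # discounting can only shrink the accruals
  tr3 <- quiet(build_trace(surv_dist("weibull", 1.2, 18), surv_dist("weibull", 1.2, 8),
                           horizon_years = 20))
  costs <- list(pfs = rep(100, nrow(tr3)), pd = rep(50, nrow(tr3)))
  o_disc <- accrue_outcomes(tr3, list(pfs = 0.7, pd = 0.5), costs, rate = 0.03)
  expect_lt(o_disc$cost, o_disc$cost_undiscounted)
  expect_lt(o_disc$qaly, o_disc$qaly_undiscounted)
  expect_error(accrue_outcomes(tr3, list(pfs = 0.7, pd = 0.5),
                               list(pfs = rep(-1, nrow(tr3)), pd = rep(0, nrow(tr3)))),
               "negative")
  expect_error(accrue_outcomes(tr3, list(pfs = 1.4, pd = 0.5)), "\\[0, 1\\]")
})

test_that("undiscounted life-years equal the cycle sum of the OS curve", {
  os <- surv_dist("weibull", 1.3, 15)
  tr <- build_trace(os, surv_dist("weibull", 1.3, 6), horizon_years = 30)
  out <- accrue_outcomes(tr, utilities = list(pfs = 1, pd = 1), rate = 0)
  dl <- cycle_length_months()
  riemann <- sum(survival_at(os, tr$time)) * dl / 12
  expect_equal(out$qaly, riemann, tolerance = 1e-12)
  # and the cycle sum brackets the continuous integral within one cycle width
  integral <- integrate(function(t) survival_at(os, t), 0, 30 * 12)$value / 12
  expect_lt(abs(out$qaly - integral), dl / 12)
})

test_that("half-cycle correction averages adjacent occupancies", {
  tr <- toy_trace(pfs = c(1, 0.5), pd = c(0, 0), death = c(0, 0.5),
                  cycle_length = 6)
  out <- accrue_outcomes(tr, utilities = list(pfs = 1, pd = 1), rate = 0,
                         half_cycle = TRUE)
  # occupancies become (0.75, 0.5): (0.75 + 0.5) * 0.5y
  expect_equal(out$qaly, 1.25 * 0.5)
})
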