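us <- default_inputs("US")
cn <- default_inputs("CN")

test_that("per-cycle drug acquisition costs match the published table", {
  body_us <- us$body
  expect_equal(drug_cycle_cost(dosing_rule("per_m2", 75), body_us, 1.345),
               185.6, tolerance = 1e-3)
  expect_equal(drug_cycle_cost(dosing_rule("flat_mg", 200), body_us, 48.987),
               9797.4)
  expect_equal(drug_cycle_cost(dosing_rule("per_m2", 500), body_us, 6.8107),
               6265.844)
  expect_equal(drug_cycle_cost(dosing_rule("per_kg", 3), body_us, 10),
               3 * 71.4 * 10)
  expect_error(dosing_rule("per_m2", -5), "> 0")
})

test_that("the Chinese donation schedule pays 5, donates 5, then alternates 3+3", {
  expect_equal(payable_fraction_cn(c(1, 3, 5)), c(1L, 1L, 1L))
  expect_equal(payable_fraction_cn(c(6, 7, 10)), c(0L, 0L, 0L))
  expect_equal(payable_fraction_cn(11:16), c(1L, 1L, 1L, 0L, 0L, 0L))
  expect_equal(payable_fraction_cn(c(17, 20, 23)), c(1L, 0L, 1L))
  expect_error(payable_fraction_cn(0), ">= 1")
})

test_that("arm cycle costs assemble regimen, monitoring, AEs and progression care", {
  # progressed disease, chemotherapy arm, US: crossover to pembrolizumab
  pd1 <- arm_cycle_cost("chemo", 1, "pd", us)
  expect_equal(pd1, 0.565 * 9797 + 0.435 * 3472, tolerance = 1e-9)
  # beyond the checkpoint-inhibitor cap those patients get supportive care
  pd40 <- arm_cycle_cost("chemo", 40, "pd", us)
  expect_equal(pd40, 3472)
  # combination arm past the 35-cycle pembrolizumab cap: pemetrexed + monitoring
  pfs36 <- arm_cycle_cost("combo", 36, "pfs", us)
  expect_equal(pfs36, 500 * 1.84 * 6.8107 + 732)
  pfs20 <- arm_cycle_cost("combo", 20, "pfs", us)
  expect_equal(pfs20 - pfs36, 9797.4)
  # death costs nothing
  expect_equal(arm_cycle_cost("combo", 5, "death", us), 0)
  # induction adds platinum and expected AE management cost
  ae_exp <- sum(us$ae_incidence$chemo * c(1814, 1043, 1654)) / 4
  plat <- 0.5 * 750 * (3.252 / 50) + 0.5 * 75 * 1.84 * (1.847 / 10)
  expect_equal(arm_cycle_cost("chemo", 2, "pfs", us),
               500 * 1.84 * 6.8107 + plat + ae_exp + 732)
})

test_that("costs are homogeneous of degree one in prices", {
  sched <- arm_cost_schedule("combo", 60, us)
  sched2 <- arm_cost_schedule("combo", 60, scale_money(us, 2))
  expect_equal(sched2$pfs, 2 * sched$pfs, tolerance = 1e-12)
  expect_equal(sched2$pd, 2 * sched$pd, tolerance = 1e-12)
})

test_that("the donation program removes exactly the donated cycles' pembrolizumab", {
  cn_nodon <- cn; cn_nodon$donation_program <- FALSE
  k <- seq_len(60)
  with_don <- arm_cycle_cost("combo", k, "pfs", cn)
  without <- arm_cycle_cost("combo", k, "pfs", cn_nodon)
  pembro <- 200 * cn$price_per_mg$pembrolizumab$value
  # oracle: explicit cycle enumeration of the payable pattern
  expected_diff <- pembro * (1 - payable_fraction_cn(k)) * (k <= 35)
  expect_equal(without - with_don, expected_diff, tolerance = 1e-9)
  expect_lt(sum(with_don), sum(without))
})

test_that("scenario multipliers scale the named drug only and validate keys", {
  sched <- arm_cost_schedule("combo", 40, us)
  sched_same <- arm_cost_schedule("combo", 40, us, scenario = c(pembrolizumab = 1))
  expect_identical(sched$pfs, sched_same$pfs)
  expect_identical(sched$pd, sched_same$pd)
  sched_cut <- arm_cost_schedule("combo", 40, us, scenario = c(pembrolizumab = 0.6))
  k <- seq_len(40)
  expect_equal(sched$pfs - sched_cut$pfs, 0.4 * 9797.4 * (k <= 35))
  expect_error(arm_cycle_cost("combo", 1, "pfs", us, scenario = c(bogus = 0.5)),
               "unknown drug")
})
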