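test_that("trial simulation honours censoring settings and the seed", {
  d20 <- surv_dist("weibull", 1.3, 12)
  spec <- trial_sim_spec(os = d20, pfs = d20, n = 200, enrolment_months = 0,
                         admin_censor_months = 1e4, censor_prob = 0)
  d <- simulate_trial(spec, seed = 3)
  expect_true(all(d$os_event == 1) && all(d$pfs_event == 1))
  expect_identical(d, simulate_trial(spec, seed = 3))
  expect_false(identical(d, simulate_trial(spec, seed = 4)))
})

test_that("subject-level progression never follows death", {
  spec <- trial_sim_spec(os = surv_dist("weibull", 1.1, 18),
                         pfs = surv_dist("weibull", 1.1, 7),
                         n = 500, censor_prob = 0.2)
  d <- simulate_trial(spec, seed = 12)
  expect_true(all(d$pfs_time <= d$os_time + 1e-12))
  spec_bad <- function() trial_sim_spec(os = surv_dist("weibull", 1, 5),
                                        pfs = surv_dist("weibull", 1, 10), n = 10)
  expect_error(spec_bad(), "dominate")
})

test_that("simulated KM medians match the generating distribution", {
  os <- surv_dist("weibull", 1, 20)  # exponential, median 20 ln 2
  spec <- trial_sim_spec(os = os, pfs = os, n = 2000, enrolment_months = 6,
                         admin_censor_months = 120, censor_prob = 0.05)
  d <- simulate_trial(spec, seed = 17)
  km <- survival::survfit(survival::Surv(os_time, os_event) ~ 1, data = d)
  med <- summary(km)$table[["median"]]
  expect_lt(abs(med - 20 * log(2)), 0.9)
})

test_that("digitized exports start at (0, 1) and carry the at-risk table", {
  rt <- round_trip_counts(surv_dist("weibull", 1.3, 9), n = 300, seed = 2)
  expect_equal(rt$export$curve$time[1], 0)
  expect_equal(rt$export$curve$surv[1], 1)
  expect_equal(rt$export$at_risk$n[1], 300)
  expect_true(all(diff(rt$export$at_risk$n) <= 0))
})

test_that("the full digitize-reconstruct-fit round trip recovers the scale", {
  rt <- round_trip_counts(surv_dist("weibull", 1.3, 9), n = 500, seed = 13)
  fit <- fit_parametric(rt$counts, "weibull", curve = rt$export$curve)
  expect_lt(abs(coef(fit)[["scale"]] - 9) / 9, 0.10)
})

test_that("jittered digitization still reconstructs after re-monotonization", {
  spec <- trial_sim_spec(os = surv_dist("weibull", 1.2, 10),
                         pfs = surv_dist("weibull", 1.2, 10), n = 400,
                         censor_prob = 0.1)
  d <- simulate_trial(spec, seed = 5)
  ex <- export_digitized(d$os_time, d$os_event, k = 25, jitter = 0.01, seed = 9)
  # jitter distorts the implied censoring; the clamp may warn by design
  cnt <- quiet(reconstruct_interval_counts(ex$curve, ex$at_risk))
  expect_equal(sum(cnt$events) + sum(cnt$censored) + attr(cnt, "n_tail"),
               400, tolerance = 1e-6)
})

test_that("shipped default inputs transcribe the published table", {
  us <- default_inputs("US"); cn <- default_inputs("CN")
  expect_equal(us$utilities$pfs$value, 0.652)
  expect_equal(us$utilities$pd$value, 0.47)
  expect_equal(cn$utilities$pfs$value, 0.804)
  expect_equal(cn$utilities$pd$value, 0.321)
  expect_equal(us$wtp, 100000)
  expect_equal(cn$wtp, 27351)
  expect_equal(us$prevalence,
               c(lt1 = 0.3287, pd1_1_49 = 0.3218, ge50 = 0.3495))
  expect_equal(us$prop_subsequent$combo$value, 0.542)
  expect_equal(us$prop_subsequent$chemo$value, 0.565)
  expect_equal(cn$exchange_rate_cny_per_usd, 6.7)
  expect_equal(cn$body, list(bsa_m2 = 1.72, weight_kg = 65))
  # both configs pass every structural invariant
  expect_silent(validate_inputs(us))
  expect_silent(validate_inputs(cn))
  bad <- us; bad$prevalence[1] <- 0.5
  expect_error(validate_inputs(bad), "prevalence")
})
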