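# Shared fixtures: quiet evaluation wrappers and small random generators.

# long-tailed subgroup curves trip the lifetime-horizon convergence
# warning by design; silence it where the test is about something else
quiet <- function(expr) suppressWarnings(expr)

random_dist <- function() {
  surv_dist(sample(c("weibull", "loglogistic"), 1),
            shape = stats::runif(1, 0.5, 3),
            scale = stats::runif(1, 2, 40))
}

# inputs with every monetary entry scaled by a common factor (used for
# price-homogeneity checks)
scale_money <- function(inputs, f) {
  s3 <- function(p) { p$value <- p$value * f; p$low <- p$low * f; p$high <- p$high * f; p }
  inputs$price_per_mg <- lapply(inputs$price_per_mg, s3)
  inputs$monitoring_cost <- s3(inputs$monitoring_cost)
  inputs$pdl1_test_cost <- s3(inputs$pdl1_test_cost)
  inputs$subsequent_cost <- lapply(inputs$subsequent_cost, s3)
  inputs$supportive_cost <- s3(inputs$supportive_cost)
  inputs$ae_cost <- lapply(inputs$ae_cost, s3)
  inputs$premedication_cost_per_cycle <- inputs$premedication_cost_per_cycle * f
  inputs
}

# minimal hand-built cohort trace for accrual arithmetic
toy_trace <- function(pfs, pd, death, cycle_length) {
  tr <- data.frame(cycle = seq_along(pfs) - 1L,
                   time = (seq_along(pfs) - 1L) * cycle_length,
                   pfs = pfs, pd = pd, death = death)
  attr(tr, "cycle_length") <- cycle_length
  class(tr) <- c("cohort_trace", "data.frame")
  tr
}

# simulate one endpoint, digitize, reconstruct: the standard round trip
round_trip_counts <- function(dist, n, seed, k = 30, censor_prob = 0.1,
                              admin = 40) {
  spec <- trial_sim_spec(os = dist, pfs = dist, n = n, enrolment_months = 6,
                         admin_censor_months = admin,
                         censor_prob = censor_prob)
  d <- simulate_trial(spec, seed = seed)
  ex <- export_digitized(d$os_time, d$os_event, k = k)
  list(data = d, export = ex,
       counts = reconstruct_interval_counts(ex$curve, ex$at_risk))
}
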