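test_that("digitized curve and at-risk table validate their invariants", {
  expect_error(digitized_curve(c(0, 5), c(1, 1.2)), "\\[0, 1\\]")
  expect_error(digitized_curve(c(5, 0), c(1, 0.5)), "ascending")
  expect_warning(digitized_curve(c(0, 3, 6), c(1, 0.5, 0.6)), "monotone")
  expect_error(at_risk_table(c(0, 6), c(50, 60)), "non-increasing")
  expect_error(at_risk_table(c(0, 6), c(0, 0)), "arm size")
})

test_that("interval counts reproduce censor-free and all-censored cases", {
  # no censoring: at-risk drops exactly by the events
  cv <- digitized_curve(c(0, 6, 12), c(1, 0.8, 0.6))
  ar <- at_risk_table(c(0, 6, 12), c(100, 80, 60))
  cnt <- reconstruct_interval_counts(cv, ar)
  expect_equal(cnt$events, c(20, 20), tolerance = 1e-9)
  expect_equal(cnt$censored, c(0, 0), tolerance = 1e-9)
  expect_equal(attr(cnt, "n_tail"), 60, tolerance = 1e-9)
  # flat survival while at-risk empties: pure censoring
  cv2 <- digitized_curve(c(0, 6, 12), c(1, 0.5, 0.5))
  ar2 <- at_risk_table(c(0, 6, 12), c(100, 50, 0))
  cnt2 <- reconstruct_interval_counts(cv2, ar2)
  expect_equal(cnt2$events, c(50, 0), tolerance = 1e-9)
  expect_equal(cnt2$censored, c(0, 50), tolerance = 1e-9)
})

test_that("reconstruction is self-consistent and conserves the cohort", {
  set.seed(41)
  for (i in 1:5) {
    rt <- round_trip_counts(surv_dist("weibull", runif(1, 0.8, 2), runif(1, 6, 20)),
                            n = 250, seed = i, censor_prob = 0.15)
    cnt <- rt$counts
    # KM recomputed from the counts matches the digitized curve
    km <- km_from_counts(cnt)
    ix <- match(rt$export$curve$time, km$time)
    expect_equal(km$surv[ix[!is.na(ix)]],
                 rt$export$curve$surv[!is.na(ix)], tolerance = 1e-6)
    # conservation: everyone is an event, a censoring, or still at risk
    # at the end of follow-up
    expect_equal(sum(cnt$events) + sum(cnt$censored) + attr(cnt, "n_tail"),
                 attr(cnt, "n0"), tolerance = 1e-6)
    expect_true(all(cnt$events >= -1e-9 & cnt$censored >= -1e-9))
  }
})

test_that("reconstructed event totals track the simulator's ground truth", {
  rt <- round_trip_counts(surv_dist("weibull", 1.2, 9), n = 300, seed = 7,
                          censor_prob = 0.10)
  true_events <- sum(rt$data$os_event)
  expect_lt(abs(sum(rt$counts$events) - true_events) / true_events, 0.05)
})

test_that("interval-censored fitting recovers simulation parameters", {
  rt <- round_trip_counts(surv_dist("weibull", 1.5, 8), n = 500, seed = 5)
  fit <- fit_parametric(rt$counts, "weibull", curve = rt$export$curve)
  expect_lt(abs(coef(fit)[["shape"]] - 1.5), 0.15)
  expect_lt(abs(coef(fit)[["scale"]] - 8), 0.8)
  expect_gt(fit$r2, 0.98)
  # exponential data: shape near 1
  rt2 <- round_trip_counts(surv_dist("weibull", 1, 12), n = 1000, seed = 6)
  fit2 <- fit_parametric(rt2$counts, "weibull")
  expect_gt(coef(fit2)[["shape"]], 0.9)
  expect_lt(coef(fit2)[["shape"]], 1.1)
  # log-logistic: recovered median (= scale) within 10%
  rt3 <- round_trip_counts(surv_dist("loglogistic", 2, 6), n = 500, seed = 8)
  fit3 <- fit_parametric(rt3$counts, "loglogistic")
  expect_lt(abs(median_survival(fit3$dist) - 6) / 6, 0.10)
})

test_that("the likelihood maximizer agrees with survreg on the same counts", {
  rt <- round_trip_counts(surv_dist("weibull", 1.4, 30), n = 600, seed = 42,
                          k = 40)
  fit <- fit_parametric(rt$counts, "weibull")
  cnt <- rt$counts
  ev <- cnt[cnt$events > 1e-9, ]; cs <- cnt[cnt$censored > 1e-9, ]
  df <- rbind(data.frame(t1 = pmax(ev$start, 1e-6), t2 = ev$end, ev = 3, w = ev$events),
              data.frame(t1 = cs$end, t2 = NA, ev = 0, w = cs$censored))
  if (attr(cnt, "n_tail") > 1e-9)
    df <- rbind(df, data.frame(t1 = attr(cnt, "t_end"), t2 = NA, ev = 0,
                               w = attr(cnt, "n_tail")))
  sr <- survival::survreg(survival::Surv(t1, t2, ev, type = "interval") ~ 1,
                          weights = df$w, data = df, dist = "weibull")
  expect_equal(coef(fit)[["shape"]], 1 / sr$scale, tolerance = 1e-3)
  expect_equal(coef(fit)[["scale"]], exp(coef(sr)[[1]]), tolerance = 1e-3)
})

test_that("family selection prefers the generating family and breaks ties to Weibull", {
  set.seed(51)
  wins <- 0L
  for (i in 1:50) {
    rt <- round_trip_counts(surv_dist("weibull", 1.6, 10), n = 300, seed = 100 + i,
                            k = 25)
    sel <- select_best_family(rt$counts, rt$export$curve)
    if (sel$family == "weibull") wins <- wins + 1L
    expect_length(sel$r2, 2)
  }
  expect_gte(wins, 40)  # >= 80% of replicates
  # single candidate is returned as-is
  rt <- round_trip_counts(surv_dist("loglogistic", 2, 8), n = 300, seed = 9)
  expect_equal(select_best_family(rt$counts, rt$export$curve,
                                  families = "loglogistic")$family, "loglogistic")
  # documented tie-break
  expect_equal(pdl1cea:::pick_family(c(loglogistic = 0.9, weibull = 0.9)), "weibull")
  expect_equal(pdl1cea:::pick_family(c(loglogistic = 0.95, weibull = 0.9)), "loglogistic")
})

test_that("curve and at-risk CSV round trips preserve the objects", {
  cv <- digitized_curve(c(0, 3, 6), c(1, 0.7, 0.4))
  ar <- at_risk_table(c(0, 6), c(80, 30))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_digitized_curve(cv, f1); write_at_risk_table(ar, f2)
  expect_equal(as.data.frame(read_digitized_curve(f1)), as.data.frame(cv))
  expect_equal(as.data.frame(read_at_risk_table(f2)), as.data.frame(ar))
})
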