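test_that("moment matching reproduces hand-computed beta/gamma parameters", {
  # symmetric utility range: alpha = beta
  d <- fit_moment_distribution(param_spec("u", 0.5, 0.3, 0.7, "utility"))
  expect_equal(d$family, "beta")
  expect_equal(d$alpha, d$beta)
  # monitoring-cost row: sd = (878-586)/3.92, gamma moments
  d2 <- fit_moment_distribution(param_spec("mon", 732, 586, 878, "cost"))
  sdv <- (878 - 586) / (2 * 1.96)
  expect_equal(d2$shape, 732^2 / sdv^2, tolerance = 1e-9)
  expect_equal(d2$scale, sdv^2 / 732, tolerance = 1e-9)
  expect_equal(d2$shape, 96.56, tolerance = 1e-3)
  expect_equal(d2$scale, 7.58, tolerance = 1e-3)
  # degenerate range: point mass
  d3 <- fit_moment_distribution(param_spec("p", 5, 5, 5, "cost"))
  expect_equal(d3, list(family = "point", value = 5))
  # infeasible beta variance is clipped with a warning
  expect_warning(fit_moment_distribution(param_spec("u", 0.98, 0, 1, "utility")),
                 "clipped")
  # inconsistent published range falls back to +/-20%
  expect_warning(sp <- param_spec("niv", 2689, 21518, 32278, "cost"),
                 "20%")
  expect_equal(c(sp$low, sp$high), c(2689 * 0.8, 2689 * 1.2))
})

test_that("PSA draws are reproducible, mean-faithful, and degenerate-exact", {
  us <- default_inputs("US")
  curves <- example_curves(subgroups = FALSE)
  specs <- build_param_specs(us)
  model <- function(ov) {
    m <- apply_overrides(us, curves, ov)
    quiet(evaluate_strategies(list(strategy_spec("all_chemo"),
                                   strategy_spec("all_combo")),
                              m$curves, m$inputs, horizon_years = 10))
  }
  p1 <- quiet(run_psa(model, specs, n = 20, seed = 99))
  p2 <- quiet(run_psa(model, specs, n = 20, seed = 99))
  expect_identical(p1$draws, p2$draws)
  expect_equal(p1$n_failed, 0)
  # larger sample: each beta/gamma parameter's empirical mean within 3 SE
  p3 <- quiet(run_psa(function(ov) data.frame(strategy = "x", cost = 1, qaly = 1),
                      specs, n = 1000, seed = 3))
  for (sp in specs) {
    x <- p3$params[, sp$name]
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - sp$base), 3 * se + 1e-12)
  }
  # all-degenerate distributions reproduce the base case in every draw
  dspecs <- lapply(specs, function(s) param_spec(s$name, s$base, s$base, s$base, s$class))
  base <- model(list())
  p4 <- quiet(run_psa(model, dspecs, n = 5, seed = 1))
  for (i in 1:5) {
    d <- p4$draws[p4$draws$draw == i, c("strategy", "cost", "qaly")]
    rownames(d) <- NULL
    expect_equal(d, base)
  }
})

test_that("acceptability curves count max-NMB wins and normalize", {
  # direct count oracle: A wins in exactly 634 of 1000 draws
  set.seed(81)
  win <- sample(c(rep(TRUE, 634), rep(FALSE, 366)))
  draws <- rbind(
    data.frame(draw = 1:1000, strategy = "A", cost = ifelse(win, 10, 30), qaly = 1),
    data.frame(draw = 1:1000, strategy = "B", cost = 20, qaly = 1))
  cc <- ceac(draws, wtp_grid = c(0, 5e4))
  expect_equal(cc$prob[cc$strategy == "A"], c(0.634, 0.634))
  expect_equal(cc$prob[cc$strategy == "B"], c(0.366, 0.366))
  # single strategy: probability one everywhere
  cc1 <- ceac(draws[draws$strategy == "A", ], wtp_grid = c(0, 1e5))
  expect_equal(cc1$prob, c(1, 1))
  # ties split equally and rows sum to one
  tied <- rbind(data.frame(draw = 1:4, strategy = "A", cost = 10, qaly = 1),
                data.frame(draw = 1:4, strategy = "B", cost = 10, qaly = 1))
  cct <- ceac(tied, wtp_grid = c(0, 1e5))
  expect_equal(cct$prob, rep(0.5, 4))
  for (w in unique(cc$wtp))
    expect_equal(sum(cc$prob[cc$wtp == w]), 1)
})

test_that("one-way DSA brackets the base case and orders by swing", {
  us <- default_inputs("US")
  curves <- example_curves(subgroups = FALSE)
  model <- function(ov) {
    m <- apply_overrides(us, curves, ov)
    chemo <- quiet(evaluate_arm("chemo", m$curves$chemo, m$inputs))
    combo <- quiet(evaluate_arm("combo", m$curves$combo, m$inputs))
    icer(chemo, combo)
  }
  base_icer <- model(list())$icer
  # every parameter at its base value reproduces the base ICER bit-identically
  specs <- build_param_specs(us)
  at_base <- lapply(specs, function(s) param_spec(s$name, s$base, s$base, s$base, s$class))
  tor0 <- one_way_dsa(model, at_base)
  expect_true(all(tor0$icer_low == base_icer))
  expect_true(all(tor0$icer_high == base_icer))
  expect_true(all(tor0$width == 0))
  # real ranges: deterministic, so a rerun gives the identical ordering
  tor <- one_way_dsa(model, specs)
  expect_identical(tor, one_way_dsa(model, specs))
  expect_true(all(diff(tor$width[!is.na(tor$width)]) <= 1e-12))
  # higher progressed-disease utility makes the combination look better
  row <- tor[tor$param == "utilities.pd", ]
  expect_lt(row$icer_high, row$icer_low)
  # cheaper pembrolizumab lowers the ICER
  row2 <- tor[tor$param == "price_per_mg.pembrolizumab", ]
  expect_lt(row2$icer_low, row2$icer_high)
  # a failing evaluation is flagged, not fatal
  boom <- one_way_dsa(function(ov) stop("nope"), specs[1])
  expect_match(boom$label_low, "error")
})
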