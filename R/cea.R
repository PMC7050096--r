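# Top-level interface: a full cost-effectiveness run for one country as a
# classed result object, plus run-config round trip and CSV artifacts.

#' Run the full cost-effectiveness analysis for one country
#'
#' Evaluates the three treatment strategies (chemotherapy for all,
#' pembrolizumab + chemotherapy for all, PD-L1-test-guided at the 1% and
#' 50% cutoffs) on the given survival curves and economic inputs,
#' computes the incremental dominance frontier and publication-style
#' pairwise comparisons, and optionally runs the price-reduction
#' scenarios, one-way deterministic sensitivity analysis of the
#' combination-vs-chemotherapy ICER, and the probabilistic sensitivity
#' analysis with acceptability curves.
#'
#' @param inputs An `econ_inputs` object (see [default_inputs()]).
#' @param curves Curve set (see [example_curves()]); subgroup entries are
#'   used by the test-guided strategies when present.
#' @param horizon_years Model horizon in years (default 20).
#' @param scenarios List of [scenario()] objects, or `NULL` to skip;
#'   defaults to the country's published price-reduction scenarios.
#' @param dsa Run the one-way DSA (logical).
#' @param psa_n Number of PSA draws (0 skips the PSA).
#' @param seed Seed for the PSA.
#' @param wtp_grid WTP grid for the acceptability curves.
#' @return An object of class `cea` with elements `results` (strategy
#'   means), `frontier`, `pairwise`, `scenarios`, `dsa`, `psa`, `ceac`,
#'   plus the call inputs. Methods: `print`, `summary`, `plot`.
#' @export
run_cea <- function(inputs, curves = example_curves(),
                    horizon_years = 20,
                    scenarios = default_scenarios(inputs$country),
                    dsa = FALSE, psa_n = 0, seed = 1,
                    wtp_grid = seq(0, 200000, by = 2000)) {
  specs <- list(strategy_spec("all_chemo"), strategy_spec("all_combo"),
                strategy_spec("test_guided", "1pct"),
                strategy_spec("test_guided", "50pct"))
  results <- evaluate_strategies(specs, curves, inputs,
                                 horizon_years = horizon_years)
  frontier <- incremental_frontier(results)
  pairwise <- pairwise_rows(results, reference = "Chemotherapy",
                            also_vs = "Pembro + Chemotherapy")
  scen <- if (!is.null(scenarios))
    run_scenarios(specs, curves, inputs, scenarios, horizon_years) else NULL

  dsa_tab <- NULL
  if (dsa) {
    sp <- build_param_specs(inputs, curves = NULL, prevalence = FALSE)
    model <- function(overrides) {
      mod <- apply_overrides(inputs, curves, overrides)
      chemo <- evaluate_arm("chemo", mod$curves$chemo, mod$inputs,
                            horizon_years = horizon_years)
      combo <- evaluate_arm("combo", mod$curves$combo, mod$inputs,
                            horizon_years = horizon_years)
      icer(chemo, combo)
    }
    dsa_tab <- one_way_dsa(model, sp)
  }

  psa_res <- ceac_tab <- NULL
  if (psa_n > 0) {
    sp <- build_param_specs(inputs, curves = curves, prevalence = FALSE)
    model <- function(overrides) {
      mod <- apply_overrides(inputs, curves, overrides)
      evaluate_strategies(specs, mod$curves, mod$inputs,
                          horizon_years = horizon_years)
    }
    psa_res <- run_psa(model, sp, n = psa_n, seed = seed)
    ceac_tab <- ceac(psa_res, wtp_grid)
  }

  structure(list(country = inputs$country, inputs = inputs, curves = curves,
                 horizon_years = horizon_years, results = results,
                 frontier = frontier, pairwise = pairwise,
                 scenarios = scen, dsa = dsa_tab, psa = psa_res,
                 ceac = ceac_tab, seed = seed),
            class = "cea")
}

#' @export
print.cea <- function(x, ...) {
  cat(sprintf("Cost-effectiveness analysis (%s, %g-year horizon, WTP $%s/QALY)\n\n",
              x$country, x$horizon_years, format(x$inputs$wtp, big.mark = " ", scientific = FALSE)))
  print(x$frontier)
  invisible(x)
}

#' @export
summary.cea <- function(object, ...) {
  x <- object
  cat(sprintf("Cost-effectiveness analysis: %s payer perspective\n", x$country))
  cat(sprintf("  horizon %g years, discount %.0f%%/yr, WTP $%s/QALY\n\n",
              x$horizon_years, 100 * x$inputs$discount_rate,
              format(x$inputs$wtp, big.mark = " ", scientific = FALSE)))
  cat("Strategy means and frontier:\n")
  print(x$frontier)
  cat("\nPairwise comparisons:\n")
  pw <- x$pairwise
  pw$delta_cost <- round(pw$delta_cost); pw$delta_qaly <- round(pw$delta_qaly, 3)
  pw$icer <- round(pw$icer)
  print(pw, row.names = FALSE)
  if (!is.null(x$scenarios) && length(x$scenarios) > 1) {
    cat("\nPrice scenarios (combination vs chemotherapy):\n")
    for (nm in names(x$scenarios)) {
      pwc <- x$scenarios[[nm]]$pairwise
      r <- pwc[pwc$strategy == "Pembro + Chemotherapy" &
                 pwc$comparator == "Chemotherapy", ]
      cat(sprintf("  %-22s dCost $%8.0f  dQALY %.3f  ICER %s\n", nm,
                  r$delta_cost, r$delta_qaly,
                  if (is.na(r$icer)) r$label else sprintf("$%.0f/QALY", r$icer)))
    }
  }
  if (!is.null(x$dsa)) {
    cat("\nMost influential parameters (one-way DSA, top 5 by ICER swing):\n")
    print(utils::head(as.data.frame(x$dsa)[, c("param", "icer_low", "icer_high", "width")], 5),
          row.names = FALSE)
  }
  if (!is.null(x$ceac)) {
    cc <- x$ceac[x$ceac$wtp == max(x$ceac$wtp[x$ceac$wtp <= x$inputs$wtp]), ]
    cat(sprintf("\nProbability cost-effective at WTP $%s/QALY (PSA n = %d):\n",
                format(x$inputs$wtp, big.mark = " ", scientific = FALSE), x$psa$n))
    for (i in seq_len(nrow(cc)))
      cat(sprintf("  %-28s %5.1f%%\n", cc$strategy[i], 100 * cc$prob[i]))
  }
  invisible(x)
}

#' Plot a cost-effectiveness analysis
#'
#' `type = "plane"` draws the cost-effectiveness plane (strategy means,
#' PSA cloud when available); `type = "ceac"` the acceptability curves;
#' `type = "tornado"` the one-way DSA bars.
#'
#' @param x A `cea` object.
#' @param type Plot type.
#' @param ... Unused.
#' @export
plot.cea <- function(x, type = c("plane", "ceac", "tornado"), ...) {
  type <- match.arg(type)
  if (type == "plane") {
    if (!is.null(x$psa)) {
      d <- x$psa$draws
      cols <- seq_along(unique(d$strategy))
      names(cols) <- unique(d$strategy)
      graphics::plot(d$qaly, d$cost, col = grDevices::adjustcolor(cols[d$strategy], 0.25),
                     pch = 16, cex = 0.4, xlab = "QALYs", ylab = "Cost (USD)",
                     main = sprintf("Cost-effectiveness plane (%s)", x$country))
      graphics::legend("topleft", legend = names(cols), col = cols, pch = 16, bty = "n")
    } else {
      graphics::plot(x$results$qaly, x$results$cost, pch = 19,
                     xlab = "QALYs", ylab = "Cost (USD)",
                     main = sprintf("Cost-effectiveness plane (%s)", x$country))
      graphics::text(x$results$qaly, x$results$cost, x$results$strategy, pos = 3, cex = 0.8)
    }
    graphics::abline(a = -x$inputs$wtp * 0 , b = x$inputs$wtp, lty = 2, col = "grey40")
  } else if (type == "ceac") {
    if (is.null(x$ceac)) stop("no PSA/CEAC in this object; rerun with psa_n > 0", call. = FALSE)
    strategies <- unique(x$ceac$strategy)
    graphics::plot(NULL, xlim = range(x$ceac$wtp), ylim = c(0, 1),
                   xlab = "Willingness to pay (USD/QALY)",
                   ylab = "Probability cost-effective",
                   main = sprintf("Acceptability curves (%s)", x$country))
    for (i in seq_along(strategies)) {
      d <- x$ceac[x$ceac$strategy == strategies[i], ]
      graphics::lines(d$wtp, d$prob, col = i, lwd = 2)
    }
    graphics::abline(v = x$inputs$wtp, lty = 2, col = "grey40")
    graphics::legend("right", legend = strategies, col = seq_along(strategies),
                     lwd = 2, bty = "n", cex = 0.8)
  } else {
    if (is.null(x$dsa)) stop("no DSA in this object; rerun with dsa = TRUE", call. = FALSE)
    d <- utils::head(x$dsa[!is.na(x$dsa$width), ], 12)
    d <- d[nrow(d):1, ]
    mid <- stats::median(c(d$icer_low, d$icer_high), na.rm = TRUE)
    graphics::par(mar = c(5, 14, 3, 1))
    graphics::plot(NULL, xlim = range(c(d$icer_low, d$icer_high), na.rm = TRUE),
                   ylim = c(0.5, nrow(d) + 0.5), yaxt = "n",
                   xlab = "ICER (USD/QALY)", ylab = "",
                   main = "One-way sensitivity (tornado)")
    for (i in seq_len(nrow(d)))
      graphics::segments(d$icer_low[i], i, d$icer_high[i], i, lwd = 8, col = "steelblue")
    graphics::abline(v = mid, lty = 2)
    graphics::axis(2, at = seq_len(nrow(d)), labels = d$param, las = 1, cex.axis = 0.7)
  }
  invisible(x)
}

#' Read or write a run configuration
#'
#' A run config bundles the country inputs, survival-curve parameters
#' (per arm and optional PD-L1 subgroup), horizon, scenario multipliers
#' and PSA settings in one JSON file.
#'
#' @param path JSON file path.
#' @param inputs,curves,horizon_years,scenarios,psa_n,seed Run settings.
#' @return `read_run_config` returns a list with the same elements,
#'   curves restored as [surv_dist] objects.
#' @export
write_run_config <- function(path, inputs, curves, horizon_years = 20,
                             scenarios = default_scenarios(inputs$country),
                             psa_n = 1000, seed = 1) {
  ser_curve <- function(cs) lapply(cs, function(d)
    if (inherits(d, "surv_dist")) unclass(d) else lapply(d, unclass))
  cfg <- list(inputs = inputs_to_list(inputs),
              curves = list(
                chemo = ser_curve(curves$chemo),
                combo = ser_curve(curves$combo),
                subgroups = if (!is.null(curves$subgroups))
                  lapply(curves$subgroups, function(s) lapply(s, ser_curve))),
              horizon_years = horizon_years,
              scenarios = lapply(scenarios, function(s)
                list(name = s$name, multipliers = as.list(s$multipliers))),
              psa_n = psa_n, seed = seed)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  de_curve <- function(x) list(os = as_surv_dist(x$os), pfs = as_surv_dist(x$pfs))
  curves <- list(chemo = de_curve(cfg$curves$chemo),
                 combo = de_curve(cfg$curves$combo))
  if (!is.null(cfg$curves$subgroups) && length(cfg$curves$subgroups))
    curves$subgroups <- lapply(cfg$curves$subgroups, function(s)
      list(chemo = de_curve(s$chemo), combo = de_curve(s$combo)))
  inputs <- cfg$inputs
  inputs$prevalence <- unlist(inputs$prevalence)
  inputs$subsequent_mix <- lapply(inputs$subsequent_mix, unlist)
  v <- unlist(inputs$subsequent_max_cycles)
  inputs$subsequent_max_cycles <- stats::setNames(as.numeric(v), names(v))
  inputs$subsequent_max_cycles[is.na(inputs$subsequent_max_cycles)] <- Inf
  inputs$platinum_mix <- unlist(inputs$platinum_mix)
  inputs$ae_incidence <- lapply(inputs$ae_incidence, unlist)
  inputs <- validate_inputs(structure(inputs, class = "econ_inputs"))
  scen <- lapply(cfg$scenarios, function(s)
    scenario(s$name, unlist(s$multipliers)))
  list(inputs = inputs, curves = curves,
       horizon_years = cfg$horizon_years, scenarios = scen,
       psa_n = cfg$psa_n, seed = cfg$seed)
}

#' Write the CSV artifacts of a run
#'
#' Emits the publication-table-shaped base-case report
#' (`base_case.csv`: strategy means plus frontier columns), the pairwise
#' table, per-scenario tables, and (when present) the DSA tornado, the
#' PSA draws and the acceptability curves, plus a small JSON run log.
#'
#' @param x A `cea` object.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cea_artifacts <- function(x, dir) {
  stopifnot(inherits(x, "cea"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(x$frontier),
                   file.path(dir, "base_case.csv"), row.names = FALSE)
  utils::write.csv(x$pairwise, file.path(dir, "pairwise.csv"), row.names = FALSE)
  if (!is.null(x$scenarios))
    for (nm in names(x$scenarios)) {
      fn <- gsub("[^A-Za-z0-9]+", "_", nm)
      utils::write.csv(x$scenarios[[nm]]$pairwise,
                       file.path(dir, paste0("scenario_", fn, ".csv")),
                       row.names = FALSE)
    }
  if (!is.null(x$dsa))
    utils::write.csv(as.data.frame(x$dsa), file.path(dir, "dsa_tornado.csv"),
                     row.names = FALSE)
  if (!is.null(x$psa))
    utils::write.csv(x$psa$draws, file.path(dir, "psa_draws.csv"),
                     row.names = FALSE)
  if (!is.null(x$ceac))
    utils::write.csv(as.data.frame(x$ceac), file.path(dir, "ceac.csv"),
                     row.names = FALSE)
  log <- list(country = x$country, horizon_years = x$horizon_years,
              seed = x$seed, psa_n = if (is.null(x$psa)) 0 else x$psa$n,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              package_version = as.character(utils::packageVersion("pdl1cea")))
  jsonlite::write_json(log, file.path(dir, "run_log.json"), auto_unbox = TRUE)
  invisible(dir)
}
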