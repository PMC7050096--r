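# One-way deterministic sensitivity analysis (tornado), probabilistic
# sensitivity analysis with beta/gamma moment matching, and
# cost-effectiveness acceptability curves.

#' Sensitivity-analysis parameter specification
#'
#' @param name Parameter name (a path understood by the model evaluator).
#' @param base,low,high Base-case value and range (low <= base <= high).
#'   Ranges are interpreted as 95\% intervals for moment matching. If the
#'   published range is inconsistent with the base value, a plausible
#'   +/-20\% range is substituted with a warning.
#' @param class One of `"probability"`, `"utility"`, `"proportion"`
#'   (sampled from beta distributions in the PSA), `"cost"`, `"price"`
#'   (gamma), or `"scale"`/`"shape"` (log-normal survival-curve
#'   parameters).
#' @return A `param_spec` object.
#' @export
param_spec <- function(name, base, low, high,
                       class = c("probability", "utility", "proportion",
                                 "cost", "price", "scale", "shape")) {
  class <- match.arg(class)
  if (!(low <= base && base <= high)) {
    warning("range for '", name, "' is inconsistent with its base value; ",
            "substituting +/-20%")
    low <- base * 0.8; high <- base * 1.2
  }
  if (class %in% c("probability", "utility", "proportion") &&
      (low < 0 || high > 1))
    stop("bounded-class parameters must have range within [0, 1]", call. = FALSE)
  structure(list(name = name, base = base, low = low, high = high,
                 class = class), class = "param_spec")
}

#' Moment-matched sampling distribution for a parameter
#'
#' The range is read as a 95\% interval, so
#' \eqn{sd = (high - low)/(2 \times 1.96)}. Bounded classes
#' (probability/utility/proportion) are matched to a beta distribution
#' (\eqn{\alpha = m(m(1-m)/v - 1)}, \eqn{\beta = (1-m)(m(1-m)/v - 1)});
#' costs and prices to a gamma (\eqn{shape = m^2/v}, \eqn{scale = v/m});
#' survival-curve parameters to a log-normal with median `base`. A beta
#' variance at or beyond the feasible bound \eqn{m(1-m)} is clipped with a
#' warning. A degenerate range yields a point mass.
#'
#' @param spec A [param_spec()].
#' @return List describing the distribution: `family` in
#'   `"beta"`/`"gamma"`/`"lognormal"`/`"point"` plus its parameters.
#' @export
fit_moment_distribution <- function(spec) {
  m <- spec$base
  sdv <- (spec$high - spec$low) / (2 * 1.96)
  if (sdv == 0) return(list(family = "point", value = m))
  v <- sdv^2
  if (spec$class %in% c("probability", "utility", "proportion")) {
    vmax <- m * (1 - m)
    if (v >= vmax) {
      warning("infeasible beta variance for '", spec$name, "'; clipped")
      v <- 0.95 * vmax
    }
    k <- m * (1 - m) / v - 1
    list(family = "beta", alpha = m * k, beta = (1 - m) * k)
  } else if (spec$class %in% c("cost", "price")) {
    if (m <= 0) return(list(family = "point", value = m))
    list(family = "gamma", shape = m^2 / v, scale = v / m)
  } else {
    # survival-curve parameters: normal on the log scale, median = base
    sdlog <- (log(spec$high) - log(spec$low)) / (2 * 1.96)
    list(family = "lognormal", meanlog = log(m), sdlog = sdlog)
  }
}

sample_param <- function(dist, n) {
  switch(dist$family,
         point     = rep(dist$value, n),
         beta      = stats::rbeta(n, dist$alpha, dist$beta),
         gamma     = stats::rgamma(n, shape = dist$shape, scale = dist$scale),
         lognormal = stats::rlnorm(n, dist$meanlog, dist$sdlog))
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Evaluates a deterministic model at each parameter's low and high value
#' with all other parameters at base, and orders the entries by the width
#' of the resulting ICER swing. Dominance outcomes (non-numeric ICERs) are
#' carried through as `NA` with the model's label preserved; a failing
#' evaluation flags the entry and the run continues.
#'
#' @param model Function of one argument: a named list of parameter values
#'   (`name` -> value); returns the model outcome, either a number (the
#'   ICER) or a list with `icer` and optional `label`.
#' @param specs List of [param_spec()] objects.
#' @return data.frame of class `tornado` with one row per parameter:
#'   `param`, `base`, `low`, `high`, `icer_low`, `icer_high`,
#'   `label_low`, `label_high`, `width`, sorted by decreasing width.
#' @export
one_way_dsa <- function(model, specs) {
  eval1 <- function(overrides) {
    out <- tryCatch(model(overrides), error = function(e) e)
    if (inherits(out, "error"))
      return(list(icer = NA_real_, label = paste("error:", conditionMessage(out))))
    if (is.numeric(out)) return(list(icer = out, label = NA_character_))
    list(icer = if (is.null(out$icer)) NA_real_ else out$icer,
         label = if (is.null(out$label)) NA_character_ else out$label)
  }
  rows <- lapply(specs, function(sp) {
    lo <- eval1(stats::setNames(list(sp$low), sp$name))
    hi <- eval1(stats::setNames(list(sp$high), sp$name))
    width <- abs(hi$icer - lo$icer)
    data.frame(param = sp$name, base = sp$base, low = sp$low, high = sp$high,
               icer_low = lo$icer, icer_high = hi$icer,
               label_low = lo$label, label_high = hi$label,
               width = if (length(width)) width else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-ifelse(is.na(out$width), -Inf, out$width)), ]
  rownames(out) <- NULL
  class(out) <- c("tornado", "data.frame")
  out
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n` joint parameter sets (independently across parameters, each
#' from its moment-matched distribution), evaluates all strategies per
#' draw, and returns the per-draw results. Fully reproducible given
#' `seed`; draws whose evaluation fails are recorded and excluded.
#'
#' @param model Function of one argument (named list of parameter values)
#'   returning a data.frame with columns `strategy`, `cost`, `qaly`.
#' @param specs List of [param_spec()] objects.
#' @param n Number of draws (the base analysis uses about 1000).
#' @param seed Integer seed.
#' @return Object of class `psa`: list with `draws` (long data.frame:
#'   `draw`, `strategy`, `cost`, `qaly`), `params` (matrix of sampled
#'   values), `n_failed`.
#' @export
run_psa <- function(model, specs, n = 1000, seed = 1) {
  stopifnot(n >= 1)
  set.seed(seed)
  dists <- lapply(specs, fit_moment_distribution)
  pnames <- vapply(specs, `[[`, character(1), "name")
  samp <- vapply(dists, sample_param, numeric(n), n = n)
  if (n == 1) samp <- matrix(samp, nrow = 1)
  colnames(samp) <- pnames
  res <- vector("list", n); failed <- 0L
  for (i in seq_len(n)) {
    overrides <- as.list(samp[i, ]); names(overrides) <- pnames
    r <- tryCatch(model(overrides), error = function(e) NULL)
    if (is.null(r)) { failed <- failed + 1L; next }
    r$draw <- i
    res[[i]] <- r
  }
  draws <- do.call(rbind, res)
  structure(list(draws = draws, params = samp, n = n, n_failed = failed,
                 seed = seed), class = "psa")
}

#' @export
print.psa <- function(x, ...) {
  cat(sprintf("PSA: %d draws (%d failed), %d strategies, seed %d\n",
              x$n, x$n_failed, length(unique(x$draws$strategy)), x$seed))
  invisible(x)
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay value, the probability that each strategy
#' has the maximal net monetary benefit across the PSA draws (ties split
#' equally). Probabilities sum to 1 at every WTP.
#'
#' @param psa A [run_psa()] result (or a data.frame shaped like its
#'   `draws`).
#' @param wtp_grid WTP values in USD/QALY (default 0 to 200 000 by 2 000).
#' @return data.frame of class `ceac`: `wtp`, `strategy`, `prob`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 200000, by = 2000)) {
  draws <- if (inherits(psa, "psa")) psa$draws else psa
  stopifnot(all(c("draw", "strategy", "cost", "qaly") %in% names(draws)))
  strategies <- unique(draws$strategy)
  ids <- unique(draws$draw)
  cost <- matrix(NA_real_, length(ids), length(strategies),
                 dimnames = list(NULL, strategies))
  qaly <- cost
  for (s in strategies) {
    d <- draws[draws$strategy == s, ]
    i <- match(d$draw, ids)
    cost[i, s] <- d$cost; qaly[i, s] <- d$qaly
  }
  out <- lapply(wtp_grid, function(w) {
    nmb <- w * qaly - cost
    best <- nmb == apply(nmb, 1, max)
    share <- best / rowSums(best)  # ties split equally
    data.frame(wtp = w, strategy = strategies, prob = colMeans(share),
               row.names = NULL)
  })
  out <- do.call(rbind, out)
  class(out) <- c("ceac", "data.frame")
  out
}

#' Build the standard sensitivity parameter set from economic inputs
#'
#' One [param_spec()] per published input-table row relevant to a model
#' run: drug prices, monitoring/test/subsequent/supportive/AE costs,
#' utilities and subsequent-therapy proportions, plus (optionally) the
#' PD-L1 prevalence weights and the survival-curve shape/scale parameters
#' with +/-20\% ranges.
#'
#' @param inputs An `econ_inputs` object.
#' @param curves Optional curve set; adds log-normal specs for every
#'   shape/scale.
#' @param prevalence Include the PD-L1 prevalence weights.
#' @return List of `param_spec` objects.
#' @export
build_param_specs <- function(inputs, curves = NULL, prevalence = FALSE) {
  sp <- list()
  add <- function(name, p, class) {
    sp[[length(sp) + 1L]] <<- suppressWarnings(
      param_spec(name, p$value, p$low, p$high, class))
  }
  for (d in names(inputs$price_per_mg))
    add(paste0("price_per_mg.", d), inputs$price_per_mg[[d]], "price")
  add("monitoring_cost", inputs$monitoring_cost, "cost")
  add("pdl1_test_cost", inputs$pdl1_test_cost, "cost")
  for (d in names(inputs$subsequent_cost)) {
    p <- inputs$subsequent_cost[[d]]
    if (!(p$low <= p$value && p$value <= p$high)) {
      warning("published range for subsequent '", d,
              "' is inconsistent; using +/-20%")
      p <- list(value = p$value, low = 0.8 * p$value, high = 1.2 * p$value)
    }
    add(paste0("subsequent_cost.", d), p, "cost")
  }
  add("supportive_cost", inputs$supportive_cost, "cost")
  for (a in names(inputs$ae_cost))
    add(paste0("ae_cost.", a), inputs$ae_cost[[a]], "cost")
  add("utilities.pfs", inputs$utilities$pfs, "utility")
  add("utilities.pd", inputs$utilities$pd, "utility")
  add("prop_subsequent.combo", inputs$prop_subsequent$combo, "proportion")
  add("prop_subsequent.chemo", inputs$prop_subsequent$chemo, "proportion")
  if (prevalence) {
    for (s in names(inputs$prevalence)) {
      v <- inputs$prevalence[[s]]
      add(paste0("prevalence.", s),
          list(value = v, low = max(0, 0.8 * v), high = min(1, 1.2 * v)),
          "proportion")
    }
  }
  if (!is.null(curves)) {
    for (arm in c("chemo", "combo")) for (ep in c("os", "pfs")) {
      d <- curves[[arm]][[ep]]
      add(paste0("curve.", arm, ".", ep, ".shape"),
          list(value = d$shape, low = 0.8 * d$shape, high = 1.2 * d$shape), "shape")
      add(paste0("curve.", arm, ".", ep, ".scale"),
          list(value = d$scale, low = 0.8 * d$scale, high = 1.2 * d$scale), "scale")
    }
  }
  sp
}

#' Apply named parameter overrides to inputs and curves
#'
#' Resolves the dotted parameter names produced by [build_param_specs()]
#' back onto an `econ_inputs` object and a curve set, returning the
#' modified pair. Prevalence overrides are renormalized to sum to 1.
#'
#' @param inputs An `econ_inputs` object.
#' @param curves A curve set (may be `NULL` if no curve parameters are
#'   overridden).
#' @param overrides Named list of parameter values.
#' @return List with modified `inputs` and `curves`.
#' @export
apply_overrides <- function(inputs, curves, overrides) {
  if (length(overrides) == 0)
    return(list(inputs = inputs, curves = curves))
  for (nm in names(overrides)) {
    v <- overrides[[nm]]
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    key <- parts[1]
    if (key == "price_per_mg") inputs$price_per_mg[[parts[2]]]$value <- v
    else if (key == "monitoring_cost") inputs$monitoring_cost$value <- v
    else if (key == "pdl1_test_cost") inputs$pdl1_test_cost$value <- v
    else if (key == "subsequent_cost") inputs$subsequent_cost[[parts[2]]]$value <- v
    else if (key == "supportive_cost") inputs$supportive_cost$value <- v
    else if (key == "ae_cost") inputs$ae_cost[[parts[2]]]$value <- v
    else if (key == "utilities") inputs$utilities[[parts[2]]]$value <- v
    else if (key == "prop_subsequent") inputs$prop_subsequent[[parts[2]]]$value <- v
    else if (key == "prevalence") inputs$prevalence[[parts[2]]] <- v
    else if (key == "curve") {
      d <- curves[[parts[2]]][[parts[3]]]
      if (parts[4] == "shape") d$shape <- v else d$scale <- v
      curves[[parts[2]]][[parts[3]]] <- surv_dist(d$family, d$shape, d$scale)
    } else stop("unknown parameter '", nm, "'", call. = FALSE)
  }
  if (any(startsWith(names(overrides), "prevalence.")))
    inputs$prevalence <- inputs$prevalence / sum(inputs$prevalence)
  list(inputs = inputs, curves = curves)
}
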