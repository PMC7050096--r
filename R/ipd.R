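# Reconstruction of interval event/censoring counts from digitized
# Kaplan-Meier coordinates plus numbers-at-risk, and interval-censored
# parametric fitting to the reconstructed counts.

#' Digitized Kaplan-Meier curve
#'
#' A set of (time, survival probability) coordinates read off a published
#' Kaplan-Meier plot. Probabilities that increase slightly with time (a
#' common digitization artifact) are clipped to a monotone non-increasing
#' sequence with a warning.
#'
#' @param times Ascending vector of times in months, first entry >= 0.
#' @param probs Survival probabilities in \[0, 1\] at `times`.
#' @return A `digitized_curve` object (data.frame with columns `time`,
#'   `surv`).
#' @export
digitized_curve <- function(times, probs) {
  if (length(times) != length(probs) || length(times) < 2L)
    stop("'times' and 'probs' must be equal-length with >= 2 points", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE)) stop("'times' must be strictly ascending", call. = FALSE)
  if (times[1] < 0) stop("times must be >= 0", call. = FALSE)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (is.unsorted(rev(probs))) {
    # isotonic clip: running minimum
    probs <- cummin(probs)
    warning("digitized probabilities were not monotone; clipped to a non-increasing sequence")
  }
  structure(data.frame(time = as.numeric(times), surv = as.numeric(probs)),
            class = c("digitized_curve", "data.frame"))
}

#' Numbers-at-risk table
#'
#' @param times Ascending vector of times in months.
#' @param n_at_risk Non-increasing, non-negative counts at risk at `times`;
#'   the first entry is the arm size.
#' @return An `at_risk_table` object (data.frame with columns `time`, `n`).
#' @export
at_risk_table <- function(times, n_at_risk) {
  if (length(times) != length(n_at_risk) || length(times) < 2L)
    stop("'times' and 'n_at_risk' must be equal-length with >= 2 points", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE)) stop("'times' must be strictly ascending", call. = FALSE)
  if (any(n_at_risk < 0)) stop("at-risk counts must be >= 0", call. = FALSE)
  if (is.unsorted(rev(n_at_risk))) stop("at-risk counts must be non-increasing", call. = FALSE)
  if (n_at_risk[1] <= 0) stop("arm size (first at-risk entry) must be > 0", call. = FALSE)
  structure(data.frame(time = as.numeric(times), n = as.numeric(n_at_risk)),
            class = c("at_risk_table", "data.frame"))
}

#' Read/write digitized curves and at-risk tables as CSV
#'
#' Two-column delimited text: `time,surv` for curves and `time,n` for
#' at-risk tables.
#' @param path File path.
#' @param x Object to write.
#' @return The parsed object, or (for writers) `path` invisibly.
#' @export
read_digitized_curve <- function(path) {
  d <- utils::read.csv(path)
  digitized_curve(d[[1]], d[[2]])
}

#' @rdname read_digitized_curve
#' @export
read_at_risk_table <- function(path) {
  d <- utils::read.csv(path)
  at_risk_table(d[[1]], d[[2]])
}

#' @rdname read_digitized_curve
#' @export
write_digitized_curve <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_digitized_curve
#' @export
write_at_risk_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Reconstruct interval event and censoring counts from a digitized curve
#'
#' Implements the interval-count reconstruction underlying pseudo-IPD
#' methods: within each at-risk interval, total censoring is assumed
#' uniform over the digitized sub-intervals and chosen so that the implied
#' number at risk matches the published at-risk table at the interval end,
#' while event counts are chosen so the implied Kaplan-Meier product
#' matches the digitized survival probabilities at every sub-interval
#' boundary. Counts are fractional (no rounding) and the procedure is
#' deterministic.
#'
#' @param curve A [digitized_curve].
#' @param at_risk An [at_risk_table] whose times align with (a subset of)
#'   the curve times; curve times are augmented with the at-risk times if
#'   needed (survival linearly interpolated).
#' @return A data.frame of class `interval_counts` with columns
#'   `start`, `end` (months), `n_enter`, `events`, `censored` (fractional
#'   counts). Attributes: `n0` (arm size), `n_tail` (subjects still at
#'   risk at the end of follow-up, administratively censored at `t_end`),
#'   so that `sum(events) + sum(censored) + n_tail == n0`.
#' @export
reconstruct_interval_counts <- function(curve, at_risk) {
  stopifnot(inherits(curve, "digitized_curve"), inherits(at_risk, "at_risk_table"))
  tt <- curve$time; ss <- curve$surv
  # ensure the grid contains every at-risk time (linear interpolation)
  extra <- setdiff(at_risk$time, tt)
  extra <- extra[extra <= max(tt) & extra >= min(tt)]
  if (length(extra)) {
    si <- stats::approx(tt, ss, xout = extra)$y
    o <- order(c(tt, extra))
    ss <- c(ss, si)[o]; tt <- c(tt, extra)[o]
  }
  if (tt[1] > 0) { tt <- c(0, tt); ss <- c(1, ss) }

  ar_t <- at_risk$time; ar_n <- at_risk$n
  if (ar_t[1] > min(tt)) { ar_t <- c(min(tt), ar_t); ar_n <- c(ar_n[1], ar_n) }
  # close the final interval at the last digitized time; everyone still at
  # risk there is treated as administratively censored at that time
  if (max(ar_t) < max(tt)) { ar_t <- c(ar_t, max(tt)); ar_n <- c(ar_n, 0) }

  out <- list(); n_enter <- ar_n[1]
  for (j in seq_len(length(ar_t) - 1L)) {
    lo <- ar_t[j]; hi <- ar_t[j + 1L]
    idx <- which(tt >= lo & tt <= hi)
    if (length(idx) < 2L) next
    st <- tt[idx]; sv <- ss[idx]
    m <- length(st) - 1L
    r <- ifelse(sv[-length(sv)] > 0, sv[-1] / pmax(sv[-length(sv)], .Machine$double.eps), 1)
    r <- pmin(r, 1)
    w <- diff(st); w <- if (sum(w) > 0) w / sum(w) else rep(1 / m, m)
    # censor c*w_k at the END of sub-interval k (after events), so the KM
    # product from the counts telescopes to the digitized ratios exactly.
    # n_exit = n_enter * prod(r) - c * sum_k w_k * prod_{l>k} r_l
    tailprod <- rev(cumprod(c(1, rev(r)))[seq_len(m)])  # prod_{l>k} r_l
    R <- prod(r)
    n_target <- ar_n[j + 1L]
    denom <- sum(w * tailprod)
    cc <- if (denom > 0) (n_enter * R - n_target) / denom else 0
    # digitization grids snap the at-risk times between KM steps, which can
    # imply a fraction of a subject of negative censoring; clamp silently
    # below half a subject, warn beyond
    if (cc < -0.5)
      warning("at-risk table implies negative censoring in [", lo, ", ", hi,
              "); clamped to 0")
    cc <- max(cc, 0)
    nk <- n_enter
    for (k in seq_len(m)) {
      ev <- nk * (1 - r[k])
      cs <- cc * w[k]
      out[[length(out) + 1L]] <- data.frame(start = st[k], end = st[k + 1L],
                                            n_enter = nk, events = ev, censored = cs)
      nk <- nk * r[k] - cs
      nk <- max(nk, 0)
    }
    n_enter <- nk
  }
  res <- do.call(rbind, out)
  # anyone still at risk when follow-up ends is administratively censored
  # there; kept out of the interval rows but carried for the likelihood
  # and the conservation identity events + censored + tail = n0
  attr(res, "n0") <- ar_n[1]
  attr(res, "n_tail") <- n_enter
  attr(res, "t_end") <- max(tt)
  class(res) <- c("interval_counts", "data.frame")
  res
}

#' Kaplan-Meier survival implied by reconstructed interval counts
#'
#' Product-limit survival at interval boundaries, the self-consistency
#' oracle for [reconstruct_interval_counts()].
#' @param counts An `interval_counts` data.frame.
#' @return data.frame with columns `time`, `surv`.
#' @export
km_from_counts <- function(counts) {
  f <- 1 - counts$events / pmax(counts$n_enter, .Machine$double.eps)
  data.frame(time = c(counts$start[1], counts$end),
             surv = c(1, cumprod(f)) * 1)
}

# negative log-likelihood of interval counts under a parametric family;
# events contribute the interval probability mass, censorings S(t) at the
# interval end (censoring placed after events within the sub-interval),
# and end-of-follow-up survivors S(t_end).
negll_counts <- function(par, counts, family) {
  d <- surv_dist(family, exp(par[1]), exp(par[2]))
  s_lo <- survival_at(d, counts$start)
  s_hi <- survival_at(d, counts$end)
  mass <- pmax(s_lo - s_hi, 1e-300)
  s_c <- pmax(s_hi, 1e-300)
  ll <- sum(counts$events * log(mass)) + sum(counts$censored * log(s_c))
  n_tail <- attr(counts, "n_tail")
  if (!is.null(n_tail) && n_tail > 0)
    ll <- ll + n_tail * log(max(survival_at(d, attr(counts, "t_end")), 1e-300))
  -ll
}

#' Fit a parametric survival model to reconstructed interval counts
#'
#' Maximizes the interval-censored likelihood in which each event
#' contributes the probability mass of its sub-interval,
#' \eqn{S(t_k) - S(t_{k+1})}, and each censored subject contributes
#' \eqn{S(t_{k+1})}. Fractional counts act as case weights.
#'
#' @param counts An `interval_counts` data.frame from
#'   [reconstruct_interval_counts()].
#' @param family `"weibull"` or `"loglogistic"`.
#' @param curve Optional [digitized_curve] used to report the r-squared of
#'   predicted vs digitized survival probabilities.
#' @return An object of class `parsurv_fit`: the fitted [surv_dist] plus
#'   `loglik`, `r2` (if `curve` given), `convergence` and the optimizer
#'   trace. Methods: [coef.parsurv_fit()], [predict.parsurv_fit()], print.
#' @export
fit_parametric <- function(counts, family = c("weibull", "loglogistic"),
                           curve = NULL) {
  family <- match.arg(family)
  if (sum(counts$events) <= 0 || nrow(counts) < 2L)
    stop("need at least two intervals with events to fit", call. = FALSE)
  # moment-flavoured start: scale near the KM median, shape 1
  km <- km_from_counts(counts)
  med <- km$time[which(km$surv <= 0.5)[1]]
  if (is.na(med)) med <- max(km$time)
  start <- c(log(1), log(max(med, 1e-3)))
  opt <- stats::optim(start, negll_counts, counts = counts, family = family,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  if (opt$convergence != 0)
    stop("parametric fit did not converge (optim code ", opt$convergence,
         "); value = ", signif(opt$value, 6), call. = FALSE)
  dist <- surv_dist(family, exp(opt$par[1]), exp(opt$par[2]))
  r2 <- if (!is.null(curve))
    goodness_of_fit_r2(survival_at(dist, curve$time), curve$surv) else NA_real_
  structure(list(dist = dist, family = family, loglik = -opt$value,
                 r2 = as.numeric(r2), convergence = opt$convergence,
                 counts = counts, optim = opt),
            class = "parsurv_fit")
}

#' @export
print.parsurv_fit <- function(x, ...) {
  cat("Interval-censored parametric survival fit\n")
  print(x$dist)
  cat(sprintf("  log-likelihood: %.3f", x$loglik))
  if (!is.na(x$r2)) cat(sprintf("   r2 vs digitized curve: %.4f", x$r2))
  cat("\n")
  invisible(x)
}

#' @export
coef.parsurv_fit <- function(object, ...) {
  c(shape = object$dist$shape, scale = object$dist$scale)
}

#' Predicted survival probabilities from a fitted parametric model
#' @param object A `parsurv_fit`.
#' @param times Times in months.
#' @param ... Unused.
#' @export
predict.parsurv_fit <- function(object, times, ...) survival_at(object$dist, times)

# highest r2 wins; exact ties break toward weibull, then input order
pick_family <- function(r2) {
  families <- names(r2)
  families[order(-r2, families != "weibull", seq_along(families))][1]
}

#' Select the best-fitting parametric family by r-squared
#'
#' Fits each candidate family to the reconstructed counts and returns the
#' one with the highest r-squared against the digitized probabilities.
#' Ties are broken toward Weibull (then by candidate order).
#'
#' @param counts Reconstructed `interval_counts`.
#' @param curve The [digitized_curve] the r-squared is computed against.
#' @param families Candidate families.
#' @return A list: `family` (the winner), `fit` (its `parsurv_fit`),
#'   `r2` (named vector over all candidates), `fits` (all fits).
#' @export
select_best_family <- function(counts, curve,
                               families = c("weibull", "loglogistic")) {
  if (length(families) < 1L) stop("need at least one candidate family", call. = FALSE)
  families <- unique(match.arg(families, c("weibull", "loglogistic"),
                               several.ok = TRUE))
  fits <- lapply(families, function(f) fit_parametric(counts, f, curve = curve))
  names(fits) <- families
  r2 <- vapply(fits, function(f) f$r2, numeric(1))
  best <- pick_family(r2)
  list(family = best, fit = fits[[best]], r2 = r2, fits = fits)
}
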