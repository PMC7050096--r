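# Synthetic two-arm trial generator: subject-level PFS/OS times with
# known ground truth, plus digitized-curve and at-risk exports that feed
# the reconstruction pipeline.

q_surv <- function(dist, u) {
  # quantile of the event-time distribution: t with S(t) = 1 - u
  s <- 1 - u
  switch(dist$family,
         weibull     = dist$scale * (-log(s))^(1 / dist$shape),
         loglogistic = dist$scale * ((1 - s) / s)^(1 / dist$shape))
}

#' Specification of a synthetic survival trial arm
#'
#' @param os,pfs [surv_dist] objects for the arm's OS and PFS. The OS
#'   curve must lie (weakly) above the PFS curve; this is checked on a
#'   grid.
#' @param n Subjects in the arm.
#' @param enrolment_months Uniform enrolment window (months).
#' @param admin_censor_months Administrative data cut measured from the
#'   start of enrolment; each subject's follow-up is this minus their
#'   entry time.
#' @param censor_prob Probability that a subject is independently
#'   censored, with the censoring time uniform on (0, follow-up).
#' @return A `trial_sim_spec` object.
#' @export
trial_sim_spec <- function(os, pfs, n, enrolment_months = 12,
                           admin_censor_months = 30, censor_prob = 0.1) {
  os <- as_surv_dist(os); pfs <- as_surv_dist(pfs)
  stopifnot(n >= 1, enrolment_months >= 0, admin_censor_months > 0,
            censor_prob >= 0, censor_prob <= 1)
  grid <- seq(0.01, admin_censor_months * 2, length.out = 200)
  if (any(survival_at(os, grid) < survival_at(pfs, grid) - 1e-9))
    stop("OS curve must dominate the PFS curve (S_OS >= S_PFS)", call. = FALSE)
  structure(list(os = os, pfs = pfs, n = as.integer(n),
                 enrolment_months = enrolment_months,
                 admin_censor_months = admin_censor_months,
                 censor_prob = censor_prob),
            class = "trial_sim_spec")
}

#' Simulate subject-level PFS and OS times for one arm
#'
#' Event times for PFS and OS are coupled comonotonically (one shared
#' uniform through each marginal's quantile function), which preserves
#' both marginal distributions exactly and guarantees PFS <= OS per
#' subject whenever the OS curve dominates the PFS curve. Administrative
#' censoring reflects a uniform enrolment window and a fixed data cut;
#' additional independent censoring hits each subject with probability
#' `censor_prob` at a time uniform on (0, follow-up).
#'
#' @param spec A [trial_sim_spec()].
#' @param seed Integer seed.
#' @return data.frame with one row per subject: `pfs_time`, `pfs_event`,
#'   `os_time`, `os_event` (times in months, event = 1 observed,
#'   0 censored).
#' @export
simulate_trial <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "trial_sim_spec"))
  set.seed(seed)
  n <- spec$n
  u <- stats::runif(n)
  t_pfs <- q_surv(spec$pfs, u)
  t_os <- pmax(q_surv(spec$os, u), t_pfs)
  entry <- stats::runif(n, 0, spec$enrolment_months)
  fup <- pmax(spec$admin_censor_months - entry, 0.001)
  cens <- fup
  hit <- stats::runif(n) < spec$censor_prob
  cens[hit] <- stats::runif(sum(hit), 0, fup[hit])
  data.frame(
    pfs_time = pmin(t_pfs, cens), pfs_event = as.integer(t_pfs <= cens),
    os_time = pmin(t_os, cens), os_event = as.integer(t_os <= cens))
}

#' Export a digitized Kaplan-Meier curve and at-risk table
#'
#' Computes the Kaplan-Meier estimate from subject-level times (via the
#' survival package), reads it off on a grid of `k` points — emulating
#' manual digitization of a published figure — and tabulates numbers at
#' risk at the requested times. Optional uniform jitter stress-tests the
#' reconstruction.
#'
#' @param time,event Subject-level times and event indicators.
#' @param k Number of digitized grid points (>= 5), evenly spaced from 0
#'   to the last observed time.
#' @param at_risk_times Times for the at-risk table (default: 6 points
#'   taken from the digitized grid itself, including 0 but excluding the
#'   final follow-up instant, as published at-risk rows align with axis
#'   ticks and the risk set at the very last event time is ambiguous —
#'   the count there includes the subjects failing at that instant,
#'   which the survival probability has already removed).
#' @param jitter Half-width of uniform noise added to the digitized
#'   probabilities (default 0); the result is re-monotonized.
#' @param seed Seed for the jitter.
#' @return List with `curve` ([digitized_curve]) and `at_risk`
#'   ([at_risk_table]).
#' @export
export_digitized <- function(time, event, k = 30, at_risk_times = NULL,
                             jitter = 0, seed = 1) {
  stopifnot(k >= 5)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  tmax <- max(time)
  grid <- seq(0, tmax, length.out = k)
  sm <- summary(fit, times = grid, extend = TRUE)
  probs <- sm$surv
  if (jitter > 0) {
    set.seed(seed)
    probs <- pmin(pmax(probs + stats::runif(k, -jitter, jitter), 0), 1)
    probs[1] <- 1
    probs <- cummin(probs)
  }
  if (is.null(at_risk_times))
    at_risk_times <- grid[unique(round(seq(1, k - 1, length.out = 6)))]
  smr <- summary(fit, times = at_risk_times, extend = TRUE)
  list(curve = suppressWarnings(digitized_curve(grid, probs)),
       at_risk = at_risk_table(at_risk_times, smr$n.risk))
}
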