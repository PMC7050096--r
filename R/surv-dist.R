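# Parametric survival distributions driving all state-transition
# probabilities in the cohort model.
#
# Parameterization (declared once, used everywhere):
#   Weibull:      S(t) = exp(-(t/scale)^shape)
#   log-logistic: S(t) = 1 / (1 + (t/scale)^shape)
# with shape dimensionless, scale in months.

#' Construct a parametric survival distribution
#'
#' Creates a `surv_dist` object holding the family and parameters of a
#' parametric survival curve. Two families are supported, in the
#' accelerated-failure-time style parameterization: Weibull with
#' \eqn{S(t) = \exp(-(t/\sigma)^k)} and log-logistic with
#' \eqn{S(t) = 1/(1 + (t/\sigma)^k)}, where \eqn{k} is `shape`
#' (dimensionless) and \eqn{\sigma} is `scale` (months).
#'
#' @param family `"weibull"` or `"loglogistic"`.
#' @param shape Positive shape parameter.
#' @param scale Positive scale parameter, in months. For the log-logistic
#'   family the scale equals the median survival time.
#' @return An object of class `surv_dist`.
#' @examples
#' d <- surv_dist("weibull", shape = 1.2, scale = 9)
#' survival_at(d, c(0, 6, 12))
#' median_survival(d)
#' @export
surv_dist <- function(family = c("weibull", "loglogistic"), shape, scale) {
  family <- match.arg(family)
  if (!is.numeric(shape) || length(shape) != 1L || !is.finite(shape) || shape <= 0)
    stop("'shape' must be a single positive number", call. = FALSE)
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0)
    stop("'scale' must be a single positive number", call. = FALSE)
  structure(list(family = family, shape = as.numeric(shape),
                 scale = as.numeric(scale)),
            class = "surv_dist")
}

#' @export
print.surv_dist <- function(x, ...) {
  cat(sprintf("%s survival distribution: shape = %.4g, scale = %.4g months (median %.3g months)\n",
              x$family, x$shape, x$scale, median_survival(x)))
  invisible(x)
}

as_surv_dist <- function(x) {
  if (inherits(x, "surv_dist")) return(x)
  if (is.list(x) && all(c("family", "shape", "scale") %in% names(x)))
    return(surv_dist(x$family, x$shape, x$scale))
  stop("cannot interpret object as a survival distribution", call. = FALSE)
}

#' Survival function of a parametric distribution
#'
#' @param dist A [surv_dist] object.
#' @param t Vector of non-negative times in months.
#' @return S(t), a vector of probabilities in \[0, 1\].
#' @export
survival_at <- function(dist, t) {
  dist <- as_surv_dist(dist)
  if (any(!is.finite(t) & !is.infinite(t)) || any(t < 0))
    stop("'t' must be non-negative", call. = FALSE)
  z <- (t / dist$scale)^dist$shape
  s <- switch(dist$family,
              weibull     = exp(-z),
              loglogistic = 1 / (1 + z))
  # guard against floating spill at t = 0 with shape < 1 etc.
  pmin(pmax(s, 0), 1)
}

#' Median survival time
#'
#' Closed-form median of the survival distribution:
#' \eqn{\sigma (\log 2)^{1/k}} for the Weibull family and \eqn{\sigma}
#' for the log-logistic family.
#'
#' @inheritParams survival_at
#' @return Median time in months; satisfies `survival_at(dist, m) == 0.5`.
#' @export
median_survival <- function(dist) {
  dist <- as_surv_dist(dist)
  switch(dist$family,
         weibull     = dist$scale * log(2)^(1 / dist$shape),
         loglogistic = dist$scale)
}

#' Per-cycle transition probability from a survival curve
#'
#' The conditional probability of leaving the curve's state during cycle
#' `cycle_index` (0-based), i.e. \eqn{1 - S(t+\Delta)/S(t)} with
#' \eqn{t = } `cycle_index` \eqn{\cdot \Delta}. This is the time-varying
#' transition probability used by the Markov engine; when the curve has
#' reached zero the state absorbs (probability 1).
#'
#' @inheritParams survival_at
#' @param cycle_index Non-negative integer cycle index (0-based), vectorized.
#' @param cycle_length Cycle length \eqn{\Delta} in months (default one
#'   3-week cycle, see [cycle_length_months()]).
#' @return Transition probabilities in \[0, 1\].
#' @export
per_cycle_transition <- function(dist, cycle_index, cycle_length = cycle_length_months()) {
  dist <- as_surv_dist(dist)
  if (cycle_length <= 0) stop("'cycle_length' must be positive", call. = FALSE)
  if (any(cycle_index < 0)) stop("'cycle_index' must be >= 0", call. = FALSE)
  t0 <- cycle_index * cycle_length
  s0 <- survival_at(dist, t0)
  s1 <- survival_at(dist, t0 + cycle_length)
  p <- ifelse(s0 <= 0, 1, 1 - s1 / s0)
  pmin(pmax(p, 0), 1)
}

#' Length of one model cycle in months
#'
#' All regimens are administered every 3 weeks, so the model cycle is
#' 3 weeks; months are defined as the mean Gregorian month of
#' 30.4375 days, giving 21/30.4375 = 0.6899... months per cycle.
#' @return Cycle length in months.
#' @export
cycle_length_months <- function() 21 / 30.4375

#' R-squared goodness of fit between predicted and observed survival
#'
#' Coefficient of determination \eqn{1 - SS_{res}/SS_{tot}} of predicted
#' survival probabilities against observed (digitized) ones, the statistic
#' used to validate parametric fits against trial curves.
#'
#' @param predicted,observed Equal-length numeric vectors of survival
#'   probabilities.
#' @return A number \eqn{\le 1}. If the observed values have zero variance
#'   the result is `NA` with attribute `degenerate = TRUE` (and 1 when the
#'   prediction is also exact).
#' @export
goodness_of_fit_r2 <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(observed) == 0L)
    stop("'predicted' and 'observed' must be equal-length, non-empty", call. = FALSE)
  ss_res <- sum((observed - predicted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    r2 <- if (ss_res == 0) 1 else NA_real_
    attr(r2, "degenerate") <- TRUE
    return(r2)
  }
  1 - ss_res / ss_tot
}
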