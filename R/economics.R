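# Incremental cost-effectiveness: pairwise ICERs, strict and extended
# dominance, the efficiency frontier, and net monetary benefit.

#' Incremental cost-effectiveness ratio between two strategies
#'
#' @param reference,alternative Lists/rows with `cost` and `qaly`.
#' @return List with `delta_cost`, `delta_qaly`, and either a numeric
#'   `icer` or a `label` among `"equivalent"`,
#'   `"alternative dominates"` (cheaper and at least as effective, or
#'   equally costly and more effective), `"reference dominates"`.
#' @export
icer <- function(reference, alternative) {
  dc <- alternative$cost - reference$cost
  dq <- alternative$qaly - reference$qaly
  out <- list(delta_cost = dc, delta_qaly = dq, icer = NA_real_, label = NA_character_)
  if (dc == 0 && dq == 0) {
    out$label <- "equivalent"
  } else if (dq >= 0 && dc <= 0) {
    out$label <- "alternative dominates"
  } else if (dq <= 0 && dc >= 0) {
    out$label <- "reference dominates"
  } else {
    out$icer <- dc / dq  # NE or SW quadrant: a meaningful ratio
  }
  out
}

#' Net monetary benefit
#'
#' \eqn{\mathrm{NMB} = \lambda \cdot \mathrm{QALY} - \mathrm{cost}} at
#' willingness-to-pay \eqn{\lambda}.
#' @param result List/row with `cost` and `qaly`.
#' @param wtp Willingness-to-pay threshold in USD/QALY (>= 0), vectorized.
#' @return NMB in USD.
#' @export
net_monetary_benefit <- function(result, wtp) {
  if (any(wtp < 0)) stop("'wtp' must be >= 0", call. = FALSE)
  wtp * result$qaly - result$cost
}

#' Incremental cost-effectiveness frontier
#'
#' Sorts strategies by cost, flags strictly dominated strategies (another
#' strategy is no more costly and no less effective, and better on at
#' least one dimension), removes extendedly (weakly) dominated ones
#' (sequential ICER exceeding that of the next more effective frontier
#' step; equal ICERs are retained), and reports the sequential ICER along
#' the frontier. Duplicate cost/QALY pairs keep the first occurrence.
#'
#' @param results data.frame with columns `strategy`, `cost`, `qaly`.
#' @return data.frame of class `icer_table`: one row per strategy with
#'   `comparator` (previous frontier strategy), `delta_cost`, `delta_qaly`,
#'   `icer`, and `status` in `frontier` / `dominated` /
#'   `extendedly_dominated`.
#' @export
incremental_frontier <- function(results) {
  stopifnot(all(c("strategy", "cost", "qaly") %in% names(results)))
  if (nrow(results) < 2L) stop("need at least two strategies", call. = FALSE)
  res <- results[order(results$cost, -results$qaly), ]
  dup <- duplicated(res[, c("cost", "qaly")])
  if (any(dup)) {
    message("dropping duplicate strategies: ",
            paste(res$strategy[dup], collapse = ", "))
    res <- res[!dup, ]
  }
  n <- nrow(res)
  status <- rep("frontier", n)
  # strict dominance
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    dom <- any(res$cost[others] <= res$cost[i] & res$qaly[others] >= res$qaly[i] &
                 (res$cost[others] < res$cost[i] | res$qaly[others] > res$qaly[i]))
    if (dom) status[i] <- "dominated"
  }
  # extended dominance on the survivors
  repeat {
    idx <- which(status == "frontier")
    if (length(idx) < 3L) break
    ic <- diff(res$cost[idx]) / diff(res$qaly[idx])
    bad <- which(ic[-length(ic)] > ic[-1])  # strictly greater than next step
    if (!length(bad)) break
    status[idx[bad[1] + 1L]] <- "extendedly_dominated"
  }
  idx <- which(status == "frontier")
  comparator <- rep(NA_character_, n); dc <- dq <- ic <- rep(NA_real_, n)
  if (length(idx) > 1L) {
    for (j in 2:length(idx)) {
      i <- idx[j]; p <- idx[j - 1L]
      comparator[i] <- res$strategy[p]
      dc[i] <- res$cost[i] - res$cost[p]
      dq[i] <- res$qaly[i] - res$qaly[p]
      ic[i] <- if (dq[i] != 0) dc[i] / dq[i] else NA_real_
    }
  }
  out <- data.frame(strategy = res$strategy, cost = res$cost, qaly = res$qaly,
                    comparator = comparator, delta_cost = dc, delta_qaly = dq,
                    icer = ic, status = status, stringsAsFactors = FALSE)
  class(out) <- c("icer_table", "data.frame")
  out
}

#' Pairwise incremental rows against named comparators
#'
#' The publication-style presentation: each strategy compared with a fixed
#' reference (and optionally with a second comparator), reporting
#' incremental cost, incremental QALYs, and either the ICER or a dominance
#' label (`"Dominated"` when the alternative is cheaper and more
#' effective than the comparator it is compared against, i.e. the
#' comparator row is dominated).
#'
#' @param results data.frame with `strategy`, `cost`, `qaly`.
#' @param reference Name of the reference strategy (e.g. chemotherapy).
#' @param also_vs Optional further comparator names (e.g. the
#'   combination-for-all strategy).
#' @return data.frame with one row per (strategy, comparator) pair.
#' @export
pairwise_rows <- function(results, reference, also_vs = character(0)) {
  get <- function(nm) {
    i <- match(nm, results$strategy)
    if (is.na(i)) stop("strategy '", nm, "' not found", call. = FALSE)
    results[i, ]
  }
  rows <- list()
  for (nm in setdiff(results$strategy, reference)) {
    for (cmp in c(reference, setdiff(also_vs, nm))) {
      if (cmp == nm) next
      r <- icer(get(cmp), get(nm))
      # publication convention: "Dominated" in the ICER cell means the
      # comparator is dominated by the listed strategy
      lab <- if (!is.na(r$label)) {
        switch(r$label,
               "alternative dominates" = "Dominated",
               "reference dominates"   = "Dominated (strategy)",
               r$label)
      } else NA_character_
      rows[[length(rows) + 1L]] <-
        data.frame(strategy = nm, comparator = cmp,
                   delta_cost = r$delta_cost, delta_qaly = r$delta_qaly,
                   icer = r$icer, label = lab, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' @export
print.icer_table <- function(x, digits = 1, ...) {
  y <- as.data.frame(x)
  y$cost <- round(y$cost); y$delta_cost <- round(y$delta_cost)
  y$qaly <- round(y$qaly, 3); y$delta_qaly <- round(y$delta_qaly, 3)
  y$icer <- round(y$icer)
  print(y, row.names = FALSE)
  invisible(x)
}
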