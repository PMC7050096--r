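# Price-reduction scenario runner.

#' Define a price scenario
#'
#' @param name Scenario label.
#' @param multipliers Named vector of positive price multipliers keyed by
#'   drug (e.g. `c(pembrolizumab = 0.6)` for a 40\% price cut). An empty
#'   vector is the base case.
#' @return A `scenario` object.
#' @export
scenario <- function(name, multipliers = numeric(0)) {
  if (length(multipliers) && any(multipliers <= 0))
    stop("price multipliers must be > 0", call. = FALSE)
  structure(list(name = name, multipliers = multipliers), class = "scenario")
}

#' Default price-reduction scenarios for a country
#'
#' United States: pembrolizumab reduced by 15\% and by 40\%. China:
#' pembrolizumab reduced by 50\% (the donation program still applies on
#' top unless disabled in the inputs).
#' @param country `"US"` or `"CN"`.
#' @return List of [scenario()] objects, the base case first.
#' @export
default_scenarios <- function(country = c("US", "CN")) {
  country <- match.arg(country)
  base <- scenario("base case")
  if (country == "US")
    list(base,
         scenario("pembrolizumab -15%", c(pembrolizumab = 0.85)),
         scenario("pembrolizumab -40%", c(pembrolizumab = 0.60)))
  else
    list(base,
         scenario("pembrolizumab -50%", c(pembrolizumab = 0.50)))
}

#' Run strategy evaluation and frontier analysis across price scenarios
#'
#' @param specs List of [strategy_spec()] objects.
#' @param curves Curve set (see [example_curves()]).
#' @param inputs An `econ_inputs` object.
#' @param scenarios List of [scenario()] objects; the all-multipliers-1
#'   base case is included by default via [default_scenarios()].
#' @param horizon_years Model horizon.
#' @return Named list (by scenario) of lists with `results` (strategy
#'   means), `frontier` ([incremental_frontier()] table) and `pairwise`
#'   ([pairwise_rows()] vs the first strategy).
#' @export
run_scenarios <- function(specs, curves, inputs,
                          scenarios = default_scenarios(inputs$country),
                          horizon_years = 20) {
  out <- lapply(scenarios, function(sc) {
    res <- evaluate_strategies(specs, curves, inputs,
                               scenario = sc$multipliers,
                               horizon_years = horizon_years)
    list(scenario = sc$name,
         results = res,
         frontier = incremental_frontier(res),
         pairwise = pairwise_rows(res, reference = res$strategy[1]))
  })
  names(out) <- vapply(scenarios, `[[`, character(1), "name")
  out
}
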