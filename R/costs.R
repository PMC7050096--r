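# Per-cycle, per-state treatment cost schedules: drug acquisition with
# body-size dosing, induction/maintenance regimens, the Chinese
# pembrolizumab donation program, adverse-event management, monitoring,
# and post-progression therapy.

#' Dosing rule for a drug
#'
#' @param basis One of `"flat_mg"` (fixed mg per administration),
#'   `"per_m2"` (mg per m2 body surface area), `"per_kg"` (mg per kg),
#'   `"fixed_dose"` (pre-computed total mg, e.g. carboplatin from the
#'   Calvert formula).
#' @param dose Positive dose in the basis unit.
#' @param max_cycles Optional cap on the number of treatment cycles.
#' @return A `dosing_rule` object.
#' @export
dosing_rule <- function(basis = c("flat_mg", "per_m2", "per_kg", "fixed_dose"),
                        dose, max_cycles = NULL) {
  basis <- match.arg(basis)
  if (!is.numeric(dose) || dose <= 0) stop("'dose' must be > 0", call. = FALSE)
  structure(list(basis = basis, dose = dose, max_cycles = max_cycles),
            class = "dosing_rule")
}

#' Drug acquisition cost for one cycle
#'
#' @param rule A [dosing_rule].
#' @param body List with `bsa_m2` and `weight_kg`.
#' @param unit_price Price in USD per mg.
#' @return Cost in USD for one administration.
#' @examples
#' # docetaxel 75 mg/m2 at $1.345/mg, BSA 1.84 m2 -> $185.6 per cycle
#' drug_cycle_cost(dosing_rule("per_m2", 75), list(bsa_m2 = 1.84, weight_kg = 71.4), 1.345)
#' @export
drug_cycle_cost <- function(rule, body, unit_price) {
  stopifnot(inherits(rule, "dosing_rule"))
  mg <- switch(rule$basis,
               flat_mg    = rule$dose,
               fixed_dose = rule$dose,
               per_m2     = rule$dose * body$bsa_m2,
               per_kg     = rule$dose * body$weight_kg)
  mg * unit_price
}

#' Payable fraction under the Chinese pembrolizumab donation program
#'
#' Eligible Chinese patients pay for five cycles, receive five donated
#' cycles, then alternate three paid with three donated cycles until 24
#' months or progression. Returns 1 (payable) or 0 (donated) for a 1-based
#' treatment cycle index; the 35-cycle treatment cap is enforced by the
#' cost schedule, not here.
#'
#' @param cycle_index 1-based treatment cycle (vectorized).
#' @return 0/1 vector.
#' @export
payable_fraction_cn <- function(cycle_index) {
  if (any(cycle_index < 1)) stop("'cycle_index' must be >= 1", call. = FALSE)
  k <- as.integer(cycle_index)
  out <- integer(length(k))
  out[k <= 5] <- 1L
  out[k > 5 & k <= 10] <- 0L
  late <- k > 10
  # alternating 3 payable / 3 donated blocks: 11-13 paid, 14-16 donated, ...
  out[late] <- ifelse(((k[late] - 11L) %/% 3L) %% 2L == 0L, 1L, 0L)
  out
}

scenario_mult <- function(scenario, drug) {
  if (is.null(scenario) || length(scenario) == 0) return(1)
  if (!is.null(names(scenario)) && !all(names(scenario) %in%
      c("pembrolizumab", "pemetrexed", "carboplatin", "cisplatin",
        "nivolumab", "docetaxel")))
    stop("unknown drug key in scenario: ",
         paste(setdiff(names(scenario),
                       c("pembrolizumab", "pemetrexed", "carboplatin",
                         "cisplatin", "nivolumab", "docetaxel")), collapse = ", "),
         call. = FALSE)
  if (drug %in% names(scenario)) scenario[[drug]] else 1
}

#' Per-cycle cost of one treatment arm in one health state
#'
#' Progression-free cycles: induction (cycles 1 to 4) accrues pemetrexed
#' plus platinum (carboplatin/cisplatin mixture), pembrolizumab in the
#' combination arm, monitoring, optional premedication, and the
#' incidence-weighted expected adverse-event management cost spread
#' uniformly over the induction cycles. Maintenance (cycle 5 on) accrues
#' pemetrexed (both arms), pembrolizumab up to the 35-cycle cap
#' (combination arm), monitoring and premedication. In China the
#' pembrolizumab acquisition cost is multiplied by
#' [payable_fraction_cn()]. Progressed-disease cycles: the
#' subsequent-therapy proportion times the per-cycle cost of the arm's
#' subsequent-therapy mixture (checkpoint-inhibitor components capped at
#' `subsequent_max_cycles` model cycles), the remainder on supportive
#' care. Death costs nothing.
#'
#' @param arm `"chemo"` or `"combo"`.
#' @param cycle_index 1-based model/treatment cycle (vectorized).
#' @param state `"pfs"`, `"pd"` or `"death"`.
#' @param inputs An `econ_inputs` object.
#' @param scenario Optional named vector of price multipliers keyed by drug
#'   name (e.g. `c(pembrolizumab = 0.6)`), applied to acquisition prices
#'   and to the matching subsequent-therapy cost rows.
#' @return Cost in USD (vectorized over `cycle_index`).
#' @export
arm_cycle_cost <- function(arm = c("chemo", "combo"), cycle_index,
                           state = c("pfs", "pd", "death"), inputs,
                           scenario = NULL) {
  arm <- match.arg(arm); state <- match.arg(state)
  if (any(cycle_index < 1)) stop("'cycle_index' must be >= 1", call. = FALSE)
  k <- as.numeric(cycle_index)
  if (state == "death") return(rep(0, length(k)))
  body <- inputs$body
  price <- function(drug) inputs$price_per_mg[[drug]]$value * scenario_mult(scenario, drug)

  if (state == "pfs") {
    n_ind <- inputs$induction_cycles
    pem_cost <- drug_cycle_cost(dosing_rule("per_m2", 500), body, price("pemetrexed"))
    plat_cost <-
      inputs$platinum_mix[["carboplatin"]] *
        drug_cycle_cost(dosing_rule("fixed_dose", inputs$carboplatin_dose_mg),
                        body, price("carboplatin")) +
      inputs$platinum_mix[["cisplatin"]] *
        drug_cycle_cost(dosing_rule("per_m2", 75), body, price("cisplatin"))
    pembro_cost <- drug_cycle_cost(dosing_rule("flat_mg", 200), body,
                                   price("pembrolizumab"))
    ae_inc <- inputs$ae_incidence[[arm]]
    ae_expected <- sum(ae_inc * vapply(names(ae_inc),
                                       function(a) inputs$ae_cost[[a]]$value,
                                       numeric(1))) / n_ind
    induction <- k <= n_ind
    cost <- numeric(length(k))
    cost <- cost + pem_cost                                   # all PFS cycles
    cost[induction] <- cost[induction] + plat_cost + ae_expected
    if (arm == "combo") {
      payable <- if (isTRUE(inputs$donation_program)) payable_fraction_cn(k) else 1
      on_pembro <- k <= inputs$pembrolizumab_max_cycles
      cost <- cost + pembro_cost * payable * on_pembro
    }
    cost <- cost + inputs$monitoring_cost$value + inputs$premedication_cost_per_cycle
    return(cost)
  }

  # progressed disease
  p_sub <- inputs$prop_subsequent[[arm]]$value
  mix <- inputs$subsequent_mix[[arm]]
  sup <- inputs$supportive_cost$value
  sub_cost_k <- vapply(k, function(kk) {
    per_drug <- vapply(names(mix), function(d) {
      active <- kk <= inputs$subsequent_max_cycles[[d]]
      if (active)
        inputs$subsequent_cost[[d]]$value * scenario_mult(scenario, d)
      else sup  # past the cap those patients fall back to supportive care
    }, numeric(1))
    sum(mix * per_drug)
  }, numeric(1))
  p_sub * sub_cost_k + (1 - p_sub) * sup
}

#' Full per-cycle cost schedule for an arm
#'
#' Convenience wrapper returning the `pfs` and `pd` cost vectors for
#' `n_cycles` model cycles, in the form [accrue_outcomes()] consumes.
#'
#' @inheritParams arm_cycle_cost
#' @param n_cycles Number of model cycles.
#' @return List with numeric vectors `pfs` and `pd` of length `n_cycles`.
#' @export
arm_cost_schedule <- function(arm, n_cycles, inputs, scenario = NULL) {
  k <- seq_len(n_cycles)
  list(pfs = arm_cycle_cost(arm, k, "pfs", inputs, scenario),
       pd  = arm_cycle_cost(arm, k, "pd", inputs, scenario))
}
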