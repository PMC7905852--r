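# Incremental analysis: ICER, net monetary benefit, threshold policy,
# acceptability curve, deterministic cost sensitivity.

#' Incremental cost-effectiveness ratio
#'
#' @param delta_cost Incremental cost (USD).
#' @param dalys_averted Incremental effect (DALYs averted).
#' @return `delta_cost / dalys_averted`, vectorised; `NA` (undefined, not an
#'   error) wherever `dalys_averted == 0` so batch callers can keep going.
#' @export
icer <- function(delta_cost, dalys_averted) {
  out <- delta_cost / dalys_averted
  out[dalys_averted == 0] <- NA_real_
  out
}

#' Net monetary benefit
#'
#' @param delta_cost Incremental cost (USD).
#' @param dalys_averted Incremental effect.
#' @param wtp Willingness to pay (USD per DALY averted, >= 0).
#' @return `wtp * dalys_averted - delta_cost`.
#' @export
nmb <- function(delta_cost, dalys_averted, wtp) {
  if (any(wtp < 0)) stop("nmb: willingness-to-pay must be >= 0")
  wtp * dalys_averted - delta_cost
}

#' Willingness-to-pay threshold policy
#'
#' The conservative threshold is a multiple of GDP per capita, rounded to
#' the nearest 10 USD (0.52 x 2,230 = 1,159.6 -> 1,160).
#'
#' @param gdp_pc GDP per capita in USD (default 2,230).
#' @param multiplier Threshold multiplier (default 0.52).
#' @return List with `gdp_pc`, `multiplier`, `threshold`.
#' @export
threshold_policy <- function(gdp_pc = 2230, multiplier = 0.52) {
  list(gdp_pc = gdp_pc, multiplier = multiplier,
       threshold = round(multiplier * gdp_pc / 10) * 10)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA draws with
#' positive net monetary benefit.
#'
#' @param delta_cost,dalys_averted Per-draw incremental cost and effect
#'   (equal length, >= 1 draw).
#' @param wtp_grid Ascending willingness-to-pay grid (non-empty).
#' @return data.frame `(wtp, probability)`; non-decreasing in `wtp` when
#'   every draw's effect is positive.
#' @export
ceac <- function(delta_cost, dalys_averted, wtp_grid) {
  if (!length(wtp_grid)) stop("ceac: empty willingness-to-pay grid")
  if (is.unsorted(wtp_grid)) stop("ceac: wtp_grid must be ascending")
  if (!length(delta_cost)) stop("ceac: need at least one sample")
  stopifnot(length(delta_cost) == length(dalys_averted))
  prob <- vapply(wtp_grid, function(w) {
    mean(nmb(delta_cost, dalys_averted, w) > 0)
  }, numeric(1))
  data.frame(wtp = wtp_grid, probability = prob)
}

#' Deterministic one-way sensitivity of the ICER to the promotion cost
#'
#' Effects are untouched, so the ICER scales exactly linearly in the cost
#' multiplier.
#'
#' @param base A `ce_result` (see [run_base_case()]).
#' @param multipliers Non-negative cost multipliers
#'   (default `c(1.25, 1.5, 1.75, 2, 8)`).
#' @return data.frame `(multiplier, delta_cost, icer)`.
#' @export
one_way_cost_sensitivity <- function(base, multipliers = c(1.25, 1.5, 1.75, 2, 8)) {
  if (any(multipliers < 0)) stop("one_way_cost_sensitivity: multipliers must be >= 0")
  data.frame(multiplier = multipliers,
             delta_cost = base$delta_cost * multipliers,
             icer = icer(base$delta_cost * multipliers, base$dalys_averted))
}

new_ce_result <- function(delta_cost, dalys_averted, deaths_averted,
                          severe_averted, hosp_cost_averted,
                          baseline = NULL, promotion = NULL) {
  structure(list(
    delta_cost = delta_cost, dalys_averted = dalys_averted,
    icer = icer(delta_cost, dalys_averted),
    deaths_averted = deaths_averted, severe_averted = severe_averted,
    hosp_cost_averted = hosp_cost_averted,
    baseline = baseline, promotion = promotion),
    class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat("<ce_result>\n")
  cat(sprintf("  incremental cost     : %s USD\n",
              format(round(x$delta_cost), big.mark = ",")))
  cat(sprintf("  DALYs averted        : %.2f\n", x$dalys_averted))
  cat(sprintf("  ICER                 : %.2f USD/DALY averted\n", x$icer))
  cat(sprintf("  deaths averted       : %.0f\n", x$deaths_averted))
  cat(sprintf("  severe cases averted : %.0f\n", x$severe_averted))
  cat(sprintf("  hosp. cost averted   : %s USD\n",
              format(round(x$hosp_cost_averted), big.mark = ",")))
  invisible(x)
}

#' Deterministic base-case analysis
#'
#' Runs both scenarios at the point estimates: builds the two transition
#' matrices, traces the cohort (40% of the under-5 population, all starting
#' well) over `n_cycles` yearly cycles, accumulates DALYs under the
#' calibrated accounting options, and compares against the one-off
#' promotion budget.
#'
#' @param params A `parameter_set` (default [default_parameters()]).
#' @param ledger A `cost_ledger` (default [default_ledger()]).
#' @param effect An [effect_options()].
#' @param daly A [daly_options()].
#' @return A `ce_result` carrying the two `scenario_outcome`s.
#' @export
run_base_case <- function(params = default_parameters(),
                          ledger = default_ledger(),
                          effect = effect_options(),
                          daly = daly_options()) {
  n_cycles <- unname(params$values["n_cycles"])
  init <- cohort_size(params)
  m0 <- build_transition_matrix(params, "no_promotion", effect)
  m1 <- build_transition_matrix(params, "promotion", effect)
  out0 <- scenario_outcomes(run_cohort(m0, init, n_cycles, effect), params, daly)
  out1 <- scenario_outcomes(run_cohort(m1, init, n_cycles, effect), params, daly)
  av <- averted(out0, out1)
  delta_cost <- total_annual_cost(ledger)
  new_ce_result(
    delta_cost = delta_cost,
    dalys_averted = av$dalys_averted,
    deaths_averted = av$deaths_averted,
    severe_averted = av$severe_averted,
    hosp_cost_averted = hospitalization_cost_averted(
      av$severe_averted, unname(params$values["careseek_facility"]),
      unname(params$values["unit_inpatient_cost"])),
    baseline = out0, promotion = out1)
}
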