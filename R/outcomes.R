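# DALY accounting: years lived with disability, years of life lost, and
# averted quantities between scenarios.

#' DALY accounting options
#'
#' Structural switches resolved by the calibration harness
#' ([calibrate_options()]); defaults are the calibration-selected set.
#'
#' @param yld_occupancy Person-time in a morbid state per cycle:
#'   `"cycle_end"` (end-of-cycle membership, calibrated default) or
#'   `"half_cycle"` (life-table half-cycle corrected person-years).
#' @param discounting Per-cycle discounting of DALY components: `"none"`
#'   (calibrated default), `"midpoint"` or `"end"`.
#' @param yll_mode `"horizon_truncated"` (deaths x remaining in-horizon
#'   years, calibrated default), `"horizon_truncated_discounted"` (remaining
#'   years valued as a discounted annuity), `"full_LE_discounted"` (deaths x
#'   life-expectancy annuity) or `"full_LE_undiscounted"` (deaths x life
#'   expectancy).
#' @return An object of class `daly_options`.
#' @export
daly_options <- function(yld_occupancy = c("cycle_end", "half_cycle"),
                         discounting = c("none", "midpoint", "end"),
                         yll_mode = c("horizon_truncated",
                                      "horizon_truncated_discounted",
                                      "full_LE_discounted",
                                      "full_LE_undiscounted")) {
  structure(list(yld_occupancy = match.arg(yld_occupancy),
                 discounting = match.arg(discounting),
                 yll_mode = match.arg(yll_mode)),
            class = "daly_options")
}

#' Standard life expectancies by age band
#'
#' @param le_under1 Life expectancy at death under 1 year (default 54.7).
#' @param le_1to4 Life expectancy at death at 1-4 years (default 57.9).
#' @return A `life_table` object.
#' @export
life_table <- function(le_under1 = 54.7, le_1to4 = 57.9) {
  stopifnot(le_under1 > 0, le_1to4 > 0)
  structure(list(under1 = le_under1, `1to4` = le_1to4), class = "life_table")
}

#' Years lived with disability
#'
#' `YLD = person-time in state x disability weight`, the yearly-cycle Markov
#' realisation of "number of cases x duration till remission or death x
#' disability weight".
#'
#' @param person_years Person-time in the morbid state (>= 0).
#' @param dw Disability weight in (0, 1).
#' @return DALYs.
#' @export
compute_yld <- function(person_years, dw) {
  if (any(person_years < 0)) stop("compute_yld: person_years must be >= 0")
  if (dw <= 0 || dw >= 1) stop("compute_yld: disability weight must be in (0, 1)")
  person_years * dw
}

#' Years of life lost to pneumonia deaths
#'
#' @param deaths Number of deaths (>= 0).
#' @param age_band `"under1"` or `"1to4"`.
#' @param lt A [life_table()].
#' @param disc Yearly discount rate for the discounted modes.
#' @param mode `"full_LE_undiscounted"` (`deaths x LE`),
#'   `"full_LE_discounted"` (`deaths x (1-(1+disc)^-LE)/disc`), or
#'   `"horizon_truncated"` (`deaths x remaining_years`, optionally as a
#'   discounted annuity when `disc > 0` and `truncated_discounted = TRUE`).
#' @param remaining_years In-horizon years remaining at death (needed for
#'   the truncated mode).
#' @param truncated_discounted Value truncated remaining years as a
#'   discounted annuity.
#' @return DALYs.
#' @export
compute_yll <- function(deaths, age_band = c("under1", "1to4"),
                        lt = life_table(), disc = 0.05,
                        mode = c("full_LE_undiscounted", "full_LE_discounted",
                                 "horizon_truncated"),
                        remaining_years = NULL, truncated_discounted = FALSE) {
  age_band <- match.arg(age_band)
  mode <- match.arg(mode)
  if (any(deaths < 0)) stop("compute_yll: deaths must be >= 0")
  le <- lt[[age_band]]
  annuity <- function(y, d) if (d > 0) (1 - (1 + d)^(-y)) / d else y
  switch(mode,
    full_LE_undiscounted = deaths * le,
    full_LE_discounted = deaths * annuity(le, disc),
    horizon_truncated = {
      if (is.null(remaining_years)) {
        stop("compute_yll: horizon_truncated mode needs 'remaining_years'")
      }
      if (truncated_discounted) deaths * annuity(remaining_years, disc)
      else deaths * remaining_years
    })
}

#' Per-cycle and total DALYs of a cohort trace
#'
#' YLD accrues from both pneumonia states; YLL accrues from the trace's
#' pneumonia deaths (age band under-1 in cycle 1, 1-4 years afterwards).
#' Under the truncated YLL modes a death in cycle `c` loses the
#' `n_cycles - c + 0.5` years left in the horizon (half a year in the cycle
#' of death). Components are discounted per `options$discounting`.
#'
#' @param trace A [run_cohort()] trace.
#' @param params A `parameter_set` (disability weights, life expectancies,
#'   effect discount rate).
#' @param options A [daly_options()].
#' @return An object of class `daly_breakdown` with per-cycle `yld_moderate`,
#'   `yld_severe`, `yll`, `daly`, and the accumulated `total`.
#' @export
compute_dalys <- function(trace, params, options = daly_options()) {
  stopifnot(inherits(trace, "cohort_trace"))
  v <- params$values
  n <- trace$n_cycles
  cyc <- seq_len(n)
  df <- switch(options$discounting,
    none = rep(1, n),
    midpoint = discount_factor(v["disc_effect"], cyc, "midpoint"),
    end = discount_factor(v["disc_effect"], cyc, "end"))
  occ <- switch(options$yld_occupancy,
    cycle_end = trace$membership[cyc + 1, , drop = FALSE],
    half_cycle = trace$person_years)
  yld_m <- df * compute_yld(occ[, "moderate"], unname(v["dw_moderate"]))
  yld_s <- df * compute_yld(occ[, "severe"], unname(v["dw_severe"]))
  lt <- life_table(unname(v["le_under1"]), unname(v["le_1to4"]))
  band <- c("under1", rep("1to4", n - 1))
  disc <- unname(v["disc_effect"])
  yll <- vapply(cyc, function(c) {
    d <- trace$pneumonia_deaths[c]
    y <- switch(options$yll_mode,
      full_LE_discounted = compute_yll(d, band[c], lt, disc, "full_LE_discounted"),
      full_LE_undiscounted = compute_yll(d, band[c], lt, mode = "full_LE_undiscounted"),
      horizon_truncated = compute_yll(d, band[c], lt, mode = "horizon_truncated",
                                      remaining_years = n - c + 0.5),
      horizon_truncated_discounted = compute_yll(
        d, band[c], lt, disc, "horizon_truncated",
        remaining_years = n - c + 0.5, truncated_discounted = TRUE))
    df[c] * y
  }, numeric(1))
  daly <- yld_m + yld_s + yll
  structure(list(yld_moderate = yld_m, yld_severe = yld_s, yll = yll,
                 daly = daly, total = sum(daly), options = options),
            class = "daly_breakdown")
}

#' @export
print.daly_breakdown <- function(x, ...) {
  cat(sprintf("<daly_breakdown> total %.1f DALYs (YLD %.1f, YLL %.1f)\n",
              x$total, sum(x$yld_moderate) + sum(x$yld_severe), sum(x$yll)))
  invisible(x)
}

#' Full outcome summary of one scenario
#'
#' @param trace A [run_cohort()] trace.
#' @param params A `parameter_set`.
#' @param options A [daly_options()].
#' @return Class `scenario_outcome`: the trace, its `daly_breakdown`, and
#'   cumulative pneumonia deaths / incident severe cases (undiscounted).
#' @export
scenario_outcomes <- function(trace, params, options = daly_options()) {
  dalys <- compute_dalys(trace, params, options)
  structure(list(trace = trace, dalys = dalys,
                 cum_pneumonia_deaths = sum(trace$pneumonia_deaths),
                 cum_incident_severe = sum(trace$incident_severe)),
            class = "scenario_outcome")
}

report_averted <- function(per_cycle, reporting) {
  switch(reporting,
    cumulative = sum(per_cycle),
    annual_mean = mean(per_cycle),
    final_cycle = per_cycle[length(per_cycle)])
}

#' Averted outcomes of the promotion relative to baseline
#'
#' DALYs averted are the accumulated difference of scenario DALY totals.
#' Deaths and severe cases averted are per-cycle differences reduced per
#' `reporting` (5-year cumulative, mean annual, or the final-cycle annual
#' figure -- the calibrated default, matching the published "in a year"
#' framing).
#'
#' @param baseline,promotion `scenario_outcome`s computed from the same
#'   parameter draw.
#' @param reporting Overrides the trace's `averted_reporting` option.
#' @return A list with `dalys_averted`, `deaths_averted`, `severe_averted`,
#'   and the per-cycle difference vectors.
#' @export
averted <- function(baseline, promotion, reporting = NULL) {
  stopifnot(inherits(baseline, "scenario_outcome"),
            inherits(promotion, "scenario_outcome"))
  if (baseline$trace$n_cycles != promotion$trace$n_cycles) {
    stop("averted: scenarios have different cycle counts")
  }
  if (is.null(reporting)) reporting <- baseline$trace$options$averted_reporting
  d_deaths <- baseline$trace$pneumonia_deaths - promotion$trace$pneumonia_deaths
  d_severe <- baseline$trace$incident_severe - promotion$trace$incident_severe
  list(
    dalys_averted = baseline$dalys$total - promotion$dalys$total,
    deaths_averted = report_averted(d_deaths, reporting),
    severe_averted = report_averted(d_severe, reporting),
    deaths_averted_by_cycle = d_deaths,
    severe_averted_by_cycle = d_severe,
    reporting = reporting)
}

#' Export per-cycle outcomes of a scenario as CSV
#'
#' @param outcome A [scenario_outcomes()] result.
#' @param path Optional CSV destination.
#' @return The per-cycle data.frame.
#' @export
export_outcomes <- function(outcome, path = NULL) {
  tr <- outcome$trace
  d <- outcome$dalys
  df <- data.frame(cycle = seq_len(tr$n_cycles),
                   yld_moderate = d$yld_moderate, yld_severe = d$yld_severe,
                   yll = d$yll, daly = d$daly,
                   pneumonia_deaths = tr$pneumonia_deaths,
                   incident_severe = tr$incident_severe,
                   discounting = d$options$discounting)
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
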