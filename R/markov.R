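# Cohort engine: scenario transition matrices, 5-cycle yearly trace with
# half-cycle correction, discount factors.

#' Health states of the cohort model
#'
#' @return `c("well", "moderate", "severe", "dead")`; `dead` is absorbing.
#' @export
health_states <- function() c("well", "moderate", "severe", "dead")

#' Options controlling where the promotion effect acts and how deaths and
#' severe cases are attributed
#'
#' The promotion's clinical benefit (relative risk `rr` of amoxicillin DT,
#' scaled by the promotion's effective coverage `s`) is applied to the
#' targeted transition probabilities; the freed probability mass moves to
#' the recovery transition of the same row (`mass_destination`). Accounting
#' switches select which rows' pneumonia deaths enter the YLL, whether
#' recurrent severe episodes count as new incident severe cases, and
#' whether averted deaths/severe cases are reported as 5-year cumulative
#' totals, mean annual values, or the final (steady-state) cycle.
#'
#' Defaults are the structural options selected by the calibration harness
#' ([calibrate_options()]); see the committed calibration report.
#'
#' @param targets Subset of `c("moderate_to_severe", "moderate_death",
#'   "severe_death")`.
#' @param scaling `"impact"` (s = promotion impact), `"impact_times_careseek"`
#'   or `"custom"` (then give `custom_s`).
#' @param custom_s Effective coverage when `scaling = "custom"`.
#' @param mass_destination State receiving the freed probability mass
#'   (recovery transition of the affected row); only `"well"` (via
#'   moderate-to-well, severe rows fall back to severe-to-moderate) is
#'   implemented.
#' @param death_states Rows whose `p_pneu_death` exits count as pneumonia
#'   deaths: `"severe"` (calibrated default) or `"both"`.
#' @param count_recurrent_severe Count severe-to-severe recurrences as new
#'   incident severe cases? Calibrated default `FALSE`.
#' @param averted_reporting `"final_cycle"` (calibrated default: the
#'   steady-state annual figure), `"annual_mean"`, or `"cumulative"` for
#'   averted deaths and severe cases.
#' @return An object of class `effect_options`.
#' @export
effect_options <- function(targets = "moderate_to_severe",
                           scaling = c("impact", "impact_times_careseek", "custom"),
                           custom_s = NULL,
                           mass_destination = "well",
                           death_states = c("severe", "both"),
                           count_recurrent_severe = FALSE,
                           averted_reporting = c("final_cycle", "annual_mean",
                                                 "cumulative")) {
  all_targets <- c("moderate_to_severe", "moderate_death", "severe_death")
  bad <- setdiff(targets, all_targets)
  if (length(bad)) stop("unknown effect target(s): ", paste(bad, collapse = ", "))
  structure(list(
    targets = targets,
    scaling = match.arg(scaling),
    custom_s = custom_s,
    mass_destination = match.arg(mass_destination, "well"),
    death_states = match.arg(death_states),
    count_recurrent_severe = isTRUE(count_recurrent_severe),
    averted_reporting = match.arg(averted_reporting)),
    class = "effect_options")
}

effective_coverage <- function(params, options) {
  v <- params$values
  switch(options$scaling,
    impact = unname(v["impact"]),
    impact_times_careseek = unname(v["impact"] * v["careseek_ppmv"]),
    custom = {
      if (is.null(options$custom_s)) stop("custom scaling needs 'custom_s'")
      options$custom_s
    })
}

check_stochastic <- function(m, tol = 1e-6) {
  if (any(m < -1e-12) || any(m > 1 + 1e-12)) {
    stop("transition matrix has entries outside [0, 1]")
  }
  dev <- abs(rowSums(m) - 1)
  if (any(dev > tol)) {
    stop(sprintf("transition matrix rows deviate from 1 by up to %.3g", max(dev)))
  }
  invisible(m)
}

#' Build the transition matrix for a scenario
#'
#' Row/column order `(well, moderate, severe, dead)`. The no-promotion
#' matrix holds the published probabilities; the promotion matrix applies
#' [apply_promotion_effect()] on top of it.
#'
#' @param params A `parameter_set` (can carry sampled values).
#' @param scenario `"no_promotion"` or `"promotion"`.
#' @param options An [effect_options()].
#' @return A 4x4 row-stochastic matrix with dimnames [health_states()].
#' @export
build_transition_matrix <- function(params,
                                    scenario = c("no_promotion", "promotion"),
                                    options = effect_options()) {
  scenario <- match.arg(scenario)
  v <- params$values
  m <- matrix(c(
    v["p_ww"], v["p_wm"], 0,          v["p_all_cause"],
    v["p_mw"], v["p_mm"], v["p_ms"],  v["p_pneu_death"],
    0,         v["p_sm"], v["p_ss"],  v["p_pneu_death"],
    0,         0,         0,          1),
    nrow = 4, byrow = TRUE, dimnames = list(health_states(), health_states()))
  check_stochastic(m)
  if (scenario == "promotion") {
    m <- apply_promotion_effect(m, rr = unname(v["rr_amox"]),
                                s = effective_coverage(params, options),
                                options = options)
  }
  m
}

#' Apply the promotion effect to a transition matrix
#'
#' Each targeted transition probability `p` becomes
#' `p * (1 - s * (1 - rr))`; the freed mass `p * s * (1 - rr)` is added to
#' the recovery transition of the same row, so rows stay stochastic.
#'
#' @param m A 4x4 row-stochastic matrix (no-promotion scenario).
#' @param rr Relative risk of the promoted treatment, in (0, 1].
#' @param s Effective coverage of the promotion, in \[0, 1\].
#' @param options An [effect_options()] naming the targeted transitions.
#' @return The promotion-scenario matrix.
#' @export
apply_promotion_effect <- function(m, rr, s, options = effect_options()) {
  if (rr <= 0) stop("apply_promotion_effect: rr must be positive")
  if (rr > 1) stop("apply_promotion_effect: rr > 1 (harmful treatment) not supported")
  if (s < 0 || s > 1) stop("apply_promotion_effect: coverage s must be in [0, 1]")
  red <- s * (1 - rr)
  shift <- function(m, row, col, dest) {
    d <- m[row, col] * red
    m[row, col] <- m[row, col] - d
    m[row, dest] <- m[row, dest] + d
    m
  }
  for (tg in options$targets) {
    m <- switch(tg,
      moderate_to_severe = shift(m, "moderate", "severe", "well"),
      moderate_death = shift(m, "moderate", "dead", "well"),
      severe_death = shift(m, "severe", "dead", "moderate"))
  }
  check_stochastic(m)
  m
}

#' Discount factor for a model cycle
#'
#' @param rate Yearly discount rate (>= 0).
#' @param cycle Cycle index (1-based).
#' @param timing `"midpoint"` (default, `(1+rate)^-(cycle-0.5)`, consistent
#'   with half-cycle occupancy) or `"end"` (`(1+rate)^-cycle`).
#' @return Discount factor(s).
#' @export
discount_factor <- function(rate, cycle, timing = c("midpoint", "end")) {
  timing <- match.arg(timing)
  if (any(rate < 0)) stop("discount_factor: rate must be >= 0")
  if (any(cycle < 1)) stop("discount_factor: cycle index starts at 1")
  expo <- if (timing == "midpoint") cycle - 0.5 else cycle
  (1 + rate)^(-expo)
}

#' Run the Markov cohort trace
#'
#' Propagates a closed cohort (all in `well` at cycle 0) through `m` for
#' `n_cycles` yearly cycles. Membership is the expected end-of-cycle state
#' count; person-years use the life-table half-cycle correction
#' `(start + end) / 2`. Incident severe cases in cycle `c` are
#' `moderate[c-1] * p(moderate->severe)` plus, when
#' `options$count_recurrent_severe`, `severe[c-1] * p(severe->severe)`.
#' Deaths are tracked separately out of each living row.
#'
#' @param m 4x4 row-stochastic transition matrix.
#' @param init_cohort Cohort size (> 0).
#' @param n_cycles Number of yearly cycles (>= 1).
#' @param options An [effect_options()] (accounting switches only).
#' @return An object of class `cohort_trace` with elements `membership`
#'   ((n_cycles+1) x 4, cycle 0 first), `person_years` (n_cycles x 4),
#'   `incident_severe`, `pneumonia_deaths`, `deaths_from_moderate`,
#'   `deaths_from_severe`, `all_cause_deaths` (length n_cycles each).
#' @export
run_cohort <- function(m, init_cohort, n_cycles = 5, options = effect_options()) {
  if (init_cohort <= 0) stop("run_cohort: init_cohort must be positive")
  if (n_cycles < 1) stop("run_cohort: n_cycles must be >= 1")
  check_stochastic(m)
  st <- health_states()
  membership <- matrix(0, n_cycles + 1, 4, dimnames = list(0:n_cycles, st))
  x <- c(init_cohort, 0, 0, 0)
  membership[1, ] <- x
  incident_severe <- deaths_m <- deaths_s <- all_cause <- numeric(n_cycles)
  for (cyc in seq_len(n_cycles)) {
    incident_severe[cyc] <- x[2] * m["moderate", "severe"] +
      if (options$count_recurrent_severe) x[3] * m["severe", "severe"] else 0
    deaths_m[cyc] <- x[2] * m["moderate", "dead"]
    deaths_s[cyc] <- x[3] * m["severe", "dead"]
    all_cause[cyc] <- x[1] * m["well", "dead"]
    x <- as.vector(x %*% m)
    membership[cyc + 1, ] <- x
  }
  pneumonia_deaths <- if (options$death_states == "both") deaths_m + deaths_s else deaths_s
  person_years <- (membership[seq_len(n_cycles), , drop = FALSE] +
                   membership[seq_len(n_cycles) + 1, , drop = FALSE]) / 2
  structure(list(
    membership = membership, person_years = person_years,
    incident_severe = incident_severe, pneumonia_deaths = pneumonia_deaths,
    deaths_from_moderate = deaths_m, deaths_from_severe = deaths_s,
    all_cause_deaths = all_cause,
    init_cohort = init_cohort, n_cycles = n_cycles, options = options),
    class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf("<cohort_trace> %d cycles, cohort %s\n", x$n_cycles,
              format(x$init_cohort, big.mark = ",")))
  print(round(x$membership))
  invisible(x)
}

#' Export a cohort trace as a per-cycle, per-state table
#'
#' @param trace A `cohort_trace`.
#' @param disc_rate Rate for the discounted person-years column.
#' @param path Optional CSV destination; written with '.' decimal, header
#'   `cycle,state,membership,person_years,person_years_discounted`.
#' @return The data.frame, invisibly when `path` is given.
#' @export
export_trace <- function(trace, disc_rate = 0.05, path = NULL) {
  n <- trace$n_cycles
  df <- expand.grid(cycle = seq_len(n), state = health_states(),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df <- df[order(df$cycle), ]
  df$membership <- as.vector(t(trace$membership[-1, , drop = FALSE]))
  df$person_years <- as.vector(t(trace$person_years))
  df$person_years_discounted <- df$person_years *
    discount_factor(disc_rate, df$cycle)
  rownames(df) <- NULL
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
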