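# Probabilistic sensitivity analysis: joint Monte Carlo over all
# distributional parameters with per-draw substream seeding.

#' Default PSA seed (documented constant so shipped results reproduce)
#' @export
DEFAULT_PSA_SEED <- 20210225L

# Deterministic per-draw substream seed: draws keep their identity when the
# total number of draws changes.
draw_seed <- function(seed, i) {
  base <- (as.numeric(seed) * 48271) %% 2147483647
  as.integer((base + i * 30269) %% 2147483647)
}

#' Empirical percentile interval
#'
#' @param values Non-empty numeric vector.
#' @param lo_p,hi_p Probabilities with `0 <= lo_p < hi_p <= 1`
#'   (default 2.5/97.5%).
#' @return `c(lo, hi)` using the linear-interpolation quantile convention
#'   (R type 7).
#' @export
percentile_interval <- function(values, lo_p = 0.025, hi_p = 0.975) {
  if (!length(values)) stop("percentile_interval: empty input")
  if (!(lo_p >= 0 && lo_p < hi_p && hi_p <= 1)) {
    stop("percentile_interval: need 0 <= lo_p < hi_p <= 1")
  }
  unname(stats::quantile(values, c(lo_p, hi_p), type = 7, names = FALSE))
}

#' Fraction of values strictly below a threshold
#'
#' @param values Non-empty numeric vector.
#' @param threshold Cut point.
#' @return Proportion in `[0, 1]`.
#' @export
proportion_below <- function(values, threshold) {
  if (!length(values)) stop("proportion_below: empty input")
  mean(values < threshold)
}

# Fit every sampled parameter's distribution once.
fit_all <- function(params, lognormal_centre = "mean") {
  fits <- lapply(params$params, fit_distribution, lognormal_centre = lognormal_centre)
  names(fits) <- names(params$params)
  fits
}

#' Sample one parameter-set realisation
#'
#' Each distributional parameter is drawn independently from its fitted
#' family. Independent sampling breaks the three row-sum identities, so
#' rows are repaired minimally: the pneumonia death probability keeps its
#' drawn value and the living transitions of the moderate and severe rows
#' are rescaled to `1 - p_pneu_death`; the well row is rescaled by its sum.
#' Row sums are exactly 1 afterwards.
#'
#' @param params A `parameter_set` (point estimates).
#' @param fits Pre-computed fits from [fit_distribution()] (recomputed when
#'   `NULL`).
#' @return A `parameter_set` realisation satisfying all invariants. Uses the
#'   current RNG state.
#' @export
sample_parameter_set <- function(params, fits = NULL) {
  if (is.null(fits)) fits <- fit_all(params)
  v <- params$values
  for (nm in names(fits)) v[nm] <- draw_from(fits[[nm]], 1)
  # minimal row repair (see above)
  w <- c("p_ww", "p_wm", "p_all_cause")
  v[w] <- v[w] / sum(v[w])
  pd <- unname(v["p_pneu_death"])
  m <- c("p_mw", "p_mm", "p_ms")
  v[m] <- v[m] * (1 - pd) / sum(v[m])
  s <- c("p_sm", "p_ss")
  v[s] <- v[s] * (1 - pd) / sum(v[s])
  v <- repair_transition_rows(v)
  out <- params
  out$values <- v
  out$table$mean <- unname(v[out$table$name])
  validate_parameter_set(out)
  out
}

#' Sample the cost ledger (each component uniform within +/-25%)
#'
#' Component costs are published with a +/-25% band and no named family;
#' they are drawn uniform on `[0.75, 1.25]` times the point unit cost.
#'
#' @param ledger A `cost_ledger`.
#' @param rel Half-width of the uniform band (default 0.25).
#' @return A `cost_ledger` with perturbed unit costs. Uses the current RNG
#'   state.
#' @export
sample_ledger <- function(ledger, rel = 0.25) {
  comp <- ledger$components
  comp$unit_cost <- comp$unit_cost * stats::runif(nrow(comp), 1 - rel, 1 + rel)
  cost_ledger(comp[setdiff(names(comp), "annual_total")],
              ledger$population_u5, ledger$careseek_ppmv)
}

#' Run the probabilistic sensitivity analysis
#'
#' `n` independent joint draws of every distributional parameter and every
#' cost component; both scenarios are run on the same draw. Each draw uses
#' its own deterministic RNG substream derived from `seed` and the draw
#' index, so results are reproducible and draw `i` is unchanged when `n`
#' changes.
#'
#' @param params A `parameter_set`.
#' @param ledger A `cost_ledger`.
#' @param n Number of draws (>= 2; default the parameter `n_psa`, 1000).
#' @param seed Integer seed (default [DEFAULT_PSA_SEED]).
#' @param effect An [effect_options()].
#' @param daly A [daly_options()].
#' @param lognormal_centre Passed to [fit_distribution()].
#' @return An object of class `psa_result`: `samples` (one row per draw:
#'   sampled parameters and all outputs), `summary` (mean and 2.5/97.5
#'   percentile interval per output), `n`, `seed`.
#' @export
run_psa <- function(params = default_parameters(), ledger = default_ledger(),
                    n = NULL, seed = DEFAULT_PSA_SEED,
                    effect = effect_options(), daly = daly_options(),
                    lognormal_centre = "mean") {
  if (is.null(n)) n <- unname(params$values["n_psa"])
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("run_psa: 'seed' must be a single integer")
  }
  if (n < 2) stop("run_psa: need n >= 2 draws")
  fits <- fit_all(params, lognormal_centre)
  sampled_names <- names(fits)[vapply(fits, function(f) f$family != "fixed",
                                      logical(1))]
  n_cycles <- unname(params$values["n_cycles"])
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(draw_seed(seed, i))
    ps_i <- sample_parameter_set(params, fits)
    led_i <- sample_ledger(ledger)
    init <- cohort_size(ps_i)
    m0 <- build_transition_matrix(ps_i, "no_promotion", effect)
    m1 <- build_transition_matrix(ps_i, "promotion", effect)
    out0 <- scenario_outcomes(run_cohort(m0, init, n_cycles, effect), ps_i, daly)
    out1 <- scenario_outcomes(run_cohort(m1, init, n_cycles, effect), ps_i, daly)
    av <- averted(out0, out1)
    dc <- total_annual_cost(led_i)
    rows[[i]] <- c(
      draw = i,
      stats::setNames(unname(ps_i$values[sampled_names]), sampled_names),
      delta_cost = dc,
      daly_baseline = out0$dalys$total,
      daly_promotion = out1$dalys$total,
      dalys_averted = av$dalys_averted,
      deaths_averted = av$deaths_averted,
      severe_averted = av$severe_averted,
      icer = icer(dc, av$dalys_averted))
  }
  samples <- as.data.frame(do.call(rbind, rows))
  outputs <- c("delta_cost", "daly_baseline", "daly_promotion",
               "dalys_averted", "deaths_averted", "severe_averted", "icer")
  summ <- do.call(rbind, lapply(outputs, function(o) {
    x <- samples[[o]]
    pi <- percentile_interval(x)
    data.frame(output = o, mean = mean(x), lo95 = pi[1], hi95 = pi[2])
  }))
  structure(list(samples = samples, summary = summ, n = n, seed = seed,
                 icer_of_means = mean(samples$delta_cost) /
                   mean(samples$dalys_averted)),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d draws, seed %s\n", x$n, format(x$seed)))
  s <- x$summary
  s$mean <- signif(s$mean, 6); s$lo95 <- signif(s$lo95, 6); s$hi95 <- signif(s$hi95, 6)
  print(s, row.names = FALSE)
  cat(sprintf("ICER of means: %.2f USD/DALY averted\n", x$icer_of_means))
  invisible(x)
}
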