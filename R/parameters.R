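# Model parameters: uncertain quantities with point value, 95% interval and a
# sampling family, plus rate<->probability conversion and distribution fitting.

PARAM_FAMILIES <- c("beta", "gamma", "lognormal", "uniform", "fixed")

#' Convert a yearly rate to a transition probability
#'
#' Uses the standard exponential conversion `p = 1 - exp(-r * t)` for a
#' constant hazard `r` acting over `t` years.
#'
#' @param r Non-negative event rate (per year).
#' @param t Exposure time in years (default 1, the model cycle length).
#' @return Probability in `[0, 1)`. Vectorised over `r` and `t`.
#' @examples
#' rate_to_probability(0.30207)  # ~0.2607
#' @export
rate_to_probability <- function(r, t = 1) {
  if (any(r < 0)) stop("rate_to_probability: rate 'r' must be non-negative")
  if (any(t < 0)) stop("rate_to_probability: time 't' must be non-negative")
  1 - exp(-r * t)
}

#' Convert a transition probability back to a yearly rate
#'
#' Inverse of [rate_to_probability()]: `r = -log(1 - p) / t`.
#'
#' @param p Probability in `[0, 1)`.
#' @param t Exposure time in years (> 0).
#' @return Rate per year. Round-trips with [rate_to_probability()] to 1e-12.
#' @export
probability_to_rate <- function(p, t = 1) {
  if (any(p < 0) || any(p >= 1)) {
    stop("probability_to_rate: 'p' must lie in [0, 1)")
  }
  if (any(t <= 0)) stop("probability_to_rate: 't' must be positive")
  -log(1 - p) / t
}

#' Create an uncertain model parameter
#'
#' A parameter holds a point value (`mean`), an optional 95% interval
#' (`lo`, `hi`) and the sampling-distribution family used in probabilistic
#' sensitivity analysis. Parameters published without uncertainty use
#' `family = "fixed"` and always sample at their mean.
#'
#' @param name Identifier.
#' @param mean Point value.
#' @param lo,hi Lower/upper 95% bounds (`NA` when not published).
#' @param family One of `"beta"`, `"gamma"`, `"lognormal"`, `"uniform"`,
#'   `"fixed"`.
#' @param units Free-text units.
#' @return An object of class `uncertain_parameter`.
#' @export
uncertain_parameter <- function(name, mean, lo = NA_real_, hi = NA_real_,
                                family = "fixed", units = "") {
  family <- match.arg(family, PARAM_FAMILIES)
  p <- structure(
    list(name = as.character(name), mean = as.numeric(mean),
         lo = as.numeric(lo), hi = as.numeric(hi),
         family = family, units = as.character(units)),
    class = "uncertain_parameter")
  validate_uncertain_parameter(p)
  p
}

validate_uncertain_parameter <- function(p) {
  has_ci <- !is.na(p$lo) && !is.na(p$hi)
  if (has_ci && !(p$lo <= p$mean && p$mean <= p$hi)) {
    stop(sprintf("parameter '%s': interval must satisfy lo <= mean <= hi", p$name))
  }
  if (p$family == "beta" && has_ci && (p$lo < 0 || p$hi > 1)) {
    stop(sprintf("parameter '%s': beta family needs bounds inside [0, 1]", p$name))
  }
  if (p$family == "gamma" && has_ci && p$lo <= 0) {
    stop(sprintf("parameter '%s': gamma family needs a positive lower bound", p$name))
  }
  if (p$family %in% c("beta", "gamma", "lognormal") && !has_ci) {
    stop(sprintf("parameter '%s': family '%s' needs both interval bounds",
                 p$name, p$family))
  }
  invisible(p)
}

#' @export
print.uncertain_parameter <- function(x, ...) {
  ci <- if (is.na(x$lo)) "" else sprintf(" (95%% CI %g-%g)", x$lo, x$hi)
  cat(sprintf("<uncertain_parameter> %s = %g%s [%s] %s\n",
              x$name, x$mean, ci, x$family, x$units))
  invisible(x)
}

#' Fit a sampling distribution from a mean and 95% interval
#'
#' Moment matching with the normal approximation `sd = (hi - lo) / 3.92`:
#' * beta: `alpha = mean * (mean (1 - mean) / var - 1)`,
#'   `beta = alpha * (1 - mean) / mean`;
#' * gamma: `shape = mean^2 / var`, `scale = var / mean`;
#' * lognormal: `meanlog = log(mean)` (or the log-midpoint of the interval
#'   when `lognormal_centre = "midpoint"`), `sdlog = (log hi - log lo) / 3.92`;
#' * uniform: the interval itself;
#' * fixed: degenerate at the mean.
#'
#' @param param An [uncertain_parameter()].
#' @param lognormal_centre `"mean"` (default; preserves the point estimate)
#'   or `"midpoint"` (log-symmetric about the published interval).
#' @return A list with `family`, the fitted parameters, and the source
#'   parameter name, of class `fitted_distribution`.
#' @export
fit_distribution <- function(param, lognormal_centre = c("mean", "midpoint")) {
  lognormal_centre <- match.arg(lognormal_centre)
  stopifnot(inherits(param, "uncertain_parameter"))
  out <- list(family = param$family, name = param$name, mean = param$mean)
  if (param$family == "fixed") {
    out$value <- param$mean
    class(out) <- "fitted_distribution"
    return(out)
  }
  if (is.na(param$lo) || is.na(param$hi) || param$lo >= param$hi) {
    stop(sprintf("parameter '%s': need lo < hi to fit a '%s' distribution",
                 param$name, param$family))
  }
  sdev <- (param$hi - param$lo) / 3.92
  v <- sdev^2
  m <- param$mean
  if (param$family == "beta") {
    if (v >= m * (1 - m)) {
      stop(sprintf(
        "parameter '%s': interval variance %.4g >= mean(1-mean) %.4g; beta moment matching infeasible",
        param$name, v, m * (1 - m)))
    }
    out$alpha <- m * (m * (1 - m) / v - 1)
    out$beta <- out$alpha * (1 - m) / m
  } else if (param$family == "gamma") {
    out$shape <- m^2 / v
    out$scale <- v / m
  } else if (param$family == "lognormal") {
    out$sdlog <- (log(param$hi) - log(param$lo)) / 3.92
    out$meanlog <- if (lognormal_centre == "mean") log(m) else {
      (log(param$hi) + log(param$lo)) / 2
    }
  } else if (param$family == "uniform") {
    out$min <- param$lo
    out$max <- param$hi
  }
  class(out) <- "fitted_distribution"
  out
}

#' Draw from a fitted distribution
#'
#' @param dist A `fitted_distribution` from [fit_distribution()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`; for `family = "fixed"` the mean is
#'   returned always.
#' @export
draw_from <- function(dist, n = 1) {
  stopifnot(inherits(dist, "fitted_distribution"))
  switch(dist$family,
    fixed = rep(dist$value, n),
    beta = stats::rbeta(n, dist$alpha, dist$beta),
    gamma = stats::rgamma(n, shape = dist$shape, scale = dist$scale),
    lognormal = stats::rlnorm(n, dist$meanlog, dist$sdlog),
    uniform = stats::runif(n, dist$min, dist$max),
    stop("unknown family: ", dist$family))
}

# Absorb floating-point residuals (a few ulp) into the largest free entry of
# each transition row so the canonical left-to-right sums are exactly 1.
# Shared by the PSA sampler and the random-model generator.
repair_transition_rows <- function(v) {
  for (row in list(c("p_ww", "p_wm", "p_all_cause"),
                   c("p_mw", "p_mm", "p_ms", "p_pneu_death"),
                   c("p_sm", "p_ss", "p_pneu_death"))) {
    free <- setdiff(row, "p_pneu_death")
    for (it in 1:16) {
      resid <- 1 - sum(v[row])
      if (resid == 0) break
      j <- free[which.max(v[free])]
      v[j] <- v[j] + resid
    }
  }
  v
}

# names every parameter set must provide
REQUIRED_PARAMS <- c(
  "p_ww", "p_wm", "p_ms", "p_mm", "p_ss", "p_mw", "p_sm",
  "p_all_cause", "p_pneu_death",
  "rr_amox", "impact", "dw_moderate", "dw_severe", "cost_per_child",
  "disc_cost", "disc_effect", "le_under1", "le_1to4",
  "children_u5", "careseek_ppmv", "careseek_facility",
  "gdp_pc", "threshold_multiplier", "unit_inpatient_cost",
  "n_psa", "n_cycles")

#' Construct a validated parameter set
#'
#' @param table A data.frame with columns `name, mean, lo, hi, family, units`,
#'   one row per model parameter (see [load_parameter_table()]).
#' @return An object of class `parameter_set`: the table plus a named vector
#'   `values` of point estimates.
#' @export
parameter_set <- function(table) {
  need <- c("name", "mean", "lo", "hi", "family", "units")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("parameter table lacks columns: ", paste(miss, collapse = ", "))
  missing_par <- setdiff(REQUIRED_PARAMS, table$name)
  if (length(missing_par)) {
    stop("parameter set is missing: ", paste(missing_par, collapse = ", "))
  }
  dup <- table$name[duplicated(table$name)]
  if (length(dup)) stop("duplicated parameters: ", paste(unique(dup), collapse = ", "))
  params <- lapply(seq_len(nrow(table)), function(i) {
    uncertain_parameter(table$name[i], table$mean[i], table$lo[i],
                        table$hi[i], table$family[i], table$units[i])
  })
  names(params) <- table$name
  ps <- structure(
    list(table = table,
         params = params,
         values = stats::setNames(as.numeric(table$mean), table$name)),
    class = "parameter_set")
  validate_parameter_set(ps)
  ps
}

#' Validate the invariants of a parameter set
#'
#' Checks that probabilities lie in `[0, 1]`, that the three Markov row-sum
#' identities hold (`well`, `moderate` and `severe` rows each close to 1),
#' that the relative risk is positive, and that disability weights lie in
#' `(0, 1)`. Violations are reported together.
#'
#' @param ps A `parameter_set`.
#' @param tol Tolerance on the row-sum identities.
#' @return `ps`, invisibly; errors listing every offender otherwise.
#' @export
validate_parameter_set <- function(ps, tol = 1e-9) {
  v <- ps$values
  bad <- character(0)
  probs <- c("p_ww", "p_wm", "p_ms", "p_mm", "p_ss", "p_mw", "p_sm",
             "p_all_cause", "p_pneu_death", "careseek_ppmv", "careseek_facility")
  for (nm in probs) {
    if (v[nm] < 0 || v[nm] > 1) bad <- c(bad, sprintf("%s = %g outside [0,1]", nm, v[nm]))
  }
  # summed in the canonical matrix-row order
  rows <- c(
    well = sum(v[c("p_ww", "p_wm", "p_all_cause")]),
    moderate = sum(v[c("p_mw", "p_mm", "p_ms", "p_pneu_death")]),
    severe = sum(v[c("p_sm", "p_ss", "p_pneu_death")]))
  for (i in seq_along(rows)) {
    if (abs(rows[i] - 1) > tol) {
      bad <- c(bad, sprintf("%s row sums to %.10f, not 1", names(rows)[i], rows[i]))
    }
  }
  if (v["rr_amox"] <= 0) bad <- c(bad, "rr_amox must be positive")
  if (v["impact"] < 0 || v["impact"] > 1) bad <- c(bad, "impact outside [0,1]")
  for (nm in c("dw_moderate", "dw_severe")) {
    if (v[nm] <= 0 || v[nm] >= 1) bad <- c(bad, sprintf("%s outside (0,1)", nm))
  }
  if (length(bad)) {
    stop("invalid parameter set:\n  ", paste(bad, collapse = "\n  "))
  }
  invisible(ps)
}

#' @export
print.parameter_set <- function(x, ...) {
  cat(sprintf("<parameter_set> %d parameters (%d sampled, %d fixed)\n",
              nrow(x$table), sum(x$table$family != "fixed"),
              sum(x$table$family == "fixed")))
  invisible(x)
}

#' Load a parameter table from CSV or JSON
#'
#' The file must provide the columns `name, mean, lo, hi, family, units`
#' ('.' decimal, UTF-8). The shipped default
#' (`system.file("extdata", "parameters.csv", package = "iccmcea")`)
#' transcribes the published model inputs.
#'
#' @param path Path to a `.csv` or `.json` file.
#' @return A validated `parameter_set`.
#' @export
load_parameter_table <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  tab <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (!is.numeric(tab$lo)) tab$lo <- suppressWarnings(as.numeric(tab$lo))
  if (!is.numeric(tab$hi)) tab$hi <- suppressWarnings(as.numeric(tab$hi))
  parameter_set(tab)
}

#' The shipped default parameter set
#'
#' Transcribes the published transition probabilities, relative risk,
#' promotion impact, disability weights, discount rates, life expectancies,
#' population constants and threshold constants.
#'
#' @return A validated `parameter_set`.
#' @export
default_parameters <- function() {
  load_parameter_table(system.file("extdata", "parameters.csv",
                                   package = "iccmcea", mustWork = TRUE))
}

#' Promotion impact from its published components
#'
#' The impact of the promotion is the product of the observed difference in
#' amoxicillin-DT/timer use between promotion and no-promotion arms and the
#' appropriateness of care.
#'
#' @param use_difference Difference in use (default 0.493).
#' @param appropriateness Proportion of appropriate care (default 0.88).
#' @return The impact proportion (0.493 * 0.88 = 0.433384...; published
#'   rounded to 43.38%).
#' @export
impact_from_components <- function(use_difference = 0.493, appropriateness = 0.88) {
  stopifnot(use_difference >= 0, use_difference <= 1,
            appropriateness >= 0, appropriateness <= 1)
  use_difference * appropriateness
}

#' Starting cohort: children reached through PPMV care-seeking
#'
#' @param params A `parameter_set`.
#' @return `children_u5 * careseek_ppmv` (13.84 million with defaults).
#' @export
cohort_size <- function(params) {
  unname(params$values["children_u5"] * params$values["careseek_ppmv"])
}
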