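#' Logistic survival model for out-of-hospital cardiac arrest
#'
#' Survival to hospital discharge as a function of the time from collapse to
#' first CPR (`T_CPR`) and to ambulance arrival (`T_EMS`), both in minutes,
#' after Waalewijn et al.:
#' `survival = 1 / (1 + exp(beta0 + beta_cpr * T_CPR + beta_ems * (T_EMS - T_CPR)))`.
#' With `beta_cpr > beta_ems > 0` survival is strictly decreasing in `T_CPR`
#' at fixed `T_EMS`; at `T_CPR = T_EMS = 13` min the defaults give 0.0191,
#' i.e. 98 expected survivors among 5,141 annual cardiac arrests when no
#' volunteer is alerted.
#'
#' @param beta0 Intercept on the logit scale (default 0.04).
#' @param beta_cpr Logit slope per minute of CPR delay (default 0.3).
#' @param beta_ems Logit slope per minute of defibrillation delay beyond the
#'   CPR delay (default 0.14). Must satisfy `beta_cpr > beta_ems > 0`.
#' @return A `cfr_survival` object.
#' @export
survival_model <- function(beta0 = 0.04, beta_cpr = 0.3, beta_ems = 0.14) {
  stopifnot(is.numeric(beta0), is.numeric(beta_cpr), is.numeric(beta_ems))
  if (!(beta_cpr > beta_ems && beta_ems > 0)) {
    stop("require beta_cpr > beta_ems > 0 (survival decreasing in T_CPR)",
         call. = FALSE)
  }
  structure(list(beta0 = beta0, beta_cpr = beta_cpr, beta_ems = beta_ems),
            class = "cfr_survival")
}

#' @export
print.cfr_survival <- function(x, ...) {
  cat(sprintf(
    "<cfr_survival> 1 / (1 + exp(%g + %g T_CPR + %g (T_EMS - T_CPR)))\n",
    x$beta0, x$beta_cpr, x$beta_ems
  ))
  invisible(x)
}

#' Survival probability given time to CPR and to EMS arrival
#'
#' @param t_cpr_min Time from collapse to first CPR, minutes; must not exceed
#'   `t_ems_min` (the first CPR provider is at latest the ambulance crew).
#'   Vectorised.
#' @param t_ems_min Time from collapse to ambulance arrival, minutes.
#' @param model A [survival_model()].
#' @param one_minus If `TRUE`, return the complement
#'   `1 - (1 + exp(...))^-1`. This variant appears in some transcriptions of
#'   the curve but increases with CPR delay, contradicting the physiology and
#'   the published zero-volunteer baseline; it is provided for auditing only.
#' @return Survival probabilities in (0, 1).
#' @examples
#' survival_prob(13, 13) # no volunteer arrives before the ambulance
#' survival_prob(4, 13)  # CPR at 4 minutes
#' @export
survival_prob <- function(t_cpr_min, t_ems_min, model = survival_model(),
                          one_minus = FALSE) {
  stopifnot(inherits(model, "cfr_survival"))
  if (any(t_cpr_min < 0 | t_ems_min < 0, na.rm = TRUE)) {
    stop("times must be non-negative", call. = FALSE)
  }
  if (any(t_cpr_min > t_ems_min + 1e-9, na.rm = TRUE)) {
    stop("t_cpr_min exceeds t_ems_min: truncate T_CPR at T_EMS first",
         call. = FALSE)
  }
  p <- 1 / (1 + exp(model$beta0 + model$beta_cpr * t_cpr_min +
                      model$beta_ems * (t_ems_min - t_cpr_min)))
  if (one_minus) 1 - p else p
}

kpi_cols <- c("coverage", "survival", "alerts", "redundant", "two_plus")

#' Aggregate a simulation into the five KPIs
#'
#' Collapses the per-outer-replication inner means of a [run_policy()] run
#' into one row of key performance indicators: 5-minute coverage, expected
#' survivors per year (mean survival times the annual incident count), mean
#' alerts per incident, mean redundant arrivals (arrivals beyond the first),
#' and the fraction of incidents with two or more arrivals. Monte Carlo
#' uncertainty is summarised by two-sided 95% t-intervals over the outer
#' replications; `max_ci_halfwidth_frac` is the largest halfwidth as a
#' fraction of the mean across the five KPIs, skipping KPIs whose mean is
#' zero.
#'
#' @param sim A `cfr_sim` object from [run_policy()].
#' @param conf_level Confidence level for the t-intervals (default 0.95).
#' @return A one-row tibble: `policy`, `n_volunteers`, `coverage`,
#'   `survivors_per_year`, `n_alerts`, `redundant_arrivals`, `frac_2plus`,
#'   `max_ci_halfwidth_frac`.
#' @export
aggregate_kpis <- function(sim, conf_level = 0.95) {
  stopifnot(inherits(sim, "cfr_sim"))
  outer <- sim$outer
  if (nrow(outer) == 0L) stop("no outer replications to aggregate", call. = FALSE)
  n <- nrow(outer)
  means <- vapply(outer[kpi_cols], mean, numeric(1))
  halfwidth <- if (n >= 2L) {
    qt(1 - (1 - conf_level) / 2, df = n - 1L) *
      vapply(outer[kpi_cols], stats::sd, numeric(1)) / sqrt(n)
  } else {
    setNames(rep(NA_real_, length(kpi_cols)), kpi_cols)
  }
  rel <- halfwidth / means
  rel <- rel[is.finite(rel) & means != 0]
  tibble::tibble(
    policy = sim$policy$label,
    family = sim$policy$family,
    n_volunteers = sim$disk$n_volunteers,
    coverage = means[["coverage"]],
    survivors_per_year = means[["survival"]] * sim$cfg$annual_ohcas,
    n_alerts = means[["alerts"]],
    redundant_arrivals = means[["redundant"]],
    frac_2plus = means[["two_plus"]],
    max_ci_halfwidth_frac = if (length(rel)) max(rel) else NA_real_
  )
}
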