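#' Simulation configuration
#'
#' Replication counts, timing constants and the master seed for the nested
#' Monte Carlo design: `n_outer` sets of volunteer distances are drawn, and
#' each set is combined with `n_inner` joint draws of view delays and
#' replies. The published experiments use 1000 x 10000; desk-scale runs
#' (e.g. 50 x 200) give the same point estimates with wider intervals.
#'
#' Timing constants convert the simulated first volunteer arrival (measured
#' from system activation) to a time-to-CPR on the collapse clock:
#' `T_CPR = min(witness_delay + triage_delay + first_arrival, T_EMS)`. The
#' witness delay (60 s) is the lag from collapse to the emergency call, the
#' triage delay (124 s, an observed median) from call to CFR-system
#' activation, and `T_EMS` (13 min) is the constant ambulance arrival time.
#'
#' @param n_outer Outer replications: volunteer location sets (default 1000).
#' @param n_inner Inner replications: behavior draws per location set
#'   (default 10000).
#' @param t_ems_min Collapse-to-ambulance time, minutes (default 13).
#' @param witness_delay_s Collapse-to-call lag, seconds (default 60).
#' @param triage_delay_s Call-to-activation lag, seconds (default 124).
#' @param coverage_threshold_s Coverage threshold on the activation clock,
#'   seconds (default 300; arrival at exactly the threshold counts).
#' @param annual_ohcas Annual incident count used to scale mean survival to
#'   survivors per year (default 5141, the national New Zealand figure).
#' @param master_seed Integer master seed; all replication streams are
#'   derived from it (default 1).
#' @return A `cfr_sim_config` list.
#' @export
sim_config <- function(n_outer = 1000, n_inner = 10000,
                       t_ems_min = 13, witness_delay_s = 60,
                       triage_delay_s = 124, coverage_threshold_s = 300,
                       annual_ohcas = 5141, master_seed = 1) {
  stopifnot(
    n_outer >= 1, n_inner >= 1,
    t_ems_min > 0, witness_delay_s > 0, triage_delay_s > 0,
    coverage_threshold_s > 0, annual_ohcas >= 1
  )
  structure(
    list(n_outer = as.integer(n_outer), n_inner = as.integer(n_inner),
         t_ems_min = as.numeric(t_ems_min),
         witness_delay_s = as.numeric(witness_delay_s),
         triage_delay_s = as.numeric(triage_delay_s),
         coverage_threshold_s = as.numeric(coverage_threshold_s),
         annual_ohcas = as.numeric(annual_ohcas),
         master_seed = as.numeric(master_seed)),
    class = "cfr_sim_config"
  )
}

# Incident KPIs from resolved alert times + responses. All accepters arrive
# (at alert + view delay + travel) and are counted, even past T_EMS; only the
# survival conversion truncates at T_EMS.
incident_metrics <- function(alert_time_s, delay, code, travel_s, cfg, surv) {
  alerted <- !is.na(alert_time_s)
  acc <- alerted & code == ACCEPT
  first <- if (any(acc)) min(alert_time_s[acc] + delay[acc] + travel_s[acc]) else Inf
  t_cpr_min <- min((cfg$witness_delay_s + cfg$triage_delay_s + first) / 60,
                   cfg$t_ems_min)
  list(
    first_arrival_s = first,
    n_alerts = sum(alerted),
    n_arrivals = sum(acc),
    covered = first <= cfg$coverage_threshold_s,
    survival = survival_prob(t_cpr_min, cfg$t_ems_min, surv)
  )
}

#' Simulate a single incident
#'
#' Resolves one incident end to end: the policy's alert schedule is computed
#' against the volunteers' prospective responses, accepters arrive at alert
#' time + view delay + travel time, and the first arrival is converted to a
#' survival probability.
#'
#' @param spec A [policy()].
#' @param distances Volunteer distances in meters, sorted ascending.
#' @param responses Data frame with one row per volunteer (in distance
#'   order): `view_delay_s`, `reply`; e.g. from [draw_responses()].
#' @param cfg A [sim_config()] (timing constants; replication counts unused).
#' @param speed A [speed_model()].
#' @param surv A [survival_model()].
#' @return One-row tibble: `first_arrival_s` (seconds from activation, `Inf`
#'   if no volunteer arrives), `n_alerts`, `n_arrivals`, `covered_5min`,
#'   `survival_prob`.
#' @examples
#' simulate_incident(policy("send_all"), distances = c(200, 800),
#'                   responses = data.frame(view_delay_s = c(30, Inf),
#'                                          reply = c("accept", "not_seen")))
#' @export
simulate_incident <- function(spec, distances, responses,
                              cfg = sim_config(), speed = speed_model(),
                              surv = survival_model()) {
  stopifnot(inherits(spec, "cfr_policy"), is.numeric(distances),
            is.data.frame(responses), nrow(responses) == length(distances),
            !is.unsorted(distances))
  code <- reply_codes(responses$reply)
  delay <- as.numeric(responses$view_delay_s)
  travel_s <- 60 * travel_time_min(distances, speed)
  at <- alert_times_core(spec, delay, code)
  m <- incident_metrics(at, delay, code, travel_s, cfg, surv)
  tibble::tibble(
    first_arrival_s = m$first_arrival_s,
    n_alerts = m$n_alerts,
    n_arrivals = m$n_arrivals,
    covered_5min = m$covered,
    survival_prob = m$survival
  )
}

# Vectorised inner loop for the static families (all alerts at t = 0):
# matrices are n_inner x k.
static_inner <- function(k, delay_m, code_m, travel_s) {
  n_inner <- nrow(delay_m)
  if (k == 0L) {
    first <- rep(Inf, n_inner)
    n_arr <- rep(0L, n_inner)
  } else {
    acc <- code_m[, seq_len(k), drop = FALSE] == ACCEPT
    arr <- delay_m[, seq_len(k), drop = FALSE] +
      matrix(travel_s[seq_len(k)], n_inner, k, byrow = TRUE)
    arr[!acc] <- Inf
    first <- do.call(pmin, lapply(seq_len(k), function(j) arr[, j]))
    n_arr <- rowSums(acc)
  }
  list(first = first, n_alerts = rep(k, n_inner), n_arr = n_arr)
}

event_inner <- function(spec, delay_m, code_m, travel_s) {
  n_inner <- nrow(delay_m)
  first <- numeric(n_inner)
  n_alerts <- integer(n_inner)
  n_arr <- integer(n_inner)
  for (r in seq_len(n_inner)) {
    delay <- delay_m[r, ]
    code <- code_m[r, ]
    at <- alert_times_core(spec, delay, code)
    alerted <- !is.na(at)
    acc <- alerted & code == ACCEPT
    first[r] <- if (any(acc)) min(at[acc] + delay[acc] + travel_s[acc]) else Inf
    n_alerts[r] <- sum(alerted)
    n_arr[r] <- sum(acc)
  }
  list(first = first, n_alerts = n_alerts, n_arr = n_arr)
}

#' Run the nested Monte Carlo for one policy
#'
#' Draws `n_outer` volunteer location sets and, for each, `n_inner` joint
#' (view delay, reply) vectors; resolves each incident under the policy and
#' records inner-mean KPIs per outer replication (the unit over which
#' confidence intervals are computed). Fully deterministic given
#' `cfg$master_seed`: each replication's distance and behavior streams are
#' derived by a fixed label-based splitting scheme, so results do not depend
#' on which other policies are run.
#'
#' @param spec A [policy()] or policy string (see [parse_policy()]).
#' @param disk A [disk_config()].
#' @param behavior A [behavior_model()].
#' @param cfg A [sim_config()].
#' @param speed A [speed_model()].
#' @param surv A [survival_model()].
#' @param couple If `TRUE`, use common random numbers: the behavior stream is
#'   keyed only by the replication (not the policy), so every policy run with
#'   `couple = TRUE` and the same seed sees identical per-rank responses —
#'   sharpening policy comparisons. Default `FALSE` (independent streams).
#' @param keep_raw If `TRUE`, also keep per-incident results (can be large).
#' @return A `cfr_sim` object; [tidy()] returns the per-outer-replication
#'   inner means, [glance()] / [aggregate_kpis()] the one-row KPI summary.
#' @examples
#' sim <- run_policy("keep:3", disk_config(10), cfg = sim_config(20, 50))
#' glance(sim)
#' @export
run_policy <- function(spec, disk, behavior = behavior_model(),
                       cfg = sim_config(), speed = speed_model(),
                       surv = survival_model(), couple = FALSE,
                       keep_raw = FALSE) {
  if (is.character(spec)) spec <- parse_policy(spec)
  stopifnot(inherits(spec, "cfr_policy"), inherits(disk, "cfr_disk"),
            inherits(behavior, "cfr_behavior"), inherits(cfg, "cfr_sim_config"))
  n <- disk$n_volunteers
  static <- spec$family %in% c("send_all", "send_n1")
  b_key <- if (couple) "common" else spec$string

  outer <- vector("list", cfg$n_outer)
  raw <- if (keep_raw) vector("list", cfg$n_outer)
  for (i in seq_len(cfg$n_outer)) {
    distances <- sample_distances(disk, derive_seed(cfg$master_seed, "disk", i))
    travel_s <- 60 * travel_time_min(distances, speed)
    draws <- with_seed(derive_seed(cfg$master_seed, "behavior", b_key, i),
                       draw_codes(behavior, cfg$n_inner * n))
    delay_m <- matrix(draws$delay, nrow = cfg$n_inner, ncol = n)
    code_m <- matrix(draws$code, nrow = cfg$n_inner, ncol = n)
    res <- if (static) {
      k <- if (spec$family == "send_all") n else min(spec$n1, n)
      static_inner(k, delay_m, code_m, travel_s)
    } else {
      event_inner(spec, delay_m, code_m, travel_s)
    }
    t_cpr_min <- pmin((cfg$witness_delay_s + cfg$triage_delay_s + res$first) / 60,
                      cfg$t_ems_min)
    sp <- survival_prob(t_cpr_min, cfg$t_ems_min, surv)
    covered <- res$first <= cfg$coverage_threshold_s
    outer[[i]] <- tibble::tibble(
      outer_rep = i,
      coverage = mean(covered),
      survival = mean(sp),
      alerts = mean(res$n_alerts),
      redundant = mean(pmax(res$n_arr - 1L, 0L)),
      two_plus = mean(res$n_arr >= 2L)
    )
    if (keep_raw) {
      raw[[i]] <- tibble::tibble(
        outer_rep = i, inner_rep = seq_len(cfg$n_inner),
        first_arrival_s = res$first, n_alerts = res$n_alerts,
        n_arrivals = res$n_arr, covered_5min = covered, survival_prob = sp
      )
    }
  }
  structure(
    list(policy = spec, disk = disk, cfg = cfg,
         outer = dplyr::bind_rows(outer),
         raw = if (keep_raw) dplyr::bind_rows(raw)),
    class = "cfr_sim"
  )
}

#' @export
print.cfr_sim <- function(x, ...) {
  cat(sprintf("<cfr_sim> %s, n = %d volunteers, %d x %d replications\n",
              x$policy$label, x$disk$n_volunteers,
              x$cfg$n_outer, x$cfg$n_inner))
  print(aggregate_kpis(x))
  invisible(x)
}

#' @rdname run_policy
#' @param x,... A `cfr_sim` object; further arguments are ignored.
#' @method tidy cfr_sim
#' @export
tidy.cfr_sim <- function(x, ...) x$outer

#' @rdname run_policy
#' @method glance cfr_sim
#' @export
glance.cfr_sim <- function(x, ...) aggregate_kpis(x)

#' Run several policies and collect their KPI rows
#'
#' Pipe-friendly batch runner: takes a policy table (e.g. from
#' [enumerate_policies()], possibly filtered) and returns one KPI row per
#' policy.
#'
#' @param policies A data frame with a `spec` list-column of [policy()]
#'   objects (or a `string` column of policy strings), or a character vector
#'   of policy strings.
#' @inheritParams run_policy
#' @return A tibble of KPI rows (see [aggregate_kpis()]), one per policy, in
#'   input order. A `cfr_kpi_table` for [autoplot()].
#' @examples
#' enumerate_policies() |>
#'   dplyr::filter(family == "keep_n2") |>
#'   head(3) |>
#'   run_policies(disk_config(10), cfg = sim_config(10, 50))
#' @export
run_policies <- function(policies, disk, behavior = behavior_model(),
                         cfg = sim_config(), speed = speed_model(),
                         surv = survival_model(), couple = FALSE) {
  specs <- if (is.character(policies)) {
    lapply(policies, parse_policy)
  } else if (is.data.frame(policies) && "spec" %in% names(policies)) {
    policies$spec
  } else if (is.data.frame(policies) && "string" %in% names(policies)) {
    lapply(policies$string, parse_policy)
  } else {
    stop("policies must be a policy table or character vector", call. = FALSE)
  }
  rows <- purrr::map(specs, function(s) {
    aggregate_kpis(run_policy(s, disk, behavior, cfg, speed, surv,
                              couple = couple))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cfr_kpi_table", class(out))
  out
}
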