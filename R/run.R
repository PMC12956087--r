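#' Reproduce the policy-comparison KPI tables
#'
#' Runs the full policy set (see [enumerate_policies()]) for each volunteer
#' density and returns the KPI rows in the conventional table order:
#' send-all, keep 1-10, send 1-15, then the NZ batched policy. Send-n1
#' policies with `n1` larger than the number of volunteers in the disk are
#' omitted (they cannot differ from send-all).
#'
#' @param n_volunteers Volunteer counts per dispatch disk (default
#'   `c(10, 30, 100)`: low, medium, high density in a 1-km disk).
#' @param radius_m Dispatch-disk radius in meters (default 1000).
#' @param out_dir If non-`NULL`, one CSV per density
#'   (`kpi_n<volunteers>.csv`) is written there with columns `policy,
#'   coverage, survivors_per_year, n_alerts, redundant_arrivals, frac_2plus,
#'   max_ci_halfwidth_frac`.
#' @inheritParams run_policy
#' @return A `cfr_kpi_table` tibble with one row per (policy, density).
#' @examples
#' run_tables(n_volunteers = 10, cfg = sim_config(5, 20))
#' @export
run_tables <- function(n_volunteers = c(10, 30, 100), radius_m = 1000,
                       behavior = behavior_model(), cfg = sim_config(),
                       speed = speed_model(), surv = survival_model(),
                       couple = FALSE, out_dir = NULL) {
  pol <- enumerate_policies()
  pol <- pol[order(match(pol$family,
                         c("send_all", "keep_n2", "send_n1", "batched"))), ]
  per_density <- purrr::map(n_volunteers, function(n) {
    keep <- purrr::map_lgl(pol$spec, function(s) {
      s$family != "send_n1" || s$n1 <= n
    })
    tbl <- run_policies(pol[keep, ], disk_config(n, radius_m), behavior, cfg,
                        speed, surv, couple = couple)
    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      readr::write_csv(
        dplyr::select(tbl, "policy", "coverage", "survivors_per_year",
                      "n_alerts", "redundant_arrivals", "frac_2plus",
                      "max_ci_halfwidth_frac"),
        file.path(out_dir, sprintf("kpi_n%d.csv", n))
      )
    }
    tbl
  })
  out <- dplyr::bind_rows(per_density)
  class(out) <- c("cfr_kpi_table", class(out))
  out
}

#' Run one experiment and write its KPI table
#'
#' Thin convenience wrapper used by the command-line interface: runs a set of
#' policy strings at one density and optionally writes the KPI CSV.
#'
#' @param policy_strings Character vector of policy strings (see
#'   [parse_policy()]).
#' @param n Number of volunteers in the dispatch disk.
#' @param out Optional CSV output path.
#' @inheritParams run_tables
#' @return The KPI tibble, invisibly if `out` is given.
#' @export
run_experiment <- function(policy_strings, n, radius_m = 1000,
                           behavior = behavior_model(), cfg = sim_config(),
                           speed = speed_model(), surv = survival_model(),
                           couple = FALSE, out = NULL) {
  tbl <- run_policies(policy_strings, disk_config(n, radius_m), behavior, cfg,
                      speed, surv, couple = couple)
  if (!is.null(out)) {
    readr::write_csv(
      dplyr::select(tbl, "policy", "coverage", "survivors_per_year",
                    "n_alerts", "redundant_arrivals", "frac_2plus",
                    "max_ci_halfwidth_frac"),
      out
    )
    return(invisible(tbl))
  }
  tbl
}
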