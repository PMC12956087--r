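test_that("a single incident resolves timings per the response timeline", {
  # lone volunteer at 1000 m, sees the alert after 30 s and accepts:
  # arrival = 30 s + 4.7506 min travel = ~315.04 s, not covered at 300 s
  res <- simulate_incident(
    policy("send_all"), distances = 1000,
    responses = data.frame(view_delay_s = 30, reply = "accept")
  )
  expect_equal(res$first_arrival_s, 30 + 60 * (60000 / 12630), tolerance = 1e-9)
  expect_equal(res$first_arrival_s, 315.04, tolerance = 1e-4)
  expect_false(res$covered_5min)
  expect_equal(res$n_alerts, 1)
  expect_equal(res$n_arrivals, 1)
  # T_CPR = (60 + 124 + 315.04)/60 min, below the 13-min ambulance time
  t_cpr <- (60 + 124 + res$first_arrival_s) / 60
  expect_equal(res$survival_prob, survival_prob(t_cpr, 13), tolerance = 1e-12)
})

test_that("incidents with no arrivals fall back to the ambulance baseline", {
  none <- simulate_incident(policy("send_all"), distances = numeric(0),
                            responses = data.frame(view_delay_s = numeric(0),
                                                   reply = character(0)))
  expect_identical(none$first_arrival_s, Inf)
  expect_equal(none$n_alerts, 0)
  expect_false(none$covered_5min)
  expect_equal(none$survival_prob, survival_prob(13, 13), tolerance = 1e-12)

  unseen <- simulate_incident(
    policy("send_all"), distances = c(100, 500),
    responses = data.frame(view_delay_s = c(Inf, Inf),
                           reply = c("not_seen", "not_seen"))
  )
  expect_identical(unseen$first_arrival_s, Inf)
  expect_equal(unseen$n_arrivals, 0)
  expect_equal(unseen$n_alerts, 2)
})

test_that("runs are reproducible and independent of other policies run", {
  cfg <- sim_config(n_outer = 3, n_inner = 40, master_seed = 11)
  a <- run_policy("keep:2", disk_config(8), cfg = cfg)
  b <- run_policy("keep:2", disk_config(8), cfg = cfg)
  expect_identical(a$outer, b$outer)

  # the distance stream is keyed by replication, not by policy
  c_ <- run_policy("send:2", disk_config(8), cfg = cfg)
  expect_false(identical(a$outer, c_$outer))
})

test_that("send-all alerts everyone; keep-1 never produces redundancy", {
  cfg <- sim_config(n_outer = 4, n_inner = 100, master_seed = 2)
  sall <- run_policy("send_all", disk_config(10), cfg = cfg, keep_raw = TRUE)
  expect_true(all(sall$raw$n_alerts == 10))

  k1 <- run_policy("keep:1", disk_config(10), cfg = cfg, keep_raw = TRUE)
  expect_true(all(k1$raw$n_arrivals <= 1))
  kpi <- glance(k1)
  expect_equal(kpi$redundant_arrivals, 0)
  expect_equal(kpi$frac_2plus, 0)
})

test_that("arrival counts never exceed alert counts and KPIs are fractions", {
  cfg <- sim_config(n_outer = 3, n_inner = 80, master_seed = 5)
  for (pstr in c("send:4", "keep:4", "batched:3:60")) {
    sim <- run_policy(pstr, disk_config(12), cfg = cfg, keep_raw = TRUE)
    expect_true(all(sim$raw$n_arrivals <= sim$raw$n_alerts))
    kpi <- glance(sim)
    expect_true(kpi$coverage >= 0 && kpi$coverage <= 1)
    expect_true(kpi$frac_2plus >= 0 && kpi$frac_2plus <= 1)
    expect_true(kpi$survivors_per_year >= round(survival_prob(13, 13) * 5141))
  }
})

test_that("send-all matches the closed-form redundancy oracle", {
  n <- 10
  cfg <- sim_config(n_outer = 20, n_inner = 500, master_seed = 17)
  sim <- run_policy("send_all", disk_config(n), cfg = cfg)
  kpi <- glance(sim)
  # Monte Carlo standard errors from the outer means
  se_red <- stats::sd(sim$outer$redundant) / sqrt(cfg$n_outer)
  se_two <- stats::sd(sim$outer$two_plus) / sqrt(cfg$n_outer)
  expect_lt(abs(kpi$redundant_arrivals - expected_redundant(n, P_ACCEPT)),
            4 * se_red)
  expect_lt(abs(kpi$frac_2plus - prob_two_plus(n, P_ACCEPT)), 4 * se_two)
})

test_that("coupled runs make survival and coverage monotone in n1 and n2", {
  cfg <- sim_config(n_outer = 5, n_inner = 200, master_seed = 23)
  disk <- disk_config(12)
  send <- purrr::map(sprintf("send:%d", 1:6), function(p) {
    glance(run_policy(p, disk, cfg = cfg, couple = TRUE))
  })
  keep <- purrr::map(sprintf("keep:%d", 1:6), function(p) {
    glance(run_policy(p, disk, cfg = cfg, couple = TRUE))
  })
  for (kpis in list(send, keep)) {
    tbl <- dplyr::bind_rows(kpis)
    expect_true(all(diff(tbl$survivors_per_year) >= 0))
    expect_true(all(diff(tbl$coverage) >= 0))
    expect_true(all(diff(tbl$n_alerts) >= 0))
  }
})

test_that("keep-k dominates send-k incident by incident under coupling", {
  cfg <- sim_config(n_outer = 4, n_inner = 150, master_seed = 29)
  disk <- disk_config(15)
  for (k in c(2, 5)) {
    keep <- run_policy(sprintf("keep:%d", k), disk, cfg = cfg,
                       couple = TRUE, keep_raw = TRUE)
    send <- run_policy(sprintf("send:%d", k), disk, cfg = cfg,
                       couple = TRUE, keep_raw = TRUE)
    expect_true(all(keep$raw$n_alerts >= send$raw$n_alerts))
    expect_true(all(keep$raw$first_arrival_s <= send$raw$first_arrival_s))
  }
})

test_that("zero-volunteer runs reproduce the no-CFR reference row", {
  sim <- run_policy("send_all", disk_config(0),
                    cfg = sim_config(n_outer = 2, n_inner = 10))
  kpi <- glance(sim)
  expect_equal(kpi$coverage, 0)
  expect_equal(kpi$n_alerts, 0)
  expect_equal(kpi$redundant_arrivals, 0)
  expect_equal(round(kpi$survivors_per_year), 98)
})
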