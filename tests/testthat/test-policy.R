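test_that("the study policy set enumerates to 27 with a 10-minute cutoff", {
  pol <- enumerate_policies()
  expect_equal(nrow(pol), 27)
  counts <- table(factor(pol$family,
                         c("send_all", "send_n1", "keep_n2", "batched")))
  expect_equal(as.integer(counts), c(1, 15, 10, 1))
  expect_true(all(purrr::map_dbl(pol$spec, "cutoff_s") == 600))
  expect_true(!anyDuplicated(pol$string))
})

test_that("policy strings parse and label correctly", {
  expect_equal(parse_policy("keep:7")$label, "Keep 7 alerts active.")
  expect_equal(parse_policy("keep:1")$label, "Keep 1 alert active.")
  expect_equal(parse_policy("send:3")$label, "Send 3 alerts at time 0.")
  expect_equal(parse_policy("batched:3:60")$label, "NZ current strategy.")
  expect_equal(parse_policy("send_all")$family, "send_all")
  expect_equal(parse_policy("batched:5:30")$batch_interval_s, 30)
  expect_error(parse_policy("keep:x"), "invalid")
  expect_error(parse_policy("nope"), "unknown")
  expect_error(policy("send_n1"), "n1")
})

test_that("static policies alert the closest ranks at time zero", {
  stream <- random_stream(10)
  all10 <- schedule_alerts(parse_policy("send_all"), stream$delay, stream$reply)
  expect_equal(all10$rank, 1:10)
  expect_true(all(all10$alert_time_s == 0))

  five <- schedule_alerts(parse_policy("send:7"), stream$delay[1:5],
                          stream$reply[1:5])
  expect_equal(nrow(five), 5) # pool exhaustion: only 5 available
})

test_that("keep-n replacement follows the hand-traced examples", {
  # closest rejects after 30 s, replacement accepts at 75 s
  out <- schedule_alerts(policy("keep_n2", n2 = 1),
                         view_delay_s = c(30, 45, 100),
                         reply = c("reject", "accept", "accept"))
  expect_equal(out$rank, c(1, 2))
  expect_equal(out$alert_time_s, c(0, 30))

  # a reject is only replaced strictly before the cutoff
  out2 <- schedule_alerts(policy("keep_n2", n2 = 1),
                          view_delay_s = c(650, 10),
                          reply = c("reject", "accept"))
  expect_equal(out2$rank, 1)

  # not-seen alerts never trigger a replacement
  out3 <- schedule_alerts(policy("keep_n2", n2 = 2),
                          view_delay_s = c(Inf, Inf, 5),
                          reply = c("not_seen", "not_seen", "accept"))
  expect_equal(out3$rank, c(1, 2))
})

test_that("the batched policy sends three per minute until accept or cutoff", {
  nz <- policy("batched")
  # no accepts, ample pool: 3 alerts at each of 0, 60, ..., 540; none at 600
  out <- schedule_alerts(nz, rep(Inf, 40), rep("not_seen", 40))
  expect_equal(nrow(out), 30)
  expect_equal(sort(unique(out$alert_time_s)), seq(0, 540, by = 60))

  # an accept at 90 s stops batches from 120 s on
  delays <- c(90, rep(Inf, 20)); replies <- c("accept", rep("not_seen", 20))
  out2 <- schedule_alerts(nz, delays, replies)
  expect_equal(sort(unique(out2$alert_time_s)), c(0, 60))
  expect_equal(nrow(out2), 6)

  # a batch due exactly at the accept instant is not sent
  delays3 <- c(60, rep(Inf, 20))
  out3 <- schedule_alerts(nz, delays3, c("accept", rep("not_seen", 20)))
  expect_equal(nrow(out3), 3)

  # pool-limited at low density
  out4 <- schedule_alerts(nz, rep(Inf, 4), rep("not_seen", 4))
  expect_equal(nrow(out4), 4)
})

test_that("event-driven schedules agree with a discrete-time oracle", {
  set.seed(99)
  for (case in 1:60) {
    n <- sample(1:30, 1)
    s <- random_stream(n)
    spec <- if (case %% 2 == 0) {
      policy("keep_n2", n2 = sample(1:5, 1))
    } else {
      policy("batched", batch_size = sample(1:4, 1),
             batch_interval_s = sample(c(30, 60, 90), 1))
    }
    got <- schedule_alerts(spec, s$delay, s$reply)
    want <- oracle_alert_times(spec, s$delay, s$reply)
    expect_equal(got$rank, which(!is.na(want)))
    expect_equal(got$alert_time_s, want[!is.na(want)])
  }
})

test_that("schedules respect the global invariants", {
  set.seed(7)
  for (case in 1:40) {
    n <- sample(1:25, 1)
    s <- random_stream(n)
    spec <- list(policy("send_all"),
                 policy("send_n1", n1 = sample(1:15, 1)),
                 policy("keep_n2", n2 = sample(1:10, 1)),
                 policy("batched"))[[sample(4, 1)]]
    out <- schedule_alerts(spec, s$delay, s$reply)
    at <- out$alert_time_s
    # alerted ranks are a prefix of the distance order, alerted in order
    expect_equal(out$rank, seq_len(nrow(out)))
    expect_true(all(diff(at) >= 0))
    # no alert at or after the cutoff or the first induced accept
    dec <- at + s$delay[out$rank]
    first_accept <- suppressWarnings(min(dec[s$reply[out$rank] == "accept"]))
    # strict: every alert precedes the first accept decision (delays >= 1 s)
    expect_true(all(at < pmin(first_accept, 600)))
  }
})

test_that("send n1 = n, keep n2 = n and send-all are the same policy", {
  set.seed(21)
  for (case in 1:25) {
    n <- sample(1:20, 1)
    s <- random_stream(n)
    a <- schedule_alerts(policy("send_all"), s$delay, s$reply)
    b <- schedule_alerts(policy("send_n1", n1 = n), s$delay, s$reply)
    c_ <- schedule_alerts(policy("keep_n2", n2 = n), s$delay, s$reply)
    expect_identical(a, b)
    expect_identical(a, c_)
  }
})

test_that("alert counts are monotone in n1 and dominate send-k under keep-k", {
  # Note: keep-n2 alert counts are NOT monotone in n2 stream by stream — a
  # larger n2 can reach a fast accepter sooner and cut off replacement alerts
  # the smaller n2 would have sent. Monotonicity holds in the mean (checked
  # at the engine level); here we check the per-stream guarantees.
  set.seed(31)
  for (case in 1:15) {
    n <- sample(5:25, 1)
    s <- random_stream(n)
    send_counts <- vapply(1:15, function(k) {
      nrow(schedule_alerts(policy("send_n1", n1 = k), s$delay, s$reply))
    }, numeric(1))
    keep_counts <- vapply(1:10, function(k) {
      nrow(schedule_alerts(policy("keep_n2", n2 = k), s$delay, s$reply))
    }, numeric(1))
    expect_true(all(diff(send_counts) >= 0))
    # keep-k alerts at least as many volunteers as send-k on every stream
    expect_true(all(keep_counts >= send_counts[1:10]))
  }
})

test_that("inconsistent response vectors are rejected", {
  expect_error(
    schedule_alerts(policy("send_all"), view_delay_s = c(10, 20),
                    reply = c("not_seen", "accept")),
    "infinite view delay"
  )
  expect_error(
    schedule_alerts(policy("send_all"), view_delay_s = 10, reply = "maybe"),
    "unknown reply"
  )
})
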