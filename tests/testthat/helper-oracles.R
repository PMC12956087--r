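# Independent oracles and fixture builders used across the test files.

# Closed forms for the send-all policy with independent acceptance
# probability p per volunteer: expected redundant arrivals and the
# probability of two or more arrivals.
expected_redundant <- function(n, p) n * p - (1 - (1 - p)^n)
prob_two_plus <- function(n, p) 1 - (1 - p)^n - n * p * (1 - p)^(n - 1)

# Empirical acceptance probability of the default synthetic behavior model
# (the printed accept count over the printed total).
P_ACCEPT <- (4009 + 1199) / 29307

# Discrete-time reference scheduler: steps through integer seconds and
# applies the alerting rules literally. Only valid for strictly positive
# integer view delays (so a replacement alerted at t cannot also decide at
# t). Independent of the event-driven implementation under test.
oracle_alert_times <- function(spec, delay, reply) {
  code <- match(reply, c("accept", "reject", "not_seen"))
  n <- length(delay)
  at <- rep(NA_real_, n)
  cutoff <- spec$cutoff_s
  m <- min(if (spec$family == "keep_n2") spec$n2 else spec$batch_size, n)
  if (m > 0) at[seq_len(m)] <- 0
  for (t in 0:cutoff) {
    dec <- which(!is.na(at) & is.finite(delay) & at + delay == t)
    if (any(code[dec] == 1L)) break          # accept stops all alerting
    if (spec$family == "keep_n2") {
      for (d in dec[code[dec] == 2L]) {
        nxt <- which(is.na(at))[1]
        if (!is.na(nxt) && t < cutoff) at[nxt] <- t
      }
    } else if (spec$family == "batched") {
      if (t > 0 && t %% spec$batch_interval_s == 0 && t < cutoff) {
        pool <- which(is.na(at))
        if (length(pool)) {
          at[pool[seq_len(min(spec$batch_size, length(pool)))]] <- t
        }
      }
    }
  }
  at
}

# Random prospective-response vectors (strictly positive integer delays, so
# the discrete-time oracle is exact).
random_stream <- function(n, p_accept = 0.3, p_reject = 0.3) {
  u <- runif(n)
  reply <- ifelse(u < p_accept, "accept",
                  ifelse(u < p_accept + p_reject, "reject", "not_seen"))
  delay <- ifelse(reply == "not_seen", Inf, sample(1:700, n, replace = TRUE))
  list(delay = delay, reply = reply)
}

# A response log in the CSV schema with exact category counts (possibly
# scaled down from the printed 4009/1199/7925/16174).
log_with_counts <- function(n_accept, n_dropped, n_reject, n_notseen) {
  reply <- rep(c("accepted", "accepted_dropped", "rejected", "not_seen"),
               c(n_accept, n_dropped, n_reject, n_notseen))
  n <- length(reply)
  alert <- seq_len(n) * 10
  delay <- rep(30, n)
  tibble::tibble(
    alert_time_s = alert,
    decision_time_s = ifelse(reply == "not_seen", NA_real_, alert + delay),
    reply = reply
  )
}

write_log <- function(log) {
  path <- tempfile(fileext = ".csv")
  write_response_log(log, path)
  path
}
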