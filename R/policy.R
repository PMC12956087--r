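#' Alerting policy specification
#'
#' An alerting policy decides who is alerted when, given the distance ranking
#' of volunteers and the replies received so far. Four families are
#' supported, all subject to two global stopping rules: no alert is sent
#' after a volunteer accepts, or once `cutoff_s` seconds (default 10 min)
#' have passed since system activation, whichever comes first. Closer
#' volunteers are always alerted before more distant ones.
#'
#' * `send_all`: alert every volunteer in the disk at time 0.
#' * `send_n1`: alert the `n1` closest volunteers at time 0, none after.
#' * `keep_n2`: alert the `n2` closest at time 0 and replace every incoming
#'   explicit reject, at the moment it arrives, with an alert to the next
#'   closest unalerted volunteer (not-seen alerts never trigger a
#'   replacement because they produce no reply).
#' * `batched`: alert `batch_size` volunteers at time 0 and `batch_size` more
#'   every `batch_interval_s` seconds while no one has accepted, time is
#'   before the cutoff, and unalerted volunteers remain. With `batch_size =
#'   3` and a 60-s interval this is GoodSAM New Zealand's current policy.
#'
#' @param family One of `"send_all"`, `"send_n1"`, `"keep_n2"`, `"batched"`.
#' @param n1 Number of alerts at time 0 (`send_n1` family).
#' @param n2 Number of alerts kept active (`keep_n2` family).
#' @param batch_size,batch_interval_s Batch size and inter-batch lag in
#'   seconds (`batched` family; defaults 3 and 60).
#' @param cutoff_s Hard stop for sending alerts, seconds (default 600).
#' @param label Row label used in KPI tables; defaults to the conventional
#'   name of the policy.
#' @return A `cfr_policy` object.
#' @examples
#' policy("keep_n2", n2 = 7)
#' parse_policy("batched:3:60")
#' @export
policy <- function(family = c("send_all", "send_n1", "keep_n2", "batched"),
                   n1 = NULL, n2 = NULL,
                   batch_size = 3, batch_interval_s = 60,
                   cutoff_s = 600, label = NULL) {
  family <- match.arg(family)
  stopifnot(is.numeric(cutoff_s), cutoff_s > 0)
  chk_count <- function(x, nm) {
    if (is.null(x) || !is.numeric(x) || length(x) != 1L || x < 1 ||
        x != trunc(x)) {
      stop(sprintf("`%s` must be a positive integer for family %s", nm, family),
           call. = FALSE)
    }
    as.integer(x)
  }
  spec <- list(family = family, cutoff_s = as.numeric(cutoff_s))
  spec$n1 <- if (family == "send_n1") chk_count(n1, "n1")
  spec$n2 <- if (family == "keep_n2") chk_count(n2, "n2")
  if (family == "batched") {
    spec$batch_size <- chk_count(batch_size, "batch_size")
    stopifnot(is.numeric(batch_interval_s), batch_interval_s > 0)
    spec$batch_interval_s <- as.numeric(batch_interval_s)
  }
  spec$string <- switch(
    family,
    send_all = "send_all",
    send_n1 = sprintf("send:%d", spec$n1),
    keep_n2 = sprintf("keep:%d", spec$n2),
    batched = sprintf("batched:%d:%g", spec$batch_size, spec$batch_interval_s)
  )
  spec$label <- label %||% default_policy_label(spec)
  structure(spec, class = "cfr_policy")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

default_policy_label <- function(spec) {
  switch(
    spec$family,
    send_all = "Send all at time 0",
    send_n1 = sprintf("Send %d alerts at time 0.", spec$n1),
    keep_n2 = sprintf("Keep %d alert%s active.", spec$n2,
                      if (spec$n2 == 1L) "" else "s"),
    batched = if (spec$batch_size == 3L && spec$batch_interval_s == 60) {
      "NZ current strategy."
    } else {
      sprintf("Batch of %d every %g s.", spec$batch_size, spec$batch_interval_s)
    }
  )
}

#' @export
print.cfr_policy <- function(x, ...) {
  cat(sprintf("<cfr_policy> %s (%s; cutoff %g s)\n", x$label, x$string,
              x$cutoff_s))
  invisible(x)
}

#' Parse a policy string
#'
#' Accepts the compact syntax `send_all`, `send:<n1>`, `keep:<n2>` or
#' `batched:<size>:<interval_s>` (the New Zealand current policy is
#' `batched:3:60`).
#'
#' @param string Policy string.
#' @param cutoff_s Alerting cutoff in seconds (default 600).
#' @return A [policy()] object.
#' @export
parse_policy <- function(string, cutoff_s = 600) {
  stopifnot(is.character(string), length(string) == 1L)
  parts <- strsplit(string, ":", fixed = TRUE)[[1]]
  num <- function(i) {
    v <- suppressWarnings(as.numeric(parts[i]))
    if (is.na(v)) stop("invalid policy string: ", string, call. = FALSE)
    v
  }
  switch(
    parts[1],
    send_all = policy("send_all", cutoff_s = cutoff_s),
    send = policy("send_n1", n1 = num(2), cutoff_s = cutoff_s),
    keep = policy("keep_n2", n2 = num(2), cutoff_s = cutoff_s),
    batched = policy("batched", batch_size = num(2), batch_interval_s = num(3),
                     cutoff_s = cutoff_s),
    stop("unknown policy family in: ", string, call. = FALSE)
  )
}

#' Enumerate the study's 27 alerting policies
#'
#' Send-all, send-n1 for n1 = 1..15, keep-n2 for n2 = 1..10, and the New
#' Zealand batched policy (3 alerts per minute), all with a 10-minute
#' alerting cutoff.
#'
#' @param cutoff_s Alerting cutoff in seconds (default 600).
#' @return A tibble with one row per policy: `label`, `string`, `family`, and
#'   a `spec` list-column of [policy()] objects.
#' @examples
#' enumerate_policies()
#' @export
enumerate_policies <- function(cutoff_s = 600) {
  specs <- c(
    list(policy("send_all", cutoff_s = cutoff_s)),
    lapply(1:15, function(k) policy("send_n1", n1 = k, cutoff_s = cutoff_s)),
    lapply(1:10, function(k) policy("keep_n2", n2 = k, cutoff_s = cutoff_s)),
    list(policy("batched", cutoff_s = cutoff_s))
  )
  tibble::tibble(
    label = purrr::map_chr(specs, "label"),
    string = purrr::map_chr(specs, "string"),
    family = purrr::map_chr(specs, "family"),
    spec = specs
  )
}

# Core scheduler: alert times (seconds, NA = never alerted) for volunteers in
# distance order, given each volunteer's view delay (Inf = never seen) and
# reply code. Replies are induced events: volunteer k alerted at time a
# replies at a + delay[k]. Stopping rules: nothing is sent at or after the
# first accept decision, nor at or after the cutoff; a reject and an accept
# at the same instant resolve toward fewer alerts (accept wins).
alert_times_core <- function(spec, delay, code) {
  n <- length(delay)
  at <- rep(NA_real_, n)
  if (n == 0L) return(at)
  cutoff <- spec$cutoff_s

  if (spec$family == "send_all") {
    at[] <- 0
    return(at)
  }
  if (spec$family == "send_n1") {
    at[seq_len(min(spec$n1, n))] <- 0
    return(at)
  }

  if (spec$family == "keep_n2") {
    m <- min(spec$n2, n)
    at[seq_len(m)] <- 0
    next_rank <- m + 1L
    ev_t <- delay[seq_len(m)]          # decision times of alerted volunteers
    ev_v <- seq_len(m)
    repeat {
      live <- is.finite(ev_t)
      if (!any(live)) break
      tm <- min(ev_t[live])
      if (tm >= cutoff) break          # no alerts at or after the cutoff
      sel <- live & ev_t == tm
      if (any(code[ev_v[sel]] == ACCEPT)) break  # first accept stops alerting
      n_new <- min(sum(sel), n - next_rank + 1L)
      keep <- !sel
      ev_t <- ev_t[keep]; ev_v <- ev_v[keep]
      if (n_new > 0L) {
        idx <- next_rank:(next_rank + n_new - 1L)
        at[idx] <- tm
        ev_t <- c(ev_t, tm + delay[idx])
        ev_v <- c(ev_v, idx)
        next_rank <- next_rank + n_new
      }
      if (next_rank > n) break         # pool exhausted; schedule fixed
    }
    return(at)
  }

  # batched: only the earliest accept matters; rejects never spawn alerts
  m <- min(spec$batch_size, n)
  at[seq_len(m)] <- 0
  accept_at <- suppressWarnings(
    min(delay[seq_len(m)][code[seq_len(m)] == ACCEPT])
  )
  next_rank <- m + 1L
  t_batch <- spec$batch_interval_s
  while (next_rank <= n && t_batch < cutoff && t_batch < accept_at) {
    b <- min(spec$batch_size, n - next_rank + 1L)
    idx <- next_rank:(next_rank + b - 1L)
    at[idx] <- t_batch
    acc <- idx[code[idx] == ACCEPT]
    if (length(acc)) accept_at <- min(accept_at, t_batch + min(delay[acc]))
    next_rank <- next_rank + b
    t_batch <- t_batch + spec$batch_interval_s
  }
  at
}

#' Resolve the alert schedule for one incident
#'
#' Given a policy and each volunteer's prospective response — the view delay
#' they would take and the reply they would give if alerted — computes when
#' (and whether) each volunteer is alerted. Volunteers are indexed by
#' distance rank (rank 1 = closest); a volunteer's reply event occurs at
#' their alert time plus their view delay, which makes the schedule a
#' well-defined fixed point. The alerted ranks always form a prefix of the
#' distance order, and no alert is sent at or after the first accept or the
#' cutoff.
#'
#' @param spec A [policy()].
#' @param view_delay_s Numeric vector of view delays in seconds per rank
#'   (`Inf` for an alert that would never be seen).
#' @param reply Character vector (`accept`/`reject`/`not_seen`) per rank.
#' @return A tibble of alert events: `rank`, `alert_time_s`, ordered by rank,
#'   one row per alerted volunteer.
#' @examples
#' # keep-1: the closest volunteer rejects after 30 s, the replacement accepts
#' schedule_alerts(policy("keep_n2", n2 = 1),
#'                 view_delay_s = c(30, 45), reply = c("reject", "accept"))
#' @export
schedule_alerts <- function(spec, view_delay_s, reply) {
  stopifnot(inherits(spec, "cfr_policy"),
            length(view_delay_s) == length(reply))
  code <- reply_codes(reply)
  if (any(code == NOT_SEEN & is.finite(view_delay_s))) {
    stop("not_seen replies must have infinite view delay", call. = FALSE)
  }
  at <- alert_times_core(spec, as.numeric(view_delay_s), code)
  alerted <- which(!is.na(at))
  tibble::tibble(rank = alerted, alert_time_s = at[alerted])
}
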