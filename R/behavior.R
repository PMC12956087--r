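# Reply categories. Internally replies are integer codes for speed in the
# simulation hot path; user-facing tibbles carry the character labels.
REPLY_LEVELS <- c("accept", "reject", "not_seen")
ACCEPT <- 1L
REJECT <- 2L
NOT_SEEN <- 3L

# Raw log vocabulary (accept-then-drop collapses to accept on load: dropped
# accepters still stopped further alerts in the live system).
LOG_REPLY_MAP <- c(
  accepted = "accept", accepted_dropped = "accept",
  rejected = "reject", not_seen = "not_seen"
)

reply_codes <- function(reply) {
  code <- match(reply, REPLY_LEVELS)
  if (anyNA(code)) {
    stop("unknown reply categories: ",
         paste(unique(reply[is.na(code)]), collapse = ", "), call. = FALSE)
  }
  code
}

#' Load a volunteer response log
#'
#' Reads a CSV of historical alert outcomes with columns `alert_time_s`,
#' `decision_time_s` and `reply` (one of `accepted`, `accepted_dropped`,
#' `rejected`, `not_seen`; times in seconds from system activation,
#' `decision_time_s` empty for alerts that were never seen). Rows with a
#' missing alert time are dropped. Both accept categories collapse to
#' `accept`; not-seen alerts get an infinite view delay.
#'
#' @param path Path to the response-log CSV (header required).
#' @return A tibble of response records with columns `view_delay_s`
#'   (seconds, `Inf` for not-seen) and `reply` (`accept`/`reject`/`not_seen`).
#' @seealso [make_synthetic_log()] to generate such a log,
#'   [behavior_model()] to bootstrap from the records.
#' @export
load_records <- function(path) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      alert_time_s = readr::col_double(),
      decision_time_s = readr::col_double(),
      reply = readr::col_character()
    )
  )
  if (!all(c("alert_time_s", "decision_time_s", "reply") %in% names(raw))) {
    stop("response log must have columns alert_time_s, decision_time_s, reply",
         call. = FALSE)
  }
  raw$.line <- seq_len(nrow(raw)) + 1L  # CSV line numbers (1 = header)

  bad_reply <- !raw$reply %in% names(LOG_REPLY_MAP)
  if (any(bad_reply)) {
    stop("unknown reply values at line(s) ",
         paste(head(raw$.line[bad_reply], 10), collapse = ", "), call. = FALSE)
  }

  kept <- raw[!is.na(raw$alert_time_s) & !is.nan(raw$alert_time_s), ]
  reply <- unname(LOG_REPLY_MAP[kept$reply])
  delay <- kept$decision_time_s - kept$alert_time_s
  delay[reply == "not_seen"] <- Inf

  missing_decision <- reply != "not_seen" & is.na(delay)
  if (any(missing_decision)) {
    stop("missing decision time for seen alert at line(s) ",
         paste(head(kept$.line[missing_decision], 10), collapse = ", "),
         call. = FALSE)
  }
  negative <- is.finite(delay) & delay < 0
  if (any(negative)) {
    stop("negative view delay at line(s) ",
         paste(head(kept$.line[negative], 10), collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(view_delay_s = as.numeric(delay), reply = reply)
  if (nrow(out) == 0L) {
    stop("no usable records after dropping rows with missing alert time",
         call. = FALSE)
  }
  out
}

# Marginal reply probabilities matching the printed GoodSAM NZ counts:
# 4009 accepted + 1199 accepted-then-dropped, 7925 rejected, 16174 not seen,
# of 29307 alerts (acceptance rate 17.77%).
default_reply_probs <- function() {
  c(accept = (4009 + 1199) / 29307,
    reject = 7925 / 29307,
    not_seen = 16174 / 29307)
}

# Intercept of the logistic acceptance-vs-log-delay curve such that the
# marginal P(accept | seen) matches `target` under Z = log(delay) ~
# N(meanlog, sdlog): solves E[plogis(a - slope * Z)] = target by quadrature.
calibrate_accept_intercept <- function(target, slope, meanlog, sdlog) {
  stopifnot(target > 0, target < 1)
  marginal <- function(a) {
    integrate(function(z) plogis(a - slope * z) * dnorm(z, meanlog, sdlog),
              meanlog - 10 * sdlog, meanlog + 10 * sdlog,
              rel.tol = 1e-10)$value
  }
  uniroot(function(a) marginal(a) - target,
          lower = -80, upper = 80, tol = 1e-12)$root
}

#' Volunteer response behavior model
#'
#' Models the joint distribution of a volunteer's view delay (time from alert
#' to reply) and reply category. Two modes:
#'
#' * `"bootstrap"`: draws whole records uniformly with replacement from a
#'   historical log (see [load_records()]), preserving the dependence between
#'   slow viewing and rejection.
#' * `"synthetic"`: a calibrated generator standing in for a log. Replies are
#'   seen with probability `1 - p_notseen`; seen view delays are log-normal
#'   (`delay_meanlog`, `delay_sdlog`); the probability of accepting declines
#'   logistically in log view delay with slope `accept_slope`, and the
#'   intercept is calibrated so the marginal acceptance probability equals
#'   `p_accept` exactly.
#'
#' Defaults reproduce the printed GoodSAM New Zealand marginals: acceptance
#' 17.77% (5208/29307), rejection 27.04%, not seen 55.19%, with a
#' right-skewed seen-delay distribution (median 30 s).
#'
#' @param mode `"synthetic"` or `"bootstrap"`.
#' @param records For bootstrap mode, a tibble as returned by
#'   [load_records()] (non-empty).
#' @param p_accept,p_reject,p_notseen Marginal reply probabilities
#'   (must sum to 1).
#' @param delay_meanlog,delay_sdlog Log-normal parameters of the seen view
#'   delay in seconds.
#' @param accept_slope Decline rate of acceptance per unit log view delay
#'   (>= 0; 0 makes acceptance independent of delay).
#' @return A `cfr_behavior` object for [draw_responses()] and [run_policy()].
#' @examples
#' m <- behavior_model()
#' draw_responses(m, 5, seed = 1)
#' @export
behavior_model <- function(mode = c("synthetic", "bootstrap"),
                           records = NULL,
                           p_accept = default_reply_probs()[["accept"]],
                           p_reject = default_reply_probs()[["reject"]],
                           p_notseen = default_reply_probs()[["not_seen"]],
                           delay_meanlog = log(30),
                           delay_sdlog = 1,
                           accept_slope = 1) {
  mode <- match.arg(mode)
  if (mode == "bootstrap") {
    if (is.null(records) || nrow(records) == 0L) {
      stop("bootstrap mode requires a non-empty records table", call. = FALSE)
    }
    stopifnot(all(c("view_delay_s", "reply") %in% names(records)))
    code <- reply_codes(records$reply)
    bad <- (code == NOT_SEEN) != is.infinite(records$view_delay_s)
    if (any(bad)) {
      stop("records violate: not_seen if and only if infinite view delay",
           call. = FALSE)
    }
    if (any(is.finite(records$view_delay_s) & records$view_delay_s < 0)) {
      stop("finite view delays must be non-negative", call. = FALSE)
    }
    return(structure(
      list(mode = "bootstrap",
           delay = as.numeric(records$view_delay_s),
           code = code,
           n_records = nrow(records)),
      class = "cfr_behavior"
    ))
  }
  probs <- c(p_accept, p_reject, p_notseen)
  stopifnot(all(probs >= 0), abs(sum(probs) - 1) < 1e-8,
            delay_sdlog > 0, accept_slope >= 0)
  p_seen <- p_accept + p_reject
  if (p_accept > 0 && p_accept >= p_seen) {
    stop("p_accept must be < p_accept + p_reject for a declining curve",
         call. = FALSE)
  }
  intercept <- if (p_accept == 0) -Inf else {
    calibrate_accept_intercept(p_accept / p_seen, accept_slope,
                               delay_meanlog, delay_sdlog)
  }
  structure(
    list(mode = "synthetic",
         p_accept = p_accept, p_reject = p_reject, p_notseen = p_notseen,
         delay_meanlog = delay_meanlog, delay_sdlog = delay_sdlog,
         accept_slope = accept_slope, accept_intercept = intercept),
    class = "cfr_behavior"
  )
}

#' @export
print.cfr_behavior <- function(x, ...) {
  if (x$mode == "bootstrap") {
    cat(sprintf("<cfr_behavior> bootstrap of %d records (acceptance %.4f)\n",
                x$n_records, mean(x$code == ACCEPT)))
  } else {
    cat(sprintf(
      "<cfr_behavior> synthetic: P(accept/reject/not_seen) = %.4f/%.4f/%.4f,\n  seen delay ~ logN(%.3f, %.3f) s, accept ~ logit(%.3f - %.3f log delay)\n",
      x$p_accept, x$p_reject, x$p_notseen,
      x$delay_meanlog, x$delay_sdlog, x$accept_intercept, x$accept_slope
    ))
  }
  invisible(x)
}

# Hot-path sampler: n joint (view delay, reply code) draws using the current
# RNG stream. Returns list(delay = numeric, code = integer).
draw_codes <- function(model, n) {
  if (n == 0L) return(list(delay = numeric(0), code = integer(0)))
  if (model$mode == "bootstrap") {
    idx <- sample.int(length(model$delay), n, replace = TRUE)
    return(list(delay = model$delay[idx], code = model$code[idx]))
  }
  seen <- runif(n) < (model$p_accept + model$p_reject)
  z <- rnorm(n, model$delay_meanlog, model$delay_sdlog)
  accept <- seen & (runif(n) < plogis(model$accept_intercept - model$accept_slope * z))
  delay <- ifelse(seen, exp(z), Inf)
  code <- ifelse(accept, ACCEPT, ifelse(seen, REJECT, NOT_SEEN))
  list(delay = delay, code = as.integer(code))
}

#' Draw joint (view delay, reply) responses
#'
#' Samples `n` volunteer responses from a [behavior_model()]. Delay and reply
#' are sampled jointly: in bootstrap mode a whole record is drawn with
#' replacement; in synthetic mode acceptance probability declines with view
#' delay, so fast viewers accept more often.
#'
#' @param model A [behavior_model()].
#' @param n Number of responses to draw.
#' @param seed Optional integer seed (global RNG state restored afterwards).
#' @return A tibble with columns `view_delay_s` and `reply`.
#' @export
draw_responses <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "cfr_behavior"), n >= 0)
  d <- with_seed(seed, draw_codes(model, as.integer(n)))
  tibble::tibble(view_delay_s = d$delay, reply = REPLY_LEVELS[d$code])
}

#' Generate a synthetic response log
#'
#' Produces a table in the response-log CSV schema (see [load_records()])
#' from a synthetic [behavior_model()]. The log is labelled synthetic: it
#' emulates the marginal reply frequencies, a right-skewed view-delay
#' distribution and the delay-dependent acceptance of a real alert log, but
#' not per-volunteer heterogeneity or time-of-day effects. Accepts are split
#' into `accepted` and `accepted_dropped` in the historical 4009:1199
#' proportion so a round trip through [load_records()] recovers the records.
#'
#' @param n_records Number of alert rows to generate (>= 0).
#' @param model A synthetic [behavior_model()].
#' @param seed Optional integer seed.
#' @param span_s Alert times are drawn uniformly over `[0, span_s]` seconds
#'   (default three years, mirroring a multi-year system log).
#' @return A tibble with columns `alert_time_s`, `decision_time_s`
#'   (`NA` for not-seen rows) and `reply` in the log vocabulary.
#' @seealso [write_response_log()]
#' @export
make_synthetic_log <- function(n_records, model = behavior_model(), seed = NULL,
                               span_s = 3 * 365 * 86400) {
  stopifnot(inherits(model, "cfr_behavior"), model$mode == "synthetic",
            n_records >= 0)
  n <- as.integer(n_records)
  with_seed(seed, {
    d <- draw_codes(model, n)
    alert <- runif(n, 0, span_s)
    dropped <- runif(n) < 1199 / (4009 + 1199)
    reply <- character(n)
    reply[d$code == ACCEPT] <- ifelse(dropped[d$code == ACCEPT],
                                      "accepted_dropped", "accepted")
    reply[d$code == REJECT] <- "rejected"
    reply[d$code == NOT_SEEN] <- "not_seen"
    tibble::tibble(
      alert_time_s = alert,
      decision_time_s = ifelse(is.finite(d$delay), alert + d$delay, NA_real_),
      reply = reply
    )
  })
}

#' Write a response log to CSV
#'
#' @param log A tibble in the schema of [make_synthetic_log()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_response_log <- function(log, path) {
  stopifnot(all(c("alert_time_s", "decision_time_s", "reply") %in% names(log)))
  readr::write_csv(log, path, na = "")
  invisible(path)
}
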