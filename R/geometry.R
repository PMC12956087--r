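#' Dispatch-disk configuration
#'
#' Volunteers are assumed to be located uniformly at random in a disk of
#' radius `radius_m` centred on the patient. Only the volunteer-patient
#' distance matters for dispatching (the patient sits at the centre), so
#' angles are never generated.
#'
#' @param n_volunteers Number of volunteers inside the disk (>= 0). The study
#'   densities correspond to 10, 30 and 100 volunteers in a 1-km disk.
#' @param radius_m Disk radius in meters (default 1000).
#' @return A `cfr_disk` list with fields `n_volunteers` and `radius_m`.
#' @examples
#' disk_config(30)
#' @export
disk_config <- function(n_volunteers, radius_m = 1000) {
  stopifnot(
    is.numeric(n_volunteers), length(n_volunteers) == 1L,
    n_volunteers >= 0, n_volunteers == trunc(n_volunteers),
    is.numeric(radius_m), length(radius_m) == 1L, radius_m > 0
  )
  structure(
    list(n_volunteers = as.integer(n_volunteers), radius_m = as.numeric(radius_m)),
    class = "cfr_disk"
  )
}

#' @export
print.cfr_disk <- function(x, ...) {
  cat(sprintf(
    "<cfr_disk> %d volunteers in a %.0f-m disk (%.2f vol/km^2)\n",
    x$n_volunteers, x$radius_m, density_of(x)
  ))
  invisible(x)
}

#' Distance-dependent volunteer travel speed
#'
#' Walking/running speed toward the patient as a linear function of the
#' straight-line distance: `speed_kmh = intercept_kmh + slope_kmh_per_m * x`
#' for distance `x` in meters. Defaults are the regression estimates from
#' GoodSAM New Zealand responder data (y = 1.83 + 0.0108 x, distances binned
#' in 100-m blocks, block medians regressed).
#'
#' @param intercept_kmh Speed at zero distance, km/h (> 0; default 1.83).
#' @param slope_kmh_per_m Speed increase per meter of distance, km/h per m
#'   (default 0.0108).
#' @param max_distance_m Largest distance the model must be valid for; the
#'   constructor rejects parameters implying non-positive speed anywhere in
#'   `[0, max_distance_m]`.
#' @return A `cfr_speed` list with the two coefficients.
#' @examples
#' speed_model()
#' travel_time_min(1000) # ~4.75 minutes at the default speeds
#' @export
speed_model <- function(intercept_kmh = 1.83, slope_kmh_per_m = 0.0108,
                        max_distance_m = 1000) {
  stopifnot(
    is.numeric(intercept_kmh), length(intercept_kmh) == 1L, intercept_kmh > 0,
    is.numeric(slope_kmh_per_m), length(slope_kmh_per_m) == 1L
  )
  if (intercept_kmh + slope_kmh_per_m * max_distance_m <= 0) {
    stop("speed model implies non-positive speed within [0, max_distance_m]",
         call. = FALSE)
  }
  structure(
    list(intercept_kmh = as.numeric(intercept_kmh),
         slope_kmh_per_m = as.numeric(slope_kmh_per_m)),
    class = "cfr_speed"
  )
}

#' @export
print.cfr_speed <- function(x, ...) {
  cat(sprintf("<cfr_speed> speed(x) = %.4g + %.4g x km/h (x in m)\n",
              x$intercept_kmh, x$slope_kmh_per_m))
  invisible(x)
}

#' Sample volunteer distances in the dispatch disk
#'
#' Draws `n_volunteers` patient-volunteer distances uniformly over the disk
#' area via the radial inverse CDF, `dist = R * sqrt(U)` (so `P(D <= d) =
#' (d/R)^2`), and returns them sorted ascending. The sort order defines the
#' alerting ranks: policies only alert a more distant volunteer once all
#' closer volunteers are already alerted.
#'
#' @param disk A [disk_config()].
#' @param seed Optional integer seed for a reproducible draw (the global RNG
#'   state is restored afterwards).
#' @return Numeric vector of distances in meters, sorted ascending (length
#'   `n_volunteers`; empty for zero volunteers).
#' @examples
#' sample_distances(disk_config(10), seed = 1)
#' @export
sample_distances <- function(disk, seed = NULL) {
  stopifnot(inherits(disk, "cfr_disk"))
  n <- disk$n_volunteers
  if (n == 0L) return(numeric(0))
  with_seed(seed, sort(disk$radius_m * sqrt(runif(n))))
}

#' Convert distance to travel time
#'
#' Travel time in minutes for a volunteer covering `distance_m` meters at the
#' distance-dependent speed of [speed_model()]:
#' `t(x) = 60 x / (1000 * intercept + 1000 * slope * x)` minutes, i.e.
#' `60x / (1830 + 10.8x)` with the default coefficients.
#'
#' @param distance_m Distance(s) in meters (>= 0); vectorised.
#' @param model A [speed_model()].
#' @return Travel time(s) in minutes.
#' @examples
#' travel_time_min(c(0, 500, 1000))
#' @export
travel_time_min <- function(distance_m, model = speed_model()) {
  stopifnot(inherits(model, "cfr_speed"), is.numeric(distance_m))
  if (any(distance_m < 0, na.rm = TRUE)) {
    stop("distance_m must be non-negative", call. = FALSE)
  }
  speed_kmh <- model$intercept_kmh + model$slope_kmh_per_m * distance_m
  if (any(speed_kmh <= 0, na.rm = TRUE)) {
    stop("speed model implies non-positive speed at a requested distance",
         call. = FALSE)
  }
  60 * distance_m / (1000 * speed_kmh)
}

#' Fit the distance-dependent speed model from observed responses
#'
#' Reproduces the estimation procedure used for the published coefficients:
#' observations with zero travel time are excluded, distances are binned in
#' 100-m blocks, the 0-100 m block is dropped (short-range GPS fixes are
#' unreliable), the median speed (km/h) is taken per block, and ordinary
#' least squares regresses the block medians on the block midpoints
#' (150 m for the 100-200 m block, and so on).
#'
#' @param pairs Data frame with columns `distance_m` and `travel_time_s`.
#' @param block_width_m Bin width in meters (default 100).
#' @return A `cfr_speed_fit` object: the fitted [speed_model()] plus the
#'   per-block medians and the regression R^2. Supports [tidy()], [glance()]
#'   and [autoplot()].
#' @examples
#' d <- seq(150, 950, by = 100)
#' pairs <- data.frame(distance_m = d,
#'                     travel_time_s = 3.6 * d / (1.83 + 0.0108 * d))
#' glance(fit_speed_model(pairs))
#' @export
fit_speed_model <- function(pairs, block_width_m = 100) {
  stopifnot(is.data.frame(pairs),
            all(c("distance_m", "travel_time_s") %in% names(pairs)))
  usable <- dplyr::filter(
    tibble::as_tibble(pairs),
    !is.na(.data$distance_m), !is.na(.data$travel_time_s),
    .data$travel_time_s > 0
  )
  blocks <- usable |>
    dplyr::mutate(
      speed_kmh = 3.6 * .data$distance_m / .data$travel_time_s,
      block = floor(.data$distance_m / block_width_m)
    ) |>
    dplyr::filter(.data$block >= 1) |>
    dplyr::group_by(.data$block) |>
    dplyr::summarise(
      midpoint_m = (dplyr::first(.data$block) + 0.5) * block_width_m,
      median_speed_kmh = median(.data$speed_kmh),
      n_obs = dplyr::n(),
      .groups = "drop"
    )
  if (nrow(blocks) < 2L) {
    stop("fewer than 2 usable 100-m blocks after exclusions; cannot fit",
         call. = FALSE)
  }
  fit <- lm(median_speed_kmh ~ midpoint_m, data = blocks)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((blocks$median_speed_kmh - mean(blocks$median_speed_kmh))^2)
  structure(
    list(
      model = speed_model(coef(fit)[[1]], coef(fit)[[2]]),
      blocks = blocks,
      r_squared = 1 - ss_res / ss_tot,
      n_blocks = nrow(blocks),
      n_obs = nrow(usable)
    ),
    class = "cfr_speed_fit"
  )
}

#' @export
print.cfr_speed_fit <- function(x, ...) {
  cat(sprintf(
    "<cfr_speed_fit> speed(x) = %.4g + %.4g x km/h; R^2 = %.3f (%d blocks, %d obs)\n",
    x$model$intercept_kmh, x$model$slope_kmh_per_m,
    x$r_squared, x$n_blocks, x$n_obs
  ))
  invisible(x)
}

#' @rdname fit_speed_model
#' @param x,... A `cfr_speed_fit` object; further arguments are ignored.
#' @method tidy cfr_speed_fit
#' @export
tidy.cfr_speed_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept_kmh", "slope_kmh_per_m"),
    estimate = c(x$model$intercept_kmh, x$model$slope_kmh_per_m)
  )
}

#' @rdname fit_speed_model
#' @method glance cfr_speed_fit
#' @export
glance.cfr_speed_fit <- function(x, ...) {
  tibble::tibble(
    intercept_kmh = x$model$intercept_kmh,
    slope_kmh_per_m = x$model$slope_kmh_per_m,
    r.squared = x$r_squared,
    n_blocks = x$n_blocks,
    n_obs = x$n_obs
  )
}

#' Volunteer density implied by a dispatch disk
#'
#' @param disk A [disk_config()].
#' @return Volunteers per square kilometer, `n / (pi * (R/1000)^2)`; 10, 30
#'   and 100 volunteers in a 1-km disk give 3.18, 9.55 and 31.83 vol/km^2.
#' @examples
#' density_of(disk_config(10))
#' @export
density_of <- function(disk) {
  stopifnot(inherits(disk, "cfr_disk"))
  disk$n_volunteers / (pi * (disk$radius_m / 1000)^2)
}
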