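#' Construct a drying run
#'
#' A drying run is one thin-layer convective drying experiment: a tray of
#' sliced material weighed repeatedly while hot air at a fixed temperature
#' and velocity removes moisture. Weights are total tray load (dry matter
#' plus water), times are minutes from loading.
#'
#' @param run_id Character label for the run.
#' @param temperature Drying-air temperature, degrees Celsius (> 0).
#' @param thickness Full slice thickness, metres (> 0).
#' @param air_velocity Drying-air velocity, m/s (> 0).
#' @param initial_load Initial tray load, kg.
#' @param dry_mass Bone-dry matter mass, kg (0 < dry_mass < initial_load).
#' @param times Measurement times in minutes; strictly increasing, first 0.
#' @param weights Tray weights in kg, same length as `times`; never below
#'   `dry_mass`.
#' @param initial_moisture_db Initial dry-basis moisture content, kg water
#'   per kg dry matter.
#'
#' @return An object of class `drying_run`.
#' @export
#' @examples
#' run <- drying_run("demo", 60, 0.004, 1.5,
#'   initial_load = 0.88, dry_mass = 0.88 / (1 + 5.9812),
#'   times = c(0, 10, 20), weights = c(0.88, 0.85, 0.82),
#'   initial_moisture_db = 5.9812
#' )
#' moisture_from_weights(run)
drying_run <- function(run_id, temperature, thickness, air_velocity,
                       initial_load, dry_mass, times, weights,
                       initial_moisture_db) {
  stopifnot_scalar_pos(temperature, "temperature")
  stopifnot_scalar_pos(thickness, "thickness")
  stopifnot_scalar_pos(air_velocity, "air_velocity")
  stopifnot_scalar_pos(initial_load, "initial_load")
  stopifnot_scalar_pos(dry_mass, "dry_mass")
  stopifnot_scalar_pos(initial_moisture_db, "initial_moisture_db")
  times <- as.numeric(times)
  weights <- as.numeric(weights)
  if (length(times) != length(weights)) {
    abort("`times` and `weights` must have the same length.")
  }
  if (length(times) < 1L || times[1] != 0) {
    abort("`times` must start at 0.")
  }
  if (any(diff(times) <= 0)) {
    abort("`times` must be strictly increasing.")
  }
  bad <- which(weights < dry_mass)
  if (length(bad) > 0L) {
    abort(sprintf(
      "weight below dry mass at index %d (%.6g kg < %.6g kg)",
      bad[1], weights[bad[1]], dry_mass
    ))
  }
  structure(
    list(
      run_id = as.character(run_id), temperature = temperature,
      thickness = thickness, air_velocity = air_velocity,
      initial_load = initial_load, dry_mass = dry_mass,
      times = times, weights = weights,
      initial_moisture_db = initial_moisture_db
    ),
    class = "drying_run"
  )
}

#' @export
print.drying_run <- function(x, ...) {
  cat(sprintf(
    "<drying_run %s>  %g degC, %g mm, %g m/s\n  %d weighings over %g min, load %.3f kg (dry %.4f kg)\n",
    x$run_id, x$temperature, x$thickness * 1000, x$air_velocity,
    length(x$times), max(x$times), x$initial_load, x$dry_mass
  ))
  invisible(x)
}

#' Dry-basis moisture content from a weight series
#'
#' Converts tray weights to moisture content on a dry basis,
#' `M = (weight - dry_mass) / dry_mass` (kg water per kg dry matter).
#' A weight exactly equal to the dry mass gives zero moisture; a weight
#' below it is physically impossible and raises an error naming the index.
#'
#' @param run A [drying_run()].
#' @return A tibble with columns `time_min` and `moisture_db`.
#' @export
moisture_from_weights <- function(run) {
  stopifnot(inherits(run, "drying_run"))
  bad <- which(run$weights < run$dry_mass)
  if (length(bad) > 0L) {
    abort(sprintf("weight below dry mass at index %d", bad[1]))
  }
  tibble::tibble(
    time_min = run$times,
    moisture_db = (run$weights - run$dry_mass) / run$dry_mass
  )
}

#' Moisture ratio of a moisture series
#'
#' Normalizes a dry-basis moisture series to the dimensionless moisture
#' ratio `MR = (M - Me) / (M0 - Me)`. Drying air is far from saturation in
#' hot-air drying, so the equilibrium moisture `Me` defaults to 0, reducing
#' to `MR = M / M0`; `mr` is 1 at time zero by construction.
#'
#' @param series Tibble with columns `time_min`, `moisture_db` (as returned
#'   by [moisture_from_weights()]).
#' @param equilibrium Equilibrium moisture content `Me`, kg/kg d.b.
#'   Default 0.
#' @return A tibble with columns `time_min` and `mr`.
#' @export
moisture_ratio <- function(series, equilibrium = 0) {
  stopifnot(is.data.frame(series), all(c("time_min", "moisture_db") %in% names(series)))
  m0 <- series$moisture_db[1]
  if (m0 <= equilibrium) {
    abort("initial moisture must exceed the equilibrium moisture (division by zero).")
  }
  tibble::tibble(
    time_min = series$time_min,
    mr = (series$moisture_db - equilibrium) / (m0 - equilibrium)
  )
}

#' Drying rate between consecutive weighings
#'
#' First-difference drying rate `DR = (M_t - M_{t+dt}) / dt`, reported per
#' hour of drying (kg water per kg dry matter per hour) at the interval
#' midpoints. Positive values mean moisture loss.
#'
#' @inheritParams moisture_ratio
#' @return A tibble with columns `mid_time_min`, `dt_min` and `rate_per_h`.
#' @export
drying_rate <- function(series) {
  stopifnot(is.data.frame(series), all(c("time_min", "moisture_db") %in% names(series)))
  t <- series$time_min
  m <- series$moisture_db
  if (length(t) < 2L) abort("need at least two measurements for a drying rate.")
  dt <- diff(t)
  if (any(dt == 0)) abort("duplicated time points (zero interval) in series.")
  tibble::tibble(
    mid_time_min = (head(t, -1) + tail(t, -1)) / 2,
    dt_min = dt,
    rate_per_h = -diff(m) / dt * 60
  )
}
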