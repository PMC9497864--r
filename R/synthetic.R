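# Seeded synthetic drying runs emulating the study protocol: 0.88 kg of
# fresh slices at 598.12% d.b. initial moisture, weighed on a schedule that
# tightens early (10-min steps in hour 1, 20-min in hour 2, 30-min in hour
# 3, hourly after), drying until the moisture ratio falls to ~0.0205
# (final moisture ~12% d.b.), with additive Gaussian weighing noise.

#' Weighing schedule of a drying experiment
#'
#' Times in minutes: every 10 min during the first hour, every 20 min in
#' the second, every 30 min in the third, then hourly.
#'
#' @param total_minutes Last time to include (> 0); the schedule stops at
#'   the last grid point `<= total_minutes`.
#' @return Numeric vector of times starting at 0.
#' @export
#' @examples
#' sampling_schedule(180)
sampling_schedule <- function(total_minutes) {
  stopifnot_scalar_pos(total_minutes, "total_minutes")
  times <- 0
  while (tail(times, 1) + schedule_step(tail(times, 1)) <= total_minutes) {
    times <- c(times, tail(times, 1) + schedule_step(tail(times, 1)))
  }
  times
}

schedule_step <- function(t) {
  if (t < 60) 10 else if (t < 120) 20 else if (t < 180) 30 else 60
}

#' Configuration of one synthetic drying run
#'
#' Defaults reproduce the study conditions: diffusion-approach forward
#' model with the published parameter triple for the given condition,
#' initial moisture 5.9812 kg/kg d.b., 0.88 kg load, 1.5 m/s air, and a
#' stopping moisture ratio of 0.0205 (~12% d.b. final moisture).
#'
#' @param temperature Drying temperature, degC (one of 50/60/70/80 for the
#'   default generator model lookup).
#' @param thickness_mm Slice thickness, mm (2/4/6/8 for the default
#'   lookup).
#' @param generator_model Named list `list(model_id =, params =)` giving
#'   the forward model; default: the published diffusion-approach triple
#'   for (`temperature`, `thickness_mm`).
#' @param initial_moisture_db Initial moisture, kg/kg d.b.
#' @param initial_load Fresh load, kg.
#' @param air_velocity Air velocity, m/s.
#' @param noise_sd Additive weighing noise s.d., kg.
#' @param stop_mr Moisture ratio at which the run ends.
#' @param seed Integer seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(temperature, thickness_mm,
                             generator_model = NULL,
                             initial_moisture_db = 5.9812,
                             initial_load = 0.88, air_velocity = 1.5,
                             noise_sd = 1e-4, stop_mr = 0.0205,
                             seed = 1L) {
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  if (stop_mr <= 0 || stop_mr >= 1) abort("`stop_mr` must lie in (0, 1).")
  if (is.null(generator_model)) {
    pars <- plantain_model_parameters()
    row <- pars[pars$temperature == temperature &
      pars$thickness_mm == thickness_mm, ]
    if (nrow(row) != 1L) {
      abort(sprintf(
        "no default generator triple for %g degC / %g mm; supply `generator_model`.",
        temperature, thickness_mm
      ))
    }
    generator_model <- list(
      model_id = "diffusion_approach",
      params = c(a = row$a, k = row$k, b = row$b)
    )
  }
  structure(
    list(
      temperature = temperature, thickness_mm = thickness_mm,
      generator_model = generator_model,
      initial_moisture_db = initial_moisture_db,
      initial_load = initial_load, air_velocity = air_velocity,
      noise_sd = noise_sd, stop_mr = stop_mr, seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

#' Generate one synthetic drying run
#'
#' Evaluates the forward model on the weighing schedule until the moisture
#' ratio first reaches `stop_mr` (hard cap 1e5 min), converts to weights
#' via `dry_mass = initial_load / (1 + M0)` and
#' `weight = dry_mass * (1 + mr * M0)`, and adds seeded Gaussian weighing
#' noise. Noisy weights that would fall below the dry mass are clamped to
#' it; the number of clamped points is recorded in
#' `attr(run, "n_clamped")` with a warning.
#'
#' @param config A [synthetic_config()].
#' @param run_id Label; default derived from the condition.
#' @return A [drying_run()].
#' @export
#' @examples
#' run <- generate_run(synthetic_config(60, 4, seed = 7))
#' run
generate_run <- function(config, run_id = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  gm <- config$generator_model
  mr_at <- function(t) evaluate_model(gm$model_id, gm$params, t)

  cap <- 1e5
  times <- 0
  repeat {
    last <- tail(times, 1)
    if (mr_at(last) <= config$stop_mr) break
    nxt <- last + schedule_step(last)
    if (nxt > cap) {
      abort(sprintf(
        "generator model never reaches stop_mr = %g within %g min.",
        config$stop_mr, cap
      ))
    }
    times <- c(times, nxt)
  }

  m0 <- config$initial_moisture_db
  dry_mass <- config$initial_load / (1 + m0)
  mr <- mr_at(times)
  weights <- dry_mass * (1 + mr * m0)
  if (config$noise_sd > 0) {
    weights <- with_seed(
      config$seed,
      weights + rnorm(length(weights), 0, config$noise_sd)
    )
  }
  n_clamped <- sum(weights < dry_mass)
  if (n_clamped > 0) {
    warn(sprintf("%d noisy weights clamped at the dry mass.", n_clamped))
    weights <- pmax(weights, dry_mass)
  }

  if (is.null(run_id)) {
    run_id <- sprintf("T%g_th%gmm", config$temperature, config$thickness_mm)
  }
  run <- drying_run(
    run_id = run_id, temperature = config$temperature,
    thickness = config$thickness_mm / 1000,
    air_velocity = config$air_velocity,
    initial_load = config$initial_load, dry_mass = dry_mass,
    times = times, weights = weights, initial_moisture_db = m0
  )
  attr(run, "n_clamped") <- n_clamped
  attr(run, "generator_model") <- gm
  run
}

#' Generate the full 4 x 4 synthetic study
#'
#' One run per combination of temperature (50/60/70/80 degC) and slice
#' thickness (2/4/6/8 mm), each driven by its published
#' diffusion-approach triple, with per-run seeds derived deterministically
#' from `seed`.
#'
#' @param seed Integer master seed.
#' @param noise_sd Weighing noise s.d., kg (shared by all runs).
#' @param ... Further arguments passed to [synthetic_config()].
#' @return Named list of 16 [drying_run()] objects, ordered by thickness
#'   then temperature.
#' @export
generate_study <- function(seed = 1L, noise_sd = 1e-4, ...) {
  grid <- plantain_model_parameters()
  runs <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- synthetic_config(
      temperature = grid$temperature[i],
      thickness_mm = grid$thickness_mm[i],
      noise_sd = noise_sd,
      seed = (as.integer(seed) * 131L + i) %% .Machine$integer.max,
      ...
    )
    generate_run(cfg)
  })
  names(runs) <- vapply(runs, `[[`, character(1), "run_id")
  runs
}
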