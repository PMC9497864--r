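# Process energy consumption of a convective tray dryer: sensible heat
# delivered to the air stream over the drying time, per the
# ET = A * v * rho_a * Ca * dT * t balance, normalized by fresh load.

#' Dry-air density from the ideal-gas law
#'
#' `rho_a = 101.325 / (0.287 * Tabs)` (kg/m^3) at atmospheric pressure,
#' with the specific gas constant of dry air 0.287 kJ/(kg K).
#'
#' @param tabs Absolute temperature, K (> 0).
#' @return Air density, kg/m^3.
#' @export
air_density <- function(tabs) {
  if (any(tabs <= 0)) abort("`tabs` must be positive (kelvin).")
  101.325 / (0.287 * tabs)
}

#' Specific heat of dry air
#'
#' Quartic dry-air correlation
#' `Ca = 1.04841 - 3.83719e-4 T + 9.45378e-7 T^2 - 5.49031e-10 T^3 +
#'  7.92981e-14 T^4` (kJ/(kg K)), valid for 250-450 K.
#'
#' @param tabs Absolute temperature, K, within `[250, 450]`.
#' @return Specific heat, kJ/(kg K).
#' @export
air_specific_heat <- function(tabs) {
  if (any(tabs < 250 | tabs > 450)) {
    abort("`tabs` outside the 250-450 K validity range of the correlation.")
  }
  1.04841 - 3.83719e-4 * tabs + 9.45378e-7 * tabs^2 -
    5.49031e-10 * tabs^3 + 7.92981e-14 * tabs^4
}

#' Dryer configuration
#'
#' @param tray_area Tray area swept by the air stream, m^2. No default:
#'   dryer geometry must be stated explicitly.
#' @param air_velocity Airflow velocity, m/s.
#' @param ambient_temperature Reference temperature for the heater's
#'   temperature rise, degrees Celsius (default 25).
#' @param initial_load Fresh-material load, kg.
#' @return A list of class `dryer_config`.
#' @export
dryer_config <- function(tray_area, air_velocity = 1.5,
                         ambient_temperature = 25, initial_load = 0.88) {
  stopifnot_scalar_pos(tray_area, "tray_area")
  stopifnot_scalar_pos(air_velocity, "air_velocity")
  stopifnot_scalar_pos(ambient_temperature, "ambient_temperature")
  stopifnot_scalar_pos(initial_load, "initial_load")
  structure(
    list(
      tray_area = tray_area, air_velocity = air_velocity,
      ambient_temperature = ambient_temperature, initial_load = initial_load
    ),
    class = "dryer_config"
  )
}

#' Total process energy of a drying run
#'
#' `ET = A * v * rho_a * Ca * dT * t` with air properties evaluated at the
#' drying-air absolute temperature and `dT` the rise above ambient. With
#' A in m^2, v in m/s, rho_a in kg/m^3, Ca in kJ/(kg K) and dT in K the
#' product is a thermal power in kW, so multiplying by the drying time in
#' hours gives kWh.
#'
#' @param config A [dryer_config()].
#' @param drying_temperature Drying-air temperature, degrees Celsius; must
#'   exceed the ambient reference.
#' @param drying_time_h Drying time, hours (>= 0).
#' @return Total energy, kWh.
#' @export
#' @examples
#' cfg <- dryer_config(tray_area = 0.5)
#' total_energy(cfg, drying_temperature = 60, drying_time_h = 5)
total_energy <- function(config, drying_temperature, drying_time_h) {
  stopifnot(inherits(config, "dryer_config"))
  if (drying_time_h < 0) abort("`drying_time_h` must be non-negative.")
  dT <- drying_temperature - config$ambient_temperature
  if (dT <= 0) abort("drying temperature must exceed the ambient reference.")
  tabs <- drying_temperature + 273.15
  config$tray_area * config$air_velocity * air_density(tabs) *
    air_specific_heat(tabs) * dT * drying_time_h
}

#' Specific energy consumption
#'
#' Energy per kilogram of fresh material loaded, `Es = ET / Wi`.
#'
#' @param et Total energy, kWh.
#' @param initial_load Fresh load, kg (> 0).
#' @return Specific energy, kWh/kg.
#' @export
specific_energy <- function(et, initial_load) {
  stopifnot_scalar_pos(initial_load, "initial_load")
  et / initial_load
}

#' Energy report for a set of drying runs
#'
#' Drying time is taken as the span of each run's weighing schedule.
#'
#' @param runs List of [drying_run()] objects.
#' @param config A [dryer_config()]; the per-run `initial_load` and
#'   `air_velocity` recorded on each run are used, the tray area and
#'   ambient reference come from `config`.
#' @return Tibble: run_id, temperature, thickness_mm, t_h, rho_a, c_a,
#'   et_kWh, es_kWh_per_kg.
#' @export
energy_table <- function(runs, config) {
  stopifnot(inherits(config, "dryer_config"))
  dplyr::bind_rows(lapply(runs, function(run) {
    cfg <- dryer_config(
      tray_area = config$tray_area, air_velocity = run$air_velocity,
      ambient_temperature = config$ambient_temperature,
      initial_load = run$initial_load
    )
    t_h <- max(run$times) / 60
    tabs <- run$temperature + 273.15
    et <- total_energy(cfg, run$temperature, t_h)
    tibble::tibble(
      run_id = run$run_id, temperature = run$temperature,
      thickness_mm = run$thickness * 1000, t_h = t_h,
      rho_a = air_density(tabs), c_a = air_specific_heat(tabs),
      et_kWh = et, es_kWh_per_kg = specific_energy(et, run$initial_load)
    )
  }))
}
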