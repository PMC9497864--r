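# Transport-property chain: Fick slab diffusivity, Arrhenius activation
# energy, and the Dincer-number correlation for the mass-transfer Biot
# number and convective mass-transfer coefficient.
#
# Two length conventions coexist deliberately. The slab solution uses the
# half thickness L = thickness/2 (drying from both faces); the Dincer and
# Biot chain uses the full slice thickness. The Dincer number further mixes
# k in 1/min with velocity in m/s and length in m — dimensionally impure
# but the convention under which the published drying literature tabulates
# Bi and hm, so it is the default here (see `si_units`).

#' Moisture ratio of an infinite slab from Fick's second law
#'
#' Series solution for a slab of full thickness `thickness` drying from
#' both faces with constant diffusivity and negligible surface resistance:
#' `MR = (8/pi^2) * sum_n 1/(2n+1)^2 exp(-(2n+1)^2 pi^2 Deff t / (4 L^2))`
#' with `L = thickness/2`. With `n_terms = 1` this is the long-time
#' single-term form whose log-linearity underlies [estimate_deff()].
#'
#' @param times_min Times in minutes.
#' @param deff Effective moisture diffusivity, m^2/s.
#' @param thickness Full slice thickness, m.
#' @param n_terms Maximum number of series terms (default 50); the series
#'   is truncated early once the next term falls below 1e-12.
#' @return Moisture ratios at `times_min`.
#' @export
fick_slab_mr <- function(times_min, deff, thickness, n_terms = 50) {
  stopifnot_scalar_pos(deff, "deff")
  stopifnot_scalar_pos(thickness, "thickness")
  half <- thickness / 2
  t_s <- times_min * 60
  out <- numeric(length(t_s))
  for (n in seq_len(n_terms) - 1L) {
    odd <- 2 * n + 1
    term <- (8 / pi^2) / odd^2 *
      exp(-odd^2 * pi^2 * deff * t_s / (4 * half^2))
    out <- out + term
    if (max(term) < 1e-12) break
  }
  out
}

#' Effective moisture diffusivity by the slope method
#'
#' Ordinary least squares of `ln(MR)` on time over the falling-rate window
#' `mr_window[1] < MR <= mr_window[2]`, then
#' `Deff = -slope * 4 L^2 / pi^2` with `L = thickness/2` and the slope
#' converted from 1/min to 1/s. The window excludes the warm-up near
#' `MR = 1` and the noise-dominated tail.
#'
#' @param times Times in minutes.
#' @param mr Moisture ratios, positive.
#' @param thickness Full slice thickness, m.
#' @param mr_window Length-2 numeric: `(floor, ceiling]` of usable MR.
#'   Default `c(0.02, 0.95)`.
#' @return List of class `deff_estimate`: `deff` (m^2/s),
#'   `slope_per_min`, `intercept`, `r2`, `n_used`.
#' @export
#' @examples
#' t <- sampling_schedule(600)
#' mr <- fick_slab_mr(t, 4e-10, 0.004, n_terms = 1)
#' estimate_deff(t, mr, 0.004)$deff
estimate_deff <- function(times, mr, thickness, mr_window = c(0.02, 0.95)) {
  stopifnot_scalar_pos(thickness, "thickness")
  if (any(mr <= 0)) abort("`mr` must be positive for the log-slope method.")
  use <- mr > mr_window[1] & mr <= mr_window[2]
  if (sum(use) < 3L) {
    abort(sprintf(
      "only %d usable points with MR in (%g, %g]; need at least 3.",
      sum(use), mr_window[1], mr_window[2]
    ))
  }
  fit <- lm(log(mr[use]) ~ times[use])
  slope <- unname(coef(fit)[2])
  if (slope >= 0) abort("non-negative log-MR slope: moisture is not decreasing.")
  half <- thickness / 2
  structure(
    list(
      deff = -(slope / 60) * 4 * half^2 / pi^2,
      slope_per_min = slope,
      intercept = unname(coef(fit)[1]),
      r2 = suppressWarnings(summary(fit)$r.squared),
      n_used = sum(use)
    ),
    class = "deff_estimate"
  )
}

#' Arrhenius fit of diffusivity against temperature
#'
#' Least squares of `ln(Deff)` on `1/(T + 273.15)`; the activation energy
#' is `Ea = -slope * R` with `R = 8.314e-3` kJ/(mol K), and the
#' pre-exponential factor `D0 = exp(intercept)`.
#'
#' @param temperatures Drying temperatures, degrees Celsius (>= 2 distinct).
#' @param deffs Effective diffusivities, m^2/s, positive, same length.
#' @return List of class `arrhenius_fit`: `ea_kJ_mol`, `d0`, `r2`,
#'   `gas_constant`.
#' @export
arrhenius_fit <- function(temperatures, deffs) {
  if (length(temperatures) != length(deffs)) abort("input lengths differ.")
  if (length(unique(temperatures)) < 2L) {
    abort("need at least two distinct temperatures for an Arrhenius fit.")
  }
  if (any(deffs <= 0)) abort("`deffs` must be positive.")
  R <- 8.314e-3 # kJ / (mol K)
  inv_t <- 1 / (temperatures + 273.15)
  fit <- lm(log(deffs) ~ inv_t)
  structure(
    list(
      ea_kJ_mol = -unname(coef(fit)[2]) * R,
      d0 = exp(unname(coef(fit)[1])),
      r2 = if (length(deffs) > 2) suppressWarnings(summary(fit)$r.squared) else 1,
      gas_constant = R
    ),
    class = "arrhenius_fit"
  )
}

#' Dincer number of a drying run
#'
#' `Di = v / (k * L)` relating the drying-air velocity to the product's
#' drying constant and characteristic length. Following the published
#' tabulation convention, `k` is per minute, `v` in m/s and `L` the full
#' slice thickness in m; pass `si_units = TRUE` to convert `k` to 1/s
#' first (values then differ from the tabulated convention by a factor
#' of 60).
#'
#' @param air_velocity Drying-air velocity, m/s.
#' @param k Drying constant of the fitted model, 1/min.
#' @param thickness Full slice thickness, m.
#' @param si_units Convert `k` to 1/s before forming the ratio
#'   (default FALSE).
#' @return Dimensionless Dincer number.
#' @export
dincer_number <- function(air_velocity, k, thickness, si_units = FALSE) {
  stopifnot_scalar_pos(air_velocity, "air_velocity")
  stopifnot_scalar_pos(k, "k")
  stopifnot_scalar_pos(thickness, "thickness")
  if (si_units) k <- k / 60
  air_velocity / (k * thickness)
}

#' Mass-transfer Biot number from the Dincer correlation
#'
#' `Bi = 24.848 * Di^(-0.375)`: internal diffusive resistance relative to
#' external convective resistance, strictly decreasing in `Di`.
#'
#' @param di Dincer number, positive.
#' @return Biot number for mass transfer.
#' @export
biot_number <- function(di) {
  if (any(di <= 0)) abort("`di` must be positive.")
  24.848 * di^(-0.375)
}

#' Convective mass-transfer coefficient
#'
#' `hm = Bi * Deff / L` with `L` the full slice thickness. The correlation
#' behind `Bi` is regarded as valid for `Bi > 0.1`; a warning is emitted
#' below that.
#'
#' @param bi Biot number, positive.
#' @param deff Effective diffusivity, m^2/s.
#' @param thickness Full slice thickness, m.
#' @return Mass-transfer coefficient, m/s.
#' @export
mass_transfer_coefficient <- function(bi, deff, thickness) {
  if (any(bi <= 0)) abort("`bi` must be positive.")
  stopifnot_scalar_pos(deff, "deff")
  stopifnot_scalar_pos(thickness, "thickness")
  if (any(bi <= 0.1)) {
    warn("Bi <= 0.1: the Dincer correlation is outside its stated validity range.")
  }
  bi * deff / thickness
}

#' Transport-property table for a set of drying runs
#'
#' For each run: effective diffusivity by the slope method on the run's
#' moisture-ratio series, then the Dincer-number chain
#' (`Di -> Bi -> hm`) using the supplied drying constant `k` of the
#' fitted diffusion-approach model. Runs sharing a slice thickness and
#' spanning at least two temperatures additionally get an Arrhenius
#' activation energy.
#'
#' @param runs List of [drying_run()] objects.
#' @param k_per_run Named numeric vector: diffusion-approach drying
#'   constant (1/min) per `run_id`. Runs without an entry are flagged
#'   (`ok = FALSE`) but do not abort the table.
#' @param mr_window Passed to [estimate_deff()].
#' @return List with `per_run` (tibble: run_id, thickness_mm, temperature,
#'   k, deff, slope_r2, di, bi, hm, ok, note) and `arrhenius` (tibble:
#'   thickness_mm, ea_kJ_mol, d0, r2, n_temperatures).
#' @export
transport_table <- function(runs, k_per_run, mr_window = c(0.02, 0.95)) {
  if (length(runs) == 0L) {
    empty <- tibble::tibble(
      run_id = character(0), thickness_mm = numeric(0),
      temperature = numeric(0), k = numeric(0), deff = numeric(0),
      slope_r2 = numeric(0), di = numeric(0), bi = numeric(0),
      hm = numeric(0), ok = logical(0), note = character(0)
    )
    return(list(per_run = empty, arrhenius = tibble::tibble(
      thickness_mm = numeric(0), ea_kJ_mol = numeric(0), d0 = numeric(0),
      r2 = numeric(0), n_temperatures = integer(0)
    )))
  }
  rows <- lapply(runs, function(run) {
    out <- tibble::tibble(
      run_id = run$run_id,
      thickness_mm = run$thickness * 1000,
      temperature = run$temperature,
      k = NA_real_, deff = NA_real_, slope_r2 = NA_real_,
      di = NA_real_, bi = NA_real_, hm = NA_real_,
      ok = FALSE, note = NA_character_
    )
    k <- k_per_run[[run$run_id]]
    if (is.null(k) || is.na(k)) {
      out$note <- "no diffusion-approach k supplied"
      return(out)
    }
    est <- tryCatch(
      {
        series <- moisture_from_weights(run)
        mr <- moisture_ratio(series)
        estimate_deff(mr$time_min, mr$mr, run$thickness, mr_window)
      },
      error = function(e) e
    )
    if (inherits(est, "error")) {
      out$note <- conditionMessage(est)
      return(out)
    }
    di <- dincer_number(run$air_velocity, k, run$thickness)
    bi <- biot_number(di)
    out$k <- k
    out$deff <- est$deff
    out$slope_r2 <- est$r2
    out$di <- di
    out$bi <- bi
    out$hm <- mass_transfer_coefficient(bi, est$deff, run$thickness)
    out$ok <- TRUE
    out
  })
  per_run <- dplyr::bind_rows(rows)

  arr <- per_run |>
    dplyr::filter(.data$ok) |>
    dplyr::group_by(.data$thickness_mm) |>
    dplyr::group_modify(function(d, key) {
      if (length(unique(d$temperature)) < 2L) {
        return(tibble::tibble(
          ea_kJ_mol = NA_real_, d0 = NA_real_, r2 = NA_real_,
          n_temperatures = length(unique(d$temperature))
        ))
      }
      f <- arrhenius_fit(d$temperature, d$deff)
      tibble::tibble(
        ea_kJ_mol = f$ea_kJ_mol, d0 = f$d0, r2 = f$r2,
        n_temperatures = length(unique(d$temperature))
      )
    }) |>
    dplyr::ungroup()

  list(per_run = per_run, arrhenius = arr)
}

#' Dincer chain from tabulated inputs
#'
#' Pure-arithmetic convenience wrapper computing `Di`, `Bi` and `hm` from
#' a drying constant, a diffusivity and a thickness — the chain used to
#' cross-check published transport tables.
#'
#' @param k Drying constant, 1/min.
#' @param deff Effective diffusivity, m^2/s.
#' @param thickness Full slice thickness, m.
#' @param air_velocity Drying-air velocity, m/s (default 1.5).
#' @return Tibble with columns `di`, `bi`, `hm`.
#' @export
#' @examples
#' transport_chain(k = 0.0341, deff = 1.79e-9, thickness = 0.008)
transport_chain <- function(k, deff, thickness, air_velocity = 1.5) {
  di <- mapply(dincer_number, air_velocity, k, thickness)
  bi <- biot_number(di)
  hm <- mapply(mass_transfer_coefficient, bi, deff, thickness)
  tibble::tibble(di = di, bi = bi, hm = hm)
}
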