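# Published reference values for convective thin-layer drying of plantain
# banana slices (four air temperatures 50-80 degC crossed with four slice
# thicknesses 2-8 mm, air velocity 1.5 m/s). These tabulated estimates are
# inputs to the analysis: the diffusion-approach parameter triples drive
# the synthetic generator, and the transport table is the surface the
# Dincer chain is cross-checked against.

#' Published diffusion-approach parameters for plantain banana drying
#'
#' Best-fit diffusion-approach coefficients
#' `MR = a exp(-k t) + (1-a) exp(-k b t)` (k in 1/min) for each of the 16
#' temperature-by-thickness drying conditions, with the reported fit
#' statistics.
#'
#' @return Tibble: `sr`, `temperature` (degC), `thickness_mm`, `a`, `k`,
#'   `b`, `r2`, `chi2_reduced`, `rmse`. Rows ordered by thickness then
#'   temperature.
#' @export
plantain_model_parameters <- function() {
  tab <- tibble::tribble(
    ~temperature, ~thickness_mm, ~a, ~k, ~b, ~r2, ~chi2_reduced, ~rmse,
    50, 2, 0.88, 0.0300, 0.0100, 0.99, 4.9e-5, 6.9e-3,
    50, 4, 0.86, 0.0287, 0.0163, 0.99, 6.7e-5, 8.2e-3,
    50, 6, 0.85, 0.0249, 0.0174, 0.99, 6.9e-5, 8.3e-3,
    50, 8, 0.83, 0.0226, 0.0186, 0.99, 6.3e-5, 8.0e-3,
    60, 2, 0.88, 0.0347, 0.0142, 0.99, 2.5e-5, 5.0e-3,
    60, 4, 0.86, 0.0304, 0.0177, 0.99, 6.9e-5, 8.3e-3,
    60, 6, 0.85, 0.0269, 0.0182, 0.99, 6.7e-5, 8.2e-3,
    60, 8, 0.84, 0.0238, 0.0177, 0.99, 7.3e-5, 8.5e-3,
    70, 2, 0.87, 0.0402, 0.0329, 0.99, 9.8e-5, 9.9e-3,
    70, 4, 0.84, 0.0351, 0.0411, 0.99, 4.1e-5, 6.4e-3,
    70, 6, 0.84, 0.0302, 0.0343, 0.99, 4.4e-5, 6.6e-3,
    70, 8, 0.83, 0.0278, 0.0284, 0.99, 4.6e-5, 6.8e-3,
    80, 2, 0.88, 0.0465, 0.0292, 0.99, 9.7e-5, 9.8e-3,
    80, 4, 0.86, 0.0427, 0.0323, 0.99, 1.0e-4, 1.0e-2,
    80, 6, 0.85, 0.0386, 0.0291, 0.99, 1.3e-4, 1.1e-2,
    80, 8, 0.86, 0.0341, 0.0233, 0.99, 1.5e-4, 1.2e-2
  )
  tab <- tab[order(tab$thickness_mm, tab$temperature), ]
  tab$sr <- seq_len(nrow(tab))
  tab[, c("sr", setdiff(names(tab), "sr"))]
}

#' Published transport properties and hardness for plantain banana drying
#'
#' Tabulated effective moisture diffusivity, mass-transfer Biot number,
#' convective mass-transfer coefficient and dried-slice hardness for the
#' 16 drying conditions.
#'
#' @return Tibble: `sr`, `thickness_mm`, `temperature` (degC),
#'   `deff_m2_s`, `bi`, `hm_m_s`, `hardness_N`.
#' @export
plantain_transport_reference <- function() {
  tibble::tribble(
    ~sr, ~thickness_mm, ~temperature, ~deff_m2_s, ~bi, ~hm_m_s, ~hardness_N,
    1, 2, 50, 1.11e-10, 0.57, 3.17e-8, 15.25,
    2, 2, 60, 1.25e-10, 0.59, 3.68e-8, 17.54,
    3, 2, 70, 1.41e-10, 0.62, 4.38e-8, 23.75,
    4, 2, 80, 1.70e-10, 0.66, 5.58e-8, 31.84,
    5, 4, 50, 3.66e-10, 0.71, 6.50e-8, 26.56,
    6, 4, 60, 4.00e-10, 0.73, 7.26e-8, 35.70,
    7, 4, 70, 4.47e-10, 0.77, 8.57e-8, 37.02,
    8, 4, 80, 5.90e-10, 0.82, 1.22e-7, 38.67,
    9, 6, 50, 6.89e-10, 0.78, 9.01e-8, 38.23,
    10, 6, 60, 7.60e-10, 0.81, 1.02e-7, 39.95,
    11, 6, 70, 8.35e-10, 0.84, 1.17e-7, 45.76,
    12, 6, 80, 1.14e-9, 0.92, 1.76e-7, 66.13,
    13, 8, 50, 1.04e-9, 0.84, 1.10e-7, 39.8,
    14, 8, 60, 1.15e-9, 0.86, 1.24e-7, 41.65,
    15, 8, 70, 1.28e-9, 0.91, 1.46e-7, 50.36,
    16, 8, 80, 1.79e-9, 0.98, 2.20e-7, 71.41
  )
}

#' Published activation energies per slice thickness
#'
#' @return Tibble: `thickness_mm`, `ea_kJ_mol`.
#' @export
plantain_activation_energy <- function() {
  tibble::tibble(
    thickness_mm = c(2, 4, 6, 8),
    ea_kJ_mol = c(13.70, 15.82, 16.93, 18.23)
  )
}

#' Published four-group sample clustering
#'
#' The reported dendrogram partition of the 16 drying conditions
#' (numbered as in [plantain_transport_reference()]) into four groups.
#'
#' @return Integer vector of length 16: group label per sample number.
#' @export
plantain_cluster_reference <- function() {
  labels <- integer(16)
  labels[c(1, 2, 5, 6)] <- 1L
  labels[c(3, 4, 7, 8)] <- 2L
  labels[c(9, 10, 11, 12, 16)] <- 3L
  labels[c(13, 14, 15)] <- 4L
  labels
}
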