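# Registry of the seven semi-empirical thin-layer drying models.
#
# All express the moisture ratio MR(t) with t in minutes and rate constants
# (k, g) in 1/min. The two-compartment "diffusion approach" form
# a*exp(-k t) + (1-a)*exp(-k b t) nests Newton (b = 1, any a) and coincides
# with Verma when g = k*b.

.model_forms <- list(
  newton = list(
    parameter_names = "k",
    fn = function(t, p) exp(-p[["k"]] * t)
  ),
  page = list(
    parameter_names = c("k", "n"),
    fn = function(t, p) exp(-p[["k"]] * t^p[["n"]])
  ),
  modified_page = list(
    parameter_names = c("k", "n"),
    fn = function(t, p) exp(-(p[["k"]] * t)^p[["n"]])
  ),
  henderson_pabis = list(
    parameter_names = c("a", "k"),
    fn = function(t, p) p[["a"]] * exp(-p[["k"]] * t)
  ),
  logarithmic = list(
    parameter_names = c("a", "k", "c"),
    fn = function(t, p) p[["a"]] * exp(-p[["k"]] * t) + p[["c"]]
  ),
  verma = list(
    parameter_names = c("a", "k", "g"),
    fn = function(t, p) {
      p[["a"]] * exp(-p[["k"]] * t) + (1 - p[["a"]]) * exp(-p[["g"]] * t)
    }
  ),
  diffusion_approach = list(
    parameter_names = c("a", "k", "b"),
    fn = function(t, p) {
      p[["a"]] * exp(-p[["k"]] * t) +
        (1 - p[["a"]]) * exp(-p[["k"]] * p[["b"]] * t)
    }
  )
)

# Shared per-parameter defaults: neutral starting values centred on the
# magnitudes typical of thin-layer drying of fruit slices, and wide bounds.
.param_defaults <- list(
  a = list(start = 0.9, lower = 1e-6, upper = 2),
  k = list(start = 0.03, lower = 1e-6, upper = 10),
  b = list(start = 0.3, lower = 1e-6, upper = 10),
  n = list(start = 1.0, lower = 0.1, upper = 5),
  c = list(start = 0.05, lower = -1, upper = 1),
  g = list(start = 0.01, lower = 1e-6, upper = 10)
)

#' Model identifiers known to the registry
#' @return Character vector of the seven model ids.
#' @export
model_ids <- function() names(.model_forms)

#' Catalogue of the seven thin-layer drying models
#'
#' One row per model with its ordered parameter names, default starting
#' values and box bounds used by [fit_model()].
#'
#' @return A tibble with columns `model_id`, `n_params`, `parameter_names`
#'   (list), `start` (list), `lower` (list), `upper` (list).
#' @export
#' @examples
#' model_catalog()
model_catalog <- function() {
  ids <- model_ids()
  tibble::tibble(
    model_id = ids,
    n_params = vapply(ids, function(i) length(.model_forms[[i]]$parameter_names), integer(1)),
    parameter_names = lapply(ids, function(i) .model_forms[[i]]$parameter_names),
    start = lapply(ids, function(i) default_start(i)),
    lower = lapply(ids, function(i) default_bounds(i)$lower),
    upper = lapply(ids, function(i) default_bounds(i)$upper)
  )
}

model_parameter_names <- function(model_id) {
  form <- .model_forms[[model_id]]
  if (is.null(form)) {
    abort(sprintf(
      "unknown model_id '%s'; known: %s", model_id,
      paste(model_ids(), collapse = ", ")
    ))
  }
  form$parameter_names
}

default_start <- function(model_id) {
  nm <- model_parameter_names(model_id)
  setNames(vapply(nm, function(p) .param_defaults[[p]]$start, numeric(1)), nm)
}

default_bounds <- function(model_id) {
  nm <- model_parameter_names(model_id)
  list(
    lower = setNames(vapply(nm, function(p) .param_defaults[[p]]$lower, numeric(1)), nm),
    upper = setNames(vapply(nm, function(p) .param_defaults[[p]]$upper, numeric(1)), nm)
  )
}

#' Evaluate a thin-layer drying model
#'
#' @param model_id One of [model_ids()].
#' @param params Named numeric vector of coefficients; names must match the
#'   model's parameter names (order-free). Rate constants are per minute.
#' @param times Times in minutes, all non-negative.
#' @return Numeric vector of predicted moisture ratios.
#' @export
#' @examples
#' evaluate_model("diffusion_approach", c(a = 0.88, k = 0.03, b = 0.01), 60)
evaluate_model <- function(model_id, params, times) {
  nm <- model_parameter_names(model_id)
  if (!all(nm %in% names(params))) {
    abort(sprintf(
      "model '%s' needs parameters {%s}, got {%s}",
      model_id, paste(nm, collapse = ", "),
      paste(names(params), collapse = ", ")
    ))
  }
  if (any(times < 0)) abort("`times` must be non-negative.")
  .model_forms[[model_id]]$fn(as.numeric(times), as.list(params[nm]))
}
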