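#' Run the full drying-analysis pipeline
#'
#' Orchestrates every stage on a set of drying runs: moisture-ratio
#' conversion, seven-model fitting and ranking per run, the transport
#' chain (Deff, Di, Bi, hm, Arrhenius Ea per thickness), optional energy
#' accounting, and Ward clustering of the per-run feature matrix. Per-run
#' failures are flagged in the output tables rather than aborting the
#' pipeline.
#'
#' @param runs Named list of [drying_run()] objects (e.g. from
#'   [generate_study()] or [read_drying_runs()]).
#' @param dryer Optional [dryer_config()]; when `NULL` the energy table is
#'   skipped (tray area has no defensible default).
#' @param models Model ids to fit per run (default: all seven).
#' @param mr_window Log-slope window passed to [estimate_deff()].
#' @param n_clusters Number of groups for the correlation stage.
#' @param seed Seed for the fit multi-starts.
#' @param out_dir Optional directory; when given, writes `fits.csv`,
#'   `transport.csv`, `arrhenius.csv`, `energy.csv` (if computed),
#'   `clusters.csv` and `pipeline_log.txt` with every resolved setting.
#' @return List: `fits` (tibble, one row per run x model), `best_model`
#'   (tibble per run), `transport`, `arrhenius`, `energy` (or `NULL`),
#'   `features`, `cluster` (labels + agreement columns).
#' @export
run_pipeline <- function(runs, dryer = NULL, models = model_ids(),
                         mr_window = c(0.02, 0.95), n_clusters = 4,
                         seed = 1405, out_dir = NULL) {
  if (length(runs) == 0L) abort("`runs` is empty: nothing to analyse.")
  stopifnot(all(vapply(runs, inherits, logical(1), "drying_run")))

  # -- model fitting per run -------------------------------------------
  fit_rows <- list()
  rankings <- list()
  for (run in runs) {
    series <- moisture_from_weights(run)
    mr <- moisture_ratio(series)
    rk <- rank_models(mr$time_min, mr$mr, models = models, seed = seed)
    rankings[[run$run_id]] <- rk
    tab <- rk[, c("rank", "model_id", "converged", "r2", "chi2_reduced", "rmse", "params")]
    tab$run_id <- run$run_id
    tab$temperature <- run$temperature
    tab$thickness_mm <- run$thickness * 1000
    fit_rows[[run$run_id]] <- tab
  }
  fits <- dplyr::bind_rows(fit_rows)
  best_model <- fits |>
    dplyr::filter(.data$rank == 1) |>
    dplyr::select("run_id", "temperature", "thickness_mm", "model_id", "r2")

  # -- transport chain --------------------------------------------------
  k_per_run <- vapply(runs, function(run) {
    rk <- rankings[[run$run_id]]
    row <- which(rk$model_id == "diffusion_approach" & rk$converged)
    if (length(row) == 0L) NA_real_ else rk$fit[[row[1]]]$estimate[["k"]]
  }, numeric(1))
  names(k_per_run) <- names(runs)
  transport <- transport_table(runs, k_per_run, mr_window = mr_window)

  # -- energy -----------------------------------------------------------
  energy <- if (!is.null(dryer)) energy_table(runs, dryer) else NULL

  # -- compound correlation --------------------------------------------
  features <- transport$per_run |>
    dplyr::filter(.data$ok) |>
    dplyr::select("run_id", "temperature", "thickness_mm", "deff", "bi", "hm")
  if (!is.null(energy)) {
    features <- dplyr::left_join(
      features, energy[, c("run_id", "es_kWh_per_kg")],
      by = "run_id"
    )
  }
  ref <- plantain_transport_reference()
  features <- dplyr::left_join(
    features,
    ref[, c("temperature", "thickness_mm", "hardness_N")],
    by = c("temperature", "thickness_mm")
  )
  feat_cols <- setdiff(names(features), "run_id")
  feat_cols <- feat_cols[vapply(
    feat_cols,
    function(cn) !anyNA(features[[cn]]) && var(features[[cn]]) > 0, logical(1)
  )]
  cluster <- NULL
  if (nrow(features) >= n_clusters && length(feat_cols) >= 2L) {
    mat <- feature_matrix(features, feat_cols)
    cl <- cluster_samples(mat, n_clusters = n_clusters)
    cluster <- list(
      labels = tibble::tibble(run_id = features$run_id, cluster = cl$labels),
      tree = cl$tree, feature_columns = feat_cols
    )
  }

  out <- list(
    fits = fits, best_model = best_model,
    transport = transport$per_run, arrhenius = transport$arrhenius,
    energy = energy, features = features, cluster = cluster
  )

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write.csv(fits[, setdiff(names(fits), "fit")],
      file.path(out_dir, "fits.csv"),
      row.names = FALSE
    )
    write.csv(transport$per_run, file.path(out_dir, "transport.csv"), row.names = FALSE)
    write.csv(transport$arrhenius, file.path(out_dir, "arrhenius.csv"), row.names = FALSE)
    if (!is.null(energy)) {
      write.csv(energy, file.path(out_dir, "energy.csv"), row.names = FALSE)
    }
    if (!is.null(cluster)) {
      write.csv(cluster$labels, file.path(out_dir, "clusters.csv"), row.names = FALSE)
    }
    log_lines <- c(
      sprintf("runs: %d", length(runs)),
      sprintf("models: %s", paste(models, collapse = ", ")),
      sprintf("mr_window: (%g, %g]", mr_window[1], mr_window[2]),
      sprintf("n_clusters: %d", n_clusters),
      sprintf("seed: %d", seed),
      sprintf(
        "dryer: %s",
        if (is.null(dryer)) {
          "none (energy stage skipped)"
        } else {
          sprintf(
            "tray_area = %g m2, ambient = %g degC",
            dryer$tray_area, dryer$ambient_temperature
          )
        }
      ),
      sprintf(
        "cluster features: %s",
        if (is.null(cluster)) "none" else paste(cluster$feature_columns, collapse = ", ")
      )
    )
    writeLines(log_lines, file.path(out_dir, "pipeline_log.txt"))
  }
  out
}
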