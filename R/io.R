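# Plain-text persistence of drying runs: one CSV (time_min, weight_kg)
# plus a JSON metadata sidecar per run, or a single long-format CSV with a
# run_id column and the metadata repeated per row.

#' Write drying runs to CSV + JSON sidecars
#'
#' Each run becomes `<run_id>.csv` (columns `time_min`, `weight_kg`) and
#' `<run_id>.json` carrying the run metadata.
#'
#' @param runs List of [drying_run()] objects.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths of the CSV files written.
#' @export
write_drying_runs <- function(runs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(runs, function(run) {
    csv <- file.path(dir, paste0(run$run_id, ".csv"))
    write.csv(
      data.frame(time_min = run$times, weight_kg = run$weights),
      csv,
      row.names = FALSE
    )
    meta <- run[c(
      "run_id", "temperature", "thickness", "air_velocity",
      "initial_load", "dry_mass", "initial_moisture_db"
    )]
    jsonlite::write_json(meta, file.path(dir, paste0(run$run_id, ".json")),
      auto_unbox = TRUE, digits = NA
    )
    csv
  }, character(1))
  invisible(paths)
}

#' Read one drying run from CSV + JSON sidecar
#'
#' @param csv_path Path to a CSV with columns `time_min`, `weight_kg`.
#' @param meta_path Path to the JSON metadata sidecar; defaults to the CSV
#'   path with the extension replaced by `.json`.
#' @return A [drying_run()].
#' @export
read_drying_run <- function(csv_path, meta_path = NULL) {
  if (is.null(meta_path)) meta_path <- sub("\\.csv$", ".json", csv_path)
  if (!file.exists(csv_path)) abort(sprintf("no such file: %s", csv_path))
  if (!file.exists(meta_path)) abort(sprintf("no metadata sidecar: %s", meta_path))
  d <- read.csv(csv_path)
  if (!all(c("time_min", "weight_kg") %in% names(d))) {
    abort("run CSV must have columns time_min and weight_kg.")
  }
  m <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  drying_run(
    run_id = m$run_id, temperature = m$temperature,
    thickness = m$thickness, air_velocity = m$air_velocity,
    initial_load = m$initial_load, dry_mass = m$dry_mass,
    times = d$time_min, weights = d$weight_kg,
    initial_moisture_db = m$initial_moisture_db
  )
}

#' Read all drying runs from a directory or long-format CSV
#'
#' A directory is scanned for `*.csv` files with matching `*.json`
#' sidecars. A single file is read as a long-format CSV with columns
#' `run_id, temperature, thickness, air_velocity, initial_load, dry_mass,
#' initial_moisture_db, time_min, weight_kg` (metadata repeated per row).
#'
#' @param path Directory or long-format CSV file.
#' @return Named list of [drying_run()] objects.
#' @export
read_drying_runs <- function(path) {
  if (dir.exists(path)) {
    csvs <- list.files(path, pattern = "\\.csv$", full.names = TRUE)
    if (length(csvs) == 0L) abort(sprintf("no run CSVs found in %s", path))
    runs <- lapply(csvs, read_drying_run)
  } else if (file.exists(path)) {
    d <- read.csv(path)
    need <- c(
      "run_id", "temperature", "thickness", "air_velocity",
      "initial_load", "dry_mass", "initial_moisture_db",
      "time_min", "weight_kg"
    )
    if (!all(need %in% names(d))) {
      abort(sprintf(
        "long-format CSV must have columns: %s", paste(need, collapse = ", ")
      ))
    }
    runs <- lapply(split(d, d$run_id), function(g) {
      g <- g[order(g$time_min), ]
      drying_run(
        run_id = g$run_id[1], temperature = g$temperature[1],
        thickness = g$thickness[1], air_velocity = g$air_velocity[1],
        initial_load = g$initial_load[1], dry_mass = g$dry_mass[1],
        times = g$time_min, weights = g$weight_kg,
        initial_moisture_db = g$initial_moisture_db[1]
      )
    })
  } else {
    abort(sprintf("no such path: %s", path))
  }
  names(runs) <- vapply(runs, `[[`, character(1), "run_id")
  runs
}

#' Write drying runs as one long-format CSV
#'
#' @param runs List of [drying_run()] objects.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_drying_runs_long <- function(runs, path) {
  d <- dplyr::bind_rows(lapply(runs, function(run) {
    data.frame(
      run_id = run$run_id, temperature = run$temperature,
      thickness = run$thickness, air_velocity = run$air_velocity,
      initial_load = run$initial_load, dry_mass = run$dry_mass,
      initial_moisture_db = run$initial_moisture_db,
      time_min = run$times, weight_kg = run$weights
    )
  }))
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}
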