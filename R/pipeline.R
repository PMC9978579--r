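# End-to-end pipeline: read -> minimum-intensity rule -> validate ->
# randomized grid search -> model selection -> write artifacts.

#' Run the full normalization pipeline
#'
#' Reads the intensity matrix and batch information named in the
#' configuration, applies the minimum-intensity rule, validates the
#' inputs, runs the randomized grid search, selects the best run, and
#' writes the normalized matrix, the ranking table, the winning run's
#' training history and a JSON manifest into `config$out_dir`.
#'
#' @param config a configuration list ([default_config()]) or the path
#'   to a configuration file ([read_run_config()]).
#' @param cores CPU processes for the grid search.
#' @return The winning `"mb_result"` (invisibly), with `$ranking` and
#'   `$evaluation` attached.
#' @export
run_pipeline <- function(config, cores = 1) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(!is.null(config$data_path), !is.null(config$info_path))
  m <- read_intensities(config$data_path, transpose = isTRUE(config$transpose))
  b <- read_batch_info(config$info_path)
  report <- validate_inputs(m, b, config$min_relevant_intensity)
  m <- apply_min_intensity(m, config$min_relevant_intensity)

  grid <- grid_search(m, b, config, cores = cores)
  best <- select_best(grid)

  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  write_normalized(best$normalized, file.path(out, "normalized.csv"))
  data.table::fwrite(best$ranking, file.path(out, "ranking.csv"))
  data.table::fwrite(best$history, file.path(out, "history.csv"))
  # model checkpoint (weights) with its layout as sidecar metadata
  wts <- best$model[c("W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4",
                      "W5", "b5")]
  jsonlite::write_json(
    list(spec = list(n_features = best$model$n_features,
                     latent_dim = best$model$latent_dim,
                     n_batches = best$model$n_batches,
                     activation = "leaky_relu", slope = best$model$slope),
         weights = wts),
    file.path(out, "model.json"), digits = NA, auto_unbox = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("metabatch")),
    r_version = R.version.string,
    seed = config$seed,
    grid_size = config$grid_size,
    latent_dim = best$latent_dim,
    stop_reason = best$stop_reason,
    validation = list(replaced_fraction = report$replaced_fraction,
                      n_batches = report$n_batches,
                      groups = report$groups),
    hyperparams = unclass(best$hyperparams))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(best)
}

#' Simulate a dataset and write it to disk
#'
#' Convenience wrapper around [simulate_batches()] writing the intensity
#' matrix, batch information and ground-truth matrices as CSVs.
#'
#' @param design a [simulation_design()].
#' @param out_dir output directory (created if needed).
#' @param seed integer seed.
#' @return Paths of the written files (invisibly).
#' @export
write_simulation <- function(design, out_dir, seed = 1) {
  sim <- simulate_batches(design, seed = seed)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c(data = file.path(out_dir, "intensities.csv"),
             info = file.path(out_dir, "batch_info.csv"),
             truth = file.path(out_dir, "true_matrix.csv"))
  dt <- data.table::data.table(sample = rownames(sim$intensities))
  data.table::fwrite(cbind(dt, data.table::as.data.table(sim$intensities)),
                     paths["data"])
  data.table::fwrite(sim$batch_info, paths["info"])
  write_normalized(sim$truth$true_matrix, paths["truth"])
  invisible(paths)
}
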