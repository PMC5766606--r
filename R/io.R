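#' Read an experiment configuration file
#'
#' Reads a YAML key-value file describing display geometry, carpet
#' layout, run design, raster grid and fitting options, and instantiates
#' the corresponding package objects.  Every section is optional;
#' omitted fields fall back to the package defaults, which encode the
#' carpet bar-mapping experiment.
#'
#' @param path Path to a YAML file, or `NULL` for all defaults.
#' @return List with elements `geometry`, `carpet`, `design`, `grid`,
#'   `search`, `hrf`.
#' @export
read_prf_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  build <- function(ctor, section) do.call(ctor, cfg[[section]] %||% list())
  list(geometry = build(display_geometry, "geometry"),
       carpet = build(carpet_spec, "carpet"),
       design = build(run_design, "design"),
       grid = build(visual_field_grid, "grid"),
       search = build(search_grid, "search"),
       hrf = build(hrf_spec, "hrf"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a fit (or any tidy) table as delimited text
#'
#' @param x Data frame.
#' @param path Output path (tab-separated).
#' @export
write_fits_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a JSON manifest describing a generated dataset
#'
#' Records seed, design and gains so a dataset can be regenerated
#' exactly.
#'
#' @param dataset A [simulate_runs()] result.
#' @param path Output path.
#' @export
write_manifest <- function(dataset, path) {
  m <- list(seed = dataset$seed,
            n_runs = dataset$n_runs,
            conditions = names(dataset$series),
            condition_gains = as.list(dataset$condition_gains),
            area_gains = as.list(dataset$area_gains),
            noise = unclass(dataset$noise),
            design = unclass(dataset$design),
            n_vertices = nrow(dataset$ground_truth))
  jsonlite::write_json(m, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
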