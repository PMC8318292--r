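#' Read and write parameter sets as JSON
#'
#' Parameter documents mirror the constructors: upper-GI parameters as
#' macronutrient-keyed records with `alpha`, `beta`, `arl`,
#' `secretion_gcod`; colon parameters as a flat record; diets as grams/day
#' by pool.
#'
#' @param x The object to write.
#' @param path File path.
#' @return Readers return the reconstructed object; writers return `path`
#'   invisibly.
#' @name gi_json
NULL

#' @rdname gi_json
#' @export
write_upper_gi_params <- function(x, path) {
  stopifnot(inherits(x, "upper_gi_params"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname gi_json
#' @export
read_upper_gi_params <- function(path) {
  do.call(upper_gi_params, jsonlite::fromJSON(path))
}

#' @rdname gi_json
#' @export
write_colon_params <- function(x, path) {
  stopifnot(inherits(x, "colon_params"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname gi_json
#' @export
read_colon_params <- function(path) {
  do.call(colon_params, jsonlite::fromJSON(path))
}

#' @rdname gi_json
#' @export
write_diet_intake <- function(x, path) {
  stopifnot(inherits(x, "diet_intake"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname gi_json
#' @export
read_diet_intake <- function(path) {
  do.call(diet_intake, jsonlite::fromJSON(path))
}

#' Read and write observation tables as CSV
#'
#' The observation schema shared by the generators and the fitting
#' functions: columns `removed_fraction`, `channel`, `boundary`,
#' `value_kcal_per_day`, `standard_error`, `n_subjects`.
#'
#' @param obs Observation data frame.
#' @param path File path.
#' @return `read_observations()` returns the validated data frame;
#'   `write_observations()` returns `path` invisibly.
#' @export
write_observations <- function(obs, path) {
  .check_observations(obs)
  utils::write.csv(obs, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  .check_observations(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a resection sweep as CSV
#'
#' Fixed column order (`removed_fraction`, `component`, `boundary`,
#' `gcod_per_day`, `kcal_per_day`) for reproducible output files.
#'
#' @param sweep Long table from [resection_sweep()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  cols <- c("removed_fraction", "component", "boundary", "gcod_per_day",
            "kcal_per_day")
  stopifnot(all(cols %in% names(sweep)))
  utils::write.csv(sweep[, cols], path, row.names = FALSE)
  invisible(path)
}
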