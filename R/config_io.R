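#' Read a key-value configuration file
#'
#' All package objects share one plain-text configuration dialect: YAML
#' key-value files. This reads one into a named list; the typed
#' constructors ([staircase_config()], [listener_params()],
#' [population_spec()], [scene_spec()], [condition_spec()]) validate the
#' values.
#'
#' @param path Path to a YAML file.
#' @return A named list.
#' @seealso [read_staircase_config()], [read_listener_params()],
#'   [write_config()]
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

#' Write an object's fields as a key-value configuration file
#'
#' @param x A named list or any of the package's configuration objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_config <- function(x, path) {
  x <- unclass(x)
  x <- x[!vapply(x, is.null, logical(1))]
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' Read a staircase configuration from file
#'
#' Keys are the arguments of [staircase_config()]; omitted keys keep the
#' standard defaults of the named track type, so an empty file yields the
#' exact standard rules (+12 dB start with 2 -> 1 dB steps for
#' `type = "tmr"`, 45-degree start with 5 -> 2 degree steps for
#' `type = "angle"`).
#'
#' @param path Path to a YAML key-value file.
#' @param type `"tmr"` or `"angle"`: which standard defaults fill omitted
#'   keys.
#' @return A [staircase_config()].
#' @export
read_staircase_config <- function(path, type = c("tmr", "angle")) {
  type <- match.arg(type)
  vals <- read_config(path)
  maker <- if (type == "tmr") tmr_track_config else angle_track_config
  do.call(maker, vals)
}

#' Read listener parameters from file
#'
#' @param path Path to a YAML key-value file with [listener_params()]
#'   fields; omitted fields keep their defaults.
#' @return A [listener_params()].
#' @export
read_listener_params <- function(path) {
  do.call(listener_params, read_config(path))
}

#' Read a population specification from file
#'
#' Accepts top-level `n_listeners` and `seed` plus nested `means:` and
#' `spreads:` maps of [listener_params()] fields.
#'
#' @param path Path to a YAML file.
#' @return A [population_spec()].
#' @export
read_population_spec <- function(path) {
  do.call(population_spec, read_config(path))
}

#' Export a track result as tidy CSV
#'
#' Writes one row per scored digit (`trial`, `onset`, `tmr`, `theta`,
#' `behavior`, `outcome`, `correct`, `latency`) joined with the staircase
#' bookkeeping for that response (`move`, `step`, `reversal`).
#'
#' @param result A `track_result` from [run_track()].
#' @param path Output CSV path.
#' @return Invisibly, the exported data frame.
#' @export
export_track_csv <- function(result, path) {
  stopifnot(inherits(result, "track_result"))
  log <- track_log(result$state)
  out <- cbind(result$responses,
               log[, c("move", "step", "reversal")])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Export a study as tidy CSV files
#'
#' Writes `<stem>_tracks.csv`, `<stem>_conditions.csv` and (when present)
#' `<stem>_srm.csv`, plus a `<stem>_manifest.yaml` echoing the seed and
#' counts for reproducibility.
#'
#' @param study An `srm_study` from [run_study()].
#' @param stem Output path stem.
#' @return Invisibly, a character vector of the files written.
#' @export
export_study_csv <- function(study, stem) {
  stopifnot(inherits(study, "srm_study"))
  files <- character(0)
  w <- function(df, suffix) {
    f <- paste0(stem, "_", suffix, ".csv")
    utils::write.csv(df, f, row.names = FALSE)
    f
  }
  files <- c(files, w(study$tracks, "tracks"), w(study$conditions,
                                                 "conditions"))
  if (!is.null(study$srm)) files <- c(files, w(study$srm, "srm"))
  manifest <- list(seed = study$seed,
                   n_listeners = length(unique(study$conditions$listener)),
                   n_conditions = length(unique(study$conditions$condition)),
                   n_tracks = nrow(study$tracks),
                   created = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  mf <- paste0(stem, "_manifest.yaml")
  write_config(manifest, mf)
  invisible(c(files, mf))
}
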