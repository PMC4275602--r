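# Configuration loading for the command-line interface.

.config_defaults <- function() {
  list(theta = 0.03,
       thresholds = c(0, 1, 2),
       n_sims = 1000L,
       seed = 1L,
       condition_on_unknowns = TRUE,
       fst_values = c(0.01, 0.02, 0.03),
       experiment = NULL,
       databases = NULL,
       out = NULL)
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration file, applies defaults (`theta = 0.03`,
#' tail thresholds `{0, 1, 2}` bans, 1000 simulations, seed 1) and
#' rejects unknown keys and out-of-range values, naming the offending
#' key.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A named list of validated settings.
#' @export
load_config <- function(path = NULL) {
  cfg <- .config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (length(user)) {
      unknown <- setdiff(names(user), names(cfg))
      if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
      cfg[names(user)] <- user
    }
  }
  if (!is.numeric(cfg$theta) || cfg$theta < 0 || cfg$theta >= 1)
    stop("config key 'theta': must lie in [0, 1)")
  if (!is.numeric(cfg$thresholds) || any(cfg$thresholds < 0))
    stop("config key 'thresholds': must be non-negative numbers")
  if (!is.numeric(cfg$n_sims) || length(cfg$n_sims) != 1L || cfg$n_sims < 1)
    stop("config key 'n_sims': must be a positive integer")
  cfg$n_sims <- as.integer(cfg$n_sims)
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L)
    stop("config key 'seed': must be an integer")
  cfg$seed <- as.integer(cfg$seed)
  if (!is.logical(cfg$condition_on_unknowns))
    stop("config key 'condition_on_unknowns': must be true/false")
  if (!is.numeric(cfg$fst_values) ||
      any(cfg$fst_values <= 0 | cfg$fst_values >= 1))
    stop("config key 'fst_values': must lie in (0, 1)")
  if (!is.null(cfg$experiment) &&
      !cfg$experiment %in% c("single", "fst", "two-known", "two-unknown"))
    stop("config key 'experiment': must be one of single, fst, ",
         "two-known, two-unknown")
  cfg
}

#' Write a run manifest
#'
#' Records the command, configuration snapshot, seed, timestamps,
#' artifact paths and package version alongside experiment outputs, so
#' any result file can be regenerated from its manifest alone.
#'
#' @param path Output path for the JSON manifest.
#' @param command Command or function name that produced the artifacts.
#' @param config Configuration list (including the seed).
#' @param artifacts Character vector of artifact paths.
#' @param started,finished POSIXct timestamps.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, config, artifacts,
                           started = Sys.time(), finished = Sys.time()) {
  manifest <- list(
    command = command,
    config = config,
    seed = config$seed,
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(finished, "%Y-%m-%dT%H:%M:%S%z"),
    artifacts = artifacts,
    package = "strwoe",
    version = as.character(utils::packageVersion("strwoe")))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}
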