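#' Load a run configuration from JSON
#'
#' A run config fully determines a simulation: environment spec(s),
#' protocol durations, dynamics constants, module geometry, recording
#' spec and named seeds.  Missing fields are filled with the published
#' defaults (dt 0.003 s, kappa 500, five modules, ...); unknown keys are
#' an error naming the key.  `load_config` followed by `save_config`
#' round-trips.
#'
#' @param path JSON file path.
#' @return a validated config list (as from [network_config()], plus
#'   `environment`, `seeds`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  build_config(raw)
}

#' @rdname load_config
#' @param raw a named list of overrides (possibly empty).
#' @export
build_config <- function(raw = list()) {
  known_top <- c("preset", "environment", "seeds", "n_modules", "nside",
                 "gains", "n_border", "n_place", "familiarize_s", "test_s",
                 "settle_s", "orientation_deg", "seed_period_units",
                 "rate_based", "rec_per_module", "constants")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  preset <- raw$preset %||% "full"
  consts <- raw$constants %||% list()
  unknown_c <- setdiff(names(consts), names(dynamics_constants()))
  if (length(unknown_c) > 0)
    stop("unknown dynamics constant(s): ", paste(unknown_c, collapse = ", "))
  overrides <- raw[setdiff(names(raw),
                           c("preset", "environment", "seeds", "constants"))]
  cfg <- do.call(network_config, c(list(preset = preset), overrides, consts))
  cfg$environment <- raw$environment %||%
    list(kind = "rectangle", width_cm = 150, height_cm = 150)
  cfg$seeds <- raw$seeds %||% list(path = 1L, wiring = 2L, spiking = 3L)
  cfg
}

#' @rdname load_config
#' @param config a config list.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Build the environment described by a config
#' @param config a config from [load_config()].
#' @return a `gt_env`.
#' @export
config_environment <- function(config) {
  e <- config$environment
  make_environment(kind = e$kind %||% "rectangle",
                   width_cm = e$width_cm,
                   height_cm = e$height_cm %||% NULL,
                   trapezoid_short_wall_cm = e$trapezoid_short_wall_cm %||% NULL,
                   inserted_walls = e$inserted_walls %||% NULL,
                   pixel_cm = e$pixel_cm %||% 2.5)
}

#' Write a reproducibility manifest
#'
#' Records the config, seeds and package version next to a result so a
#' run can be reproduced bit-for-bit.
#'
#' @param config the run config.
#' @param path output JSON path.
#' @param extra optional named list of extra fields.
#' @export
write_manifest <- function(config, path, extra = list()) {
  m <- c(list(package = "gridtether",
              version = as.character(utils::packageVersion("gridtether")),
              config = config), extra)
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
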