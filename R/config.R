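# Run configuration: nested defaults, YAML ingestion with strict key
# validation, and the resolved-config echo written with every bundle.

#' Default pipeline configuration
#'
#' All tunables of the end-to-end pipeline with their defaults: corpus
#' size and seed, template discretisation, shape-variation parameters,
#' fluid constants (air: density 1.18 kg/m³, dynamic viscosity
#' 1.86e-5 Pa·s), the restful-breathing flow rate (200 ml/s), the losses
#' flag, CoV masking thresholds and WSS histogram bin edges.
#'
#' @return A nested named list of class `noseflow_config`.
#' @export
default_config <- function() {
  structure(list(
    schema_version = 1L,
    corpus = list(n_subjects = 25L, seed = 1L),
    template = list(n_stations = 21L, n_ring = 24L, length_mm = 70,
                    nostril_area_mm2 = 100, isthmus_position = 0.15),
    variation = list(n_modes = 3L, mode_sd = 8 * 0.65^(0:2),
                     noise_sd = 0.05),
    fluid = list(density = 1.18, viscosity_pas = 1.86e-5),
    phase = list(flow_mls = 200),
    losses = TRUE,
    mapping = list(eps_wss_pa = 1e-3, eps_pressure_pa = 1e-2),
    histogram = list(bin_edges = c(0, 0.01, 0.02, 0.05, 0.1, 0.2, 0.5,
                                   Inf))),
    class = "noseflow_config")
}

# Merge user values over defaults, rejecting unknown keys at any level.
merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      stop("unknown configuration key: ", full)
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]]))
        stop("configuration key ", full, " must be a mapping")
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Read a pipeline configuration file
#'
#' Parses a YAML file and overlays it on [default_config()]; unknown keys
#' are rejected so typos cannot silently fall back to defaults.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return A `noseflow_config`.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- structure(merge_config(unclass(cfg), user),
                     class = "noseflow_config")
  }
  cfg
}

write_config_echo <- function(config, path) {
  cfg <- unclass(config)
  cfg$software <- list(
    package = "noseflow",
    version = as.character(utils::packageVersion("noseflow")))
  yaml::write_yaml(cfg, path)
  invisible(path)
}
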