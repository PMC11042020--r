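# YAML run configuration: schema-validated nested defaults reproducing
# the standard simulation environment (8 cm x 5 cm cylinder, 16 x 3
# electrodes, 350 uS/cm background, 0.0001 uS/cm inclusions, SNR set
# {30, 40, 50} dB).

#' Default run configuration
#'
#' @return nested list of class `eit_config` with all defaults filled.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    geometry = list(radius_cm = 5, height_cm = 8,
                    ring_heights_cm = c(2, 4, 6),
                    electrodes_per_ring = 16L,
                    electrode_angular_width_deg = 10,
                    electrode_height_cm = 0.5),
    mesh = list(refinement = 1L, na = NULL, nr = NULL),
    cem = list(contact_impedance_ohm_m2 = 1e-4, current_amplitude_A = 1e-3),
    phantom = list(kind = "sphere",
                   sigma_background_uScm = 350,
                   sigma_inclusion_uScm = 0.0001),
    noise = list(snr_db = c(30, 40, 50), seed = 1L),
    dataset = list(n_samples = 100L, split_ratio = 0.8, split_seed = 1L),
    network = list(stage_depths = c(3L, 4L, 6L, 3L),
                   stage_widths = c(64L, 128L, 256L, 512L),
                   expansion = 4L),
    train = list(epochs = 50L, batch_size = 32L, base_lr = 1e-4,
                 alpha = 100, lr_factor = 0.5, lr_patience = 5L,
                 weight_decay = 0, normalization = "range"),
    gn = list(lambda = 1e-2, prior = "identity", max_iters = 10L,
              step_halvings = 8L, sigma_floor = 1e-10),
    metrics = list(ssim_k1 = 0.01, ssim_k2 = 0.03),
    quality = list(n_windows = 10L, k_neighbors = 5L, grid_points = 512L),
    paths = list(workdir = "eit3d-run")
  ), class = "eit_config")
}

validate_against <- function(cfg, template, path = "") {
  unknown <- setdiff(names(cfg), names(template))
  stop_if(length(unknown) > 0, "unknown configuration key(s): ",
          paste0(path, unknown, collapse = ", "))
  for (nm in names(cfg)) {
    tv <- template[[nm]]
    if (is.list(tv) && !is.null(names(tv))) {
      stop_if(!is.list(cfg[[nm]]),
              "configuration key ", path, nm, " must be a mapping")
      validate_against(cfg[[nm]], tv, paste0(path, nm, "."))
    } else if (!is.null(tv) && !is.null(cfg[[nm]])) {
      stop_if(is.numeric(tv) && !is.numeric(cfg[[nm]]),
              "configuration key ", path, nm, " must be numeric")
      stop_if(is.character(tv) && !is.character(cfg[[nm]]),
              "configuration key ", path, nm, " must be a string")
    }
  }
  invisible(TRUE)
}

#' Load a run configuration
#'
#' Reads a YAML file, validates every key against the schema (unknown
#' keys are rejected by name), fills defaults, and applies command-line
#' style overrides (a named list using dotted paths, e.g.
#' `list("noise.snr_db" = 40)`), which take precedence over file values.
#' An empty or missing file yields the pure defaults.
#'
#' @param path YAML file path, or `NULL` for defaults.
#' @param overrides named list of dotted-path overrides.
#' @return an `eit_config`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    stop_if(!file.exists(path), "no such config file: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    stop_if(!is.list(user), "config file must contain a YAML mapping")
    validate_against(user, unclass(cfg))
    cfg <- modifyList(cfg, user)
  }
  for (key in names(overrides)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
    node <- unclass(cfg)
    # validate the path exists in the schema
    tmpl <- unclass(default_config())
    for (p in parts) {
      stop_if(!p %in% names(tmpl), "unknown configuration key: ", key)
      tmpl <- tmpl[[p]]
      if (!is.list(tmpl)) break
    }
    cfg[[parts]] <- overrides[[key]]
  }
  class(cfg) <- "eit_config"
  cfg
}

config_cylinder_spec <- function(cfg) {
  g <- cfg$geometry
  cylinder_spec(radius = g$radius_cm, height = g$height_cm,
                ring_heights = g$ring_heights_cm,
                electrodes_per_ring = g$electrodes_per_ring,
                electrode_angular_width = g$electrode_angular_width_deg,
                electrode_height = g$electrode_height_cm)
}

config_cem <- function(cfg) {
  cem_params(contact_impedance = cfg$cem$contact_impedance_ohm_m2,
             current_amplitude = cfg$cem$current_amplitude_A)
}
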