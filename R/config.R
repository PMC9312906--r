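#' Default pipeline configuration
#'
#' Fully populated configuration driving the end-to-end pipeline; every key
#' can be overridden from a YAML/JSON file or an override list. The
#' defaults reproduce the reference planning scenario: the smaller study
#' phantom, 10-slot antenna at 2.45 GHz, 0.8 mm grid, 600 s treatment with
#' snapshots at 200/400/600 s, Arrhenius completeness, 1 W power grid.
#'
#' @return nested named list of class `mwa_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 0L,
    phantom = list(preset = "ircad-1.07", amplitude = 0, seed = 0L,
                   subdivisions = 4L, mesh_path = NULL),
    materials = as.list(mwa_properties()),
    antenna = list(n_slots = 10L, slot_width = 0.6e-3, slot_spacing = 0.8e-3,
                   inner_radius = 0.135e-3, dielectric_radius = 0.47e-3,
                   outer_radius = 0.595e-3, catheter_radius = 0.895e-3,
                   feed_permittivity = 2.03, catheter_permittivity = 2.6,
                   tip_length = 2.0e-3, frequency = 2.45e9, power = 10,
                   efficiency = 1),
    em = list(backend = "slot", resolve_dT = 10, dz = 0.2e-3,
              dr_fine = 0.03e-3),
    grid = list(spacing = 0.8e-3, margin = 15e-3),
    simulation = list(duration = 600, dt = 0.25,
                      snapshot_times = c(200, 400, 600)),
    damage = list(frequency_factor = 7.39e39, activation_energy = 2.577e5,
                  necrosis_threshold = 0.99, isotherm_threshold = 60,
                  mode = "arrhenius"),
    planning = list(powers = 8:25, duration = 600, t_max = 900,
                    elongation_ratio = 1.6,
                    anchor = list(preset = "ircad-1.07", power = 10,
                                  time = 600, tol_s = 5)),
    output = list(dir = "mwa-output", formats = c("vtk", "csv"))
  ), class = "mwa_config")
}

# recursive unknown-key check of a user config against the default skeleton
check_config_keys <- function(user, ref, path = "") {
  for (nm in names(user)) {
    here <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(ref)) {
      stop("unknown config key: ", here)
    }
    if (is.list(user[[nm]]) && is.list(ref[[nm]]) &&
        !is.null(names(ref[[nm]]))) {
      check_config_keys(user[[nm]], ref[[nm]], here)
    }
  }
  invisible(TRUE)
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(base[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load and validate a pipeline configuration
#'
#' Merges a YAML (or JSON) configuration file and/or an override list over
#' [default_config()]. Unknown keys anywhere in the tree are rejected.
#'
#' @param path optional YAML/JSON config file.
#' @param overrides optional named list of overrides (applied after the
#'   file).
#' @return validated `mwa_config` list.
#' @export
load_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    check_config_keys(user, cfg)
    cfg <- merge_config(cfg, user)
  }
  if (!is.null(overrides)) {
    check_config_keys(overrides, cfg)
    cfg <- merge_config(cfg, overrides)
  }
  if (!cfg$em$backend %in% c("slot", "axisym")) {
    stop("em.backend must be 'slot' or 'axisym'")
  }
  if (!cfg$damage$mode %in% c("arrhenius", "isotherm")) {
    stop("damage.mode must be 'arrhenius' or 'isotherm'")
  }
  if (cfg$simulation$dt <= 0) stop("simulation.dt must be positive")
  if (cfg$simulation$duration < 0) stop("simulation.duration must be >= 0")
  structure(cfg, class = "mwa_config")
}

# constructors from config sections
config_props <- function(cfg) properties_from_list(cfg$materials)
config_antenna <- function(cfg) antenna_from_list(cfg$antenna)
config_damage <- function(cfg) {
  d <- cfg$damage
  damage_params(frequency_factor = d$frequency_factor,
                activation_energy = d$activation_energy,
                necrosis_threshold = d$necrosis_threshold,
                isotherm_threshold = d$isotherm_threshold)
}

# phantom + grid from config
config_grid <- function(cfg) {
  mesh <- if (!is.null(cfg$phantom$mesh_path)) {
    load_tumor_mesh(cfg$phantom$mesh_path)
  } else {
    generate_tumor_phantom(preset = cfg$phantom$preset,
                           perturbation_amplitude = cfg$phantom$amplitude,
                           seed = cfg$phantom$seed,
                           subdivisions = cfg$phantom$subdivisions)
  }
  voxelize(mesh, spacing = cfg$grid$spacing, antenna = config_antenna(cfg),
           margin = cfg$grid$margin)
}
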