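#' Tissue, blood and physical constants with temperature/damage dependence
#'
#' Bundles the baseline dielectric and thermal properties of healthy and
#' tumoral liver tissue and of blood, together with the parameters of the
#' temperature-dependent property models: the water-content sigmoid that
#' drives evaporation, the latent-heat correction of the specific heat, the
#' evaporation-driven decline of the dielectric properties, and the
#' damage-triggered cessation of blood perfusion.
#'
#' Units are SI throughout except temperatures, which are degrees Celsius:
#' densities kg/m^3, conductivities S/m (electric) and W/(m.degC) (thermal),
#' specific heats J/(kg.degC), perfusion rate 1/s, latent heat J/kg.
#'
#' @param healthy,tumor named lists with elements `density`,
#'   `rel_permittivity`, `conductivity`, `thermal_conductivity`,
#'   `specific_heat` for the two tissue classes.
#' @param blood named list with `density`, `thermal_conductivity`,
#'   `specific_heat`, `temperature` (arterial, degC) and `perfusion_rate`
#'   (volumetric blood flow per tissue volume, 1/s).
#' @param latent_heat latent heat of vaporization of tissue water (J/kg).
#' @param water_baseline baseline water mass fraction of liver tissue.
#' @param water_T50 centre (degC) of the logistic water-content drop; just
#'   above boiling so that evaporation acts as a heat sink near 100 degC.
#' @param water_width width (degC) of the logistic drop.
#' @param dielectric_floor residual fraction of the baseline permittivity and
#'   electric conductivity retained after complete desiccation.
#' @param perfusion_damage_threshold damage fraction theta above which
#'   capillary perfusion has ceased (coagulation); at or below the threshold
#'   perfusion stays at baseline.
#' @param metabolic_heat volumetric metabolic heat source Q_m (W/m^3);
#'   negligible next to the antenna deposition and 0 by default.
#' @param latent_heat_density_scaling if `TRUE`, the latent-heat term of the
#'   effective specific heat is scaled by (water density)/(tissue density),
#'   reading the water content as a volume fraction instead of a mass
#'   fraction. Off by default; kept for sensitivity studies.
#' @param evaporation if `FALSE`, all evaporation effects are disabled:
#'   c_eff = c and the dielectric properties stay at baseline. Used to freeze
#'   temperature dependence in linearity checks.
#'
#' @return An object of class `mwa_properties`.
#' @export
mwa_properties <- function(
    healthy = list(density = 1079, rel_permittivity = 44.3, conductivity = 1.8,
                   thermal_conductivity = 0.52, specific_heat = 3540),
    tumor = list(density = 1040, rel_permittivity = 54.8, conductivity = 2.0,
                 thermal_conductivity = 0.57, specific_heat = 3960),
    blood = list(density = 1060, thermal_conductivity = 0.5,
                 specific_heat = 3600, temperature = 37,
                 perfusion_rate = 0.0064),
    latent_heat = 2.260e6,
    water_baseline = 0.78,
    water_T50 = 102,
    water_width = 1.5,
    dielectric_floor = 0.1,
    perfusion_damage_threshold = 0.8,
    metabolic_heat = 0,
    latent_heat_density_scaling = FALSE,
    evaporation = TRUE) {
  tissue_fields <- c("density", "rel_permittivity", "conductivity",
                     "thermal_conductivity", "specific_heat")
  for (cls in list(healthy = healthy, tumor = tumor)) {
    missing <- setdiff(tissue_fields, names(cls))
    if (length(missing)) {
      stop("tissue property list lacks fields: ", paste(missing, collapse = ", "))
    }
    pos <- c("density", "rel_permittivity", "conductivity", "specific_heat")
    if (any(unlist(cls[pos]) <= 0)) {
      stop("tissue density, permittivity, conductivity and specific heat must be strictly positive")
    }
    if (cls$thermal_conductivity < 0) {
      stop("thermal conductivity must be non-negative")
    }
  }
  blood_fields <- c("density", "thermal_conductivity", "specific_heat",
                    "temperature", "perfusion_rate")
  missing <- setdiff(blood_fields, names(blood))
  if (length(missing)) {
    stop("blood property list lacks fields: ", paste(missing, collapse = ", "))
  }
  if (blood$density <= 0 || blood$specific_heat <= 0 ||
      blood$thermal_conductivity <= 0 || blood$perfusion_rate < 0) {
    stop("blood properties must be positive (perfusion rate non-negative)")
  }
  stopifnot(latent_heat > 0, water_baseline > 0, water_baseline < 1,
            water_width > 0, dielectric_floor >= 0, dielectric_floor <= 1,
            perfusion_damage_threshold > 0, perfusion_damage_threshold < 1)
  structure(list(
    healthy = healthy[tissue_fields],
    tumor = tumor[tissue_fields],
    blood = blood[blood_fields],
    latent_heat = latent_heat,
    water_baseline = water_baseline,
    water_T50 = water_T50,
    water_width = water_width,
    dielectric_floor = dielectric_floor,
    perfusion_damage_threshold = perfusion_damage_threshold,
    metabolic_heat = metabolic_heat,
    latent_heat_density_scaling = latent_heat_density_scaling,
    evaporation = evaporation
  ), class = "mwa_properties")
}

#' @export
print.mwa_properties <- function(x, ...) {
  cat("<mwa_properties>\n")
  cat(sprintf("  healthy: rho=%g, eps_r=%g, sigma=%g S/m, k=%g, c=%g\n",
              x$healthy$density, x$healthy$rel_permittivity,
              x$healthy$conductivity, x$healthy$thermal_conductivity,
              x$healthy$specific_heat))
  cat(sprintf("  tumor:   rho=%g, eps_r=%g, sigma=%g S/m, k=%g, c=%g\n",
              x$tumor$density, x$tumor$rel_permittivity, x$tumor$conductivity,
              x$tumor$thermal_conductivity, x$tumor$specific_heat))
  cat(sprintf("  blood:   rho=%g, c=%g, T=%g degC, W_b=%g 1/s\n",
              x$blood$density, x$blood$specific_heat, x$blood$temperature,
              x$blood$perfusion_rate))
  cat(sprintf("  water: W0=%g, T50=%g degC, width=%g degC; alpha=%g J/kg\n",
              x$water_baseline, x$water_T50, x$water_width, x$latent_heat))
  invisible(x)
}

#' Tissue water mass fraction as a function of temperature
#'
#' Logistic desiccation curve W(T) = W0 / (1 + exp((T - T50)/s)): equal to the
#' baseline water fraction at body temperature, dropping smoothly to zero
#' across a narrow band centred just above 100 degC as tissue water boils off.
#' Its (continuous) temperature derivative feeds the latent-heat correction of
#' [effective_specific_heat()].
#'
#' @param temperature temperature(s), degC. Vectorized.
#' @param props an [mwa_properties()] object.
#' @return water mass fraction(s) in (0, W0).
#' @export
water_content <- function(temperature, props = mwa_properties()) {
  stopifnot(inherits(props, "mwa_properties"), all(is.finite(temperature)))
  if (!props$evaporation) {
    return(rep(props$water_baseline, length(temperature)))
  }
  props$water_baseline /
    (1 + exp((temperature - props$water_T50) / props$water_width))
}

#' Temperature derivative of the water content curve
#'
#' @inheritParams water_content
#' @return dW/dT (1/degC), non-positive everywhere.
#' @export
water_content_deriv <- function(temperature, props = mwa_properties()) {
  stopifnot(inherits(props, "mwa_properties"), all(is.finite(temperature)))
  if (!props$evaporation) {
    return(rep(0, length(temperature)))
  }
  x <- (temperature - props$water_T50) / props$water_width
  # -W0 * e^x / (s * (1+e^x)^2), written via the stable logistic product
  p <- 1 / (1 + exp(-x))
  -props$water_baseline * p * (1 - p) / props$water_width
}

#' Effective specific heat with the latent heat of water evaporation
#'
#' Replaces the constant specific heat c by c_eff(T) = c - alpha * dW/dT,
#' where alpha is the latent heat of vaporization and W(T) the tissue water
#' mass fraction. Since W is non-increasing, c_eff >= c everywhere, and the
#' excess integrates (over the desiccation band) to alpha * W0: the energy
#' needed to boil off the tissue water appears as a narrow heat-capacity
#' peak, which caps the simulated temperature rise near 100 degC without an
#' explicit phase-change model.
#'
#' @inheritParams water_content
#' @param tissue `"tumor"` or `"healthy"` — selects the baseline c.
#' @return effective specific heat(s), J/(kg.degC).
#' @export
effective_specific_heat <- function(temperature, props = mwa_properties(),
                                    tissue = c("tumor", "healthy")) {
  tissue <- match.arg(tissue)
  c0 <- props[[tissue]]$specific_heat
  scale <- if (props$latent_heat_density_scaling) {
    1000 / props[[tissue]]$density
  } else {
    1
  }
  c0 - props$latent_heat * scale * water_content_deriv(temperature, props)
}

#' Temperature-dependent dielectric properties
#'
#' Relative permittivity and electric conductivity decline with temperature in
#' proportion to the remaining water content, floored at a residual fraction
#' of the 37 degC baseline: desiccated tissue keeps roughly a tenth of its
#' hydrated permittivity and conductivity, which deepens microwave
#' penetration as the ablation zone dries out.
#'
#' @inheritParams water_content
#' @param tissue_class `"tumor"` or `"healthy"`.
#' @return list with vectors `eps_r` and `sigma` (S/m).
#' @export
dielectric_at <- function(temperature, tissue_class, props = mwa_properties()) {
  if (!is.character(tissue_class) || length(tissue_class) != 1 ||
      !tissue_class %in% c("healthy", "tumor")) {
    stop("unknown tissue class: ", paste(tissue_class, collapse = ","))
  }
  base <- props[[tissue_class]]
  scale <- dielectric_scale(temperature, props)
  list(eps_r = base$rel_permittivity * scale,
       sigma = base$conductivity * scale)
}

# shared decline factor max(W(T)/W0, floor), used voxel-wise by the EM update
dielectric_scale <- function(temperature, props) {
  pmax(water_content(temperature, props) / props$water_baseline,
       props$dielectric_floor)
}

#' Blood perfusion rate as a function of accumulated thermal damage
#'
#' Capillary perfusion stays at the baseline rate while the tissue is viable
#' and ceases once coagulative damage passes a threshold: the perfusion rate
#' is W_b for damage fraction theta = 1 - exp(-Omega) at or below the
#' threshold (default 0.8) and 0 above it. The step makes perfusion monotone
#' non-increasing in Omega; ties sit on the perfused side.
#'
#' @param temperature temperature(s), degC (reserved; the cessation model is
#'   driven by damage, not instantaneous temperature).
#' @param omega Arrhenius damage integral(s), dimensionless, >= 0.
#' @param props an [mwa_properties()] object.
#' @return perfusion rate(s), 1/s.
#' @export
perfusion_at <- function(temperature, omega, props = mwa_properties()) {
  stopifnot(inherits(props, "mwa_properties"))
  if (any(omega < 0)) stop("damage integral omega must be non-negative")
  theta <- 1 - exp(-omega)
  ifelse(theta > props$perfusion_damage_threshold, 0,
         props$blood$perfusion_rate)
}

#' @rdname mwa_properties
#' @param x an `mwa_properties` object.
#' @param ... unused.
#' @export
as.list.mwa_properties <- function(x, ...) {
  unclass(x)
}

#' Rebuild a property set from a plain list (e.g. parsed YAML)
#'
#' @param x a named list as produced by `as.list()` on an `mwa_properties`
#'   object, possibly partial: absent entries keep their defaults.
#' @return an [mwa_properties()] object.
#' @export
properties_from_list <- function(x) {
  defaults <- formals(mwa_properties)
  args <- list()
  for (nm in names(x)) {
    if (!nm %in% names(defaults)) {
      stop("unknown materials key: ", nm)
    }
    if (nm %in% c("healthy", "tumor", "blood")) {
      base <- eval(defaults[[nm]])
      extra <- setdiff(names(x[[nm]]), names(base))
      if (length(extra)) stop("unknown materials key: ", nm, ".", extra[1])
      base[names(x[[nm]])] <- x[[nm]]
      args[[nm]] <- base
    } else {
      args[[nm]] <- x[[nm]]
    }
  }
  do.call(mwa_properties, args)
}
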