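#' Arrhenius thermal-damage parameters
#'
#' First-order irreversible-injury kinetics: the damage integral
#' Omega(t) = integral of A * exp(-dE / (R * T_K)) dt accumulates along the
#' temperature history, and the damage fraction theta = 1 - exp(-Omega) is
#' the locally killed cell fraction. Defaults are the standard liver
#' coagulation kinetics (A = 7.39e39 1/s, dE = 2.577e5 J/mol).
#'
#' @param frequency_factor A (1/s).
#' @param activation_energy dE (J/mol).
#' @param necrosis_threshold damage fraction theta* above which tissue is
#'   counted necrotic (complete ablation requires theta >= theta* in every
#'   tumor voxel); 0.99 corresponds to Omega ~ 4.6.
#' @param isotherm_threshold lethal-temperature alternative (degC): the 60
#'   degC isotherm is the classical instantly-lethal contour.
#' @return object of class `mwa_damage_params`.
#' @export
damage_params <- function(frequency_factor = 7.39e39,
                          activation_energy = 2.577e5,
                          necrosis_threshold = 0.99,
                          isotherm_threshold = 60) {
  stopifnot(frequency_factor > 0, activation_energy > 0,
            necrosis_threshold > 0, necrosis_threshold < 1)
  structure(list(
    frequency_factor = frequency_factor,
    activation_energy = activation_energy,
    gas_constant = 8.314,
    necrosis_threshold = necrosis_threshold,
    isotherm_threshold = isotherm_threshold
  ), class = "mwa_damage_params")
}

#' Arrhenius reaction rate at a temperature
#'
#' @param temperature degC, vectorized.
#' @param params [damage_params()].
#' @return damage accumulation rate (1/s).
#' @export
arrhenius_rate <- function(temperature, params = damage_params()) {
  params$frequency_factor *
    exp(-params$activation_energy /
          (params$gas_constant * (temperature + 273.15)))
}

#' Accumulate the Arrhenius damage integral across one time step
#'
#' Trapezoidal update Omega += dt/2 * (rate(T_start) + rate(T_end)); with
#' `temperature_end` omitted the temperature is held constant over the step
#' and the update reduces to the closed form dt * A * exp(-dE/(R T_K)).
#'
#' @param omega damage integral field (any numeric shape), >= 0.
#' @param temperature temperature field at the start of the step (degC),
#'   same shape as `omega`.
#' @param dt time step (s), >= 0.
#' @param params [damage_params()].
#' @param temperature_end optional temperature field at the end of the step.
#' @return updated damage integral, same shape as `omega`.
#' @export
arrhenius_increment <- function(omega, temperature, dt,
                                params = damage_params(),
                                temperature_end = NULL) {
  if (dt < 0) stop("dt must be non-negative")
  if (any(omega < 0)) stop("damage integral omega must be non-negative")
  r1 <- arrhenius_rate(temperature, params)
  r2 <- if (is.null(temperature_end)) r1 else
    arrhenius_rate(temperature_end, params)
  omega + dt * (r1 + r2) / 2
}

#' Damage fraction from the damage integral
#'
#' theta = 1 - exp(-Omega): the fraction of cells killed at a point.
#'
#' @param omega damage integral, >= 0.
#' @return damage fraction in \[0, 1).
#' @export
damage_fraction <- function(omega) {
  if (any(omega < 0)) stop("damage integral omega must be non-negative")
  1 - exp(-omega)
}

#' Necrosis mask from a thermal state
#'
#' Two lesion-boundary conventions: `"arrhenius"` marks voxels whose damage
#' fraction has reached the necrosis threshold; `"isotherm"` marks voxels at
#' or above the lethal isotherm (default 60 degC) in the instantaneous
#' temperature field.
#'
#' @param temperature temperature field (degC); used by the isotherm mode.
#' @param omega damage integral field; used by the arrhenius mode.
#' @param params [damage_params()].
#' @param mode `"arrhenius"` (default) or `"isotherm"`.
#' @return logical field of the same shape as the input field.
#' @export
necrosis_mask <- function(temperature = NULL, omega = NULL,
                          params = damage_params(),
                          mode = c("arrhenius", "isotherm")) {
  mode <- match.arg(mode)
  if (mode == "arrhenius") {
    if (is.null(omega)) stop("arrhenius mode requires the omega field")
    damage_fraction(omega) >= params$necrosis_threshold
  } else {
    if (is.null(temperature)) stop("isotherm mode requires the temperature field")
    temperature >= params$isotherm_threshold
  }
}

#' @rdname damage_params
#' @param x object.
#' @param ... unused.
#' @export
print.mwa_damage_params <- function(x, ...) {
  cat(sprintf("<mwa_damage_params> A=%g 1/s, dE=%g J/mol, theta*=%g, isotherm=%g degC\n",
              x$frequency_factor, x$activation_energy,
              x$necrosis_threshold, x$isotherm_threshold))
  invisible(x)
}
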