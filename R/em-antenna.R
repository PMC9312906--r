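#' Multi-slot coaxial microwave antenna specification
#'
#' Geometry and drive of the interstitial applicator: a thin coaxial line
#' whose outer conductor carries an array of radiating ring slots near the
#' tip (default 10 slots, 0.6 mm wide, spaced 0.8 mm apart), encased in a
#' dielectric catheter, operating at 2.45 GHz. The conductor radii of such
#' applicators are vendor-specific; the defaults below are a standard thin
#' MWA coax and are all configurable.
#'
#' The efficiency factor `efficiency` multiplies the port power before
#' deposition: it absorbs everything not modelled geometrically (the
#' impedance matching network, reflection losses, exact conductor radii) and
#' is normally set by [calibrate_efficiency()] against a reference operating
#' point.
#'
#' @param n_slots number of radiating slots (>= 1).
#' @param slot_width axial slot width (m).
#' @param slot_spacing axial gap between adjacent slots (m).
#' @param inner_radius inner-conductor radius (m).
#' @param dielectric_radius outer radius of the feed dielectric (m).
#' @param outer_radius outer-conductor outer radius (m).
#' @param catheter_radius catheter (sheath) outer radius (m).
#' @param feed_permittivity relative permittivity of the feed dielectric
#'   (PTFE ~ 2.03).
#' @param catheter_permittivity relative permittivity of the catheter sheath.
#' @param tip_length metallic tip length beyond the last slot (m).
#' @param frequency operating frequency (Hz).
#' @param power port input power P_in (W).
#' @param efficiency calibration factor eta in (0, 1.5].
#' @return object of class `mwa_antenna`.
#' @export
antenna_spec <- function(n_slots = 10,
                         slot_width = 0.6e-3,
                         slot_spacing = 0.8e-3,
                         inner_radius = 0.135e-3,
                         dielectric_radius = 0.47e-3,
                         outer_radius = 0.595e-3,
                         catheter_radius = 0.895e-3,
                         feed_permittivity = 2.03,
                         catheter_permittivity = 2.6,
                         tip_length = 2.0e-3,
                         frequency = 2.45e9,
                         power = 10,
                         efficiency = 1) {
  stopifnot(n_slots >= 1, slot_width > 0, slot_spacing >= 0,
            frequency > 0, power > 0, tip_length >= 0,
            feed_permittivity >= 1, catheter_permittivity >= 1)
  radii <- c(inner_radius, dielectric_radius, outer_radius, catheter_radius)
  if (any(diff(radii) <= 0) || inner_radius <= 0) {
    stop("antenna radii must be strictly increasing and positive")
  }
  if (efficiency <= 0 || efficiency > 1.5) {
    stop("efficiency must lie in (0, 1.5]")
  }
  structure(list(
    n_slots = as.integer(n_slots),
    slot_width = slot_width,
    slot_spacing = slot_spacing,
    inner_radius = inner_radius,
    dielectric_radius = dielectric_radius,
    outer_radius = outer_radius,
    catheter_radius = catheter_radius,
    feed_permittivity = feed_permittivity,
    catheter_permittivity = catheter_permittivity,
    tip_length = tip_length,
    frequency = frequency,
    power = power,
    efficiency = efficiency
  ), class = "mwa_antenna")
}

#' @export
print.mwa_antenna <- function(x, ...) {
  cat(sprintf("<mwa_antenna> %d slots (%.2g/%.2g mm width/gap), f=%.3g GHz, P=%g W, eta=%.3g\n",
              x$n_slots, 1e3 * x$slot_width, 1e3 * x$slot_spacing,
              x$frequency / 1e9, x$power, x$efficiency))
  invisible(x)
}

# total axial extent of the slot array (m)
slot_array_length <- function(antenna) {
  antenna$n_slots * antenna$slot_width +
    (antenna$n_slots - 1) * antenna$slot_spacing
}

# slot centre offsets relative to the slot-array midpoint (m)
slot_offsets <- function(antenna) {
  l <- slot_array_length(antenna)
  first <- -l / 2 + antenna$slot_width / 2
  first + (seq_len(antenna$n_slots) - 1) *
    (antenna$slot_width + antenna$slot_spacing)
}

antenna_from_list <- function(x) {
  if (is.null(x)) return(antenna_spec())
  known <- names(formals(antenna_spec))
  extra <- setdiff(names(x), known)
  if (length(extra)) stop("unknown antenna key: ", extra[1])
  do.call(antenna_spec, x)
}
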