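#' Initial thermal state on a labeled grid
#'
#' Temperature everywhere at the initial/body temperature and zero
#' accumulated damage.
#'
#' @param grid an `mwa_grid`.
#' @param T0 initial temperature (degC).
#' @return object of class `mwa_thermal_state` with fields `T` (degC),
#'   `omega` (damage integral), `time` (s) and `T_ref` (temperature at the
#'   last EM solve).
#' @export
thermal_state <- function(grid, T0 = 37) {
  tfield <- array(T0, dim = grid$dim)
  structure(list(T = tfield, omega = array(0, dim = grid$dim),
                 time = 0, T_ref = tfield),
            class = "mwa_thermal_state")
}

#' @export
print.mwa_thermal_state <- function(x, ...) {
  cat(sprintf("<mwa_thermal_state> t = %.1f s, T in [%.1f, %.1f] degC, max omega %.3g\n",
              x$time, min(x$T), max(x$T), max(x$omega)))
  invisible(x)
}

# lookup tables on a fine temperature grid for the C++ stepper
bioheat_tables <- function(props, dmg, t_grid = seq(-50, 400, by = 0.05)) {
  dwdt <- water_content_deriv(t_grid, props)
  sc_h <- if (props$latent_heat_density_scaling) 1000 / props$healthy$density else 1
  sc_t <- if (props$latent_heat_density_scaling) 1000 / props$tumor$density else 1
  list(grid = t_grid,
       ceff_add_healthy = -props$latent_heat * sc_h * dwdt,
       ceff_add_tumor = -props$latent_heat * sc_t * dwdt,
       arr_rate = arrhenius_rate(t_grid, dmg))
}

bioheat_cpp_args <- function(grid, props, dmg) {
  tabs <- bioheat_tables(props, dmg)
  list(labels = grid$labels, dim = grid$dim, spacing = grid$spacing,
       rho_l = c(props$healthy$density, props$tumor$density),
       k_l = c(props$healthy$thermal_conductivity,
               props$tumor$thermal_conductivity),
       c_l = c(props$healthy$specific_heat, props$tumor$specific_heat),
       blood_T = props$blood$temperature,
       perf_coeff = props$blood$density * props$blood$specific_heat *
         props$blood$perfusion_rate,
       omega_perf_off = -log1p(-props$perfusion_damage_threshold),
       Qm = props$metabolic_heat,
       tab_grid = tabs$grid,
       ceff_add_healthy = tabs$ceff_add_healthy,
       ceff_add_tumor = tabs$ceff_add_tumor,
       arr_rate = tabs$arr_rate,
       omega_necrosis = -log1p(-dmg$necrosis_threshold))
}

#' Advance the bioheat equation by one or more time steps
#'
#' One (or `nsteps`) implicit operator-split step(s) of the Pennes equation
#' with evaporation-corrected heat capacity, damage-gated perfusion and the
#' given EM heat source; the Arrhenius damage integral is accumulated
#' trapezoidally alongside. Diffusion is integrated implicitly
#' (unconditionally stable), perfusion and sources explicitly.
#'
#' @param state an [thermal_state()].
#' @param grid the `mwa_grid` the state lives on.
#' @param qext volumetric heat source array (W/m^3), e.g. from
#'   [em_source()].
#' @param dt time step (s).
#' @param props an [mwa_properties()] object.
#' @param dmg a [damage_params()] object.
#' @param nsteps number of steps to take.
#' @return the updated `mwa_thermal_state`.
#' @export
step_bioheat <- function(state, grid, qext, dt, props = mwa_properties(),
                         dmg = damage_params(), nsteps = 1) {
  stopifnot(inherits(state, "mwa_thermal_state"), dt > 0, nsteps >= 1)
  args <- bioheat_cpp_args(grid, props, dmg)
  res <- bioheat_run_cpp(state$T, state$omega, args$labels, args$dim,
                         args$spacing, qext, dt, as.integer(nsteps),
                         state$time, args$rho_l, args$k_l, args$c_l,
                         args$blood_T, args$perf_coeff, args$omega_perf_off,
                         args$Qm, args$tab_grid, args$ceff_add_healthy,
                         args$ceff_add_tumor, args$arr_rate,
                         0, state$T, -1L, args$omega_necrosis, FALSE)
  state$T <- array(res$T, dim = grid$dim)
  state$omega <- array(res$Omega, dim = grid$dim)
  state$time <- state$time + res$steps * dt
  state
}

#' Run a full ablation simulation
#'
#' Orchestrates the coupled loop: compute the EM heat source for the current
#' tissue state, integrate the bioheat equation, accumulate Arrhenius
#' damage, and re-solve the EM source whenever any voxel has drifted more
#' than `em_resolve_dT` degrees since the last solve (the dielectric
#' properties are temperature-dependent). Emits snapshots at requested
#' times and a per-step temperature series at the heating-centre monitor
#' point (the tissue voxel against the antenna surface at the slot-array
#' midpoint).
#'
#' @param grid an `mwa_grid`.
#' @param antenna an [antenna_spec()] (defaults to the grid's); set `power`
#'   and `efficiency` here.
#' @param duration simulated time (s).
#' @param props an [mwa_properties()] object.
#' @param dmg a [damage_params()] object.
#' @param dt time step (s).
#' @param backend EM backend, `"slot"` or `"axisym"`.
#' @param em_resolve_dT re-solve the EM source when the maximum temperature
#'   change since the last solve exceeds this (degC); 0 disables re-solves.
#' @param snapshot_times times (s) at which to store full (T, omega) fields.
#' @param stop_on_coverage stop as soon as every tumor voxel is necrotic
#'   (used by the ablation-time search).
#' @param t_max hard cap on simulated time when `stop_on_coverage` is set.
#' @param em_opts options passed to the axisym solver.
#' @return object of class `mwa_run`: final `state`, `snapshots` (list of
#'   states), `series` (data.frame time/T_monitor), `t_abl` (earliest time
#'   of complete tumor necrosis, NA if not reached), `qext` (last source).
#' @export
run_simulation <- function(grid, antenna = grid$antenna, duration,
                           props = mwa_properties(), dmg = damage_params(),
                           dt = 0.25, backend = c("slot", "axisym"),
                           em_resolve_dT = 10, snapshot_times = numeric(0),
                           stop_on_coverage = FALSE, t_max = duration,
                           em_opts = list()) {
  backend <- match.arg(backend)
  stopifnot(duration >= 0)
  state <- thermal_state(grid, T0 = props$blood$temperature)
  horizon <- if (stop_on_coverage) max(duration, t_max) else duration
  snapshots <- list()
  if (horizon == 0) {
    return(structure(list(grid = grid, antenna = antenna, state = state,
                          snapshots = list(state), t_abl = NA_real_,
                          series = data.frame(time = numeric(0),
                                              T_monitor = numeric(0)),
                          backend = backend, qext = NULL),
                     class = "mwa_run"))
  }
  args <- bioheat_cpp_args(grid, props, dmg)
  monitor <- heating_center_index(grid)
  midx <- (monitor[1] - 1L) + grid$dim[1] * (monitor[2] - 1L) +
    grid$dim[1] * grid$dim[2] * (monitor[3] - 1L)
  qext <- em_source(grid, antenna, props, temperature = NULL,
                    backend = backend, em_opts = em_opts)
  state$T_ref <- state$T
  events <- sort(unique(c(snapshot_times[snapshot_times > 0 &
                                           snapshot_times <= horizon],
                          horizon)))
  t_abl <- NA_real_
  ser_t <- list(); ser_m <- list()
  done <- FALSE
  for (ev in events) {
    while (state$time < ev - dt / 2 && !done) {
      nst <- max(1L, as.integer(round((ev - state$time) / dt)))
      res <- bioheat_run_cpp(state$T, state$omega, args$labels, args$dim,
                             args$spacing, qext, dt, nst, state$time,
                             args$rho_l, args$k_l, args$c_l, args$blood_T,
                             args$perf_coeff, args$omega_perf_off, args$Qm,
                             args$tab_grid, args$ceff_add_healthy,
                             args$ceff_add_tumor, args$arr_rate,
                             em_resolve_dT, state$T_ref, midx,
                             args$omega_necrosis, stop_on_coverage)
      state$T <- array(res$T, dim = grid$dim)
      state$omega <- array(res$Omega, dim = grid$dim)
      state$time <- res$times[length(res$times)]
      ser_t[[length(ser_t) + 1]] <- res$times
      ser_m[[length(ser_m) + 1]] <- res$monitor
      if (is.na(t_abl) && !is.na(res$t_abl)) t_abl <- res$t_abl
      if (res$reason == 1) { # EM re-solve cadence fired
        qext <- em_source(grid, antenna, props, temperature = state$T,
                          backend = backend, em_opts = em_opts)
        state$T_ref <- state$T
      } else if (res$reason == 2 && stop_on_coverage) {
        done <- TRUE
      }
    }
    if (ev %in% snapshot_times) {
      snapshots[[length(snapshots) + 1]] <- state
    }
    if (done) break
  }
  structure(list(grid = grid, antenna = antenna, state = state,
                 snapshots = snapshots, t_abl = t_abl,
                 series = data.frame(time = unlist(ser_t),
                                     T_monitor = unlist(ser_m)),
                 backend = backend, qext = qext),
            class = "mwa_run")
}

#' @export
print.mwa_run <- function(x, ...) {
  cat(sprintf("<mwa_run> P=%g W (eta=%.3g), t=%.0f s, backend=%s\n",
              x$antenna$power, x$antenna$efficiency, x$state$time, x$backend))
  if (!is.na(x$t_abl)) {
    cat(sprintf("  complete tumor necrosis at t = %.2f s\n", x$t_abl))
  }
  invisible(x)
}
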