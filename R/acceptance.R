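#' Recompute the headline planning quantities of the reference study
#'
#' End-to-end reproduction of the study's planning analysis on the two
#' synthetic phantoms: calibrates the antenna efficiency so the smaller
#' phantom (preset `ircad-1.07`) is just completely ablated at the anchor
#' operating point (10 W, 600 s), then measures ablation times for both
#' phantoms across the printed powers, the minimal power that fully
#' ablates the larger phantom (preset `ircad-1.03`) within 600 s, the
#' relative time differences between the phantoms, the high-power time
#' reductions, and the heating-centre temperatures after 600 s at each
#' tumor's selected power.
#'
#' All quantities are computed from scratch by simulation; runs are cached
#' within one call (the same power/phantom pair is never simulated twice).
#'
#' @param seed integer seed controlling every stochastic input (the
#'   amplitude-0 phantoms are deterministic; the seed still fixes their
#'   generator state).
#' @param spacing voxel size (m) of the simulation grids.
#' @param dt bioheat time step (s).
#' @param backend EM backend (`"slot"` or `"axisym"`).
#' @param margin healthy-tissue margin (m).
#' @param opt_powers ascending power grid (W) searched for the minimal
#'   achieving power of the larger phantom.
#' @param reuse_center_runs if `TRUE`, the heating-centre temperatures are
#'   read from the cached ablation runs at each tumor's selected power
#'   (whose monitor series end within ~30 s of the 600 s mark) instead of
#'   two dedicated 600 s runs; saves two full simulations at a <1 degC
#'   cost near thermal saturation.
#' @param verbose print progress lines.
#' @return named list of scalar results: `optimal_power_103`,
#'   `t_abl_107_15W`, `t_abl_107_17W`, `t_abl_103_15W`, `t_abl_103_17W`,
#'   `rel_diff_12W_pct`, `rel_diff_25W_pct`, `reduction_107_10_25_pct`,
#'   `reduction_103_12_25_pct`, `T_center_107_10W`, `T_center_103_12W`,
#'   plus `eta` and the cached ablation-time tables.
#' @export
compute_acceptance_targets <- function(seed = 0, spacing = 0.8e-3,
                                       dt = 0.25, backend = "axisym",
                                       margin = 15e-3,
                                       opt_powers = 9:15,
                                       reuse_center_runs = FALSE,
                                       verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  ant <- antenna_spec(power = 10)
  g07 <- voxelize(generate_tumor_phantom("ircad-1.07", seed = seed),
                  spacing = spacing, antenna = ant, margin = margin)
  g03 <- voxelize(generate_tumor_phantom("ircad-1.03", seed = seed),
                  spacing = spacing, antenna = ant, margin = margin)
  say("grids: 1.07 %s voxels, 1.03 %s voxels",
      prod(g07$dim), prod(g03$dim))
  cal <- calibrate_efficiency(g07, ant, anchor_power = 10,
                              anchor_time = 600, tol_s = 5,
                              dt = dt, backend = backend)
  ant$efficiency <- cal$eta
  say("calibrated eta = %.4f (anchor ablation %.1f s)", cal$eta, cal$t_abl)
  cache <- new.env()
  get_run <- function(grid, tag, power, t_max = 900) {
    key <- sprintf("%s_%g", tag, power)
    hit <- cache[[key]]
    # re-run when a shorter-budget scan result (NA) is asked for in full
    if (is.null(hit) || (is.na(hit$t_abl) && t_max > hit$t_max)) {
      res <- ablation_time(grid, ant, power = power, t_max = t_max,
                           dt = dt, backend = backend)
      res$t_max <- t_max
      cache[[key]] <- res
      say("t_abl %s @ %g W: %.1f s", tag, power, res$t_abl)
    }
    cache[[key]]
  }
  t_abl <- function(grid, tag, power, t_max = 900) {
    if (tag == "107" && power == 10 &&
        is.null(cache[["107_10"]])) {
      return(cal$t_abl)
    }
    get_run(grid, tag, power, t_max)$t_abl
  }
  # minimal power fully ablating the 1.03 phantom within 600 s; the scan
  # runs only need to decide "within 600 s or not", so they stop at 660 s
  opt103 <- NA_real_
  for (p in opt_powers) {
    tp <- t_abl(g03, "103", p, t_max = 660)
    if (!is.na(tp) && tp <= 600) { opt103 <- p; break }
  }
  res <- list(eta = cal$eta,
              n_tumor_107 = sum(g07$labels == 2L),
              n_tumor_103 = sum(g03$labels == 2L))
  res$optimal_power_103 <- opt103
  res$t_abl_107_15W <- t_abl(g07, "107", 15)
  res$t_abl_107_17W <- t_abl(g07, "107", 17)
  res$t_abl_103_15W <- t_abl(g03, "103", 15)
  res$t_abl_103_17W <- t_abl(g03, "103", 17)
  t07_12 <- t_abl(g07, "107", 12)
  t03_12 <- t_abl(g03, "103", 12)
  t07_25 <- t_abl(g07, "107", 25)
  t03_25 <- t_abl(g03, "103", 25)
  t07_10 <- t_abl(g07, "107", 10)
  res$rel_diff_12W_pct <- (t03_12 - t07_12) / t07_12 * 100
  res$rel_diff_25W_pct <- (t03_25 - t07_25) / t07_25 * 100
  res$reduction_107_10_25_pct <- (t07_10 - t07_25) / t07_10 * 100
  res$reduction_103_12_25_pct <- (t03_12 - t03_25) / t03_12 * 100
  # heating-centre temperatures after the full 600 s treatments
  if (reuse_center_runs) {
    last_T <- function(run) run$series$T_monitor[nrow(run$series)]
    res$T_center_107_10W <- last_T(get_run(g07, "107", 10)$run)
    res$T_center_103_12W <- last_T(get_run(g03, "103", 12)$run)
  } else {
    a10 <- ant; a10$power <- 10
    r07 <- run_simulation(g07, a10, duration = 600, dt = dt,
                          backend = backend)
    res$T_center_107_10W <- r07$series$T_monitor[nrow(r07$series)]
    a12 <- ant; a12$power <- 12
    r03 <- run_simulation(g03, a12, duration = 600, dt = dt,
                          backend = backend)
    res$T_center_103_12W <- r03$series$T_monitor[nrow(r03$series)]
  }
  res$times_107 <- c(`10` = t07_10, `12` = t07_12, `15` = res$t_abl_107_15W,
                     `17` = res$t_abl_107_17W, `25` = t07_25)
  res$times_103 <- c(`12` = t03_12, `15` = res$t_abl_103_15W,
                     `17` = res$t_abl_103_17W, `25` = t03_25)
  res
}
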