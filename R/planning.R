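#' Ablation-zone coverage, healthy damage and safety margin
#'
#' Quantifies a thermal state against the treatment goal: `coverage` is the
#' fraction of tumor voxels inside the necrosis zone, `healthy_damage_cm3`
#' the necrosed healthy-tissue volume, and `margin_mm` the minimal signed
#' distance (mm) from the tumor surface to the necrosis boundary — positive
#' when the whole surface sits inside the necrotic zone with room to spare,
#' negative as soon as any surface point lies outside it.
#'
#' @param state an `mwa_thermal_state`.
#' @param grid the `mwa_grid`.
#' @param dmg a [damage_params()] object.
#' @param mode necrosis criterion, `"arrhenius"` or `"isotherm"`.
#' @return one-row data.frame with `coverage`, `healthy_damage_cm3`,
#'   `margin_mm`.
#' @export
coverage_metrics <- function(state, grid, dmg = damage_params(),
                             mode = c("arrhenius", "isotherm")) {
  mode <- match.arg(mode)
  lab <- grid$labels
  n_tumor <- sum(lab == LBL_TUMOR)
  if (n_tumor == 0) stop("grid contains no tumor voxels")
  mask <- necrosis_mask(temperature = state$T, omega = state$omega,
                        params = dmg, mode = mode)
  coverage <- sum(mask & lab == LBL_TUMOR) / n_tumor
  healthy_cm3 <- sum(mask & lab == LBL_HEALTHY) * voxel_volume(grid) * 1e6
  margin <- necrosis_margin_mm(mask, grid)
  data.frame(coverage = coverage, healthy_damage_cm3 = healthy_cm3,
             margin_mm = margin)
}

# signed distance (mm) from tumor-surface mesh vertices to the necrosis
# boundary: + when every vertex is inside the necrotic zone, - otherwise
necrosis_margin_mm <- function(mask, grid) {
  verts <- grid$mesh$vertices
  if (!any(mask)) return(-Inf)
  # boundary voxels: masked with an unmasked / outside face neighbor
  d <- dim(mask)
  shift_or <- function(m) {
    out <- array(FALSE, dim = d)
    out[-1, , ] <- out[-1, , ] | !m[-d[1], , ]
    out[-d[1], , ] <- out[-d[1], , ] | !m[-1, , ]
    out[, -1, ] <- out[, -1, ] | !m[, -d[2], ]
    out[, -d[2], ] <- out[, -d[2], ] | !m[, -1, ]
    out[, , -1] <- out[, , -1] | !m[, , -d[3]]
    out[, , -d[3]] <- out[, , -d[3]] | !m[, , -1]
    # domain faces also count as boundary
    out[c(1, d[1]), , ] <- TRUE
    out[, c(1, d[2]), ] <- TRUE
    out[, , c(1, d[3])] <- TRUE
    out
  }
  bnd <- mask & shift_or(mask)
  idx <- which(bnd, arr.ind = TRUE)
  bpts <- cbind(grid_centers(grid, 1)[idx[, 1]],
                grid_centers(grid, 2)[idx[, 2]],
                grid_centers(grid, 3)[idx[, 3]])
  dist <- min_dist_cpp(verts, bpts)
  # sign: vertex inside the necrosis mask (nearest-voxel membership)
  vi <- pmin(pmax(ceiling((verts[, 1] - grid$origin[1]) / grid$spacing), 1), d[1])
  vj <- pmin(pmax(ceiling((verts[, 2] - grid$origin[2]) / grid$spacing), 1), d[2])
  vk <- pmin(pmax(ceiling((verts[, 3] - grid$origin[3]) / grid$spacing), 1), d[3])
  inside <- mask[cbind(vi, vj, vk)]
  signed <- ifelse(inside, dist, -dist)
  min(signed) * 1e3
}

# axial / transverse aspect ratio of the necrosis zone
necrosis_elongation <- function(mask, grid) {
  if (!any(mask)) return(NA_real_)
  idx <- which(mask, arr.ind = TRUE)
  ax <- (max(idx[, 3]) - min(idx[, 3]) + 1)
  tr <- max(max(idx[, 1]) - min(idx[, 1]) + 1,
            max(idx[, 2]) - min(idx[, 2]) + 1)
  ax / tr
}

#' Earliest time of complete tumor necrosis at a given input power
#'
#' Runs the calibrated simulation at power `power` and reports the first
#' time at which every tumor voxel has reached the Arrhenius necrosis
#' threshold (or the lethal isotherm). Completion is monitored at every
#' time step, so the returned time is resolved to the integration step —
#' well inside the +-5 s reporting convention. Returns `NA` when coverage
#' is not reached within `t_max`.
#'
#' @param grid an `mwa_grid`.
#' @param antenna an [antenna_spec()]; its `power` field is overridden.
#' @param power input power P_in (W).
#' @param t_max time budget (s).
#' @param props,dmg material and damage parameters.
#' @param ... further arguments to [run_simulation()] (`dt`, `backend`, ...).
#' @return list with `t_abl` (s or NA), and the finished `run`.
#' @export
ablation_time <- function(grid, antenna = grid$antenna, power,
                          t_max = 900, props = mwa_properties(),
                          dmg = damage_params(), ...) {
  stopifnot(power > 0, t_max > 0)
  antenna$power <- power
  run <- run_simulation(grid, antenna, duration = t_max, props = props,
                        dmg = dmg, stop_on_coverage = TRUE, t_max = t_max,
                        ...)
  list(t_abl = run$t_abl, run = run)
}

#' Ablation-time-versus-power sweep
#'
#' Evaluates [ablation_time()] across a power grid, returning the t(P)
#' curve together with the per-power treatment metrics (coverage at the
#' end of the run, healthy damage, margin, elongation flag).
#'
#' @inheritParams ablation_time
#' @param powers ascending power grid (W).
#' @param elongation_ratio axial/transverse aspect ratio above which the
#'   necrosis zone is flagged as undesirably elongated.
#' @return data.frame with one row per power: `power`, `t_abl`, `achieved`,
#'   `coverage`, `healthy_damage_cm3`, `margin_mm`, `elongation`,
#'   `elongated`.
#' @export
power_sweep <- function(grid, antenna = grid$antenna, powers,
                        t_max = 900, props = mwa_properties(),
                        dmg = damage_params(), elongation_ratio = 1.6, ...) {
  stopifnot(length(powers) >= 1, !is.unsorted(powers))
  rows <- lapply(powers, function(p) {
    at <- ablation_time(grid, antenna, power = p, t_max = t_max,
                        props = props, dmg = dmg, ...)
    st <- at$run$state
    met <- coverage_metrics(st, grid, dmg)
    mask <- necrosis_mask(omega = st$omega, params = dmg)
    elo <- necrosis_elongation(mask, grid)
    data.frame(power = p, t_abl = at$t_abl, achieved = !is.na(at$t_abl),
               coverage = met$coverage,
               healthy_damage_cm3 = met$healthy_damage_cm3,
               margin_mm = met$margin_mm, elongation = elo,
               elongated = !is.na(elo) && elo > elongation_ratio)
  })
  do.call(rbind, rows)
}

#' Minimal input power that completely ablates the tumor in a time budget
#'
#' Walks an ascending power grid and returns the smallest power whose
#' ablation completes within `duration`; powers are also screened for
#' undesirably elongated necrosis zones (axial extent much larger than
#' transverse), the failure mode of high-power settings.
#'
#' @inheritParams power_sweep
#' @param duration treatment time budget (s).
#' @param stop_at_first stop evaluating once the first achieving power is
#'   found (the optimum is by definition the smallest achieving power).
#' @return list with `optimal_power` (W, or NA if no power achieves
#'   coverage), and `sweep`, the evaluated subset of the power grid.
#' @export
optimal_power <- function(grid, antenna = grid$antenna, duration = 600,
                          powers = 8:25, props = mwa_properties(),
                          dmg = damage_params(), elongation_ratio = 1.6,
                          stop_at_first = TRUE, ...) {
  stopifnot(length(powers) >= 1, !is.unsorted(powers))
  rows <- list()
  opt <- NA_real_
  for (p in powers) {
    at <- ablation_time(grid, antenna, power = p, t_max = duration,
                        props = props, dmg = dmg, ...)
    st <- at$run$state
    met <- coverage_metrics(st, grid, dmg)
    mask <- necrosis_mask(omega = st$omega, params = dmg)
    elo <- necrosis_elongation(mask, grid)
    rows[[length(rows) + 1]] <-
      data.frame(power = p, t_abl = at$t_abl, achieved = !is.na(at$t_abl),
                 coverage = met$coverage,
                 healthy_damage_cm3 = met$healthy_damage_cm3,
                 margin_mm = met$margin_mm, elongation = elo,
                 elongated = !is.na(elo) && elo > elongation_ratio)
    if (is.na(opt) && !is.na(at$t_abl)) {
      opt <- p
      if (stop_at_first) break
    }
  }
  list(optimal_power = opt, sweep = do.call(rbind, rows))
}

#' Calibrate the antenna efficiency factor against an anchor operating point
#'
#' The model's single bridge to an absolute operating point: finds the
#' efficiency factor eta such that the anchor phantom is just completely
#' ablated at the anchor power and time (default: the smaller study phantom
#' at 10 W reaching complete necrosis at 600 s). Solved by bisection on
#' eta, for which the ablation time is monotone decreasing; iteration ends
#' when the achieved ablation time is within `tol_s` of the anchor time.
#'
#' @param grid the anchor phantom's `mwa_grid`.
#' @param antenna an [antenna_spec()].
#' @param anchor_power anchor input power (W).
#' @param anchor_time anchor ablation time (s).
#' @param tol_s ablation-time tolerance (s).
#' @param eta_range search interval for eta.
#' @param props,dmg material and damage parameters.
#' @param ... further arguments to [run_simulation()].
#' @return list with `eta`, `t_abl` (achieved anchor ablation time, s) and
#'   `iterations`.
#' @export
calibrate_efficiency <- function(grid, antenna = grid$antenna,
                                 anchor_power = 10, anchor_time = 600,
                                 tol_s = 5, eta_range = c(0.05, 1.5),
                                 props = mwa_properties(),
                                 dmg = damage_params(), ...) {
  t_max <- anchor_time * 1.4
  eval_eta <- function(eta) {
    a <- antenna
    a$efficiency <- eta
    ablation_time(grid, a, power = anchor_power, t_max = t_max,
                  props = props, dmg = dmg, ...)$t_abl
  }
  lo <- eta_range[1]; hi <- eta_range[2]
  t_hi <- eval_eta(hi)
  if (is.na(t_hi) || t_hi > anchor_time + tol_s) {
    stop(sprintf("no efficiency in (%g, %g] ablates the anchor phantom at %g W within %g s",
                 lo, hi, anchor_power, anchor_time + tol_s))
  }
  if (abs(t_hi - anchor_time) <= tol_s) {
    return(list(eta = hi, t_abl = t_hi, iterations = 1L))
  }
  # bracketed secant on the monotone decreasing t_abl(eta); not-achieved
  # runs enter the secant as t_max (they only tighten the lower bracket)
  it <- 1L
  best <- c(eta = hi, t = t_hi)
  pts <- data.frame(eta = hi, t = t_hi)
  while (it < 25L) {
    cand <- NA_real_
    if (nrow(pts) >= 2) {
      p <- pts[order(abs(pts$t - anchor_time))[1:2], ]
      if (diff(p$t) != 0) {
        cand <- p$eta[1] + (anchor_time - p$t[1]) *
          diff(p$eta) / diff(p$t)
      }
    } else if (is.finite(t_hi) && t_hi > 0) {
      # first interior guess: ablation time scales roughly inversely with
      # the deposited power over the relevant range
      cand <- hi * (t_hi / anchor_time)^0.7
    }
    frac_lo <- lo + 0.05 * (hi - lo)
    frac_hi <- hi - 0.05 * (hi - lo)
    mid <- if (is.na(cand) || cand < frac_lo || cand > frac_hi) {
      (lo + hi) / 2
    } else {
      cand
    }
    t_mid <- eval_eta(mid)
    it <- it + 1L
    if (!is.na(t_mid) && abs(t_mid - anchor_time) <= tol_s) {
      return(list(eta = mid, t_abl = t_mid, iterations = it))
    }
    pts <- rbind(pts, data.frame(eta = mid,
                                 t = if (is.na(t_mid)) t_max else t_mid))
    if (is.na(t_mid) || t_mid > anchor_time) {
      lo <- mid
    } else {
      hi <- mid
      best <- c(eta = mid, t = t_mid)
    }
    if (hi - lo < 1e-4) break
  }
  list(eta = unname(best["eta"]), t_abl = unname(best["t"]), iterations = it)
}
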