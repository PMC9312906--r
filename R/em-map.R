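#' Map an axisymmetric EM solution onto the 3D voxel grid
#'
#' Rotates the (r, z) dissipation density around the antenna axis:
#' Q(x, y, z) = Q2d(r = sqrt((x-x0)^2 + (y-y0)^2), z - z_slot) by bilinear
#' interpolation, zeroed inside the antenna, then renormalized so the
#' voxel-integrated power equals efficiency * P_in exactly.
#'
#' @param sol an `mwa_em` from [solve_axisym_field()].
#' @param grid an `mwa_grid` (antenna axis along +z, as built by
#'   [voxelize()]).
#' @return 3D array of Q_ext (W/m^3) with attribute `power` (W).
#' @export
sar_to_grid <- function(sol, grid) {
  stopifnot(inherits(sol, "mwa_em"), inherits(grid, "mwa_grid"))
  lab <- grid$labels
  tissue <- lab == LBL_HEALTHY | lab == LBL_TUMOR
  xc <- grid_centers(grid, 1) - grid$axis$x
  yc <- grid_centers(grid, 2) - grid$axis$y
  zc <- grid_centers(grid, 3) - grid$axis$slot_center_z
  rho <- sqrt(outer(xc^2, yc^2, "+"))
  nr <- length(sol$r); nz <- length(sol$z)
  # radial interpolation weights (nonuniform r axis)
  ir <- findInterval(rho, sol$r)
  ir[ir < 1] <- 1
  ir[ir > nr - 1] <- nr - 1
  r1 <- sol$r[ir]; r2 <- sol$r[ir + 1]
  wr <- pmin(pmax((rho - r1) / (r2 - r1), 0), 1)
  q <- array(0, dim = grid$dim)
  q2 <- sol$Q2d
  for (k in seq_len(grid$dim[3])) {
    jz <- findInterval(zc[k], sol$z)
    if (jz < 1 || jz >= nz) next # outside the EM domain: negligible far field
    wz <- (zc[k] - sol$z[jz]) / (sol$z[jz + 1] - sol$z[jz])
    qa <- (1 - wr) * q2[cbind(as.vector(ir), jz)] +
      wr * q2[cbind(as.vector(ir + 1), jz)]
    qb <- (1 - wr) * q2[cbind(as.vector(ir), jz + 1)] +
      wr * q2[cbind(as.vector(ir + 1), jz + 1)]
    q[, , k] <- (1 - wz) * qa + wz * qb
  }
  q[!tissue] <- 0
  target <- sol$antenna$efficiency * sol$antenna$power
  tot <- sum(q) * voxel_volume(grid)
  if (tot <= 0) stop("mapped EM solution deposits no power in tissue")
  q <- q * (target / tot)
  attr(q, "power") <- target
  q
}

#' Compute the volumetric EM heat source for the current tissue state
#'
#' One switchable entry point over the two interchangeable backends: the
#' axisymmetric full-wave solve ([solve_axisym_field()] + [sar_to_grid()])
#' and the analytic [slot_source_model()]. Both return the heat source on
#' the voxel grid normalized to efficiency * P_in.
#'
#' @param grid an `mwa_grid`.
#' @param antenna an [antenna_spec()]; defaults to the grid's.
#' @param props an [mwa_properties()] object.
#' @param temperature optional temperature field for property decline.
#' @param backend `"slot"` or `"axisym"`.
#' @param em_opts list of axisym options (`r_max`, `z_range`, `dz`,
#'   `dr_fine`) overriding the solver defaults.
#' @return 3D Q_ext array (W/m^3) with attribute `power`.
#' @export
em_source <- function(grid, antenna = grid$antenna, props = mwa_properties(),
                      temperature = NULL,
                      backend = c("slot", "axisym"), em_opts = list()) {
  backend <- match.arg(backend)
  if (backend == "slot") {
    return(slot_source_model(antenna, grid, props, temperature))
  }
  prof <- profile_from_grid(grid, props, temperature)
  zspan <- range(grid_centers(grid, 3)) - grid$axis$slot_center_z
  # the (r, z) solve domain covers the whole voxel grid plus a small pad,
  # so the 3D mapping never truncates deposited power
  args <- list(antenna = antenna, tissue_profile = prof,
               r_max = max(abs(c(grid_centers(grid, 1) - grid$axis$x,
                                 grid_centers(grid, 2) - grid$axis$y))) +
                 2e-3,
               z_range = zspan + c(-2e-3, 2e-3))
  args[names(em_opts)] <- em_opts
  sol <- do.call(solve_axisym_field, args)
  sar_to_grid(sol, grid)
}
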