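# voxel label codes
LBL_HEALTHY <- 1L
LBL_TUMOR <- 2L
LBL_METAL <- 3L
LBL_DIELECTRIC <- 4L

#' Choose the antenna insertion axis for a tumor mesh
#'
#' The simulation frame fixes the antenna axis parallel to +z (insertion
#' from above). The default strategy drops a vertical axis through the
#' volume centroid of the mesh and centres the slot array at the centroid;
#' the explicit strategy places the slot-array midpoint at a user-given
#' target point.
#'
#' @param mesh an `mwa_mesh`.
#' @param strategy `"centroid-z"` (default) or `"explicit"`.
#' @param target for `"explicit"`: length-3 point (m) where the slot-array
#'   midpoint is placed; the axis is the vertical line through it.
#' @return list with `x`, `y` (axis position, m) and `slot_center_z` (m).
#' @export
place_antenna <- function(mesh, strategy = c("centroid-z", "explicit"),
                          target = NULL) {
  strategy <- match.arg(strategy)
  if (strategy == "centroid-z") {
    cen <- mesh_centroid(mesh)
    axis <- list(x = cen[1], y = cen[2], slot_center_z = cen[3])
  } else {
    stopifnot(!is.null(target), length(target) == 3)
    axis <- list(x = target[1], y = target[2], slot_center_z = target[3])
  }
  # the vertical line through (x, y) must traverse the tumor
  bb <- mesh_bbox(mesh)
  zs <- seq(bb[1, 3], bb[2, 3], length.out = 101)
  probe <- cbind(axis$x, axis$y, zs)
  if (!any(points_in_mesh_cpp(mesh$vertices, mesh$faces, probe))) {
    stop("antenna axis does not intersect the tumor mesh")
  }
  axis
}

#' Voxelize a tumor mesh and antenna into a labeled simulation grid
#'
#' Builds a uniform Cartesian grid containing the mesh plus a healthy-tissue
#' margin on all sides, labels voxels whose centres fall inside the mesh as
#' tumor (ray-parity point-in-polyhedron test), and overrides tissue labels
#' with the antenna cross-section (metal core, dielectric catheter annulus)
#' along the insertion axis from the grid top down to the antenna tip.
#'
#' @param mesh an `mwa_mesh`.
#' @param spacing voxel edge length (m), at most 1 mm.
#' @param antenna an [antenna_spec()].
#' @param margin healthy-tissue margin added around the mesh bounding box on
#'   all sides (m).
#' @param axis optional placement from [place_antenna()]; default is the
#'   centroid-z strategy.
#' @return object of class `mwa_grid` with fields `origin` (m), `spacing`,
#'   `dim`, `labels` (integer array: 1 healthy, 2 tumor, 3 antenna metal,
#'   4 antenna dielectric), `axis`, `antenna`, `mesh`.
#' @export
voxelize <- function(mesh, spacing = 0.5e-3, antenna = antenna_spec(),
                     margin = 15e-3, axis = NULL) {
  stopifnot(inherits(mesh, "mwa_mesh"), inherits(antenna, "mwa_antenna"))
  if (spacing <= 0 || spacing > 1e-3) {
    stop("spacing must be positive and at most 1 mm")
  }
  if (margin < 0) stop("margin must be non-negative")
  if (is.null(axis)) axis <- place_antenna(mesh)
  bb <- mesh_bbox(mesh)
  origin <- bb[1, ] - margin
  dim3 <- as.integer(ceiling((bb[2, ] + margin - origin) / spacing))
  inside <- voxelize_mesh_cpp(mesh$vertices, mesh$faces, origin, spacing, dim3)
  labels <- array(LBL_HEALTHY, dim = dim3)
  labels[inside] <- LBL_TUMOR
  # antenna column: from grid top down to the metallic tip
  arr_len <- slot_array_length(antenna)
  z_tip <- axis$slot_center_z - arr_len / 2 - antenna$tip_length
  xc <- origin[1] + (seq_len(dim3[1]) - 0.5) * spacing
  yc <- origin[2] + (seq_len(dim3[2]) - 0.5) * spacing
  zc <- origin[3] + (seq_len(dim3[3]) - 0.5) * spacing
  r2 <- outer((xc - axis$x)^2, (yc - axis$y)^2, "+")
  in_cath <- r2 <= antenna$catheter_radius^2
  in_metal <- r2 <= antenna$outer_radius^2
  if (!any(in_cath)) {
    # antenna thinner than half a voxel: claim the nearest column
    nearest <- which(r2 == min(r2), arr.ind = TRUE)[1, ]
    in_cath[nearest[1], nearest[2]] <- TRUE
    in_metal[nearest[1], nearest[2]] <- TRUE
  }
  kz <- which(zc >= z_tip)
  for (k in kz) {
    lay <- labels[, , k]
    lay[in_cath] <- LBL_DIELECTRIC
    lay[in_metal] <- LBL_METAL
    labels[, , k] <- lay
  }
  if (!any(labels == LBL_TUMOR)) {
    stop("voxelization produced no tumor voxels; check mesh and spacing")
  }
  structure(list(origin = origin, spacing = spacing, dim = dim3,
                 labels = labels, axis = c(axis, list(z_tip = z_tip)),
                 antenna = antenna, mesh = mesh),
            class = "mwa_grid")
}

#' @export
print.mwa_grid <- function(x, ...) {
  n <- prod(x$dim)
  cat(sprintf("<mwa_grid> %d x %d x %d voxels @ %.2g mm (%d total)\n",
              x$dim[1], x$dim[2], x$dim[3], 1e3 * x$spacing, n))
  cat(sprintf("  tumor %.2f cm^3 (%d voxels), antenna %d voxels\n",
              1e6 * sum(x$labels == LBL_TUMOR) * x$spacing^3,
              sum(x$labels == LBL_TUMOR),
              sum(x$labels >= LBL_METAL)))
  invisible(x)
}

#' Voxel-centre coordinates along one axis of a grid
#' @param grid an `mwa_grid`.
#' @param axis 1 (x), 2 (y) or 3 (z).
#' @return numeric vector of centre coordinates (m).
#' @export
grid_centers <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$dim[axis]) - 0.5) * grid$spacing
}

# volume of one voxel (m^3)
voxel_volume <- function(grid) grid$spacing^3

# index (i, j, k) of the monitoring point: the tissue voxel adjacent to the
# antenna surface at the height of the slot-array midpoint
heating_center_index <- function(grid) {
  xc <- grid_centers(grid, 1)
  yc <- grid_centers(grid, 2)
  zc <- grid_centers(grid, 3)
  k <- which.min(abs(zc - grid$axis$slot_center_z))
  jy <- which.min(abs(yc - grid$axis$y))
  # first tissue voxel in +x from the axis at (jy, k)
  ix_axis <- which.min(abs(xc - grid$axis$x))
  for (i in ix_axis:grid$dim[1]) {
    if (grid$labels[i, jy, k] <= LBL_TUMOR) return(c(i, jy, k))
  }
  stop("no tissue voxel found adjacent to the antenna at the slot midpoint")
}
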