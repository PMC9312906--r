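#' Write fields on a voxel grid as a legacy-VTK structured-points file
#'
#' ASCII legacy VTK, readable by ParaView/VTK viewers; one SCALARS block
#' per field.
#'
#' @param grid an `mwa_grid`.
#' @param fields named list of 3D arrays on the grid.
#' @param path output `.vtk` path.
#' @return `path`, invisibly.
#' @export
write_vtk_grid <- function(grid, fields, path) {
  stopifnot(length(fields) >= 1, !is.null(names(fields)))
  con <- file(path, "wb")
  on.exit(close(con))
  n <- prod(grid$dim)
  writeLines(c("# vtk DataFile Version 3.0",
               "mwaplan field export", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", grid$dim[1], grid$dim[2], grid$dim[3]),
               sprintf("ORIGIN %.9g %.9g %.9g",
                       grid$origin[1] + grid$spacing / 2,
                       grid$origin[2] + grid$spacing / 2,
                       grid$origin[3] + grid$spacing / 2),
               sprintf("SPACING %.9g %.9g %.9g", grid$spacing, grid$spacing,
                       grid$spacing),
               sprintf("POINT_DATA %d", n)), con)
  for (nm in names(fields)) {
    f <- fields[[nm]]
    stopifnot(length(f) == n)
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.7g", as.numeric(f)), con)
  }
  invisible(path)
}

#' Extract a cut plane of a field
#'
#' Returns the field on the grid plane closest to `at` along `axis` as a
#' long data.frame, the 2D analogue of the 3D fields for plotting.
#'
#' @param grid an `mwa_grid`.
#' @param field 3D array on the grid.
#' @param axis 1 (x), 2 (y) or 3 (z).
#' @param at plane coordinate (m); default the antenna axis position.
#' @return data.frame with the two in-plane coordinates (m) and `value`.
#' @export
cut_plane <- function(grid, field, axis = 1, at = NULL) {
  if (is.null(at)) {
    at <- switch(axis, grid$axis$x, grid$axis$y, grid$axis$slot_center_z)
  }
  cent <- grid_centers(grid, axis)
  i <- which.min(abs(cent - at))
  others <- setdiff(1:3, axis)
  sl <- switch(axis, field[i, , ], field[, i, ], field[, , i])
  c1 <- grid_centers(grid, others[1])
  c2 <- grid_centers(grid, others[2])
  df <- expand.grid(u = c1, v = c2)
  df$value <- as.vector(sl)
  names(df)[1:2] <- c("x", "y", "z")[others]
  df
}

#' Export the necrosis boundary as a triangulated STL surface
#'
#' Extracts the voxel-face boundary of the necrosis mask (the set of faces
#' between necrotic and non-necrotic voxels) and writes it as a closed
#' triangulated surface, the lesion-boundary analogue of the tumor surface
#' mesh.
#'
#' @param mask logical 3D necrosis mask on the grid.
#' @param grid an `mwa_grid`.
#' @param path output `.stl` path.
#' @return `path`, invisibly.
#' @export
write_necrosis_stl <- function(mask, grid, path) {
  if (!any(mask)) stop("empty necrosis mask: nothing to export")
  h <- grid$spacing
  o <- grid$origin
  d <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  # voxel corner offsets per face (+x,-x,+y,-y,+z,-z), right-handed outward
  face_corners <- list(
    rbind(c(1, 0, 0), c(1, 1, 0), c(1, 1, 1), c(1, 0, 1)),
    rbind(c(0, 0, 0), c(0, 0, 1), c(0, 1, 1), c(0, 1, 0)),
    rbind(c(0, 1, 0), c(0, 1, 1), c(1, 1, 1), c(1, 1, 0)),
    rbind(c(0, 0, 0), c(1, 0, 0), c(1, 0, 1), c(0, 0, 1)),
    rbind(c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1)),
    rbind(c(0, 0, 0), c(0, 1, 0), c(1, 1, 0), c(1, 0, 0)))
  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))
  tri <- list()
  for (f in 1:6) {
    nb <- sweep(idx, 2, shifts[f, ], "+")
    outside <- nb[, 1] < 1 | nb[, 1] > d[1] | nb[, 2] < 1 | nb[, 2] > d[2] |
      nb[, 3] < 1 | nb[, 3] > d[3]
    open_face <- outside
    inb <- which(!outside)
    if (length(inb)) {
      open_face[inb] <- !mask[nb[inb, , drop = FALSE]]
    }
    sel <- idx[open_face, , drop = FALSE]
    if (!nrow(sel)) next
    # corners on the exact lattice origin + integer * h, so coincident
    # corners of neighbouring faces are bit-identical and merge on re-read
    fc <- face_corners[[f]]
    corner <- function(q) sweep((sel - 1 + matrix(fc[q, ], nrow(sel), 3,
                                                  byrow = TRUE)) * h,
                                2, o, "+")
    p1 <- corner(1); p2 <- corner(2); p3 <- corner(3); p4 <- corner(4)
    tri[[length(tri) + 1]] <- list(a = rbind(p1, p1), b = rbind(p2, p3),
                                   c = rbind(p3, p4))
  }
  a <- do.call(rbind, lapply(tri, `[[`, "a"))
  b <- do.call(rbind, lapply(tri, `[[`, "b"))
  c_ <- do.call(rbind, lapply(tri, `[[`, "c"))
  verts <- rbind(a, b, c_)
  nf <- nrow(a)
  faces <- cbind(seq_len(nf), nf + seq_len(nf), 2 * nf + seq_len(nf))
  mesh <- new_tumor_mesh(verts, faces, provenance = "necrosis-isosurface")
  write_tumor_mesh(mesh, path)
}

#' Write the heating-centre temperature series as CSV
#'
#' @param run an `mwa_run`.
#' @param path output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_center_series_csv <- function(run, path) {
  utils::write.csv(run$series, path, row.names = FALSE)
  invisible(path)
}
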