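# shared fixtures, built in code and cached per test session

.fixtures <- new.env()

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# small ellipsoid phantom (12 x 10 x 14 mm) on a 1 mm grid: cheap enough for
# unit tests, large enough to exercise the full pipeline
small_grid <- function() {
  fixture("small_grid", function() {
    mesh <- generate_tumor_phantom(semi_axes = c(6e-3, 5e-3, 7e-3),
                                   subdivisions = 3)
    voxelize(mesh, spacing = 1e-3, antenna = antenna_spec(), margin = 8e-3)
  })
}

# uniform no-conduction, no-perfusion properties for closed-form oracles
adiabatic_props <- function(k = 0, perfusion = 0, evaporation = TRUE) {
  p <- mwa_properties(evaporation = evaporation)
  if (!is.null(k)) {
    p$healthy$thermal_conductivity <- k
    p$tumor$thermal_conductivity <- k
  }
  p$blood$perfusion_rate <- perfusion
  p
}

# bare tissue-only grid (no mesh, no antenna) for PDE oracles
synthetic_grid <- function(dim, spacing, label = 1L) {
  structure(list(origin = c(0, 0, 0), spacing = spacing, dim = as.integer(dim),
                 labels = array(label, dim = dim),
                 axis = list(x = 0, y = 0, slot_center_z = 0, z_tip = 0),
                 antenna = antenna_spec(), mesh = NULL),
            class = "mwa_grid")
}

# trilinear interpolation of a grid field at a physical point
interp3 <- function(grid, field, p) {
  w <- numeric(3); i0 <- integer(3)
  for (d in 1:3) {
    cc <- grid_centers(grid, d)
    i <- findInterval(p[d], cc)
    i <- min(max(i, 1L), grid$dim[d] - 1L)
    i0[d] <- i
    w[d] <- (p[d] - cc[i]) / (cc[i + 1] - cc[i])
  }
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wt <- prod(ifelse(c(dx, dy, dz) == 1, w, 1 - w))
    acc <- acc + wt * field[i0[1] + dx, i0[2] + dy, i0[3] + dz]
  }
  acc
}

# uniform heat source on the tissue voxels of a grid
uniform_source <- function(grid, q) {
  qf <- array(0, dim = grid$dim)
  qf[grid$labels <= 2L] <- q
  qf
}
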