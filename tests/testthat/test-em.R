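test_that("antenna spec validates geometry and drive", {
  a <- antenna_spec()
  expect_identical(a$n_slots, 10L)
  expect_equal(a$slot_width, 0.6e-3)
  expect_equal(a$slot_spacing, 0.8e-3)
  expect_equal(a$frequency, 2.45e9)
  # 10 slots of 0.6 mm with 0.8 mm gaps span 13.2 mm
  expect_equal(mwaplan:::slot_array_length(a), 13.2e-3)
  expect_length(mwaplan:::slot_offsets(a), 10)
  expect_error(antenna_spec(outer_radius = 0.3e-3), "increasing")
  expect_error(antenna_spec(efficiency = 2), "efficiency")
  expect_error(antenna_spec(power = -1))
})

test_that("axisym solve reproduces the coax TEM mode and EM invariants", {
  ant <- antenna_spec(power = 10)
  sol <- fixture("axisym_sol", function()
    solve_axisym_field(ant, uniform_profile(44.3, 1.8),
                       r_max = 0.02, z_range = c(-0.025, 0.025)))
  # feed-region field follows the analytic 1/r TEM profile within 2%
  fe <- which(sol$materials == 1L, arr.ind = TRUE)
  jz <- max(fe[, 2]) - 10 # a few cells below the port
  sel <- fe[fe[, 2] == jz, 1]
  expect_gt(length(sel), 5)
  hr <- abs(sol$u[cbind(sel, jz)]) * sol$r[sel]
  expect_lt((max(hr) - min(hr)) / mean(hr), 0.02)
  # dissipation is non-negative and zero in metal
  expect_true(all(sol$Q2d >= 0))
  expect_true(all(sol$Q2d[sol$materials == 0L] == 0))
  expect_gt(sol$power, 0)
  # lossless medium: no dissipation anywhere
  sol0 <- solve_axisym_field(ant, uniform_profile(44.3, 0),
                             r_max = 0.02, z_range = c(-0.025, 0.025))
  expect_equal(sol0$power, 0)
  # under-resolved axial grid is rejected with the required resolution
  expect_error(solve_axisym_field(ant, uniform_profile(44.3, 1.8),
                                  dz = 0.5e-3), "resolve")
})

test_that("mapped 3D source is normalized, axisymmetric and metal-free", {
  grid <- small_grid()
  ant <- antenna_spec(power = 10, efficiency = 0.8)
  props <- mwa_properties()
  for (backend in c("slot", "axisym")) {
    q <- em_source(grid, ant, props, backend = backend,
                   em_opts = list(dz = 0.2e-3))
    expect_equal(sum(q) * grid$spacing^3, 0.8 * 10, tolerance = 1e-6)
    expect_true(all(q >= 0))
    expect_true(all(q[grid$labels >= 3L] == 0))
    # mirror symmetry through the antenna axis: compare voxels whose
    # centres are exact reflections x -> 2 x0 - x
    xc <- grid_centers(grid, 1)
    jc <- which.min(abs(grid_centers(grid, 2) - grid$axis$y))
    k <- floor(grid$dim[3] / 2)
    ic <- which.min(abs(xc - grid$axis$x))
    for (off in 2:5) {
      i1 <- ic + off
      i2 <- which.min(abs(xc - (2 * grid$axis$x - xc[i1])))
      expect_equal(xc[i2] - grid$axis$x, -(xc[i1] - grid$axis$x),
                   tolerance = 1e-6)
      expect_equal(q[i2, jc, k], q[i1, jc, k], tolerance = 0.05)
    }
  }
})

test_that("doubling input power doubles the deposition everywhere", {
  grid <- small_grid()
  props <- mwa_properties()
  a1 <- antenna_spec(power = 10)
  a2 <- antenna_spec(power = 20)
  q1 <- slot_source_model(a1, grid, props)
  q2 <- slot_source_model(a2, grid, props)
  expect_equal(q2, 2 * q1, tolerance = 1e-12, ignore_attr = TRUE)
  s1 <- em_source(grid, a1, props, backend = "axisym",
                  em_opts = list(dz = 0.2e-3))
  s2 <- em_source(grid, a2, props, backend = "axisym",
                  em_opts = list(dz = 0.2e-3))
  expect_equal(s2, 2 * s1, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("slot kernel is spherical around one slot and shrinks with sigma", {
  mesh <- generate_tumor_phantom(semi_axes = c(6e-3, 6e-3, 6e-3),
                                 subdivisions = 3)
  ant1 <- antenna_spec(n_slots = 1, power = 10)
  grid <- voxelize(mesh, spacing = 1e-3, antenna = ant1, margin = 8e-3)
  props <- mwa_properties()
  q <- slot_source_model(ant1, grid, props)
  # deposition isosurfaces around a single slot are spheres: inside the
  # homogeneous tumor, q * (d^2 + d0^2) * exp(2 alpha d) is constant
  xc <- grid_centers(grid, 1) - grid$axis$x
  yc <- grid_centers(grid, 2) - grid$axis$y
  zc <- grid_centers(grid, 3) - grid$axis$slot_center_z
  dist <- sqrt(outer(outer(xc^2, yc^2, "+"), zc^2, "+"))
  omega <- 2 * pi * ant1$frequency
  eps_c <- complex(real = props$tumor$rel_permittivity,
                   imaginary = -props$tumor$conductivity /
                     (omega * 8.8541878128e-12))
  alpha <- -(omega / 299792458) * Im(sqrt(eps_c))
  sel <- which(grid$labels == 2L & dist > 3e-3 & dist < 5e-3 &
                 array(rep(abs(xc) > 2e-3, length(yc) * length(zc)),
                       dim = grid$dim))
  kernel <- exp(-2 * alpha * dist[sel]) /
    (dist[sel]^2 + ant1$catheter_radius^2)
  ratio <- q[sel] / kernel
  expect_gt(length(sel), 50)
  expect_lt(diff(range(ratio)) / mean(ratio), 0.01)
  # higher conductivity shortens the attenuation length: the fraction of
  # power deposited beyond 6 mm from the axis must drop
  props_hi <- mwa_properties()
  props_hi$healthy$conductivity <- 3.6
  props_hi$tumor$conductivity <- 4.0
  qh <- slot_source_model(ant1, grid, props_hi)
  xc <- grid_centers(grid, 1) - grid$axis$x
  yc <- grid_centers(grid, 2) - grid$axis$y
  far <- array(outer(xc^2, yc^2, "+") > 36e-6, dim = grid$dim)
  expect_lt(sum(qh[far]) / sum(qh), sum(q[far]) / sum(q))
})

test_that("normalized deposition profile is stable under EM grid refinement", {
  ant <- antenna_spec(power = 10)
  prof <- uniform_profile(44.3, 1.8)
  s1 <- solve_axisym_field(ant, prof, r_max = 0.02,
                           z_range = c(-0.025, 0.025))
  s2 <- solve_axisym_field(ant, prof, r_max = 0.02,
                           z_range = c(-0.025, 0.025),
                           dz = 0.1e-3, dr_fine = 0.015e-3)
  # fraction of dissipated power inside a 5 mm cylinder around the slots
  frac <- function(s) {
    ring <- outer(2 * pi * s$r * s$dr, rep(s$dz, length(s$z)))
    sum((s$Q2d * ring)[s$r < 5e-3, ]) / sum(s$Q2d * ring)
  }
  expect_lt(abs(frac(s1) - frac(s2)), 0.03)
})
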