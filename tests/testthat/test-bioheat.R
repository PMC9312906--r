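test_that("body-temperature equilibrium is preserved without a source", {
  grid <- synthetic_grid(c(8, 8, 8), 1e-3)
  st <- thermal_state(grid)
  q0 <- array(0, dim = grid$dim)
  st2 <- step_bioheat(st, grid, q0, dt = 0.25, nsteps = 40)
  expect_equal(st2$T, st$T, tolerance = 1e-12)
  expect_equal(st2$time, 10)
  expect_true(all(st2$omega >= 0))
})

test_that("conduction-free heating follows the adiabatic closed form", {
  # k = 0, W_b = 0, constant Q: dT = Q t / (rho c_eff), per tissue class
  grid <- synthetic_grid(c(6, 6, 6), 1e-3)
  grid$labels[4:6, , ] <- 2L # half tumor to test both classes
  props <- adiabatic_props()
  q <- 4e5
  st <- step_bioheat(thermal_state(grid), grid, uniform_source(grid, q),
                     dt = 0.25, props = props, nsteps = 80)
  dt_h <- q * 20 / (props$healthy$density * props$healthy$specific_heat)
  dt_t <- q * 20 / (props$tumor$density * props$tumor$specific_heat)
  expect_equal(st$T[1, 1, 1] - 37, dt_h, tolerance = 0.005)
  expect_equal(st$T[6, 6, 6] - 37, dt_t, tolerance = 0.005)
})

test_that("perfusion relaxes hot tissue to arterial temperature exponentially", {
  grid <- synthetic_grid(c(5, 5, 5), 1e-3)
  props <- adiabatic_props(perfusion = 0.0064)
  # inert damage kinetics: this oracle tests the perfusion term alone
  dmg <- damage_params(frequency_factor = 1e-30)
  st <- thermal_state(grid)
  st$T[] <- 60
  st$T_ref <- st$T
  lam <- props$blood$density * props$blood$perfusion_rate *
    props$blood$specific_heat /
    (props$healthy$density * props$healthy$specific_heat)
  dt <- 0.1
  st2 <- step_bioheat(st, grid, array(0, grid$dim), dt = dt, props = props,
                      dmg = dmg, nsteps = 3000)
  analytic <- 37 + 23 * exp(-lam * 300)
  expect_equal(st2$T[3, 3, 3] - 37, analytic - 37, tolerance = 0.01)
})

test_that("insulated, perfusion-free runs conserve energy to 1%", {
  grid <- small_grid()
  props <- adiabatic_props(k = NULL, perfusion = 0)
  props$healthy$thermal_conductivity <- 0.52
  props$tumor$thermal_conductivity <- 0.57
  ant <- antenna_spec(power = 4) # keep max T below the evaporation band
  q <- slot_source_model(ant, grid, props)
  st0 <- thermal_state(grid)
  st <- step_bioheat(st0, grid, q, dt = 0.25, props = props, nsteps = 240)
  expect_lt(max(st$T), 95)
  tissue <- grid$labels <= 2L
  rho_c <- array(props$healthy$density * props$healthy$specific_heat,
                 dim = grid$dim)
  rho_c[grid$labels == 2L] <- props$tumor$density * props$tumor$specific_heat
  enthalpy <- sum((rho_c * (st$T - 37))[tissue]) * grid$spacing^3
  deposited <- sum(q) * grid$spacing^3 * 60
  expect_equal(enthalpy, deposited, tolerance = 0.01)
})

test_that("1D conduction with constant wall flux matches the erfc solution", {
  nx <- 600
  h <- 0.05e-3
  grid <- synthetic_grid(c(nx, 1, 1), h)
  props <- adiabatic_props(k = NULL, perfusion = 0, evaporation = FALSE)
  props$healthy$thermal_conductivity <- 0.52
  k <- 0.52
  alpha <- k / (props$healthy$density * props$healthy$specific_heat)
  q0 <- 2000 # W/m^2 entering through the x = 0 wall
  qf <- array(0, dim = grid$dim)
  qf[1, 1, 1] <- q0 / h
  st <- step_bioheat(thermal_state(grid), grid, qf, dt = 0.05,
                     props = props, nsteps = 2000)
  tt <- 100
  x <- (seq_len(nx) - 0.5) * h
  analytic <- 37 + (q0 / k) * (2 * sqrt(alpha * tt / pi) *
                                 exp(-x^2 / (4 * alpha * tt)) -
                                 x * (1 - pracma::erf(x / (2 * sqrt(alpha * tt)))))
  num <- st$T[, 1, 1]
  expect_lt(max(abs(num - analytic)) / max(analytic - 37), 0.01)
})

test_that("with frozen properties the temperature rise is linear in power", {
  grid <- small_grid()
  props <- adiabatic_props(k = NULL, perfusion = 0, evaporation = FALSE)
  props$healthy$thermal_conductivity <- 0.52
  props$tumor$thermal_conductivity <- 0.57
  r1 <- run_simulation(grid, antenna_spec(power = 2), duration = 20,
                       props = props, backend = "slot", em_resolve_dT = 0)
  r2 <- run_simulation(grid, antenna_spec(power = 4), duration = 20,
                       props = props, backend = "slot", em_resolve_dT = 0)
  tissue <- grid$labels <= 2L
  expect_equal(r2$state$T[tissue] - 37, 2 * (r1$state$T[tissue] - 37),
               tolerance = 1e-6)
})

test_that("run_simulation honours duration zero, snapshots and monotone damage", {
  grid <- small_grid()
  r0 <- run_simulation(grid, antenna_spec(power = 8), duration = 0)
  expect_length(r0$snapshots, 1)
  expect_equal(r0$state$time, 0)
  r <- run_simulation(grid, antenna_spec(power = 8), duration = 30,
                      snapshot_times = c(10, 20, 30), backend = "slot")
  expect_length(r$snapshots, 3)
  expect_equal(vapply(r$snapshots, function(s) s$time, 0), c(10, 20, 30))
  om1 <- r$snapshots[[1]]$omega
  om2 <- r$snapshots[[2]]$omega
  om3 <- r$snapshots[[3]]$omega
  expect_true(all(om2 - om1 >= 0))
  expect_true(all(om3 - om2 >= 0))
  # monitor series is per-step and strictly heating early on
  expect_equal(nrow(r$series), 120)
  expect_gt(r$series$T_monitor[120], r$series$T_monitor[1])
})

test_that("centre temperature is stable under grid refinement", {
  mesh <- generate_tumor_phantom(semi_axes = c(5e-3, 5e-3, 6e-3),
                                 subdivisions = 3)
  ant <- antenna_spec(power = 6)
  probe <- c(4e-3, 0, 0)
  temps <- vapply(c(1e-3, 0.5e-3), function(h) {
    g <- voxelize(mesh, spacing = h, antenna = ant, margin = 8e-3)
    r <- run_simulation(g, ant, duration = 60, backend = "slot")
    interp3(g, r$state$T, probe)
  }, 0)
  expect_lt(abs(temps[1] - temps[2]) / (temps[2] - 37), 0.02)
})

test_that("a divergent step aborts with a diagnostic", {
  grid <- synthetic_grid(c(4, 4, 4), 1e-3)
  qf <- array(Inf, dim = grid$dim)
  expect_error(step_bioheat(thermal_state(grid), grid, qf, dt = 0.25),
               "diverged")
  expect_error(step_bioheat(thermal_state(grid), grid,
                            array(0, grid$dim), dt = -1))
})
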