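test_that("default property set carries the baseline liver/blood constants", {
  p <- mwa_properties()
  expect_identical(p$healthy$density, 1079)
  expect_identical(p$healthy$rel_permittivity, 44.3)
  expect_identical(p$healthy$conductivity, 1.8)
  expect_identical(p$healthy$thermal_conductivity, 0.52)
  expect_identical(p$healthy$specific_heat, 3540)
  expect_identical(p$tumor$density, 1040)
  expect_identical(p$tumor$rel_permittivity, 54.8)
  expect_identical(p$tumor$conductivity, 2.0)
  expect_identical(p$tumor$thermal_conductivity, 0.57)
  expect_identical(p$tumor$specific_heat, 3960)
  expect_identical(p$blood$density, 1060)
  expect_identical(p$blood$thermal_conductivity, 0.5)
  expect_identical(p$blood$specific_heat, 3600)
  expect_identical(p$blood$temperature, 37)
  expect_identical(p$latent_heat, 2.260e6)
  expect_identical(p$water_baseline, 0.78)
  # round trip through a plain list (YAML-shaped) is lossless
  p2 <- properties_from_list(as.list(p))
  expect_identical(as.list(p2), as.list(p))
  expect_error(properties_from_list(list(bogus_key = 1)), "unknown")
  expect_error(mwa_properties(healthy = list(density = -1,
                                             rel_permittivity = 44.3,
                                             conductivity = 1.8,
                                             thermal_conductivity = 0.52,
                                             specific_heat = 3540)),
               "positive")
})

test_that("water content is a smooth non-increasing sigmoid anchored at 78%", {
  p <- mwa_properties()
  expect_equal(water_content(37, p), 0.78, tolerance = 0.01)
  expect_lt(water_content(200, p), 0.01 * p$water_baseline)
  tt <- seq(-20, 300, by = 0.5)
  w <- water_content(tt, p)
  expect_true(all(diff(w) <= 0))
  expect_true(all(water_content_deriv(tt, p) <= 0))
  # derivative consistent with a numerical difference
  h <- 1e-4
  num <- (water_content(100 + h, p) - water_content(100 - h, p)) / (2 * h)
  expect_equal(water_content_deriv(100, p), num, tolerance = 1e-6)
})

test_that("effective specific heat adds the latent-heat peak over baseline c", {
  p <- mwa_properties()
  expect_equal(effective_specific_heat(37, p, "tumor"),
               p$tumor$specific_heat, tolerance = 1e-3)
  expect_equal(effective_specific_heat(37, p, "healthy"),
               p$healthy$specific_heat, tolerance = 1e-3)
  tt <- seq(0, 300, by = 0.25)
  expect_true(all(effective_specific_heat(tt, p, "tumor") >=
                    p$tumor$specific_heat))
  # far from the evaporation band c_eff returns to c within 0.1%
  far <- c(seq(0, 60, 5), seq(150, 300, 10))
  expect_equal(effective_specific_heat(far, p, "healthy"),
               rep(p$healthy$specific_heat, length(far)), tolerance = 1e-3)
  # peak sits at the sigmoid inflection with height alpha * W0 / (4 s)
  peak <- effective_specific_heat(p$water_T50, p, "tumor")
  expect_equal(peak - p$tumor$specific_heat,
               p$latent_heat * p$water_baseline / (4 * p$water_width),
               tolerance = 1e-6)
  # energy identity: integral of (c_eff - c) dT = alpha * (W(37) - W(200))
  excess <- stats::integrate(function(x)
    effective_specific_heat(x, p, "tumor") - p$tumor$specific_heat,
    37, 200, rel.tol = 1e-9)$value
  expect_equal(excess,
               p$latent_heat * (water_content(37, p) - water_content(200, p)),
               tolerance = 0.01)
})

test_that("dielectric properties decline with the water fraction to a floor", {
  p <- mwa_properties()
  d <- dielectric_at(37, "tumor", p)
  expect_equal(d$eps_r, 54.8, tolerance = 1e-6)
  expect_equal(d$sigma, 2.0, tolerance = 1e-6)
  dh <- dielectric_at(37, "healthy", p)
  expect_equal(dh$eps_r, 44.3, tolerance = 1e-6)
  expect_equal(dh$sigma, 1.8, tolerance = 1e-6)
  hot <- dielectric_at(200, "tumor", p)
  expect_equal(hot$eps_r, 5.48, tolerance = 1e-6)
  expect_equal(hot$sigma, 0.20, tolerance = 1e-6)
  tt <- seq(0, 300, by = 1)
  dd <- dielectric_at(tt, "healthy", p)
  expect_true(all(diff(dd$eps_r) <= 0))
  expect_true(all(diff(dd$sigma) <= 0))
  expect_true(all(dd$eps_r >= 0.1 * 44.3 - 1e-12))
  expect_error(dielectric_at(37, "bone", p), "unknown tissue class")
})

test_that("perfusion stays at baseline until the damage threshold, then stops", {
  p <- mwa_properties()
  expect_equal(perfusion_at(37, 0, p), p$blood$perfusion_rate)
  expect_equal(perfusion_at(60, 10, p), 0)
  # theta exactly at the threshold keeps baseline (ties perfused)
  om_thr <- -log(1 - p$perfusion_damage_threshold)
  expect_equal(perfusion_at(50, om_thr, p), p$blood$perfusion_rate)
  expect_equal(perfusion_at(50, om_thr + 1e-9, p), 0)
  om <- seq(0, 5, by = 0.01)
  expect_true(all(diff(perfusion_at(45, om, p)) <= 0))
  expect_error(perfusion_at(37, -0.1, p), "non-negative")
})
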