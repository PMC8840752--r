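test_that("trivial and limiting cases solve in closed form", {
  bed <- default_bed()
  tt <- seq(0, 7200, by = 1800)
  # no solute -> no yield
  z <- reverchon_yield(tt, ti = 600, K = 1e-3, bed = bed, q0 = 0)
  expect_equal(z$yield, rep(0, length(tt)))

  # K = 0 with residence time << ti: solid depletes as exp(-t/ti) and the
  # outlet integrates to 1 - exp(-t/ti)
  fast <- bed_properties(porosity = 0.55, fluid_density = 910,
                         solid_density = 1200, residence_time = 1710 / 1000)
  y <- reverchon_yield(c(0, 1710, 3420), ti = 1710, K = 0, bed = fast)
  expect_equal(y$yield[2], 1 - exp(-1), tolerance = 1e-3)
  expect_equal(y$yield[3], 1 - exp(-2), tolerance = 1e-3)
})

test_that("solute mass is conserved at every output time", {
  bed <- default_bed()
  tt <- seq(0, 6 * 3600, length.out = 25)
  y <- reverchon_yield(tt, ti = 1710, K = 5.294e-3, bed = bed, q0 = 0.05)
  mb <- attr(y, "mass_balance")
  expect_lt(max(abs(mb$rel_error)), 1e-6)
  # the three pools are individually sensible
  expect_true(all(mb$extracted >= 0 & mb$in_fluid >= 0 & mb$in_solid >= 0))
})

test_that("the yield curve starts at zero, is nondecreasing and bounded", {
  bed <- default_bed()
  set.seed(3)
  for (i in 1:5) {
    ti <- 10^runif(1, 2, 4)
    K <- 10^runif(1, -4, -1)
    tt <- seq(0, 6 * 3600, length.out = 30)
    y <- reverchon_yield(tt, ti = ti, K = K, bed = bed)
    expect_equal(y$yield[1], 0, tolerance = 1e-12)
    expect_true(all(diff(y$yield) >= -1e-9))
    expect_true(all(y$yield <= 1 + 1e-9))
  }
})

test_that("doubling the axial grid changes the curve negligibly", {
  bed <- default_bed()
  tt <- seq(600, 6 * 3600, length.out = 15)
  y50 <- reverchon_yield(tt, ti = 1710, K = 5.294e-3, bed = bed, n_cells = 50)
  y100 <- reverchon_yield(tt, ti = 1710, K = 5.294e-3, bed = bed, n_cells = 100)
  expect_lt(max(abs(y100$yield - y50$yield) / pmax(y100$yield, 1e-6)), 1e-4)
})

test_that("faster internal kinetics monotonically approach the equilibrium limit", {
  bed <- default_bed()
  tt <- seq(1800, 4 * 3600, length.out = 8)
  ref <- reverchon_yield(tt, ti = 0.5, K = 5.294e-3, bed = bed)$yield
  dev <- vapply(c(100, 10, 1), function(ti) {
    max(abs(reverchon_yield(tt, ti = ti, K = 5.294e-3, bed = bed)$yield - ref))
  }, numeric(1))
  expect_true(all(diff(dev) < 0)) # deviation shrinks as ti -> 0
  expect_lt(dev[3], 1e-3)
})

test_that("invalid physical inputs are rejected", {
  bed <- default_bed()
  expect_error(reverchon_yield(0:10, ti = -1, K = 0, bed = bed), "positive")
  expect_error(reverchon_yield(0:10, ti = 10, K = -1, bed = bed), "non-negative")
  expect_error(reverchon_yield(c(0, 0, 1), ti = 10, K = 0, bed = bed), "increasing")
  no_tau <- bed_properties(porosity = 0.5, fluid_density = 900, solid_density = 1100)
  expect_error(reverchon_yield(0:10, ti = 10, K = 0, bed = no_tau), "residence_time")
})

test_that("physical coefficient conversions are exact", {
  geo <- particle_geometry(radius = 3e-4)
  expect_equal(geo$char_length, 1e-4)
  expect_equal(geo$shape_constant, 3 / 5)
  # mu l^2 / ti with mu = 3/5, l = 1e-4, ti = 600 -> 1e-11
  expect_equal(unname(reverchon_coefficients(600, geo)["Di"]), 1e-11,
               tolerance = 1e-12)
  # round trip
  ti <- internal_diffusion_time(1e-11, geo)
  expect_rel_equal(unname(reverchon_coefficients(ti, geo)["Di"]), 1e-11, 1e-12)

  # characteristic length implied by the published ti and Di
  l <- sqrt(1.228e-12 * 1710 / (3 / 5))
  expect_equal(l, 5.92e-5, tolerance = 1e-3)

  bed <- default_bed()
  ktm <- reverchon_coefficients(1710, geo, bed)[["kTM"]]
  expect_rel_equal(ktm, (1 - bed$porosity) * bed$extractor_volume /
                     (bed$particle_area * 1710), 1e-12)
  expect_error(reverchon_coefficients(0, geo), "positive")
})

test_that("sieve-table and geometry helpers validate their inputs", {
  expect_equal(mesh_to_mm(c(42, 60, 150)), c(0.423, 0.303, 0.125))
  expect_error(mesh_to_mm(99), "not in the sieve table")
  expect_equal(particle_geometry(mesh = 42)$radius, 0.423e-3 / 2)
  expect_error(particle_geometry(), "give one of")
  # residence-time consistency check in bed_properties
  expect_error(
    bed_properties(porosity = 0.55, fluid_density = 910, solid_density = 1200,
                   solvent_flow = 800 / 1000 / 3600, extractor_volume = 5e-4,
                   residence_time = 99),
    "inconsistent"
  )
})
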