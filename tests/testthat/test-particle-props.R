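test_that("Sterling particle count per agglomerate matches hand-evaluated cases", {
  # identity: agglomerate equal to one primary sphere
  one <- agglomerate_spec(13, 2.1, 1, spio_particle())
  expect_equal(as.numeric(particles_per_agglomerate(one)), 1)

  # volume-filling limit: doubling the diameter at DF = 3, PF = 1 packs 8 spheres
  cube <- agglomerate_spec(26, 3, 1, spio_particle())
  expect_equal(as.numeric(particles_per_agglomerate(cube)), 8)

  # study agglomerate: 0.637 * (276/13)^2.1, evaluated independently
  n_ref <- 0.637 * (276 / 13)^2.1
  expect_equal(as.numeric(particles_per_agglomerate(spio_agglomerate())), n_ref)
  expect_lt(abs(n_ref - 390), 2)  # ~3.9e2 particles

  expect_error(agglomerate_spec(10, 2.1, 0.637, spio_particle()),
               "primary particle diameter")
})

test_that("effective density interpolates between medium and solid", {
  med <- rpmi_medium()

  # solid-sphere limit (DF = 3, PF = 1 gives phi = 1)
  solid <- agglomerate_spec(276, 3, 1, spio_particle())
  expect_equal(as.numeric(effective_density(solid, med)), 5.2)

  # neutral buoyancy: particle density equal to medium density
  neutral <- agglomerate_spec(276, 2.1, 0.637, particle_spec(13, 1.0))
  expect_equal(as.numeric(effective_density(neutral, med)), 1.0)

  # study value: chain N -> phi -> rho_eff computed independently
  N <- 0.637 * (276 / 13)^2.1
  phi <- N * (13 / 276)^3
  rho_ref <- 1.0 + (5.2 - 1.0) * phi
  expect_equal(as.numeric(effective_density(spio_agglomerate(), med)), rho_ref)
  expect_equal(rho_ref, 1.17, tolerance = 0.005)
})

test_that("effective density is monotone in fractal dimension and bounded", {
  med <- rpmi_medium()
  for (ratio in c(2, 10, 21.2, 50)) {
    dfs <- seq(1.2, 3, by = 0.2)
    rhos <- vapply(dfs, function(df) {
      agg <- agglomerate_spec(13 * ratio, df, 0.637, spio_particle())
      as.numeric(effective_density(agg, med))
    }, numeric(1))
    expect_true(all(diff(rhos) >= -1e-12))
    expect_true(all(rhos >= med$density_g_cm3 - 1e-12))
    expect_true(all(rhos <= 5.2 + 1e-12))
  }
})

test_that("Stokes-Einstein diffusion coefficient matches hand evaluation and scalings", {
  med <- rpmi_medium()
  D <- as.numeric(diffusion_coefficient(276, med))
  D_ref <- 1.380649e-23 * 310 / (3 * pi * 0.00074 * 276e-9)
  expect_equal(D, D_ref)
  expect_equal(D, 2.2e-12, tolerance = 0.02)

  # identity: D * 3 pi mu d / (kB T) = 1 exactly
  expect_equal(D * 3 * pi * 0.00074 * 276e-9 / (1.380649e-23 * 310), 1)

  # 1/d scaling and 1/mu scaling
  expect_equal(as.numeric(diffusion_coefficient(2760, med)), D / 10)
  med2 <- medium_spec(1.0, 2 * 0.00074, 310)
  expect_equal(as.numeric(diffusion_coefficient(276, med2)), D / 2)

  expect_error(diffusion_coefficient(0, med), "positive")
  expect_error(diffusion_coefficient(-5, med), "positive")
})

test_that("Stokes settling velocity matches hand evaluation and scalings", {
  med <- rpmi_medium()
  rho_eff <- as.numeric(effective_density(spio_agglomerate(), med))
  V <- as.numeric(sedimentation_velocity(276, rho_eff, med))
  V_ref <- 9.80665 * (276e-9)^2 * (rho_eff - 1.0) * 1000 / (18 * 0.00074)
  expect_equal(V, V_ref)
  expect_equal(V, 9.6e-9, tolerance = 0.02)

  # neutral buoyancy gives zero; buoyant particles a negative velocity
  expect_equal(as.numeric(sedimentation_velocity(276, 1.0, med)), 0)
  expect_lt(as.numeric(sedimentation_velocity(276, 0.9, med)), 0)

  # d^2 scaling
  expect_equal(as.numeric(sedimentation_velocity(552, rho_eff, med)), 4 * V)
})

test_that("mass to number and surface-area conversion is exact and linear", {
  p <- spio_particle()
  zero <- mass_number_surface_convert(0, p)
  expect_equal(zero$number, 0)
  expect_equal(zero$surface_area_cm2, 0)

  one_pg <- mass_number_surface_convert(1, p)
  # surface area: 6 / (rho d) per unit mass
  expect_equal(one_pg$surface_area_cm2, 8.87e-7, tolerance = 0.005)
  # number: mass / (rho pi d^3 / 6); the independent oracle gives ~1.67e5
  n_oracle <- 1e-12 / (5.2 * pi * (13e-7)^3 / 6)
  expect_equal(one_pg$number, n_oracle)
  expect_equal(n_oracle, 1.67e5, tolerance = 0.01)

  # round trip: number * per-particle mass recovers input mass exactly
  masses <- c(0.1, 1, 7.3, 1000)
  conv <- mass_number_surface_convert(masses, p)
  per_particle_pg <- 5.2 * pi * (13e-7)^3 / 6 * 1e12
  expect_equal(conv$number * per_particle_pg, masses)

  # linearity in mass
  expect_equal(mass_number_surface_convert(2, p)$number, 2 * one_pg$number)
  expect_error(mass_number_surface_convert(-1, p), "non-negative")
})

test_that("Hatch-Choate count-to-mass median conversion and round trip", {
  # monodisperse: GSD 1 leaves the median unchanged
  mono <- aerosol_distribution(100, 1)
  expect_equal(as.numeric(cmd_to_mmd(mono)), 100)

  # study aerosol: 68.6 nm CMD, GSD 1.65 -> about 146 nm
  mmd <- as.numeric(cmd_to_mmd(spio_aerosol()))
  expect_equal(mmd, 68.6 * exp(3 * log(1.65)^2))
  expect_equal(mmd, 146, tolerance = 0.01)

  # MMD >= CMD always; exact inverse round trip
  for (gsd in c(1, 1.2, 1.65, 2.5)) {
    d <- aerosol_distribution(68.6, gsd)
    m <- as.numeric(cmd_to_mmd(d))
    expect_gte(m, 68.6 - 1e-12)
    expect_equal(as.numeric(mmd_to_cmd(m, gsd)), 68.6, tolerance = 1e-12)
  }
  expect_error(aerosol_distribution(100, 0.9), "gsd")
  expect_error(mmd_to_cmd(100, 0.5), "gsd")
})

test_that("specification constructors enforce their invariants", {
  expect_error(particle_spec(-1, 5.2), "positive")
  expect_error(particle_spec(13, 0), "positive")
  expect_error(agglomerate_spec(276, 1, 0.637, spio_particle()), "fractal")
  expect_error(agglomerate_spec(276, 3.5, 0.637, spio_particle()), "fractal")
  expect_error(agglomerate_spec(276, 2.1, 0, spio_particle()), "packing")
  expect_error(agglomerate_spec(276, 2.1, 1.2, spio_particle()), "packing")
  expect_error(medium_spec(0), "positive")
  # unit tags travel with returned scalars
  expect_equal(attr(cmd_to_mmd(spio_aerosol()), "unit"), "nm")
  expect_equal(attr(diffusion_coefficient(276, rpmi_medium()), "unit"), "m^2/s")
})
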