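test_that("total inhaled mass follows MV x duration x concentration", {
  # arithmetic oracle: 100 ml/min for 1 h at 10 mg/m^3 = 6 L x 10 ug/L = 60 ug
  phys <- respiratory_physiology(1, 100, 100)
  expect_equal(as.numeric(total_inhaled_mass(phys, exposure_scenario(10, 1))), 60)

  # measured mouse physiology and exposure: ~365-368 ug
  tim <- as.numeric(total_inhaled_mass(mouse_physiology(),
                                       mouse_exposure_scenario()))
  expect_gte(tim, 365)
  expect_lte(tim, 368)

  # zero concentration inhales nothing
  expect_equal(as.numeric(total_inhaled_mass(mouse_physiology(),
                                             exposure_scenario(0, 4))), 0)

  # minute volume defaults to TV x RR
  expect_equal(respiratory_physiology(0.24, 317)$minute_volume_ml_min,
               0.24 * 317)
})

test_that("deposition fraction is a guarded ratio", {
  expect_equal(as.numeric(deposition_fraction(14.5, 14.5)), 1)
  expect_equal(as.numeric(deposition_fraction(0, 365)), 0)
  expect_equal(as.numeric(deposition_fraction(14.5, 365)), 0.0397,
               tolerance = 0.01)
  expect_warning(deposition_fraction(400, 365), "exceeds")
  expect_error(deposition_fraction(1, 0), "positive")
})

test_that("regional mass allocation conserves the measured total exactly", {
  tab <- mouse_table()
  reg <- suppressMessages(allocate_regional_mass(tab, 14.5))
  expect_equal(sum(reg$mass_ug), 14.5, tolerance = 1e-10)

  # regional rollup reproduces the split of the deposited mass
  roll <- regional_rollup(surface_area_dose(reg))
  shares <- roll$mass_ug / 14.5
  expect_equal(shares[roll$region == "trachea_main_bronchus"], 0.028 / 0.988,
               tolerance = 1e-9)
  expect_equal(shares[roll$region == "bronchiolar"], 0.34 / 0.988,
               tolerance = 1e-9)
  expect_equal(shares[roll$region == "alveolar"], 0.62 / 0.988,
               tolerance = 1e-9)

  # fractions not summing to 1 are renormalised with a message
  expect_message(allocate_regional_mass(tab, 14.5), "renormalised")

  # single-row table takes everything
  one <- tibble::tibble(generation = 1, region = "alveolar",
                        deposition_fraction = 0.4, surface_area_cm2 = 10,
                        n_alveoli = 100)
  expect_equal(suppressMessages(allocate_regional_mass(one, 14.5))$mass_ug, 14.5)

  expect_error(allocate_regional_mass(tab[0, ], 14.5), "empty")
  zero <- dplyr::mutate(tab, deposition_fraction = 0)
  expect_error(allocate_regional_mass(zero, 14.5), "zero")
})

test_that("regional allocation with the 2.8/34/62 split matches hand arithmetic", {
  # three-region arithmetic oracle: {0.028, 0.34, 0.62} x 14.5
  tab <- tibble::tibble(
    generation = 1:3,
    region = c("trachea_main_bronchus", "bronchiolar", "alveolar"),
    deposition_fraction = c(0.028, 0.34, 0.62),
    surface_area_cm2 = c(0.4, 6, 500),
    n_alveoli = c(0, 0, 4e6))
  reg <- suppressMessages(allocate_regional_mass(tab, 14.5))
  expect_equal(reg$mass_ug, c(0.028, 0.34, 0.62) / 0.988 * 14.5,
               tolerance = 1e-12)
  expect_equal(reg$mass_ug, c(0.41, 4.93, 8.99), tolerance = 0.02)
})

test_that("surface-area dose divides mass by generation area", {
  tab <- tibble::tibble(
    generation = 1:2, region = c("bronchiolar", "alveolar"),
    deposition_fraction = c(0.5, 0.5),
    surface_area_cm2 = c(1, 500), n_alveoli = c(0, 1e6))
  reg <- surface_area_dose(allocate_regional_mass(tab, 2))
  expect_equal(reg$surface_dose_ug_cm2, c(1 / 1, 1 / 500))
})

test_that("macrophage allocation conserves count and alveolar mass", {
  tab <- mouse_table()
  reg <- regional_dosimetry(tab, 14.5, total_macrophages = 1.25e6,
                            scavenging_fraction = 1)
  alv <- reg[reg$region == "alveolar", ]
  # all 1.25e6 macrophages distributed, in proportion to alveoli
  expect_equal(sum(alv$n_macrophages), 1.25e6, tolerance = 1e-10)
  expect_equal(alv$n_macrophages / 1.25e6, alv$n_alveoli / sum(alv$n_alveoli))
  # mass conservation: sum(dose x count) recovers alveolar mass
  expect_equal(sum(alv$macrophage_dose_pg * alv$n_macrophages) / 1e6,
               sum(alv$mass_ug), tolerance = 1e-10)

  # whole-alveolar mean dose: 62% x 14.5 ug over 1.25e6 cells ~ 7.2 pg
  roll <- regional_rollup(reg)
  mean_dose <- roll$macrophage_dose_pg[roll$region == "alveolar"]
  expect_equal(mean_dose, 0.62 / 0.988 * 14.5 * 1e6 / 1.25e6,
               tolerance = 1e-9)
  expect_equal(mean_dose, 7.2, tolerance = 0.02)

  # all alveoli in one generation -> that generation gets every macrophage
  tab1 <- tibble::tibble(
    generation = 1:2, region = c("alveolar", "alveolar"),
    deposition_fraction = c(1, 0), surface_area_cm2 = c(1, 1),
    n_alveoli = c(1e6, 0))
  reg1 <- regional_dosimetry(tab1, 1)
  expect_equal(reg1$n_macrophages[1], 1.25e6)

  # alveolar mass landing in a generation without alveoli is an error
  tab2 <- dplyr::mutate(tab1, deposition_fraction = c(0.5, 0.5))
  expect_error(suppressMessages(regional_dosimetry(tab2, 1)), "zero alveoli")
})

test_that("halving by macrophage scavenging reproduces the 9-31 pg band", {
  # 50% scavenging halves a [18.5, 61.7] pg/cell band to [9.25, 30.85]
  tab <- tibble::tibble(
    generation = 1:2, region = "alveolar",
    deposition_fraction = c(0.5, 0.5), surface_area_cm2 = c(1, 1),
    n_alveoli = c(1e6, 1e6))
  full <- suppressMessages(regional_dosimetry(tab, 1, scavenging_fraction = 1))
  half <- suppressMessages(regional_dosimetry(tab, 1, scavenging_fraction = 0.5))
  expect_equal(half$macrophage_dose_pg, full$macrophage_dose_pg / 2)
  band <- c(18.5, 61.7) * 0.5
  expect_equal(band, c(9.25, 30.85))
  expect_equal(round(band), c(9, 31))
})

test_that("all dose metrics scale linearly with the deposited total", {
  tab <- mouse_table()
  r1 <- regional_dosimetry(tab, 14.5)
  r3 <- regional_dosimetry(tab, 3 * 14.5)
  expect_equal(r3$mass_ug, 3 * r1$mass_ug)
  expect_equal(r3$surface_dose_ug_cm2, 3 * r1$surface_dose_ug_cm2)
  alv <- r1$region == "alveolar"
  expect_equal(r3$macrophage_dose_pg[alv], 3 * r1$macrophage_dose_pg[alv])
})

test_that("hot-spot enhancement multiplies the average dose", {
  expect_equal(as.numeric(hotspot_dose(0.1, 65)), 6.5)
  expect_equal(as.numeric(hotspot_dose(0.37, 1)), 0.37)
  expect_equal(as.numeric(hotspot_dose(0, 65)), 0)
  expect_error(hotspot_dose(-0.1, 65), "non-negative")
})
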