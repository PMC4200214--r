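test_that("deposition-table generator honours its structural contract", {
  tab <- gen_deposition_table("mouse_like", seed = 1)
  expect_equal(nrow(tab), 22)
  expect_equal(tab$generation, 1:22)

  # regional rollup reproduces the requested split exactly
  split <- c(trachea_main_bronchus = 0.028, bronchiolar = 0.34,
             alveolar = 0.62)
  for (r in names(split)) {
    expect_equal(sum(tab$deposition_fraction[tab$region == r]),
                 unname(split[r]), tolerance = 1e-12)
  }

  # surface areas increase distally; alveoli only in alveolar rows
  expect_true(all(diff(tab$surface_area_cm2) > 0))
  expect_true(all(tab$n_alveoli[tab$region != "alveolar"] == 0))
  expect_true(all(tab$n_alveoli[tab$region == "alveolar"] > 0))

  # custom split is honoured
  tab2 <- gen_deposition_table("mouse_like",
                               regional_split = c(0.1, 0.3, 0.6), seed = 1)
  expect_equal(sum(tab2$deposition_fraction[tab2$region == "alveolar"]), 0.6,
               tolerance = 1e-12)
  expect_error(gen_deposition_table("mouse_like",
                                    regional_split = c(0.5, 0.5, 0.5)),
               "summing")
})

test_that("different seeds change per-generation detail but not the rollup", {
  t1 <- gen_deposition_table("mouse_like", seed = 1)
  t2 <- gen_deposition_table("mouse_like", seed = 2)
  expect_false(isTRUE(all.equal(t1$deposition_fraction,
                                t2$deposition_fraction)))
  r1 <- tapply(t1$deposition_fraction, t1$region, sum)
  r2 <- tapply(t2$deposition_fraction, t2$region, sum)
  expect_equal(r1, r2, tolerance = 1e-12)

  # identical seed is bit-reproducible
  expect_identical(gen_deposition_table("mouse_like", seed = 7),
                   gen_deposition_table("mouse_like", seed = 7))
})

test_that("tiny and human-like lungs are generated consistently", {
  one <- gen_deposition_table("mouse_like", n_generations = 1,
                              regional_split = c(0, 0, 1), seed = 1)
  expect_equal(nrow(one), 1)
  expect_equal(one$deposition_fraction, 1, tolerance = 1e-12)
  expect_equal(one$region, "alveolar")

  h <- gen_deposition_table("human_like", seed = 1)
  expect_equal(nrow(h), 24)
  expect_equal(sum(h$deposition_fraction), 0.494, tolerance = 1e-9)
  expect_true(all(diff(h$surface_area_cm2) > 0))
})

test_that("retention generator produces a seeded noisy line around the truth", {
  # noiseless mode is the exact line
  s0 <- gen_retention_series(14.5, 0.05, noise_rel_sd = 0, seed = 1)
  expect_equal(s0$mass_ug, 14.5 - 0.05 * s0$time_h)

  # lognormal noise keeps masses positive and near the line
  s <- gen_retention_series(14.5, 0.05, noise_rel_sd = 0.05, seed = 1)
  expect_true(all(s$mass_ug > 0))
  line <- 14.5 - 0.05 * s$time_h
  expect_true(all(abs(s$mass_ug / line - 1) < 0.25))  # 5 sigma envelope
  expect_identical(s, gen_retention_series(14.5, 0.05, noise_rel_sd = 0.05,
                                           seed = 1))

  # depletion before the last time point is rejected
  expect_error(gen_retention_series(1, 0.05, times_h = c(0, 100)), "depletes")
})

test_that("in vitro time-course generator is an exact fixture when noiseless", {
  dd <- paper_delivered()
  fr <- default_association_fractions()
  m0 <- gen_invitro_timecourse(spio_exposure(10), fr, noise_rel_sd = 0,
                               seed = 1, delivered = dd)
  expect_equal(m0$measured_mass_ug, dd$mass_ug * fr$fraction)
  expect_equal(unique(m0$well_area_cm2), 2.5 / 0.26, tolerance = 1e-9)

  # unit fractions, no noise: generator output equals the solver output
  all_one <- dplyr::mutate(fr, fraction = 1)
  m1 <- gen_invitro_timecourse(spio_exposure(10), all_one, noise_rel_sd = 0,
                               seed = 1, delivered = dd)
  expect_equal(m1$measured_mass_ug, dd$mass_ug)

  # linearity in the nominal concentration (noiseless)
  dd20 <- dplyr::mutate(dd, mass_ug = 2 * mass_ug)
  m2 <- gen_invitro_timecourse(spio_exposure(20), fr, noise_rel_sd = 0,
                               seed = 1, delivered = dd20)
  expect_equal(m2$measured_mass_ug, 2 * m0$measured_mass_ug)

  expect_error(gen_invitro_timecourse(
    spio_exposure(10), dplyr::mutate(fr, fraction = 1.2), delivered = dd),
    "\\[0, 1\\]")
})

test_that("MPD standard curve quantification inverts the calibration", {
  # noiseless: exact recovery, zero signal maps to zero mass
  curve <- gen_mpd_standard_curve(gain = 2.5, noise_rel_sd = 0, seed = 1)
  cal <- mpd_calibrate(curve)
  expect_equal(cal$gain, 2.5, tolerance = 1e-12)
  expect_equal(as.numeric(mpd_quantify(0, cal)), 0, tolerance = 1e-12)
  expect_equal(as.numeric(mpd_quantify(2.5 * 3.7, cal)), 3.7,
               tolerance = 1e-12)

  # degenerate calibrations are rejected
  expect_error(mpd_calibrate(curve[1:2, ]), "3 calibration points")
  flat <- tibble::tibble(mass_ug = rep(1, 4), signal = 1:4)
  expect_error(mpd_calibrate(flat), "degenerate")
})

test_that("MPD gain recovered within twice the noise SD over 100 replicates", {
  gain <- 2.5
  rel_sd <- 0.02
  gains <- vapply(1:100, function(i) {
    mpd_calibrate(gen_mpd_standard_curve(gain = gain, noise_rel_sd = rel_sd,
                                         seed = 3000 + i))$gain
  }, numeric(1))
  expect_lt(abs(mean(gains) - gain), 2 * rel_sd * gain)
  # individual replicates stay within a few noise SDs too
  expect_gt(mean(abs(gains - gain) < 2 * rel_sd * gain), 0.9)
})

test_that("generators restore the caller's RNG state", {
  set.seed(99)
  before <- stats::runif(1)
  set.seed(99)
  invisible(gen_retention_series(seed = 4))
  invisible(gen_deposition_table("mouse_like", seed = 4))
  after <- stats::runif(1)
  expect_identical(before, after)
})
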