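# Run code with a local RNG seed, restoring the caller's RNG state after.
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Multiplicative lognormal noise with unit mean and the requested relative
# SD; positive by construction (doses and instrument signals cannot go
# negative).
.lognormal_noise <- function(n, rel_sd) {
  if (rel_sd < 0) abort("`rel_sd` must be non-negative")
  if (rel_sd == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + rel_sd^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Geometric sequence of length n with ratio r, scaled to sum to `total`.
.geom_profile <- function(n, r, total) {
  w <- r^(seq_len(n) - 1)
  w / sum(w) * total
}

#' Generate a synthetic per-generation deposition table
#'
#' Builds a deposition table with the structure a multi-path regional lung
#' deposition model would produce: per-generation deposition fractions that
#' roll up *exactly* to a requested regional split
#' (trachea/main-bronchus : bronchiolar : alveolar), epithelial surface
#' areas increasing distally, and alveoli confined to the alveolar region.
#' Within each region the fractions follow a smooth deterministic profile
#' perturbed by seeded lognormal jitter, so different seeds give different
#' per-generation detail but the identical regional rollup.
#'
#' The `mouse_like` defaults target a 22-generation Balb/c-style lung with
#' the regional split 2.8 / 34 / 62 percent of deposited mass. The
#' `human_like` defaults target a 24-generation lung whose fractions are
#' expressed relative to *inhaled* mass (summing to 0.5, the approximate
#' total deposition efficiency of a ~70 nm aerosol), for direct use with
#' [human_scenario_doses()]. Both are synthetic stand-ins for real
#' deposition-model output and are labelled as such; their regional rollups,
#' not their per-generation detail, are the constrained quantities.
#'
#' @param kind `"mouse_like"` or `"human_like"`
#' @param n_generations number of airway generations (defaults 22 / 24)
#' @param regional_split three regional deposition fractions (TB,
#'   bronchiolar, alveolar) summing to at most 1
#' @param seed integer seed for the per-generation jitter
#' @param jitter_rel_sd relative SD of the within-region jitter (default 0.1)
#' @return a validated deposition-table tibble (see
#'   [validate_deposition_table()])
#' @examples
#' gen_deposition_table("mouse_like", seed = 1)
#' @export
gen_deposition_table <- function(kind = c("mouse_like", "human_like"),
                                 n_generations = NULL, regional_split = NULL,
                                 seed = 1, jitter_rel_sd = 0.1) {
  kind <- match.arg(kind)
  cfg <- switch(kind,
    mouse_like = list(n = 22, split = c(0.028, 0.34, 0.62),
                      counts = c(2, 13, 7),
                      area_totals = c(0.4, 6, 500),
                      area_ratios = c(1.1, 1.12, 2.2),
                      alv_mass_ratio = 1.15, total_alveoli = 4e6),
    human_like = list(n = 24, split = c(0.014, 0.170, 0.310),
                      counts = c(2, 14, 8),
                      area_totals = c(30, 2500, 5e5),
                      area_ratios = c(1.1, 1.2, 2.0),
                      alv_mass_ratio = 1.2, total_alveoli = 4.8e8))
  split <- regional_split %||% cfg$split
  if (length(split) != 3 || any(split < 0) || sum(split) > 1 + 1e-9) {
    abort("`regional_split` must be three non-negative fractions summing to <= 1")
  }
  n <- n_generations %||% cfg$n
  if (n < 1) abort("`n_generations` must be at least 1")
  if (n == cfg$n) {
    counts <- cfg$counts
  } else if (n >= 6) {
    n_tb <- 2
    n_alv <- max(1, round(n * cfg$counts[3] / cfg$n))
    counts <- c(n_tb, n - n_tb - n_alv, n_alv)
  } else {
    # tiny lungs: everything is one alveolar region
    counts <- c(0, 0, n)
  }
  region <- rep(.deposition_regions, counts)
  gen <- seq_len(n)

  # surface areas: deterministic geometric growth within each region, scaled
  # to realistic region totals; distally increasing
  area <- unlist(purrr::map(1:3, function(i) {
    if (counts[i] == 0) return(numeric(0))
    .geom_profile(counts[i], cfg$area_ratios[i], cfg$area_totals[i])
  }))

  .with_seed(seed, {
    frac <- unlist(purrr::map(1:3, function(i) {
      if (counts[i] == 0) return(numeric(0))
      share <- if (all(counts[1:2] == 0)) sum(split) else split[i]
      base <- if (i == 3) {
        cfg$alv_mass_ratio^(seq_len(counts[i]) - 1)
      } else {
        # conducting airways: mass roughly proportional to area (near-uniform
        # per-area dose)
        .geom_profile(counts[i], cfg$area_ratios[i], 1)
      }
      w <- base * .lognormal_noise(counts[i], jitter_rel_sd)
      w / sum(w) * share
    }))
    alveoli <- rep(0, n)
    alv_idx <- which(region == "alveolar")
    if (length(alv_idx)) {
      a <- area[alv_idx] / sum(area[alv_idx]) * cfg$total_alveoli
      a <- round(a)
      a[length(a)] <- a[length(a)] + (cfg$total_alveoli - sum(a))
      alveoli[alv_idx] <- a
    }
    validate_deposition_table(
      tibble(generation = gen, region = region,
             deposition_fraction = frac,
             surface_area_cm2 = area, n_alveoli = alveoli))
  })
}

#' Generate a synthetic retained-mass (clearance) time series
#'
#' Linear single-phase decay `m0 - rate * t` with multiplicative lognormal
#' measurement noise, emulating repeated post-exposure lung-burden
#' measurements.
#'
#' @param m0 initial deposited mass (ug)
#' @param rate_ug_h clearance rate (ug/h)
#' @param times_h sacrifice times (h post exposure)
#' @param noise_rel_sd relative SD of the measurement noise (default 0.05)
#' @param seed integer seed
#' @return a tibble with columns `time_h`, `mass_ug`
#' @examples
#' gen_retention_series(seed = 1)
#' @export
gen_retention_series <- function(m0 = 14.5, rate_ug_h = 0.05,
                                 times_h = c(0, 6, 24, 48, 96, 168),
                                 noise_rel_sd = 0.05, seed = 1) {
  .check_positive(m0, "m0")
  if (rate_ug_h < 0) abort("`rate_ug_h` must be non-negative")
  if (is.unsorted(times_h) || any(times_h < 0)) {
    abort("`times_h` must be sorted and non-negative")
  }
  mean_line <- m0 - rate_ug_h * times_h
  if (any(mean_line < 0)) {
    abort("burden depletes before the last time point; reduce `rate_ug_h` or times")
  }
  .with_seed(seed, {
    tibble(time_h = times_h,
           mass_ug = mean_line * .lognormal_noise(length(times_h), noise_rel_sd))
  })
}

#' Default association-fraction schedule
#'
#' The time-dependent cell-association fractions used by the packaged in
#' vitro fixtures: high (93 percent) during the early delivery-limited
#' phase, declining to a 67-68 percent plateau by 8-24 h.
#'
#' @return a tibble with columns `time_h`, `fraction`
#' @export
default_association_fractions <- function() {
  tibble(time_h = c(1, 2, 4, 8, 24),
         fraction = c(0.93, 0.93, 0.89, 0.67, 0.68))
}

#' Generate a synthetic in vitro cellular-dose time course
#'
#' Runs the transport solver for the exposure, multiplies the delivered mass
#' by prescribed true association fractions, and adds multiplicative
#' lognormal measurement noise emulating magnetic-particle-detection (MPD)
#' quantification. The noiseless output equals delivered x fraction exactly,
#' so the series is an exact inverse-crime fixture for
#' [fit_association_fractions()].
#'
#' @param exposure a [suspension_exposure()]
#' @param fractions tibble with `time_h` and `fraction` columns (defaults to
#'   [default_association_fractions()])
#' @param n_cells cells per well
#' @param noise_rel_sd relative measurement noise SD (default 0.05)
#' @param seed integer seed
#' @param delivered optional precomputed `delivered_dose` covering the
#'   fraction times (to avoid re-running the solver)
#' @param ... further arguments passed to [simulate_delivery()]
#' @return a tibble with columns `time_h`, `nominal_ug_per_ml`,
#'   `measured_mass_ug`, `n_cells`, `well_area_cm2`
#' @examples
#' \donttest{
#' gen_invitro_timecourse(spio_exposure(10), seed = 1)
#' }
#' @export
gen_invitro_timecourse <- function(exposure,
                                   fractions = default_association_fractions(),
                                   n_cells = 2.5e5, noise_rel_sd = 0.05,
                                   seed = 1, delivered = NULL, ...) {
  stopifnot(inherits(exposure, "suspension_exposure"),
            is.data.frame(fractions))
  if (any(fractions$fraction < 0 | fractions$fraction > 1)) {
    abort("true fractions must lie in [0, 1]")
  }
  if (is.null(delivered)) {
    delivered <- simulate_delivery(exposure, fractions$time_h, ...)
  }
  idx <- match(round(fractions$time_h, 9), round(delivered$time_h, 9))
  if (any(is.na(idx))) abort("`delivered` does not cover all fraction times")
  area <- as.numeric(well_area_cm2(exposure$geometry))
  .with_seed(seed, {
    noise <- .lognormal_noise(nrow(fractions), noise_rel_sd)
    tibble(time_h = fractions$time_h,
           nominal_ug_per_ml = exposure$nominal_concentration_ug_ml,
           measured_mass_ug = delivered$mass_ug[idx] * fractions$fraction * noise,
           n_cells = n_cells,
           well_area_cm2 = area)
  })
}

#' Generate a synthetic MPD standard curve
#'
#' Magnetic particle detection is calibrated by serial dilutions of the
#' particle stock in the relevant biological matrix; the instrument signal
#' is proportional to particulate mass. The generator emulates this with
#' `signal = gain * mass * noise`. Different matrices (cells vs tissue) are
#' modelled as different gains.
#'
#' @param true_masses_ug calibration masses (ug); at least 3 distinct values
#'   are needed for quantification
#' @param gain instrument gain (signal units per ug)
#' @param noise_rel_sd relative signal noise SD (default 0.02)
#' @param seed integer seed
#' @return a tibble with columns `mass_ug`, `signal`
#' @examples
#' gen_mpd_standard_curve(seed = 1)
#' @export
gen_mpd_standard_curve <- function(true_masses_ug = c(0.25, 0.5, 1, 2, 4, 8),
                                   gain = 1, noise_rel_sd = 0.02, seed = 1) {
  if (any(true_masses_ug < 0)) abort("calibration masses must be non-negative")
  .check_positive(gain, "gain")
  .with_seed(seed, {
    tibble(mass_ug = true_masses_ug,
           signal = gain * true_masses_ug *
             .lognormal_noise(length(true_masses_ug), noise_rel_sd))
  })
}

#' Calibrate and invert an MPD standard curve
#'
#' `mpd_calibrate()` fits an ordinary least-squares line through the
#' calibration set; `mpd_quantify()` inverts it to convert signals to
#' particulate mass. A noiseless curve recovers mass exactly and maps zero
#' signal to zero mass.
#'
#' @param curve a standard-curve tibble from [gen_mpd_standard_curve()] (or
#'   measured equivalent with columns `mass_ug`, `signal`)
#' @return for `mpd_calibrate()`, an object of class `mpd_calibration` with
#'   elements `intercept`, `gain` and `model`
#' @examples
#' cal <- mpd_calibrate(gen_mpd_standard_curve(noise_rel_sd = 0, seed = 1))
#' mpd_quantify(2.5, cal)
#' @export
mpd_calibrate <- function(curve) {
  stopifnot(is.data.frame(curve))
  miss <- setdiff(c("mass_ug", "signal"), names(curve))
  if (length(miss)) {
    abort(paste0("calibration set is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (nrow(curve) < 3) abort("at least 3 calibration points are required")
  if (stats::sd(curve$mass_ug) == 0) {
    abort("degenerate calibration: all masses identical")
  }
  fit <- lm(signal ~ mass_ug, data = curve)
  structure(list(intercept = unname(coef(fit)[1]),
                 gain = unname(coef(fit)[2]),
                 model = fit),
            class = "mpd_calibration")
}

#' @rdname mpd_calibrate
#' @param signal measured signal(s); vectorised
#' @param calibration an `mpd_calibration`
#' @export
mpd_quantify <- function(signal, calibration) {
  stopifnot(inherits(calibration, "mpd_calibration"))
  if (calibration$gain == 0) abort("calibration gain is zero")
  with_unit((signal - calibration$intercept) / calibration$gain, "ug")
}
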