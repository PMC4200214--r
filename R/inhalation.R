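#' Respiratory physiology
#'
#' Breathing parameters of the exposed subject. If `minute_volume_ml_min` is
#' omitted it is computed as tidal volume times respiratory rate. The
#' deposition model and the measured physiology may legitimately differ (a
#' deposition table is often generated with nominal breathing parameters
#' while inhaled mass uses the measured minute volume); keep two objects in
#' that case.
#'
#' @param tidal_volume_ml tidal volume (ml/breath)
#' @param respiratory_rate_bpm respiratory rate (breaths/min)
#' @param minute_volume_ml_min minute volume (ml/min); default TV x RR
#' @return an object of class `respiratory_physiology`
#' @examples
#' mouse_physiology()
#' human_physiology()
#' @export
respiratory_physiology <- function(tidal_volume_ml, respiratory_rate_bpm,
                                   minute_volume_ml_min = NULL) {
  .check_positive(tidal_volume_ml, "tidal_volume_ml")
  .check_positive(respiratory_rate_bpm, "respiratory_rate_bpm")
  if (is.null(minute_volume_ml_min)) {
    minute_volume_ml_min <- tidal_volume_ml * respiratory_rate_bpm
  }
  .check_positive(minute_volume_ml_min, "minute_volume_ml_min")
  structure(list(tidal_volume_ml = tidal_volume_ml,
                 respiratory_rate_bpm = respiratory_rate_bpm,
                 minute_volume_ml_min = minute_volume_ml_min),
            class = c("respiratory_physiology", "particledose_spec"))
}

#' @rdname respiratory_physiology
#' @details `mouse_physiology()` carries the measured plethysmography values
#'   for aerosol-exposed Balb/c mice (RR 371/min, TV 0.24 ml, MV 77 ml/min);
#'   `mouse_deposition_physiology()` the nominal breathing rate used for
#'   deposition modelling (RR 317/min); `human_physiology()` a resting adult
#'   reference (TV 625 ml, RR 12/min).
#' @export
mouse_physiology <- function() respiratory_physiology(0.24, 371, 77)

#' @rdname respiratory_physiology
#' @export
mouse_deposition_physiology <- function() respiratory_physiology(0.24, 317)

#' @rdname respiratory_physiology
#' @export
human_physiology <- function() respiratory_physiology(625, 12)

#' Exposure scenario
#'
#' @param mass_concentration_mg_m3 aerosol mass concentration (mg/m^3)
#' @param duration_h exposure duration (h)
#' @param label free-text scenario label
#' @return an object of class `exposure_scenario`
#' @examples
#' mouse_exposure_scenario()
#' @export
exposure_scenario <- function(mass_concentration_mg_m3, duration_h,
                              label = "") {
  .check_positive(mass_concentration_mg_m3, "mass_concentration_mg_m3",
                  strict = FALSE)
  .check_positive(duration_h, "duration_h", strict = FALSE)
  structure(list(mass_concentration_mg_m3 = mass_concentration_mg_m3,
                 duration_h = duration_h, label = label),
            class = c("exposure_scenario", "particledose_spec"))
}

#' @rdname exposure_scenario
#' @export
mouse_exposure_scenario <- function() {
  exposure_scenario(19.9, 4, "mouse nose-only SPIO aerosol")
}

#' Total inhaled mass
#'
#' `TIM = MV x duration x concentration`, with unit conversion from ml/min,
#' hours and mg/m^3 to micrograms.
#'
#' @param phys a [respiratory_physiology()]
#' @param scenario an [exposure_scenario()]
#' @return inhaled mass (ug)
#' @examples
#' total_inhaled_mass(mouse_physiology(), mouse_exposure_scenario())  # ~366 ug
#' @export
total_inhaled_mass <- function(phys, scenario) {
  stopifnot(inherits(phys, "respiratory_physiology"),
            inherits(scenario, "exposure_scenario"))
  vol_m3 <- phys$minute_volume_ml_min * scenario$duration_h * 60 * 1e-6
  with_unit(vol_m3 * scenario$mass_concentration_mg_m3 * 1000, "ug")
}

#' Deposition fraction of inhaled mass
#'
#' @param deposited_ug deposited mass (ug)
#' @param inhaled_ug inhaled mass (ug, > 0)
#' @return dimensionless fraction; a warning is raised if it exceeds 1
#' @export
deposition_fraction <- function(deposited_ug, inhaled_ug) {
  if (inhaled_ug <= 0) abort("`inhaled_ug` must be positive")
  f <- deposited_ug / inhaled_ug
  if (f > 1) warn("deposited mass exceeds inhaled mass (fraction > 1)")
  with_unit(f, "fraction")
}

.deposition_regions <- c("trachea_main_bronchus", "bronchiolar", "alveolar")

#' Validate a per-generation deposition table
#'
#' A deposition table is the per-airway-generation output of a regional
#' deposition model (supplied externally or generated synthetically by
#' [gen_deposition_table()]): columns `generation` (1-based index), `region`
#' (one of `trachea_main_bronchus`, `bronchiolar`, `alveolar`),
#' `deposition_fraction`, `surface_area_cm2` and `n_alveoli`. Fractions must
#' be non-negative and sum to at most 1; alveoli may appear only in alveolar
#' rows.
#'
#' @param table a data frame
#' @return the validated table as a tibble (invisibly the same data)
#' @export
validate_deposition_table <- function(table) {
  stopifnot(is.data.frame(table))
  req <- c("generation", "region", "deposition_fraction",
           "surface_area_cm2", "n_alveoli")
  miss <- setdiff(req, names(table))
  if (length(miss)) {
    abort(paste0("deposition table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (nrow(table) == 0) abort("deposition table is empty")
  if (!all(table$region %in% .deposition_regions)) {
    abort(paste0("`region` must be one of: ",
                 paste(.deposition_regions, collapse = ", ")))
  }
  if (any(table$deposition_fraction < 0)) {
    abort("deposition fractions must be non-negative")
  }
  if (sum(table$deposition_fraction) > 1 + 1e-9) {
    abort("deposition fractions must sum to at most 1")
  }
  if (any(table$surface_area_cm2 <= 0)) {
    abort("surface areas must be positive")
  }
  if (any(table$n_alveoli[table$region != "alveolar"] != 0)) {
    abort("`n_alveoli` must be zero outside the alveolar region")
  }
  as_tibble(table)
}

#' Allocate a measured total deposited mass across airway generations
#'
#' Multiplies per-generation deposition fractions (renormalised to sum to 1
#' over the table, with a message when renormalisation changes them) by the
#' experimentally measured total deposited lung burden. The regional rollup
#' sums exactly to the supplied total by construction.
#'
#' @param table a deposition table (see [validate_deposition_table()])
#' @param total_deposited_ug measured total deposited mass (ug)
#' @return a tibble of class `regional_dose`: the table plus `mass_ug`
#' @examples
#' tab <- gen_deposition_table("mouse_like", seed = 1)
#' allocate_regional_mass(tab, 14.5)
#' @export
allocate_regional_mass <- function(table, total_deposited_ug) {
  table <- validate_deposition_table(table)
  .check_positive(total_deposited_ug, "total_deposited_ug", strict = FALSE)
  fsum <- sum(table$deposition_fraction)
  if (fsum <= 0) abort("all deposition fractions are zero")
  if (abs(fsum - 1) > 1e-9) {
    inform(sprintf(
      "deposition fractions sum to %.4g; renormalised to 1 before allocation",
      fsum))
  }
  out <- dplyr::mutate(table,
                       mass_ug = .data$deposition_fraction / fsum *
                         total_deposited_ug)
  structure(out, class = c("regional_dose", class(as_tibble(out))),
            total_deposited_ug = total_deposited_ug)
}

#' Per-surface-area dose by generation
#'
#' Divides the deposited mass in each generation by that generation's
#' epithelial surface area.
#'
#' @param regional a `regional_dose` tibble from [allocate_regional_mass()]
#' @return the same tibble with a `surface_dose_ug_cm2` column added
#' @export
surface_area_dose <- function(regional) {
  stopifnot(is.data.frame(regional), "mass_ug" %in% names(regional))
  if (any(regional$surface_area_cm2 <= 0)) abort("zero or negative surface area")
  dplyr::mutate(regional,
                surface_dose_ug_cm2 = .data$mass_ug / .data$surface_area_cm2)
}

#' Per-macrophage dose in the alveolar region
#'
#' Distributes a fixed pool of alveolar macrophages across alveolar
#' generations in proportion to the number of alveoli in each, then divides
#' the scavenged share of each generation's deposited mass by its macrophage
#' count. The default scavenging fraction of 1 reflects the guiding
#' assumption that macrophages take up essentially all particles deposited
#' in the deep lung; sensitivity sweeps (e.g. 0.2-0.8) are supported through
#' the `scavenging_fraction` argument.
#'
#' @param regional a `regional_dose` tibble from [allocate_regional_mass()]
#' @param total_macrophages total alveolar macrophage count (default
#'   1.25e6, the mouse value)
#' @param scavenging_fraction fraction of alveolar-deposited particles taken
#'   up by macrophages, in (0, 1]
#' @return the tibble with `n_macrophages` and `macrophage_dose_pg` columns
#'   added (`NA` outside the alveolar region)
#' @export
macrophage_dose <- function(regional, total_macrophages = 1.25e6,
                            scavenging_fraction = 1) {
  stopifnot(is.data.frame(regional), "mass_ug" %in% names(regional))
  .check_positive(total_macrophages, "total_macrophages")
  if (!(scavenging_fraction > 0 && scavenging_fraction <= 1)) {
    abort("`scavenging_fraction` must lie in (0, 1]")
  }
  alv <- regional$region == "alveolar"
  if (any(alv & regional$mass_ug > 0 & regional$n_alveoli == 0)) {
    abort("alveolar mass present in a generation with zero alveoli")
  }
  n_alv_total <- sum(regional$n_alveoli[alv])
  if (any(alv) && n_alv_total <= 0) {
    abort("no alveoli in the alveolar region")
  }
  macs <- ifelse(alv, total_macrophages * regional$n_alveoli / n_alv_total,
                 NA_real_)
  dose_pg <- ifelse(alv & macs > 0,
                    scavenging_fraction * regional$mass_ug * 1e6 / macs,
                    NA_real_)
  dplyr::mutate(regional, n_macrophages = macs, macrophage_dose_pg = dose_pg)
}

#' Full regional dosimetry chain
#'
#' Convenience wrapper: allocation of the measured total to generations,
#' per-area dose and per-macrophage dose in one call.
#'
#' @inheritParams allocate_regional_mass
#' @inheritParams macrophage_dose
#' @return a `regional_dose` tibble with all dose columns
#' @examples
#' tab <- gen_deposition_table("mouse_like", seed = 1)
#' regional_dosimetry(tab, 14.5)
#' @export
regional_dosimetry <- function(table, total_deposited_ug,
                               total_macrophages = 1.25e6,
                               scavenging_fraction = 1) {
  allocate_regional_mass(table, total_deposited_ug) |>
    surface_area_dose() |>
    macrophage_dose(total_macrophages = total_macrophages,
                    scavenging_fraction = scavenging_fraction)
}

#' Regional rollup of a per-generation dose table
#'
#' @param regional a `regional_dose` tibble
#' @return one row per region with summed mass, area, alveoli and
#'   macrophages, mean surface dose (mass-weighted total / total area) and
#'   mean macrophage dose (total scavenged mass / total macrophages)
#' @export
regional_rollup <- function(regional) {
  stopifnot(is.data.frame(regional), "mass_ug" %in% names(regional))
  out <- regional |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(
      n_generations = dplyr::n(),
      mass_ug = sum(.data$mass_ug),
      surface_area_cm2 = sum(.data$surface_area_cm2),
      n_alveoli = sum(.data$n_alveoli),
      .groups = "drop") |>
    dplyr::mutate(surface_dose_ug_cm2 = .data$mass_ug / .data$surface_area_cm2)
  if ("n_macrophages" %in% names(regional)) {
    mac <- regional |>
      dplyr::group_by(.data$region) |>
      dplyr::summarise(
        scavenged_mass_ug = sum(.data$macrophage_dose_pg *
                                  .data$n_macrophages, na.rm = TRUE) / 1e6,
        n_macrophages = sum(.data$n_macrophages, na.rm = TRUE),
        .groups = "drop") |>
      dplyr::mutate(macrophage_dose_pg = ifelse(
        .data$n_macrophages > 0,
        .data$scavenged_mass_ug * 1e6 / .data$n_macrophages, NA_real_)) |>
      dplyr::select("region", "n_macrophages", "macrophage_dose_pg")
    out <- dplyr::left_join(out, mac, by = "region")
  }
  out[order(match(out$region, .deposition_regions)), ]
}

#' Hot-spot dose at airway bifurcations
#'
#' Local deposition at bifurcation carinae exceeds the regional average by
#' an enhancement factor that depends on the averaging area; computational
#' fluid dynamics studies report a factor of about 65 for ~200 nm particles
#' over a 100 um (10 x 10 cell) patch. This helper simply multiplies an
#' average surface dose by the supplied scalar factor.
#'
#' @param average_surface_dose_ug_cm2 regional average dose (ug/cm^2)
#' @param enhancement_factor dimensionless local enhancement (default 65)
#' @return local hot-spot dose (ug/cm^2)
#' @examples
#' hotspot_dose(0.1)  # 6.5
#' @export
hotspot_dose <- function(average_surface_dose_ug_cm2, enhancement_factor = 65) {
  if (any(average_surface_dose_ug_cm2 < 0) || any(enhancement_factor < 0)) {
    abort("dose and enhancement factor must be non-negative")
  }
  with_unit(average_surface_dose_ug_cm2 * enhancement_factor, "ug/cm^2")
}

#' @method autoplot regional_dose
#' @export
autoplot.regional_dose <- function(object, ...) {
  cols <- intersect(c("mass_ug", "surface_dose_ug_cm2", "macrophage_dose_pg"),
                    names(object))
  long <- tidyr::pivot_longer(as_tibble(object), cols = all_of(cols),
                              names_to = "metric", values_to = "value")
  ggplot(long, aes(x = .data$generation, y = .data$value,
                   fill = .data$region)) +
    geom_col() +
    facet_wrap(~metric, scales = "free_y", ncol = 1) +
    labs(x = "Airway generation", y = NULL,
         title = "Regional dose by airway generation") +
    theme_minimal()
}
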