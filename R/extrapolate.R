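#' Occupational exposure limit
#'
#' @param limit_value_mg_m3 limit concentration (mg/m^3)
#' @param basis what the limit mass refers to: `"as_Fe"` (elemental iron) or
#'   `"as_oxide"` (the oxide particle itself)
#' @param duration_h workday duration the limit applies over (h, default 8)
#' @return an object of class `occupational_limit`
#' @examples
#' osha_iron_oxide_pel()
#' @export
occupational_limit <- function(limit_value_mg_m3, basis = c("as_Fe", "as_oxide"),
                               duration_h = 8) {
  basis <- match.arg(basis)
  .check_positive(limit_value_mg_m3, "limit_value_mg_m3", strict = FALSE)
  .check_positive(duration_h, "duration_h")
  structure(list(limit_value_mg_m3 = limit_value_mg_m3, basis = basis,
                 duration_h = duration_h),
            class = c("occupational_limit", "particledose_spec"))
}

#' @rdname occupational_limit
#' @details `osha_iron_oxide_pel()` is the OSHA permissible exposure limit
#'   for iron oxide dust and fume: 10 mg/m^3 as Fe over an 8 h workday.
#' @export
osha_iron_oxide_pel <- function() occupational_limit(10, "as_Fe", 8)

#' Mass fraction of iron in an iron oxide species
#'
#' Computed from conventional atomic masses (Fe 55.845, O 15.999 g/mol).
#'
#' @param species one of `"Fe3O4"` (magnetite), `"Fe2O3"` (hematite),
#'   `"FeO"` (wustite)
#' @return dimensionless iron mass fraction
#' @examples
#' iron_mass_fraction("Fe3O4")  # about 0.724
#' @export
iron_mass_fraction <- function(species = c("Fe3O4", "Fe2O3", "FeO")) {
  species <- match.arg(species)
  comp <- switch(species,
                 Fe3O4 = c(Fe = 3, O = 4),
                 Fe2O3 = c(Fe = 2, O = 3),
                 FeO = c(Fe = 1, O = 1))
  total <- sum(comp * .atomic_mass[names(comp)])
  with_unit(unname(comp["Fe"] * .atomic_mass["Fe"] / total), "fraction")
}

#' Express an as-Fe exposure limit as particle mass
#'
#' A limit stated as elemental iron allows a proportionally larger mass of
#' the oxide particle: `limit / iron_fraction`. A limit already stated on an
#' oxide basis is returned unchanged.
#'
#' @param limit an [occupational_limit()]
#' @param iron_fraction iron mass fraction of the particle, in (0, 1];
#'   see [iron_mass_fraction()]
#' @return adjusted limit concentration (mg/m^3 as particle)
#' @examples
#' adjust_limit_for_iron(osha_iron_oxide_pel(), 0.72)  # about 13.9
#' @export
adjust_limit_for_iron <- function(limit, iron_fraction) {
  stopifnot(inherits(limit, "occupational_limit"))
  if (!(iron_fraction > 0 && iron_fraction <= 1)) {
    abort("`iron_fraction` must lie in (0, 1]")
  }
  if (limit$basis == "as_oxide") {
    return(with_unit(limit$limit_value_mg_m3, "mg/m^3"))
  }
  with_unit(limit$limit_value_mg_m3 / iron_fraction, "mg/m^3")
}

#' Cumulative (time-weighted) exposure
#'
#' @param scenario an [exposure_scenario()]
#' @return concentration x duration (mg h/m^3)
#' @examples
#' cumulative_exposure(mouse_exposure_scenario())  # 79.6
#' @export
cumulative_exposure <- function(scenario) {
  stopifnot(inherits(scenario, "exposure_scenario"))
  with_unit(scenario$mass_concentration_mg_m3 * scenario$duration_h,
            "mg*hr/m^3")
}

#' Human-scenario regional doses at an exposure limit
#'
#' Runs the same regional dose chain as the rodent analysis for a human
#' deposition table and breathing pattern, with the deposited mass obtained
#' as inhaled mass times the table's per-generation deposition fractions
#' (which are therefore interpreted as fractions of *inhaled*, not
#' deposited, mass, and are deliberately not renormalised). Clearance is
#' not considered: the result is the deposited dose at the end of the
#' exposure.
#'
#' @param table a human deposition table (fractions of inhaled mass)
#' @param phys a human [respiratory_physiology()]
#' @param scenario an [exposure_scenario()] (e.g. 8 h at the iron-adjusted
#'   limit)
#' @param total_macrophages total human alveolar macrophage count
#' @param scavenging_fraction see [macrophage_dose()]
#' @return a `regional_dose` tibble with mass, per-area and per-macrophage
#'   columns
#' @examples
#' htab <- gen_deposition_table("human_like", seed = 1)
#' sc <- exposure_scenario(14, 8, "PEL workday")
#' human_scenario_doses(htab, human_physiology(), sc)
#' @export
human_scenario_doses <- function(table, phys, scenario,
                                 total_macrophages = 2e9,
                                 scavenging_fraction = 1) {
  table <- validate_deposition_table(table)
  stopifnot(inherits(phys, "respiratory_physiology"),
            inherits(scenario, "exposure_scenario"))
  tim <- as.numeric(total_inhaled_mass(phys, scenario))
  out <- dplyr::mutate(table, mass_ug = .data$deposition_fraction * tim)
  out <- structure(out, class = c("regional_dose", class(as_tibble(out))),
                   total_deposited_ug = sum(out$mass_ug),
                   total_inhaled_ug = tim)
  out |>
    surface_area_dose() |>
    macrophage_dose(total_macrophages = total_macrophages,
                    scavenging_fraction = scavenging_fraction)
}

#' Dose band
#'
#' A closed interval of effective (or experienced) dose, tagged with its
#' metric, exposure system and cellular context, for cross-system
#' comparison. The in vitro "effect" band follows the lowest-observed-effect
#' convention: its lower edge is the lowest tested dose with a significant
#' response.
#'
#' @param lower,upper interval edges, `0 <= lower <= upper`
#' @param metric `"per_area"` (ug/cm^2) or `"per_cell"` (pg/cell)
#' @param system `"in_vitro"`, `"in_vivo"` or `"human_scenario"`
#' @param cell_context free text, e.g. `"BMM"` or `"alveolar macrophage"`
#' @param effect_observed `"yes"`, `"no"` or `"unknown"`
#' @return an object of class `dose_band`
#' @examples
#' dose_band(8, 35, "per_cell", "in_vitro", "BMM", "yes")
#' @export
dose_band <- function(lower, upper, metric = c("per_area", "per_cell"),
                      system = c("in_vitro", "in_vivo", "human_scenario"),
                      cell_context = "", effect_observed = "unknown") {
  metric <- match.arg(metric)
  system <- match.arg(system)
  if (!(lower >= 0 && lower <= upper)) {
    abort("need 0 <= lower <= upper")
  }
  if (!effect_observed %in% c("yes", "no", "unknown")) {
    abort("`effect_observed` must be yes, no or unknown")
  }
  structure(list(lower = lower, upper = upper, metric = metric,
                 system = system, cell_context = cell_context,
                 effect_observed = effect_observed),
            class = c("dose_band", "particledose_spec"))
}

#' Compare two dose bands on the same metric
#'
#' Closed-interval intersection plus simple summary ratios, the quantitative
#' form of an "in vitro effective doses fall inside / outside the in vivo
#' range" statement.
#'
#' @param a,b [dose_band()] objects with the same `metric`
#' @return a tibble with one row: `overlaps` (logical), `overlap_lower`,
#'   `overlap_upper` (NA when disjoint), `midpoint_ratio` (midpoint of `a` /
#'   midpoint of `b`), plus the band labels
#' @examples
#' bmm <- dose_band(8, 35, "per_cell", "in_vitro", "BMM", "yes")
#' am  <- dose_band(1, 100, "per_cell", "in_vivo", "alveolar macrophage", "yes")
#' compare_dose_bands(bmm, am)
#' @export
compare_dose_bands <- function(a, b) {
  stopifnot(inherits(a, "dose_band"), inherits(b, "dose_band"))
  if (a$metric != b$metric) {
    abort(sprintf("cannot compare bands on different metrics (%s vs %s)",
                  a$metric, b$metric))
  }
  lo <- max(a$lower, b$lower)
  hi <- min(a$upper, b$upper)
  overlaps <- lo <= hi
  mid_a <- (a$lower + a$upper) / 2
  mid_b <- (b$lower + b$upper) / 2
  tibble(metric = a$metric,
         system_a = a$system, context_a = a$cell_context,
         system_b = b$system, context_b = b$cell_context,
         overlaps = overlaps,
         overlap_lower = if (overlaps) lo else NA_real_,
         overlap_upper = if (overlaps) hi else NA_real_,
         midpoint_ratio = if (mid_b > 0) mid_a / mid_b else NA_real_)
}

#' Plot a set of dose bands
#'
#' @param bands a data frame with columns `system`, `metric`, `lower`,
#'   `upper`, `cell_context`, `effect` (as written by the pipeline's bands
#'   table)
#' @return a ggplot object (log10 dose axis, one facet per metric)
#' @export
plot_dose_bands <- function(bands) {
  stopifnot(is.data.frame(bands))
  bands <- dplyr::mutate(bands,
                         label = paste(.data$system, .data$cell_context))
  ggplot(bands, aes(y = .data$label, xmin = pmax(.data$lower, 1e-6),
                    xmax = .data$upper, colour = .data$effect)) +
    geom_errorbarh(aes(height = 0.3)) +
    scale_x_log10() +
    facet_wrap(~metric, scales = "free", ncol = 1) +
    labs(x = "Dose (per_area: ug/cm^2; per_cell: pg/cell)", y = NULL,
         title = "Effective dose bands across exposure systems") +
    theme_minimal()
}
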