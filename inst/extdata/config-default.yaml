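# Default study configuration: carboxylated SPIO (magnetite) nanoparticles,
# serum-supplemented RPMI, 6-well culture format, Balb/c mouse inhalation
# exposure and the OSHA iron oxide PEL human scenario.
particle:
  diameter_nm: 13
  density_g_cm3: 5.2
agglomerate:
  hydrodynamic_diameter_nm: 276
  fractal_dimension: 2.1
  packing_factor: 0.637
medium:
  density_g_cm3: 1.0
  viscosity_pa_s: 0.00074
  temperature_k: 310
geometry:
  media_height_mm: 2.6
  media_volume_ml: 2.5
aerosol:
  cmd_nm: 68.6
  gsd: 1.65
  mass_concentration_mg_m3: 19.9
physiology:
  mouse_measured:
    tidal_volume_ml: 0.24
    respiratory_rate_bpm: 371
    minute_volume_ml_min: 77
  mouse_deposition:
    tidal_volume_ml: 0.24
    respiratory_rate_bpm: 317
  human:
    tidal_volume_ml: 625
    respiratory_rate_bpm: 12
scenarios:
  mouse:
    mass_concentration_mg_m3: 19.9
    duration_h: 4
    label: mouse nose-only SPIO aerosol
  occupational_limit:
    limit_value_mg_m3: 10
    basis: as_Fe
    duration_h: 8
    species: Fe3O4
invitro:
  nominal_concentration_ug_ml: 10
  times_h: [1, 2, 4, 8, 24]
  true_fractions: [0.93, 0.93, 0.89, 0.67, 0.68]
  n_cells: 250000
  noise_rel_sd: 0.05
  association_covariate: delivered
deposition:
  total_deposited_ug: 14.5
  mouse_total_macrophages: 1250000
  human_total_macrophages: 2000000000
  scavenging_fraction: 1.0
  enhancement_factor: 65
clearance:
  m0_ug: 14.5
  rate_ug_h: 0.05
  times_h: [0, 6, 24, 48, 96, 168]
  noise_rel_sd: 0.05
bands:
  - system: in_vitro
    metric: per_cell
    lower: 8
    upper: 35
    cell_context: BMM
    effect: "yes"
  - system: in_vivo
    metric: per_cell
    lower: 1
    upper: 100
    cell_context: alveolar macrophage
    effect: "yes"
  - system: in_vitro
    metric: per_area
    lower: 1.2
    upper: 4
    cell_context: C10 epithelial
    effect: "yes"
  - system: in_vivo
    metric: per_area
    lower: 0.009
    upper: 0.13
    cell_context: alveolar tissue
    effect: "yes"
solver:
  n_nodes: 300
  dt_s: 6
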