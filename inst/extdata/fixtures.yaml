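# Packaged fixture presets for the synthetic-data generators.
# Temperatures in degC, concentrations in uM, rates in 1/s, chemical shift in
# ppm, wavenumbers in cm-1. Tm and Kd presets mirror the reported screen
# values; everything else (plateaus, rates, amplitudes, noise levels) is a
# package choice documented in the methods vignette.

dsf:
  control:
    tm: 53.4
    transition_slope: 1.0
    f_pre: 1000
    f_post: 10000
    decay_onset_offset: 12.0   # decay onset = tm + offset
    decay_rate: 0.12
    noise_sd: 90               # 1% of the 9000 a.u. amplitude
    n_replicates: 2
    temp_min: 25.0
    temp_max: 95.0
    temp_step: 0.25
  KG-96:  {tm: 57.2}
  KG-408: {tm: 57.3}
  KG-484: {tm: 63.4}

std:
  regions:
    - {label: "8.42-8.39ppm", ppm_lo: 8.39, ppm_hi: 8.42}
    - {label: "7.83-7.78ppm", ppm_lo: 7.78, ppm_hi: 7.83}
    - {label: "7.42-7.26ppm", ppm_lo: 7.26, ppm_hi: 7.42}
  protein_conc_uM: 20
  ligand_concs_uM: [200, 400, 600, 800, 1000]
  sat_times_s: [0.5, 0.75, 1, 1.5, 2, 2.5, 3.5, 5]
  noise_cv: 0.03
  KG-96:
    kd_uM: 171
    alpha_std: [0.60, 0.45, 0.30]
    ksat_ref: [0.80, 0.70, 0.60]
  KG-408:
    kd_uM: 376
    alpha_std: [0.50, 0.40, 0.28]
    ksat_ref: [0.75, 0.65, 0.60]
  KG-484:
    kd_uM: 841
    alpha_std: [0.45, 0.35, 0.25]
    ksat_ref: [0.70, 0.65, 0.55]

screen:
  n_compounds: 760
  control_tm: 53.4
  library_delta_sd: 1.21244    # uniform jitter, half-width 2.1 degC
  hit_fraction: 0.0657895      # 50 / 760
  hit_delta_lo: 3.0
  hit_delta_hi: 12.0
  n_control_wells: 8

mms:
  wavenumber_min: 1588
  wavenumber_max: 1712
  wavenumber_step: 1
  temp_min: 25
  temp_max: 75
  temp_step: 1
  noise_sd: 0.006              # ~0.5% of the peak absorbance
  apo:
    bands:
      - {center: 1605, width: 6, base_amplitude: 0.15, structure_class: side_chain,     melt_tm: 50, melt_slope: 3.0, post_melt_fraction: 0.60}
      - {center: 1633, width: 6, base_amplitude: 0.50, structure_class: native_beta,    melt_tm: 53, melt_slope: 2.0, post_melt_fraction: 0.10}
      - {center: 1640, width: 6, base_amplitude: 0.45, structure_class: native_beta,    melt_tm: 53, melt_slope: 2.0, post_melt_fraction: 0.10}
      - {center: 1645, width: 6, base_amplitude: 0.30, structure_class: unordered,      melt_tm: 53, melt_slope: 2.5, post_melt_fraction: 1.50}
      - {center: 1651, width: 6, base_amplitude: 0.55, structure_class: alpha_helix_cc, melt_tm: 54, melt_slope: 2.0, post_melt_fraction: 0.15}
      - {center: 1656, width: 6, base_amplitude: 0.60, structure_class: alpha_helix,    melt_tm: 54, melt_slope: 2.0, post_melt_fraction: 0.15}
      - {center: 1667, width: 6, base_amplitude: 0.35, structure_class: turn,           melt_tm: 53, melt_slope: 2.0, post_melt_fraction: 0.30}
      - {center: 1678, width: 6, base_amplitude: 0.25, structure_class: turn,           melt_tm: 53, melt_slope: 2.0, post_melt_fraction: 0.30}
    aggregate: {center: 1619, width: 7, amplitude: 0.70, growth_tm: 54, growth_slope: 2.5}
  bound_shifts:               # degC added to apo melt midpoints per class
    native_beta: 14.0
    alpha_helix_cc: 4.0
    alpha_helix: 5.0
    turn: 2.0
    unordered: 2.0
    side_chain: 2.0
    aggregate: 14.0
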