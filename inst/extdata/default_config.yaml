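# Default srtriplex run configuration (all values equal the package defaults;
# any subset may be overridden).
phantom:
  lengths_mm: {proximal: 30, middle: 25, distal: 20}
  r_outer_mm: [4.5, 4.0, 3.25]
  r_inner_mm: [3.0, 2.6, 2.0]
  soft_tissue_mm: 3
  C_trab_ppm: 150
  trab_cort_ratio: 4
  porosity: 0.8
geometry:
  sdd_mm: 150
  sod_mm: 100
  pitch_mm: 0.05
sensor:
  noise_floor_keV: 5
  thickness_mm: 0.75
  density_g_cm3: 5.85
  escape_fraction: 0.12
spectrum:
  anode_filter: W/Ag
  kvp: 24
  fluence_scale: 1.0e+7
acquisition:
  thresholds_keV: [12.5, 15.5, 20.5]
grid:
  kvp_range: [20, 50]
  threshold_step: 0.5
scenario:
  seed: 1
  loq_target_ppm: 100
  snr_dose_uGy: 20
output:
  dir: "."
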