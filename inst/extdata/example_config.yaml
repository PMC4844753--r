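# Example configuration for the alveolus3d CLI. Every key mirrors a
# function argument; CLI flags (--seed, --set section.key=value) override
# values given here.
seed: 42

scene:                      # scene_spec()
  alveolus_radius: 40       # um
  lumen_radius: 25          # um
  n_cells: 40
  p_binucleated: 0.77       # lactation-like; use ~0 for mid-pregnancy
  nucleus_radius: 4         # um
  membrane_thickness: 1     # um
  psf_sigma: [0.6, 0.2, 0.2] # (z, y, x) um
  read_sd: 0.02
  photons: 100
  spacing: [1.0, 0.5, 0.5]  # (dz, dy, dx) um
  marker_probs:
    EdU: [0.1, 0.6]         # P(positive | mononucleated), P(... | binucleated)
  reporter_colors: 0

segmentation:               # segmentation_params()
  smooth_sigma: [0.4, 0.2, 0.2]
  threshold_method: otsu
  h_maxima: 2.0             # um
  min_seed_separation: 6    # um
  size_min: 200             # um^3
  size_max: 20000           # um^3
  exclude_border: true

nuclei:                     # nucleus_params()
  size_min: 30              # um^3
  size_max: 800             # um^3

ploidy:                     # population_spec()
  n_cells: 100000
  p_G0G1: 0.83
  p_S: 0.0
  p_G2M: 0.05
  p_binucleated: 0.12
  stain_cv: 0.05
  p_loss_binucleated: 0.0
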