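# Example pipeline configuration; unset keys fall back to package defaults.
simulate:
  sigma: 150          # stationary per-axis SD of the inter-locus vector (nm)
  theta: 30           # relaxation time of the mean reversion (s)
  frame_interval: 6   # s between Z-stacks
  n_frames: 100
  noise_sd: 27.9      # per-axis localisation noise per channel (nm)
  channel_offset: [50.0, -20.0, 80.0]
  n_cells: 40
  fraction_paired: 0.5
  n_colocalising: 20
  inheritance_coefficient: 0
strains:
  - strain_id: sep71kb
    a_bp: 60600
    x_p_bp: 10400
    x_q_bp: 10400
qc:
  z_margin: 1000      # nm from each stack boundary
  contrast_min_green: 12
  contrast_min_red: 12
  intensity_min_red: 25
  intensity_min_green: 16
dynamics:
  bin_width_s: 6
  plateau_t_min_s: 150
  n_boot: 5000
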