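# Default pipeline configuration: one synthetic study emulating
# dose-structured fibroblast measurements (control, T50, T100, T200).
# All randomness derives from `seed`.

seed: 1

# --- acquisition geometry (quantitative-phase arm) ---
image_size: 512          # pixels (square field of view)
pixel_size: 0.1          # um/pixel (60x / 1.0 NA system)
wavelength: 0.8          # um, centre wavelength
carrier_frequency: [0.25, 0.0]   # cycles/pixel; magnitude must be in (0.1, 0.4)
fringe_background: 1.0   # fringe offset A
fringe_amplitude: 0.8    # fringe modulation B
noise_model: gaussian    # gaussian | shot
noise_sd: 0.01           # additive noise SD as a fraction of B

# --- densitometry ---
alpha: 0.185             # specific refractive index increment, um^3/pg

# --- synthetic cohorts (QPI arm) ---
phantoms_per_group: 10   # cells per exposure group
mass_means:              # group mean dry mass, pg (strictly decreasing)
  control: 300
  T50: 240
  T100: 190
  T200: 160
mass_sd: 20              # between-cell SD, pg

# --- Raman arm ---
spectra_per_group: 15    # 3 repeats x 5 cells
raman_noise_sd: 0.02     # per-point intensity noise SD
n_components: 3          # PCs retained

# --- viability assay ---
viability_means:         # configured mean corrected absorbance (decreasing)
  control: 0.85
  T50: 0.62
  T100: 0.45
  T200: 0.30
viability_noise_sd: 0.015
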