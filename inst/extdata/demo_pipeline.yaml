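# Bundled demonstration pipeline: simulated atrial myocyte imaged at
# STED-like resolution, plus Ca2+ transients and an optical AP trace.
# All quantities in physical units (nm, um, s, ms).
seed: 1
simulate:
  network:
    cell_length: 15
    cell_width: 8
    target_density: 0.368
    frac_at: 0.62
    frac_ot: 0.23
    frac_tt: 0.15
  imaging:
    pixel_size: 32.46
    psf_fwhm: 60
  transients:
    k_syst: 2.0
    k_caff: 0.68
    noise_sd: 0.075
  ap:
    true_onset_delay: 2.0
    sample_interval: 0.1
    noise_sd: 0.005
params:
  orientation:
    bin_width: 5
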