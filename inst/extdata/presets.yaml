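# Reconstruction protocol presets for the SPECT emulator.
# ASCC system_sigma_mm is calibrated by scripts/calibrate_sigma.R so that the
# mean recovery coefficient over the 36-kidney reference shell cohort
# (volumes 31-243 mL, rim thickness 12-22 mm, 4.42 mm grid) equals 0.85.
# AC models the attenuation-only, heavily post-filtered protocol as the ASCC
# PSF plus 6 mm of Gaussian smoothing in quadrature.
presets:
  ASCC:
    system_sigma_mm: 2.374
    Q_cps_per_MBq: 10
    acq_time_s: 3600
  AC:
    base: ASCC
    extra_sigma_mm: 6
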