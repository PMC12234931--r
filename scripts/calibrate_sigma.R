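#!/usr/bin/env Rscript
# Calibrate the ASCC preset's PSF sigma.
#
# The ASCC protocol's system resolution is a free parameter of the emulator.
# It is fixed once, by bisection, so that the mean recovery coefficient over
# the 36-kidney reference shell cohort (volumes 31-243 mL, rim thickness
# 12-22 mm, 4.42 mm grid) equals 0.85. The result is written into
# inst/extdata/presets.yaml and not revisited.
#
# Usage: Rscript scripts/calibrate_sigma.R  (from the repository root)

suppressMessages(library(svdose))

target <- 0.85
spec <- cohort_spec(seed = 42L, texture_cv = 0, background_fraction = 0)
cohort <- make_cohort(spec)
masks <- lapply(cohort, function(ph) ph$wkp_mask)

mean_rc <- function(sigma) {
  m <- acquisition_model(sigma, Q_cps_per_MBq = 10)
  mean(vapply(masks, function(mk) simulate_rc(mk, m)$rc, numeric(1)))
}

lo <- 1.5; hi <- 5.5
f_lo <- mean_rc(lo) - target
f_hi <- mean_rc(hi) - target
stopifnot(f_lo > 0, f_hi < 0)
for (i in 1:14) {
  mid <- (lo + hi) / 2
  f <- mean_rc(mid) - target
  message(sprintf("iter %2d: sigma = %.4f mm, mean RC = %.4f", i, mid, f + target))
  if (f > 0) lo <- mid else hi <- mid
}
sigma <- round((lo + hi) / 2, 3)
message(sprintf("calibrated ASCC system sigma: %.3f mm (mean RC %.4f)",
                sigma, mean_rc(sigma)))
message(sprintf("AC preset effective sigma %.3f mm, mean RC %.4f",
                sqrt(sigma^2 + 36), mean_rc(sqrt(sigma^2 + 36))))

path <- "inst/extdata/presets.yaml"
cfg <- yaml::read_yaml(path)
cfg$presets$ASCC$system_sigma_mm <- sigma
yaml::write_yaml(cfg, path)
message("wrote ", path)
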