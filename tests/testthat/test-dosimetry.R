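test_that("Q calibration recovers the model sensitivity", {
  cal <- make_calibration_phantom(80, volume = 4000, voi_margin_mm = 15)
  # perfect resolution: exact
  img0 <- acquire(cal$image, acquisition_model(0, Q_cps_per_MBq = 10))
  expect_equal(calibrate_Q(img0, cal$voi, cal$activity_in_voi), 10,
               tolerance = 1e-12)
  # 4 mm PSF with an interior VOI: spill-in ~ spill-out, within 0.5%
  img4 <- acquire(cal$image, acquisition_model(4, Q_cps_per_MBq = 10))
  expect_lt(abs(calibrate_Q(img4, cal$voi, cal$activity_in_voi) / 10 - 1),
            0.005)
  # noisy replicates: mean within 3 SE of the model Q
  mn <- acquisition_model(4, Q_cps_per_MBq = 10, noise = TRUE)
  qs <- sapply(1:30, function(s) {
    calibrate_Q(acquire(cal$image, mn, seed = s), cal$voi, cal$activity_in_voi)
  })
  expect_lt(abs(mean(qs) - 10), 3 * sd(qs) / sqrt(30))
  expect_error(calibrate_Q(img0, cal$voi, 0), "> 0")
})

test_that("the concentration formula matches hand calculation and scaling laws", {
  expect_equal(concentration(1000, 10, 0.85, 100, 1.05), 1000 / 892.5,
               tolerance = 1e-12)
  expect_equal(round(concentration(1000, 10, 0.85, 100, 1.05), 4), 1.1204)
  expect_equal(concentration(7, 1, 1, 1, 1), 7)
  expect_equal(concentration(100, 10, 0.4, 50, 1.05),
               2 * concentration(100, 10, 0.8, 50, 1.05))
  expect_error(concentration(-1, 10, 0.8, 50), "counts")
  expect_error(concentration(10, 10, 1.2, 50), "rc")
  expect_error(concentration(10, 0, 0.8, 50), "Q")
})

test_that("SV concentration is the RC-free formula and is exact in a uniform medium", {
  expect_equal(sv_concentration(50, 10, 4), concentration(50, 10, 1, 4))
  # uniform medium: blur of a constant is constant, so an interior SV reads
  # the true concentration at any sigma
  cal <- make_calibration_phantom(200, volume = 6000, voi_margin_mm = 20)
  img <- acquire(cal$image, acquisition_model(5, Q_cps_per_MBq = 10))
  sv <- sphere_voi(c(0, 0, 0), 4, img)
  c_sv <- sv_concentration(voi_counts(img, sv), 10, voi_volume(sv), rho = 1)
  c_true <- cal$image$values[cal$voi$weights == 1][1]
  expect_lt(abs(c_sv / c_true - 1), 1e-3)
})

test_that("a large SV straddling a thin rim under-reads the rim concentration", {
  ph <- make_kidney_phantom(80, 12, C0 = 1, texture_cv = 0)
  img <- acquire(ph$truth_image, fixture_model())
  svs <- place_svs(img, ph$wkp_mask, 4, k = 1)
  c_sv <- sv_concentration(voi_counts(img, svs$masks[[1]]),
                           fixture_model()$Q_cps_per_MBq, 4)
  expect_lt(c_sv, ph$C0)
})

test_that("mono-exponential fitting is exact on clean data and robust to noise", {
  t <- c(24, 48, 168)
  y <- 1 * exp(-log(2) / 48 * t)
  fit <- fit_monoexp(data.frame(t = t, concentration = y))
  expect_lt(abs(fit$C0 - 1), 1e-10)
  expect_lt(abs(fit$lambda - log(2) / 48), 1e-10)
  fit_ll <- fit_monoexp(data.frame(t = t, concentration = y),
                        refine = "loglinear")
  expect_lt(abs(fit_ll$lambda - log(2) / 48), 1e-12)

  expect_error(fit_monoexp(data.frame(t = 24, concentration = 1)), "two")
  expect_error(
    fit_monoexp(data.frame(t = t, concentration = c(1, 1, 1))), "floor"
  )
  expect_error(
    fit_monoexp(data.frame(t = t, concentration = c(1, -1, 0.5))), "positive"
  )

  # 5% multiplicative noise, 3 points: median relative lambda error < 10%
  lam <- log(2) / 48
  errs <- withr::with_seed(4, {
    sapply(1:200, function(i) {
      yy <- exp(-lam * t) * exp(rnorm(3, 0, 0.05))
      abs(fit_monoexp(data.frame(t = t, concentration = yy))$lambda / lam - 1)
    })
  })
  expect_lt(median(errs), 0.10)
})

test_that("TIAC is C0/lambda and matches long-horizon quadrature", {
  fit <- fit_monoexp(data.frame(t = c(24, 48, 168),
                                concentration = exp(-log(2) / 48 * c(24, 48, 168))))
  expect_equal(tiac(fit), 48 / log(2), tolerance = 1e-9)
  expect_equal(round(tiac(fit), 2), 69.25)
  q <- stats::integrate(function(tt) fit$C0 * exp(-fit$lambda * tt), 0, 1e4,
                        rel.tol = 1e-10)$value
  expect_lt(abs(tiac(fit) / q - 1), 1e-3)
  # doubling C0 doubles TIAC
  fit2 <- fit
  fit2$C0 <- 2 * fit$C0
  expect_equal(tiac(fit2), 2 * tiac(fit))
})

test_that("the LED dose conversion matches an independent unit recomputation", {
  # 1 MBq h/g: 3.6e9 decays/g, 147 keV each, to J/kg
  k <- 3.6e9 * 147e3 * 1.602177e-19 * 1000
  expect_equal(absorbed_dose(1), k, tolerance = 1e-12)
  expect_equal(round(absorbed_dose(1), 5), 0.08479)
  expect_equal(absorbed_dose(0), 0)
  expect_equal(absorbed_dose(4), 2 * absorbed_dose(2))
  expect_error(absorbed_dose(-1), ">= 0")
})

test_that("the WKP chain recovers ground-truth dose and is scale equivariant", {
  ph <- fixture_kidney()
  m <- fixture_model()
  imgs <- fixture_images()
  times <- c(24, 48, 168)
  rc <- simulate_rc(ph$wkp_mask, m)$rc
  d <- estimate_dose(ph, imgs, times, method = "WKP",
                     Q = m$Q_cps_per_MBq, rc = rc)
  truth <- ph$C0 / ph$lambda * dose_constants()$gy_per_mbq_h_g
  expect_lt(abs(d$dose_Gy / truth - 1), 0.02)
  expect_equal(d$dose_rate_Gy_GBq, d$dose_Gy / ph$admin_activity_GBq)

  # scaling every image by alpha scales the dose by alpha
  alpha <- 2.7
  scaled <- lapply(imgs, function(im) { im$values <- im$values * alpha; im })
  d2 <- estimate_dose(ph, scaled, times, method = "WKP",
                      Q = m$Q_cps_per_MBq, rc = rc)
  expect_equal(d2$dose_Gy, alpha * d$dose_Gy, tolerance = 1e-9)

  # SV chain is scale equivariant too
  svs <- place_svs(imgs[[1]], ph$wkp_mask, 2, k = 3)
  ds <- estimate_dose(ph, imgs, times, method = "SV2",
                      Q = m$Q_cps_per_MBq, sv_set = svs, n_svs = 3)
  ds2 <- estimate_dose(ph, scaled, times, method = "SV2",
                       Q = m$Q_cps_per_MBq, sv_set = svs, n_svs = 3)
  expect_equal(ds2$dose_Gy, alpha * ds$dose_Gy, tolerance = 1e-9)
  expect_error(estimate_dose(ph, imgs, times, method = "WKP",
                             Q = m$Q_cps_per_MBq), "rc")
  expect_error(estimate_dose(ph, imgs, times, method = "SV2",
                             Q = m$Q_cps_per_MBq), "sv_set")
})

test_that("WKP dose with the fitted RC curve stays within 5% of truth", {
  m <- fixture_model()
  cohort <- lapply(c(45, 90, 150, 220), function(v) {
    make_kidney_phantom(v, 15, C0 = 0.4, lambda = log(2) / 45,
                        kidney_id = sprintf("v%d", v))
  })
  recs <- purrr::map_dfr(cohort, function(ph) simulate_rc(ph$wkp_mask, m))
  fit <- fit_rc_curve(recs)
  times <- c(24, 48, 168)
  for (ph in cohort) {
    imgs <- lapply(times, function(t) acquire(activity_at(ph, t), m))
    d <- estimate_dose(ph, imgs, times, method = "WKP", Q = m$Q_cps_per_MBq,
                       rc = rc_predict(fit, ph$volume))
    truth <- ph$C0 / ph$lambda * dose_constants()$gy_per_mbq_h_g
    expect_lt(abs(d$dose_Gy / truth - 1), 0.05)
  }
})
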