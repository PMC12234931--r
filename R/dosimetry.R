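#' Absorbed-dose chain: calibration, concentration, kinetics, dose
#'
#' Count rates become activity concentrations through the calibration factor
#' Q and (for the WKP method) a recovery coefficient; per-time concentrations
#' are fitted with a mono-exponential and integrated from zero to infinity to
#' give the time-integrated activity concentration (TIAC); the absorbed dose
#' follows under the local-energy-deposit (LED) assumption for the Lu-177
#' electron emissions.
#'
#' @name dosimetry
NULL

#' Physical constants of the dose chain
#'
#' Mean electron energy per Lu-177 disintegration 147 keV, kidney parenchyma
#' density 1.05 g/mL, and the resulting LED conversion:
#' `1 MBq h/g = 3.6e9 decays/g x 147 keV x 1.602177e-16 J/keV x 1000 g/kg
#' = 0.0847872 Gy`.
#'
#' @return Named list of constants.
#' @export
dose_constants <- function() {
  decays_per_mbq_h <- 3.6e9
  j_per_kev <- 1.602177e-16
  led_kev <- 147
  list(
    decays_per_mbq_h = decays_per_mbq_h,
    led_kev = led_kev,
    j_per_kev = j_per_kev,
    rho_g_per_ml = KIDNEY_DENSITY_G_PER_ML,
    gy_per_mbq_h_g = decays_per_mbq_h * led_kev * j_per_kev * 1000
  )
}

#' Calibrate the sensitivity factor Q
#'
#' Counts in a large VOI centred inside a uniform phantom divided by the
#' known activity within the VOI. Keep the VOI at least 3 PSF sigmas from
#' the phantom wall so spill-in balances spill-out.
#'
#' @param count_image emulated [voxel_image()] in cps/voxel.
#' @param voi measurement [mask_voi()].
#' @param true_activity_in_voi known activity inside the VOI, MBq (> 0).
#' @return Calibration factor Q in cps/MBq.
#' @export
calibrate_Q <- function(count_image, voi, true_activity_in_voi) {
  if (true_activity_in_voi <= 0) {
    stop("`true_activity_in_voi` must be > 0", call. = FALSE)
  }
  voi_counts(count_image, voi) / true_activity_in_voi
}

check_positive <- function(value, name, max = Inf) {
  if (!is.numeric(value) || any(value <= 0)) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  if (any(value > max)) {
    stop(sprintf("`%s` must be <= %g", name, max), call. = FALSE)
  }
  invisible(value)
}

#' Activity concentration from VOI counts (WKP method)
#'
#' `C = counts / (Q x RC x V x rho)` in MBq/g: the VOI count rate corrected
#' by the calibration factor, the volume-specific recovery coefficient, the
#' segmented volume and the tissue density.
#'
#' @param counts VOI count rate, cps.
#' @param Q calibration factor, cps/MBq.
#' @param rc recovery coefficient (0 < rc <= 1.05).
#' @param V VOI volume, mL.
#' @param rho tissue density, g/mL (kidney parenchyma: 1.05).
#' @return Activity concentration, MBq/g.
#' @export
concentration <- function(counts, Q, rc, V, rho = KIDNEY_DENSITY_G_PER_ML) {
  check_positive(counts, "counts")
  check_positive(Q, "Q")
  check_positive(rc, "rc", max = 1.05)
  check_positive(V, "V")
  check_positive(rho, "rho")
  counts / (Q * rc * V * rho)
}

#' Activity concentration in a small VOI
#'
#' The SV method applies the concentration formula without a recovery
#' coefficient (rc = 1) and with the sphere volume in the denominator.
#'
#' @param counts SV count rate, cps.
#' @param Q calibration factor, cps/MBq.
#' @param sv_volume sphere volume, mL.
#' @param rho tissue density, g/mL.
#' @return Activity concentration, MBq/g.
#' @export
sv_concentration <- function(counts, Q, sv_volume,
                             rho = KIDNEY_DENSITY_G_PER_ML) {
  concentration(counts, Q, rc = 1, V = sv_volume, rho = rho)
}

#' Fit a mono-exponential washout curve
#'
#' `C(t) = C0 exp(-lambda t)` fitted to time-activity samples. The log-linear
#' least-squares solution (exact on noiseless mono-exponential data) is used
#' as the start; by default it is refined by nonlinear least squares on the
#' linear scale.
#'
#' @param samples data frame with columns `t` (h) and `concentration`
#'   (MBq/g); at least two distinct times, all concentrations > 0.
#' @param refine `"nonlinear"` (default) refines on the linear scale;
#'   `"loglinear"` returns the log-domain solution.
#' @return A `monoexp_fit` with `C0` (MBq/g) and `lambda` (1/h).
#' @export
fit_monoexp <- function(samples, refine = c("nonlinear", "loglinear")) {
  refine <- match.arg(refine)
  stopifnot(is.data.frame(samples),
            all(c("t", "concentration") %in% names(samples)))
  t <- samples$t
  y <- samples$concentration
  if (length(unique(t)) < 2) {
    stop("need at least two distinct time points", call. = FALSE)
  }
  if (any(y <= 0)) stop("concentrations must be positive", call. = FALSE)
  co <- stats::coef(stats::lm(log(y) ~ t))
  lambda0 <- -co[[2]]
  if (lambda0 <= 1e-6) {
    stop(sprintf(
      "fitted washout rate %.3g 1/h is at or below the 1e-6 floor; samples do not decay",
      lambda0
    ), call. = FALSE)
  }
  C0 <- exp(co[[1]])
  lambda <- lambda0
  if (refine == "nonlinear") {
    df <- data.frame(t = t, y = y)
    fit <- minpack.lm::nlsLM(
      y ~ C0 * exp(-lambda * t), data = df,
      start = list(C0 = C0, lambda = lambda0),
      lower = c(C0 = 0, lambda = 1e-8),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                           ptol = 1e-15)
    )
    est <- stats::coef(fit)
    C0 <- est[["C0"]]
    lambda <- est[["lambda"]]
  }
  structure(
    list(C0 = C0, lambda = lambda, n = length(t), refine = refine,
         data = tibble::as_tibble(samples)),
    class = "monoexp_fit"
  )
}

#' @export
print.monoexp_fit <- function(x, ...) {
  cat(sprintf(
    "<monoexp_fit> C0 = %.4g MBq/g, lambda = %.4g 1/h (T1/2 = %.1f h, n = %d)\n",
    x$C0, x$lambda, log(2) / x$lambda, x$n
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.monoexp_fit <- function(x, ...) {
  tibble::tibble(term = c("C0", "lambda"), estimate = c(x$C0, x$lambda))
}

#' @exportS3Method generics::glance
glance.monoexp_fit <- function(x, ...) {
  tibble::tibble(C0 = x$C0, lambda = x$lambda,
                 half_life_h = log(2) / x$lambda,
                 tiac = tiac(x), n = x$n)
}

#' Time-integrated activity concentration
#'
#' Integral of the fitted mono-exponential from zero to infinity: `C0 / lambda`.
#'
#' @param fit a `monoexp_fit`.
#' @return TIAC in MBq h/g.
#' @export
tiac <- function(fit) {
  stopifnot(inherits(fit, "monoexp_fit"))
  fit$C0 / fit$lambda
}

#' Absorbed dose from TIAC under local energy deposit
#'
#' `D = TIAC x 0.0847872 Gy per (MBq h/g)`; all emitted electron energy is
#' absorbed where it is emitted, photon self- and cross-dose omitted.
#'
#' @param tiac_mbq_h_g TIAC in MBq h/g (>= 0).
#' @return Absorbed dose in Gy.
#' @export
absorbed_dose <- function(tiac_mbq_h_g) {
  if (any(tiac_mbq_h_g < 0)) stop("`tiac_mbq_h_g` must be >= 0", call. = FALSE)
  tiac_mbq_h_g * dose_constants()$gy_per_mbq_h_g
}

#' Estimate the kidney absorbed dose from an emulated image series
#'
#' Runs the full chain for one kidney: per-time VOI counts, concentration
#' (WKP with recovery coefficient, or SV mean over the first `n_svs` spheres
#' without one), mono-exponential fit, TIAC, LED dose, and dose per
#' administered activity.
#'
#' @param phantom the `kidney_phantom` (supplies WKP mask, volume, id and
#'   administered activity).
#' @param images list of [voxel_image()] count-rate images, one per time.
#' @param times acquisition times, h (>= 2 distinct).
#' @param method `"WKP"`, `"SV4"`, `"SV2"` or `"SV06"`.
#' @param Q calibration factor, cps/MBq.
#' @param rc recovery coefficient for the WKP method: either the per-kidney
#'   simulated value (default source) or a prediction from [rc_predict()].
#' @param sv_set an `sv_set` from [place_svs()] (SV methods only).
#' @param n_svs number of spheres averaged (first `n_svs` of the set).
#' @param refine passed to [fit_monoexp()].
#' @return One-row tibble: `kidney_id`, `method`, `n_svs`, `tiac_MBq_h_g`,
#'   `dose_Gy`, `dose_rate_Gy_GBq`.
#' @export
estimate_dose <- function(phantom, images, times,
                          method = c("WKP", "SV4", "SV2", "SV06"),
                          Q, rc = NULL, sv_set = NULL,
                          n_svs = NULL, refine = "nonlinear") {
  method <- match.arg(method)
  stopifnot(inherits(phantom, "kidney_phantom"), length(images) == length(times))
  if (length(times) < 2) stop("need at least two time points", call. = FALSE)

  if (method == "WKP") {
    if (is.null(rc)) stop("WKP method requires an `rc`", call. = FALSE)
    wkp <- wkp_from_mask(phantom$wkp_mask)
    conc <- purrr::map_dbl(images, function(img) {
      concentration(voi_counts(img, wkp$mask), Q, rc, wkp$volume)
    })
    n_used <- NA_integer_
  } else {
    if (is.null(sv_set)) stop("SV methods require an `sv_set`", call. = FALSE)
    n_used <- as.integer(n_svs %||% length(sv_set$masks))
    if (n_used < 1 || n_used > length(sv_set$masks)) {
      stop("`n_svs` must be between 1 and the number of placed SVs",
           call. = FALSE)
    }
    masks <- sv_set$masks[seq_len(n_used)]
    conc <- purrr::map_dbl(images, function(img) {
      mean(purrr::map_dbl(masks, function(m) {
        sv_concentration(voi_counts(img, m), Q, sv_set$sv_volume)
      }))
    })
  }

  fit <- fit_monoexp(data.frame(t = times, concentration = conc),
                     refine = refine)
  ta <- tiac(fit)
  d <- absorbed_dose(ta)
  tibble::tibble(
    kidney_id = phantom$kidney_id, method = method, n_svs = n_used,
    tiac_MBq_h_g = ta, dose_Gy = d,
    dose_rate_Gy_GBq = d / phantom$admin_activity_GBq
  )
}
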