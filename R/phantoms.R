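#' Digital kidney, sphere and calibration phantoms
#'
#' The phantom generators stand in for the patient CT/SPECT data: parenchyma
#' masks with known geometry, uniform (optionally textured) activity with
#' per-kidney mono-exponential washout, and a uniform cylinder with known
#' total activity for sensitivity calibration.
#'
#' @name phantoms
NULL

KIDNEY_DENSITY_G_PER_ML <- 1.05

# continuous volume (mL) of the ellipsoid-minus-cavity shell for outer
# transverse semi-axis a, rim thickness t, polar elongation e
shell_volume_ml <- function(a, t, elongation) {
  outer <- a * a * (elongation * a)
  inner <- pmax(a - t, 0)^2 * pmax(elongation * a - t, 0)
  4 * pi / 3 * (outer - inner) / 1000
}

# largest rim thickness the shell geometry can realise for a target volume
max_feasible_thickness <- function(volume, elongation = 1.8) {
  (volume * 1000 * 3 / (4 * pi * elongation))^(1 / 3)
}

#' Generate a digital kidney parenchyma phantom
#'
#' The parenchyma (cortex + medulla, excluding the renal pelvis) is modelled
#' as an outer ellipsoid minus a concentric interior cavity, giving a shell of
#' uniform rim thickness. The transverse semi-axis is solved so that the
#' continuous shell volume matches `volume`; the mask is then voxelized with
#' partial-voxel weights (3x supersampling at the boundary).
#'
#' Activity is uniform inside the shell at concentration `C0 * rho` (MBq/mL),
#' optionally multiplied by a voxelwise lognormal texture with unit mean, and
#' a flat background of `background_fraction` times the parenchyma
#' concentration fills the rest of the grid (including the pelvis cavity).
#' Washout is mono-exponential with rate `lambda`; `truth_image` holds the
#' reference-time (t = 0) concentration field.
#'
#' @param volume target parenchyma volume in mL (20-300).
#' @param thickness parenchyma rim thickness in mm (8-30).
#' @param spacing isotropic voxel size in mm (must not exceed `thickness`).
#' @param C0 parenchyma activity concentration at t = 0, MBq/g.
#' @param lambda effective washout rate, 1/h.
#' @param seed optional seed for the texture draw.
#' @param texture_cv coefficient of variation of the lognormal uptake texture
#'   (0 = uniform).
#' @param background_fraction background concentration as a fraction of the
#'   parenchyma concentration, in `[0, 0.5]`.
#' @param elongation polar/transverse axis ratio of the outer ellipsoid.
#' @param margin_mm zero-background margin between phantom and grid edge, so
#'   that emulated blur does not clip appreciable counts at the boundary.
#' @param kidney_id identifier carried through result tables.
#' @param admin_activity_GBq administered activity used for Gy/GBq reporting.
#' @return A `kidney_phantom`: list with `truth_image` ([voxel_image()],
#'   MBq/mL at t = 0), `wkp_mask` ([mask_voi()]), geometry and kinetics.
#' @export
make_kidney_phantom <- function(volume, thickness, spacing = 4.42,
                                C0 = 0.5, lambda = log(2) / 50,
                                seed = NULL, texture_cv = 0,
                                background_fraction = 0, elongation = 1.8,
                                margin_mm = 35, kidney_id = "kidney",
                                admin_activity_GBq = 7.4) {
  if (volume < 20 || volume > 300) {
    stop("`volume` must be in [20, 300] mL", call. = FALSE)
  }
  if (thickness < 8 || thickness > 30) {
    stop("`thickness` must be in [8, 30] mm", call. = FALSE)
  }
  if (any(spacing > thickness)) {
    stop("`spacing` must not exceed `thickness`", call. = FALSE)
  }
  if (C0 <= 0 || lambda <= 0) stop("C0 and lambda must be > 0", call. = FALSE)
  if (background_fraction < 0 || background_fraction > 0.5) {
    stop("`background_fraction` must be in [0, 0.5]", call. = FALSE)
  }
  t_max <- max_feasible_thickness(volume, elongation)
  if (thickness >= t_max) {
    stop(sprintf(
      paste0("infeasible geometry: a %.0f mL ellipsoid shell cannot have a ",
             "%.1f mm rim (max feasible thickness %.1f mm); reduce thickness ",
             "or increase volume"),
      volume, thickness, t_max
    ), call. = FALSE)
  }

  f <- function(a) shell_volume_ml(a, thickness, elongation) - volume
  upper <- max(t_max, sqrt(volume * 1000 / (4 * pi * elongation * thickness)))
  upper <- 3 * upper + thickness
  a <- stats::uniroot(f, c(thickness * (1 + 1e-9), upper), tol = 1e-10)$root

  half <- c(a, a, elongation * a)
  g <- centered_grid(half, spacing, margin_mm)
  inside_shell <- function(x, y, z) {
    outer <- (x / half[1])^2 + (y / half[2])^2 + (z / half[3])^2 <= 1
    ci <- pmax(half - thickness, 0)
    if (any(ci == 0)) return(outer)
    inner <- (x / ci[1])^2 + (y / ci[2])^2 + (z / ci[3])^2 <= 1
    outer & !inner
  }
  w <- voxelize_solid(inside_shell, g$dim, g$spacing, g$origin, supersample = 3L)
  mask <- mask_voi(w, g$spacing, g$origin, label = kidney_id)

  conc <- C0 * KIDNEY_DENSITY_G_PER_ML
  tex <- 1
  if (texture_cv > 0) {
    sdlog <- sqrt(log(1 + texture_cv^2))
    draw <- function() {
      array(stats::rlnorm(prod(g$dim), meanlog = -sdlog^2 / 2, sdlog = sdlog),
            dim = g$dim)
    }
    tex <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  }
  vals <- conc * w * tex + background_fraction * conc * (1 - w)
  truth <- voxel_image(vals, g$spacing, g$origin, units = "MBq/mL")

  structure(
    list(
      truth_image = truth, wkp_mask = mask,
      parenchyma_thickness = thickness, volume = voi_volume(mask),
      C0 = C0, lambda = lambda, kidney_id = kidney_id,
      admin_activity_GBq = admin_activity_GBq,
      background_fraction = background_fraction, texture_cv = texture_cv,
      geometry = list(semi_axes = half, elongation = elongation,
                      thickness = thickness)
    ),
    class = "kidney_phantom"
  )
}

#' @export
print.kidney_phantom <- function(x, ...) {
  cat(sprintf(
    "<kidney_phantom> '%s'  %.1f mL, rim %.1f mm, C0 %.3g MBq/g, T1/2 %.1f h\n",
    x$kidney_id, x$volume, x$parenchyma_thickness, x$C0, log(2) / x$lambda
  ))
  invisible(x)
}

#' Generate a uniform sphere phantom
#'
#' A centred sphere with partial-voxel weighting, used for recovery-coefficient
#' comparisons against the kidney-shell geometry.
#'
#' @inheritParams make_kidney_phantom
#' @param volume sphere volume in mL; must exceed 8 voxel volumes.
#' @return A `kidney_phantom` whose mask is the sphere.
#' @export
make_sphere_phantom <- function(volume, spacing = 4.42, C0 = 1,
                                lambda = log(2) / 48, margin_mm = 35,
                                kidney_id = "sphere",
                                admin_activity_GBq = 7.4) {
  spacing <- rep_len(spacing, 3L)
  if (volume <= 8 * prod(spacing) / 1000) {
    stop("sphere volume must exceed 8 voxel volumes", call. = FALSE)
  }
  r <- (3 * volume * 1000 / (4 * pi))^(1 / 3)
  g <- centered_grid(rep(r, 3), spacing, margin_mm)
  inside <- function(x, y, z) x^2 + y^2 + z^2 <= r^2
  w <- voxelize_solid(inside, g$dim, g$spacing, g$origin, supersample = 5L)
  mask <- mask_voi(w, g$spacing, g$origin, label = kidney_id)
  conc <- C0 * KIDNEY_DENSITY_G_PER_ML
  truth <- voxel_image(conc * w, g$spacing, g$origin, units = "MBq/mL")
  structure(
    list(
      truth_image = truth, wkp_mask = mask,
      parenchyma_thickness = 2 * r, volume = voi_volume(mask),
      C0 = C0, lambda = lambda, kidney_id = kidney_id,
      admin_activity_GBq = admin_activity_GBq,
      background_fraction = 0, texture_cv = 0,
      geometry = list(radius = r, diameter = 2 * r)
    ),
    class = "kidney_phantom"
  )
}

#' Generate a uniform cylindrical calibration phantom
#'
#' Emulates filling a Jaszczak-style cylinder with a known activity and
#' measuring counts in a large VOI centred well inside the cylinder, the
#' procedure used to determine the SPECT calibration factor Q.
#'
#' @param activity total activity in the cylinder, MBq (>= 0).
#' @param volume cylinder volume in mL.
#' @param spacing isotropic voxel size, mm.
#' @param voi_margin_mm distance between the measurement VOI and the cylinder
#'   wall; keep at least 3x the emulator PSF sigma so spill-in balances
#'   spill-out inside the VOI.
#' @param margin_mm zero background margin around the cylinder.
#' @return List with `image` (truth [voxel_image()], MBq/mL), `voi`
#'   ([mask_voi()]), `activity_in_voi` (MBq) and `total_activity` (MBq).
#' @export
make_calibration_phantom <- function(activity, volume = 6000, spacing = 4.42,
                                     voi_margin_mm = 15, margin_mm = 35) {
  if (activity < 0) stop("`activity` must be >= 0", call. = FALSE)
  # height = 1.8 * radius, roughly the Jaszczak aspect ratio
  r <- (volume * 1000 / (1.8 * pi))^(1 / 3)
  h <- 1.8 * r
  if (voi_margin_mm >= min(r, h / 2)) {
    stop("`voi_margin_mm` leaves no interior VOI", call. = FALSE)
  }
  g <- centered_grid(c(r, r, h / 2), spacing, margin_mm)
  cyl <- function(rr, hh) {
    function(x, y, z) (x^2 + y^2 <= rr^2) & (abs(z) <= hh / 2)
  }
  w <- voxelize_solid(cyl(r, h), g$dim, g$spacing, g$origin, supersample = 3L)
  wv <- voxelize_solid(cyl(r - voi_margin_mm, h - 2 * voi_margin_mm),
                       g$dim, g$spacing, g$origin, supersample = 3L)
  phantom_volume <- sum(w) * prod(g$spacing) / 1000
  conc <- if (activity > 0) activity / phantom_volume else 0
  img <- voxel_image(conc * w, g$spacing, g$origin, units = "MBq/mL")
  voi <- mask_voi(wv, g$spacing, g$origin, label = "calibration_voi")
  list(
    image = img, voi = voi,
    activity_in_voi = conc * voi_volume(voi),
    total_activity = activity,
    radius = r, height = h, voi_margin_mm = voi_margin_mm
  )
}

#' Cohort specification for the synthetic patient population
#'
#' Defines the study conditions emulated by [make_cohort()]: 18 patients with
#' two kidneys each, parenchyma volumes spanning 31-243 mL, rim thicknesses
#' 12-22 mm, lognormal baseline concentrations and effective half-lives of
#' 30-70 h.
#'
#' @param n_patients number of patients (two kidneys each).
#' @param volume_range parenchyma volume range, mL.
#' @param thickness_range rim thickness range, mm. Draws are clipped to 95% of
#'   the maximum feasible thickness for the drawn volume, so small kidneys get
#'   anatomically consistent thin rims.
#' @param C0_distribution `c(log_mean, log_sd)` of the lognormal baseline
#'   concentration in MBq/g.
#' @param half_life_range effective half-life range, h.
#' @param background_fraction flat background as a fraction of parenchyma
#'   concentration.
#' @param texture_cv voxelwise lognormal uptake texture CV.
#' @param spacing isotropic voxel size, mm.
#' @param admin_activity_GBq administered activity per cycle, GBq.
#' @param seed integer seed making the cohort reproducible.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 18,
                        volume_range = c(31, 243),
                        thickness_range = c(12, 22),
                        C0_distribution = c(log(0.5), 0.4),
                        half_life_range = c(30, 70),
                        background_fraction = 0.05,
                        texture_cv = 0.10,
                        spacing = 4.42,
                        admin_activity_GBq = 7.4,
                        seed = 1L) {
  stopifnot(
    n_patients >= 1,
    all(volume_range > 0), all(thickness_range > 0),
    all(half_life_range > 0),
    background_fraction >= 0, background_fraction <= 0.5,
    texture_cv >= 0
  )
  structure(
    list(
      n_patients = n_patients, volume_range = volume_range,
      thickness_range = thickness_range, C0_distribution = C0_distribution,
      half_life_range = half_life_range,
      background_fraction = background_fraction, texture_cv = texture_cv,
      spacing = spacing, admin_activity_GBq = admin_activity_GBq,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' Generate a synthetic kidney cohort
#'
#' Draws per-kidney volume, rim thickness, baseline concentration and
#' effective half-life from the [cohort_spec()] distributions and builds two
#' kidney phantoms per patient. Deterministic under the spec's seed.
#'
#' @param spec a [cohort_spec()].
#' @return A list of `kidney_phantom` objects (class `kidney_cohort`) with a
#'   `manifest` attribute; see [cohort_manifest()].
#' @export
make_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients * 2L
  draws <- withr::with_seed(spec$seed, {
    tibble::tibble(
      patient = rep(seq_len(spec$n_patients), each = 2L),
      side = rep(c("L", "R"), times = spec$n_patients),
      volume = stats::runif(n, spec$volume_range[1], spec$volume_range[2]),
      thickness_draw = stats::runif(n, spec$thickness_range[1],
                                    spec$thickness_range[2]),
      C0 = stats::rlnorm(n, spec$C0_distribution[1], spec$C0_distribution[2]),
      half_life = stats::runif(n, spec$half_life_range[1],
                               spec$half_life_range[2]),
      texture_seed = sample.int(.Machine$integer.max, n)
    )
  })
  draws$thickness <- pmin(draws$thickness_draw,
                          0.95 * max_feasible_thickness(draws$volume))
  draws$kidney_id <- sprintf("P%02d-%s", draws$patient, draws$side)

  phantoms <- purrr::pmap(
    list(draws$volume, draws$thickness, draws$C0, draws$half_life,
         draws$texture_seed, draws$kidney_id),
    function(v, t, c0, th, ts, id) {
      make_kidney_phantom(
        volume = v, thickness = t, spacing = spec$spacing,
        C0 = c0, lambda = log(2) / th, seed = ts,
        texture_cv = spec$texture_cv,
        background_fraction = spec$background_fraction,
        kidney_id = id, admin_activity_GBq = spec$admin_activity_GBq
      )
    }
  )
  manifest <- tibble::tibble(
    kidney_id = draws$kidney_id, patient = draws$patient, side = draws$side,
    volume_mL = purrr::map_dbl(phantoms, "volume"),
    thickness_mm = draws$thickness,
    C0_MBq_g = draws$C0, lambda_per_h = log(2) / draws$half_life,
    half_life_h = draws$half_life, seed = spec$seed
  )
  structure(phantoms, class = "kidney_cohort", manifest = manifest)
}

#' Cohort manifest table
#'
#' @param cohort a `kidney_cohort` from [make_cohort()].
#' @return Tibble with one row per kidney: id, patient, side, volume, rim
#'   thickness, kinetics, and the generating seed.
#' @export
cohort_manifest <- function(cohort) {
  stopifnot(inherits(cohort, "kidney_cohort"))
  attr(cohort, "manifest")
}

#' @export
print.kidney_cohort <- function(x, ...) {
  m <- attr(x, "manifest")
  cat(sprintf(
    "<kidney_cohort> %d kidneys (%d patients), volumes %.0f-%.0f mL\n",
    length(x), length(unique(m$patient)), min(m$volume_mL), max(m$volume_mL)
  ))
  invisible(x)
}

#' Activity concentration field at time t
#'
#' Scales the phantom's reference-time truth image by `exp(-lambda * t)`;
#' phantom kinetics are mono-exponential by construction, so the dosimetry
#' chain's fit model is exact on synthetic truth.
#'
#' @param phantom a `kidney_phantom`.
#' @param t time after administration, h (>= 0).
#' @return A [voxel_image()] in MBq/mL.
#' @export
activity_at <- function(phantom, t) {
  stopifnot(inherits(phantom, "kidney_phantom"))
  if (t < 0) stop("`t` must be >= 0", call. = FALSE)
  img <- phantom$truth_image
  img$values <- img$values * exp(-phantom$lambda * t)
  img
}
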