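#' Spherical small volumes of interest and VOI count summation
#'
#' The SV method samples the kidney parenchyma with small spheres (nominally
#' 4, 2 or 0.6 mL) instead of segmenting the whole parenchyma. Spheres are
#' voxelized with partial-voxel weights and are deliberately *not* clipped to
#' the parenchyma mask: a sphere wider than the rim sums all counts inside
#' itself, which is the mechanism behind the volume-dependent SV bias.
#'
#' @name vois
NULL

#' Diameter of a sphere of given volume
#'
#' @param volume sphere volume in mL.
#' @return Diameter in mm, `2 * (3V / 4 pi)^(1/3)`.
#' @export
sv_diameter_mm <- function(volume) 2 * (3 * volume * 1000 / (4 * pi))^(1 / 3)

#' Build a spherical VOI on an existing grid
#'
#' Partial-voxel weights from 5x supersampling at the sphere boundary; the
#' weighted volume matches the nominal volume within 0.5%.
#'
#' @param center sphere centre in world coordinates, mm (length 3).
#' @param volume sphere volume, mL.
#' @param grid a [voxel_image()] or [mask_voi()] supplying the voxel grid.
#' @param label VOI label.
#' @return A [mask_voi()] aligned to `grid`.
#' @export
sphere_voi <- function(center, volume, grid, label = "sv") {
  g <- grid_of(grid)
  center <- as.numeric(center)
  lo <- g$origin - g$spacing / 2
  hi <- g$origin + (g$dim - 0.5) * g$spacing
  if (any(center < lo) || any(center > hi)) {
    stop("sphere centre lies outside the grid", call. = FALSE)
  }
  r <- sv_diameter_mm(volume) / 2
  # voxelize only inside the sphere's bounding box, then embed
  i0 <- pmax(floor((center - r - g$origin) / g$spacing) + 1, 1)
  i1 <- pmin(ceiling((center + r - g$origin) / g$spacing) + 1, g$dim)
  sub_dim <- as.integer(i1 - i0 + 1)
  sub_origin <- g$origin + (i0 - 1) * g$spacing
  inside <- function(x, y, z) {
    (x - center[1])^2 + (y - center[2])^2 + (z - center[3])^2 <= r^2
  }
  # adapt the boundary supersampling to the sphere curvature: spheres much
  # smaller than the voxel need a finer subdivision to stay within 0.5%
  ss <- min(41L, max(5L, as.integer(ceiling(30 * max(g$spacing) / r))))
  sub_w <- voxelize_solid(inside, sub_dim, g$spacing, sub_origin,
                          supersample = ss)
  w <- array(0, g$dim)
  w[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]] <- sub_w
  mask_voi(w, g$spacing, g$origin, label = label)
}

#' Sum count rate over a VOI
#'
#' Weighted sum of voxel values over the VOI mask; for a count-rate image in
#' cps/voxel the result is the VOI count rate in cps.
#'
#' @param image a [voxel_image()].
#' @param voi a [mask_voi()] on the same grid.
#' @return Weighted sum (scalar).
#' @export
voi_counts <- function(image, voi) {
  stopifnot(inherits(image, "voxel_image"), inherits(voi, "mask_voi"))
  stop_if_grid_mismatch(image, voi)
  sum(image$values * voi$weights)
}

#' Whole-kidney-parenchyma VOI from a mask
#'
#' The phantom parenchyma mask plays the role of the CT-delineated WKP; its
#' weighted volume enters the concentration formula.
#'
#' @param mask a non-empty [mask_voi()].
#' @return List with `volume` (mL) and the `mask`.
#' @export
wkp_from_mask <- function(mask) {
  stopifnot(inherits(mask, "mask_voi"))
  if (sum(mask$weights) == 0) stop("mask is empty", call. = FALSE)
  list(volume = voi_volume(mask), mask = mask)
}

# Sphere-shaped averaging kernel as offset table (di, dj, dk, weight),
# weights from partial-volume voxelization of the sphere at the grid spacing.
sphere_kernel_offsets <- function(volume, spacing) {
  r <- sv_diameter_mm(volume) / 2
  nr <- as.integer(ceiling(r / spacing))
  d <- 2L * nr + 1L
  inside <- function(x, y, z) x^2 + y^2 + z^2 <= r^2
  w <- voxelize_solid(inside, rep(d, 3L), rep(spacing, 3L),
                      rep(-nr * spacing, 3L), supersample = 3L)
  keep <- which(w > 0)
  idx <- arrayInd(keep, rep(d, 3L)) - nr - 1L
  list(offsets = idx, weights = w[keep])
}

# Mean of `values` over a sphere kernel centred at each candidate voxel.
# Off-grid voxels contribute zero, consistent with the zero background
# outside the grid.
sphere_means_at <- function(values, cand_idx, kern) {
  d <- dim(values)
  acc <- numeric(nrow(cand_idx))
  for (m in seq_along(kern$weights)) {
    ii <- cand_idx[, 1] + kern$offsets[m, 1]
    jj <- cand_idx[, 2] + kern$offsets[m, 2]
    kk <- cand_idx[, 3] + kern$offsets[m, 3]
    ok <- ii >= 1 & ii <= d[1] & jj >= 1 & jj <= d[2] & kk >= 1 & kk <= d[3]
    lin <- ii[ok] + (jj[ok] - 1) * d[1] + (kk[ok] - 1) * d[1] * d[2]
    acc[ok] <- acc[ok] + values[lin] * kern$weights[m]
  }
  acc / sum(kern$weights)
}

#' Deterministic placement of representative small VOIs
#'
#' Algorithmic surrogate for the visual placement rule "representative of the
#' mean activity concentration, avoiding hotspots of high and low activity,
#' toward the pelvis and at a slight distance from the outer cortex":
#'
#' 1. Candidate centres are in-mask voxels in the inner half of the
#'    parenchyma by Euclidean distance to background (the "toward the
#'    pelvis" rule; the pelvis cavity counts as background).
#' 2. Each candidate is scored by the absolute difference between the
#'    sphere-kernel mean of the image at that centre and the median in-mask
#'    concentration (a robust central tendency, insensitive to hotspots).
#' 3. Centres are selected greedily by ascending score, subject to a pairwise
#'    separation of at least `max(sphere diameter, min_sep_mm)`; ties break
#'    by ascending linear voxel index.
#'
#' The greedy order makes the selection a pure function of its inputs and
#' gives the prefix property: the first `k` centres do not change when more
#' are requested.
#'
#' @param image observed [voxel_image()] the SVs are placed on.
#' @param wkp parenchyma [mask_voi()] on the same grid.
#' @param sv_volume sphere volume, mL (4, 2 or 0.6 in the standard method).
#' @param k number of SVs requested (>= 1; up to 5 in the standard method).
#' @param min_sep_mm minimum pairwise centre separation; defaults to the
#'   sphere diameter.
#' @param inner_quantile distance-transform quantile defining the inner
#'   candidate region (0.5 = inner half).
#' @return An `sv_set`: centres (mm), per-SV [sphere_voi()] masks, scores,
#'   and `complete = FALSE` (with a warning) if fewer than `k` feasible
#'   centres exist.
#' @export
place_svs <- function(image, wkp, sv_volume, k = 5L, min_sep_mm = NULL,
                      inner_quantile = 0.5) {
  stopifnot(inherits(image, "voxel_image"), inherits(wkp, "mask_voi"), k >= 1)
  stop_if_grid_mismatch(image, wkp)
  if (diff(range(image$spacing)) > 1e-9) {
    stop("SV placement requires an isotropic grid", call. = FALSE)
  }
  binary <- wkp$weights > 0.5
  if (!any(binary)) stop("WKP mask is empty", call. = FALSE)

  dt <- as.numeric(EBImage::distmap(array(as.numeric(binary), dim(binary)))) *
    image$spacing[1]
  dim(dt) <- dim(binary)
  thr <- stats::quantile(dt[binary], inner_quantile, names = FALSE)
  cand_lin <- which(binary & dt >= thr)
  cand_idx <- arrayInd(cand_lin, dim(binary))

  kern <- sphere_kernel_offsets(sv_volume, image$spacing[1])
  m_sv <- sphere_means_at(image$values, cand_idx, kern)
  med <- stats::median(image$values[binary])
  score <- abs(m_sv - med)

  ord <- order(score, cand_lin)
  sep <- max(sv_diameter_mm(sv_volume), min_sep_mm %||% 0)
  centers <- matrix(numeric(0), ncol = 3)
  chosen <- integer(0)
  for (i in ord) {
    ctr <- image$origin + (cand_idx[i, ] - 1) * image$spacing
    if (nrow(centers) == 0 ||
        min(sqrt(rowSums((centers - matrix(ctr, nrow(centers), 3,
                                           byrow = TRUE))^2))) >= sep) {
      centers <- rbind(centers, ctr)
      chosen <- c(chosen, i)
      if (length(chosen) == k) break
    }
  }
  complete <- length(chosen) == k
  if (!complete) {
    warning(sprintf(
      "only %d of %d requested SVs could be placed with %.1f mm separation",
      length(chosen), k, sep
    ), call. = FALSE)
  }
  masks <- lapply(seq_len(nrow(centers)), function(j) {
    sphere_voi(centers[j, ], sv_volume, image,
               label = sprintf("SV%.1fmL_%d", sv_volume, j))
  })
  structure(
    list(
      centers = unname(centers), sv_volume = sv_volume, masks = masks,
      scores = unname(score[chosen]), complete = complete,
      min_sep_mm = sep
    ),
    class = "sv_set"
  )
}

#' @export
print.sv_set <- function(x, ...) {
  cat(sprintf(
    "<sv_set> %d x %.1f mL spheres (min separation %.1f mm)%s\n",
    length(x$masks), x$sv_volume, x$min_sep_mm,
    if (x$complete) "" else "  [incomplete]"
  ))
  invisible(x)
}
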