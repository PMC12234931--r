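#' 3-D voxel image
#'
#' A minimal container for a 3-D scalar field on a regular grid: the value
#' array, the voxel spacing in mm per axis, a world-coordinate origin in mm,
#' and a declared unit (e.g. `"MBq/mL"` for activity concentration or
#' `"cps/voxel"` for reconstructed count rate).
#'
#' World coordinates are in mm; the centre of voxel `(i, j, k)` (1-based) sits
#' at `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param values numeric 3-D array; all values finite, each dimension >= 8.
#' @param spacing numeric length-3, mm per axis, all > 0. A single number is
#'   recycled (isotropic grid).
#' @param origin numeric length-3, mm offset of the first voxel centre.
#' @param units unit label carried along for bookkeeping.
#' @return An object of class `voxel_image`.
#' @export
voxel_image <- function(values, spacing, origin = c(0, 0, 0),
                        units = "dimensionless") {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be a 3-D array", call. = FALSE)
  }
  if (any(dim(values) < 8L)) {
    stop("grid dimensions must be >= 8 per axis", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("`values` must be finite", call. = FALSE)
  }
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("all spacing must be > 0", call. = FALSE)
  origin <- rep_len(as.numeric(origin), 3L)
  structure(
    list(values = values, spacing = spacing, origin = origin, units = units),
    class = "voxel_image"
  )
}

#' @export
print.voxel_image <- function(x, ...) {
  cat(sprintf(
    "<voxel_image> %s  %s mm spacing  [%s]  range [%.4g, %.4g]\n",
    paste(dim(x$values), collapse = "x"),
    paste(signif(x$spacing, 4), collapse = "x"),
    x$units, min(x$values), max(x$values)
  ))
  invisible(x)
}

#' Voxel volume in mL
#'
#' @param x a `voxel_image` or `mask_voi`.
#' @return Volume of one voxel in mL.
#' @export
voxel_volume <- function(x) prod(x$spacing) / 1000

#' Weighted VOI mask
#'
#' Voxel membership weights in `[0, 1]` on the same grid as a companion
#' [voxel_image()]. Weights are fractional at the VOI boundary (partial-voxel
#' weighting), so `sum(weights) * voxel_volume` estimates the continuous VOI
#' volume.
#'
#' @param weights numeric 3-D array with values in `[0, 1]`.
#' @param spacing,origin grid geometry, as in [voxel_image()].
#' @param label text label for the VOI.
#' @param nominal_volume optional nominal volume in mL; when supplied the
#'   weighted volume must agree within 1%.
#' @return An object of class `mask_voi`.
#' @export
mask_voi <- function(weights, spacing, origin = c(0, 0, 0), label = "voi",
                     nominal_volume = NULL) {
  if (!is.array(weights) || length(dim(weights)) != 3L) {
    stop("`weights` must be a 3-D array", call. = FALSE)
  }
  if (min(weights) < 0 || max(weights) > 1 + 1e-9) {
    stop("mask weights must lie in [0, 1]", call. = FALSE)
  }
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("all spacing must be > 0", call. = FALSE)
  m <- structure(
    list(
      weights = weights, spacing = spacing,
      origin = rep_len(as.numeric(origin), 3L), label = label,
      nominal_volume = nominal_volume
    ),
    class = "mask_voi"
  )
  if (!is.null(nominal_volume)) {
    v <- voi_volume(m)
    if (abs(v - nominal_volume) > 0.01 * nominal_volume) {
      stop(sprintf(
        "weighted volume %.3f mL deviates more than 1%% from nominal %.3f mL",
        v, nominal_volume
      ), call. = FALSE)
    }
  }
  m
}

#' @export
print.mask_voi <- function(x, ...) {
  cat(sprintf(
    "<mask_voi> '%s'  %s  weighted volume %.2f mL\n",
    x$label, paste(dim(x$weights), collapse = "x"), voi_volume(x)
  ))
  invisible(x)
}

#' Weighted volume of a VOI in mL
#'
#' @param voi a `mask_voi`.
#' @return Weighted volume, `sum(weights) * voxel_volume`, in mL.
#' @export
voi_volume <- function(voi) {
  stopifnot(inherits(voi, "mask_voi"))
  sum(voi$weights) * voxel_volume(voi)
}

grid_of <- function(x) {
  vals <- if (inherits(x, "mask_voi")) x$weights else x$values
  list(dim = dim(vals), spacing = x$spacing, origin = x$origin)
}

#' Do two objects share the same voxel grid?
#'
#' Grids match when dimensions are identical and spacing/origin agree to
#' 1e-6 mm. Masks are aligned to images by exact grid identity; no resampling
#' happens anywhere in the pipeline.
#'
#' @param a,b `voxel_image` or `mask_voi` objects.
#' @return `TRUE` or `FALSE`.
#' @export
same_grid <- function(a, b) {
  ga <- grid_of(a)
  gb <- grid_of(b)
  identical(ga$dim, gb$dim) &&
    all(abs(ga$spacing - gb$spacing) < 1e-6) &&
    all(abs(ga$origin - gb$origin) < 1e-6)
}

stop_if_grid_mismatch <- function(a, b) {
  if (!same_grid(a, b)) {
    stop("image and mask are not on the same voxel grid", call. = FALSE)
  }
  invisible(TRUE)
}

# World-coordinate voxel centres along each axis (list of 3 numeric vectors).
axis_coords <- function(g) {
  lapply(1:3, function(d) g$origin[d] + (seq_len(g$dim[d]) - 1) * g$spacing[d])
}
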