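#' NIfTI image and mask IO
#'
#' Voxel images and VOI masks round-trip through NIfTI-1 (`.nii.gz`), with
#' voxel spacing carried in the NIfTI pixdim and the unit label plus world
#' origin in a JSON sidecar next to the image. Masks are validated to `[0, 1]`
#' on read.
#'
#' @name io
NULL

sidecar_path <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

#' @rdname io
#' @param image a [voxel_image()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `write_image()`/`write_mask()` return `path` invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "voxel_image"))
  nii <- RNifti::asNifti(image$values)
  RNifti::pixdim(nii) <- image$spacing
  RNifti::writeNifti(nii, path, datatype = "double")
  jsonlite::write_json(
    list(units = image$units, origin_mm = image$origin),
    sidecar_path(path), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname io
#' @return `read_image()` returns a [voxel_image()]; `read_mask()` a
#'   [mask_voi()].
#' @export
read_image <- function(path) {
  if (!grepl("\\.nii(\\.gz)?$", path)) {
    stop("expected a NIfTI file (.nii or .nii.gz)", call. = FALSE)
  }
  nii <- tryCatch(RNifti::readNifti(path), error = function(e) {
    stop(sprintf("not a readable NIfTI file: %s (%s)", path,
                 conditionMessage(e)), call. = FALSE)
  })
  spacing <- RNifti::pixdim(nii)[1:3]
  if (length(spacing) < 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("NIfTI header carries no usable voxel spacing", call. = FALSE)
  }
  units <- "dimensionless"
  origin <- c(0, 0, 0)
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    units <- meta$units %||% units
    origin <- meta$origin_mm %||% origin
  }
  voxel_image(array(as.numeric(nii), dim = dim(nii)[1:3]), spacing, origin,
              units = units)
}

#' @rdname io
#' @param mask a [mask_voi()].
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "mask_voi"))
  nii <- RNifti::asNifti(mask$weights)
  RNifti::pixdim(nii) <- mask$spacing
  RNifti::writeNifti(nii, path, datatype = "double")
  jsonlite::write_json(
    list(label = mask$label, origin_mm = mask$origin),
    sidecar_path(path), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname io
#' @export
read_mask <- function(path) {
  img <- read_image(path)
  w <- img$values
  if (min(w) < 0 || max(w) > 1 + 1e-9) {
    stop("mask values outside [0, 1]", call. = FALSE)
  }
  label <- "voi"
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    label <- meta$label %||% label
  }
  mask_voi(w, img$spacing, img$origin, label = label)
}

#' Run configuration round-trip and hashing
#'
#' A run configuration is a plain named list (cohort spec parameters,
#' acquisition presets, sweep grids, seed, ...). It serialises losslessly to
#' YAML, and `config_hash()` gives a stable fingerprint recorded with every
#' artifact so a run can be reproduced bit-for-bit.
#'
#' @param config named list.
#' @param path YAML file path.
#' @return `write_run_config()` returns `path`; `read_run_config()` the list;
#'   `config_hash()` a short hash string.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) yaml::read_yaml(path)

#' @rdname write_run_config
#' @export
config_hash <- function(config) rlang::hash(config)
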