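#' Construct a 3D image volume
#'
#' Light container for a scalar 3D grid with anisotropic voxel spacing and a
#' modality tag, the unit every preprocessing step operates on.
#'
#' @param values 3D numeric array of voxel intensities.
#' @param spacing Numeric length-3, voxel spacing in mm (all > 0).
#' @param modality `"t1w"` or `"t2w"`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(values, spacing, modality = c("t1w", "t2w")) {
  modality <- match.arg(modality)
  values <- as_array3d(values)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive finite values (mm)")
  if (any(!is.finite(values))) stop("volume contains non-finite values")
  structure(list(values = values, spacing = spacing, modality = modality),
            class = "image_volume")
}

#' Construct a labelled ROI mask
#'
#' @param labels 3D array of non-negative integer labels on the same lattice
#'   as its companion volume; 0 is background.
#' @param spacing Voxel spacing in mm.
#' @param unit_position Optional `"superior"` or `"inferior"` tag for a
#'   half-vertebra unit mask.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(labels, spacing, unit_position = NULL) {
  labels <- as_array3d(labels)
  if (any(!is.finite(labels)) || any(labels < 0) || any(labels != round(labels)))
    stop("mask labels must be non-negative integers")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three strictly positive values (mm)")
  storage.mode(labels) <- "integer"
  if (!is.null(unit_position))
    unit_position <- match.arg(unit_position, c("superior", "inferior"))
  structure(list(labels = labels, spacing = spacing,
                 unit_position = unit_position),
            class = "roi_mask")
}

# Internal constructors without validation, for hot paths whose inputs are
# correct by construction.
new_image_volume <- function(values, spacing, modality)
  structure(list(values = values, spacing = spacing, modality = modality),
            class = "image_volume")

new_roi_mask <- function(labels, spacing, unit_position = NULL)
  structure(list(labels = labels, spacing = spacing,
                 unit_position = unit_position), class = "roi_mask")

as_array3d <- function(x) {
  if (is.null(dim(x))) dim(x) <- c(length(x), 1L, 1L)
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 3L) stop("expected a 3D array")
  x
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume %s: %s voxels, spacing %s mm>\n", x$modality,
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x")))
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  labs <- setdiff(sort(unique(as.vector(x$labels))), 0L)
  cat(sprintf("<roi_mask: %s voxels, labels {%s}%s>\n",
              paste(dim(x$labels), collapse = "x"),
              paste(labs, collapse = ","),
              if (is.null(x$unit_position)) "" else paste0(", ", x$unit_position)))
  invisible(x)
}

#' Resample a volume to an isotropic grid
#'
#' Trilinear interpolation onto a grid of spacing `target_mm` in every
#' direction. Voxel centres of the input sit at `index * spacing` per axis;
#' the output samples `index * target_mm`, preserving the physical extent to
#' within one voxel. Use [resample_mask()] for label images.
#'
#' @param vol An [image_volume()].
#' @param target_mm Target isotropic spacing in mm (default 1).
#' @return An `image_volume` with spacing `c(t, t, t)`.
#' @export
resample_isotropic <- function(vol, target_mm = 1.0) {
  stopifnot(inherits(vol, "image_volume"))
  if (!is.numeric(target_mm) || length(target_mm) != 1L || target_mm <= 0)
    stop("target_mm must be a single positive number")
  d <- dim(vol$values)
  if (any(d < 2L))
    stop("cannot interpolate a volume with a single plane along an axis (dims ",
         paste(d, collapse = "x"), ")")
  res <- cpp_resample_trilinear(as.numeric(vol$values), as.integer(d),
                                vol$spacing, target_mm)
  new_image_volume(array(res$values, dim = res$dim), rep(target_mm, 3),
                   vol$modality)
}

#' Resample a label mask to an isotropic grid
#'
#' Nearest-neighbour counterpart of [resample_isotropic()], preserving label
#' integrity.
#'
#' @inheritParams resample_isotropic
#' @param mask An [roi_mask()].
#' @return An `roi_mask` on the isotropic lattice.
#' @export
resample_mask <- function(mask, target_mm = 1.0) {
  stopifnot(inherits(mask, "roi_mask"))
  if (target_mm <= 0) stop("target_mm must be positive")
  d <- dim(mask$labels)
  if (any(d < 2L))
    stop("cannot resample a mask with a single plane along an axis")
  res <- cpp_resample_nearest(as.integer(mask$labels), as.integer(d),
                              mask$spacing, target_mm)
  new_roi_mask(array(res$values, dim = res$dim), rep(target_mm, 3),
               mask$unit_position)
}

#' Normalize a volume to its global mean and standard deviation
#'
#' Maps intensities to `scale * (x - mean) / sd`, computed over the whole
#' volume, then truncates values outside `[-3 * scale, +3 * scale]` to the
#' boundary. The default `scale = 100` keeps the subsequent fixed-bin-width
#' discretization (width 3) in the 32-128 occupied-bin range for typical
#' marrow ROIs.
#'
#' @param vol An [image_volume()].
#' @param scale Multiplier applied after the z-transform (default 100).
#' @return A normalized `image_volume`.
#' @export
normalize_volume <- function(vol, scale = 100) {
  stopifnot(inherits(vol, "image_volume"))
  mu <- mean(vol$values)
  sigma <- stats::sd(as.vector(vol$values))
  if (!is.finite(sigma) || sigma == 0) {
    warning("volume has zero intensity variance; normalized to all zeros")
    out <- array(0, dim = dim(vol$values))
  } else {
    out <- scale * (vol$values - mu) / sigma
    out[out > 3 * scale] <- 3 * scale
    out[out < -3 * scale] <- -3 * scale
  }
  new_image_volume(out, vol$spacing, vol$modality)
}

#' Discretize intensities inside an ROI with a fixed bin width
#'
#' Gray level of a voxel with intensity `x` is
#' `floor((x - min_ROI) / w) + 1`; the ROI maximum falls in the top occupied
#' bin. Levels are defined only inside the mask (0 outside).
#'
#' @param vol A (normalized) [image_volume()].
#' @param mask An [roi_mask()]; voxels with `label > 0` (or `== label`) form
#'   the ROI.
#' @param bin_width Fixed bin width `w` (default 3).
#' @param label Optional single label to select from a multi-label mask.
#' @return An object of class `discretized_roi` with fields `levels`
#'   (3D integer array), `n_levels`, `bin_width`, `min_value`, `spacing`.
#' @export
discretize_roi <- function(vol, mask, bin_width = 3, label = NULL) {
  stopifnot(inherits(vol, "image_volume"), inherits(mask, "roi_mask"))
  if (bin_width <= 0) stop("bin_width must be positive")
  if (!identical(dim(vol$values), dim(mask$labels)))
    stop("volume and mask are not on the same lattice")
  sel <- if (is.null(label)) mask$labels > 0L else mask$labels == label
  if (!any(sel))
    stop("empty ROI mask",
         if (!is.null(mask$unit_position)) paste0(" (", mask$unit_position, " unit)") else "")
  vals <- vol$values[sel]
  lev <- array(0L, dim = dim(vol$values))
  lev[sel] <- as.integer(floor((vals - min(vals)) / bin_width) + 1)
  structure(list(levels = lev, n_levels = max(lev), bin_width = bin_width,
                 min_value = min(vals), spacing = vol$spacing),
            class = "discretized_roi")
}

#' Split a vertebral mask into superior and inferior half-units
#'
#' The split plane is perpendicular to the cranio-caudal axis at the label's
#' centroid slice. Increasing index along that axis is taken as superior
#' (cranial); a centroid falling exactly on a slice assigns that slice to the
#' superior half. The two halves partition the vertebra and differ by at most
#' one slice's worth of voxels.
#'
#' @param mask An [roi_mask()] containing the vertebra.
#' @param label Label of the vertebra (defaults to the single positive label).
#' @param axis Index (1-3) of the cranio-caudal axis; the package's canonical
#'   array order puts it on axis 2.
#' @return List with elements `superior` and `inferior`, each an `roi_mask`.
#' @export
split_vertebra <- function(mask, label = NULL, axis = 2L) {
  stopifnot(inherits(mask, "roi_mask"), axis %in% 1:3)
  if (is.null(label)) {
    labs <- setdiff(unique(as.vector(mask$labels)), 0L)
    if (length(labs) != 1L)
      stop("mask has ", length(labs), " labels; pass `label` explicitly")
    label <- labs
  }
  sel <- mask$labels == label
  if (!any(sel)) stop("label ", label, " not present in mask")
  idx <- which(sel, arr.ind = TRUE)
  slices <- idx[, axis]
  if (length(unique(slices)) < 2L)
    stop("vertebra ", label, " spans fewer than 2 slices along axis ", axis)
  centroid <- mean(slices)
  sup <- array(0L, dim = dim(mask$labels))
  inf <- array(0L, dim = dim(mask$labels))
  is_sup <- slices >= centroid
  sup[idx[is_sup, , drop = FALSE]] <- label
  inf[idx[!is_sup, , drop = FALSE]] <- label
  list(superior = new_roi_mask(sup, mask$spacing, "superior"),
       inferior = new_roi_mask(inf, mask$spacing, "inferior"))
}

#' Contract (erode) an ROI mask
#'
#' Morphological erosion of the ROI by `voxels` applications of a 3D
#' structuring element (26-connected 3x3x3 by default), emulating a
#' segmentation drawn one pixel tighter in all directions. Voxels beyond the
#' array border count as background.
#'
#' @param mask An [roi_mask()]; all positive labels are eroded as one ROI and
#'   relabelled with their original values.
#' @param voxels Number of one-voxel contractions (default 1).
#' @param connectivity 26 (full 3x3x3 element) or 6 (faces only).
#' @return The contracted `roi_mask`.
#' @export
contract_mask <- function(mask, voxels = 1L, connectivity = 26L) {
  stopifnot(inherits(mask, "roi_mask"))
  connectivity <- match.arg(as.character(connectivity), c("26", "6"))
  if (!any(mask$labels > 0L)) stop("cannot contract an empty mask")
  bin <- cpp_erode(as.integer(mask$labels > 0L), as.integer(dim(mask$labels)),
                   connectivity == "26", as.integer(voxels))
  out <- array(0L, dim = dim(mask$labels))
  keep <- bin == 1L
  if (!any(keep))
    stop("contraction emptied the mask",
         if (!is.null(mask$unit_position)) paste0(" (", mask$unit_position, " unit)") else "")
  out[keep] <- mask$labels[keep]
  new_roi_mask(out, mask$spacing, mask$unit_position)
}

# Crop a volume/mask pair to the mask bounding box plus a margin; speeds up
# per-unit texture extraction without changing any feature value.
crop_to_mask <- function(vol, mask, margin = 1L) {
  sel <- which(mask$labels > 0L, arr.ind = TRUE)
  if (nrow(sel) == 0L) stop("empty mask")
  d <- dim(mask$labels)
  lo <- pmax(apply(sel, 2, min) - margin, 1L)
  hi <- pmin(apply(sel, 2, max) + margin, d)
  v <- vol$values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  m <- mask$labels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  list(vol = new_image_volume(v, vol$spacing, vol$modality),
       mask = new_roi_mask(m, mask$spacing, mask$unit_position))
}
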