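#' Names of the per-modality feature catalog
#'
#' 18 first-order + 24 GLCM + 16 GLRLM + 16 GLSZM + 14 GLDM + 5 NGTDM = 93
#' features per modality; no shape features and no filtered-image features.
#'
#' @param modality Optional modality suffix (`"t1w"`/`"t2w"`); when given,
#'   the 93 names of that modality are returned as
#'   `family_Feature_modality`. With no argument the full 186-name
#'   catalog (t1w block, then t2w block) is returned.
#' @return Character vector of feature names.
#' @export
feature_catalog <- function(modality = NULL) {
  if (is.null(modality))
    return(c(feature_catalog("t1w"), feature_catalog("t2w")))
  base <- c(
    names(compute_first_order(
      image_volume(array(c(1, 2, 3, 4, 5, 6, 7, 8), c(2, 2, 2)), c(1, 1, 1)),
      roi_mask(array(1L, c(2, 2, 2)), c(1, 1, 1)))) , # catalog via a probe unit
    names(glcm_features_one(diag(2) / 2)),
    names(sz_features(matrix(1, 2, 2), 4, 4, "glrlm", c("Run", "Run"))),
    names(sz_features(matrix(1, 2, 2), 4, 4, "glszm", c("Area", "Zone"))),
    names(gldm_features(texture_matrix("GLDM", matrix(1, 2, 2), 4, 4))),
    c("ngtdm_Coarseness", "ngtdm_Contrast", "ngtdm_Busyness",
      "ngtdm_Complexity", "ngtdm_Strength"))
  paste(base, modality, sep = "_")
}

# All 93 features for one modality on one preprocessed unit.
features_one_modality <- function(vol, mask, bin_width = 3, gldm_alpha = 0,
                                  connectivity = 26L) {
  cr <- crop_to_mask(vol, mask)
  d <- discretize_roi(cr$vol, cr$mask, bin_width = bin_width)
  fo <- compute_first_order(cr$vol, cr$mask, d)
  glcm <- glcm_features(build_glcm(d))
  glrlm <- glrlm_features(build_glrlm(d))
  glszm <- glszm_features(build_glszm(d, connectivity = connectivity))
  gldm <- gldm_features(build_gldm(d, alpha = gldm_alpha,
                                   connectivity = connectivity))
  ngtdm <- ngtdm_features(build_ngtdm(d))
  c(fo, glcm, glrlm, glszm, gldm, ngtdm)
}

#' Compute the full 186-feature vector for one vertebral unit
#'
#' Runs the 93-feature catalog on the T1W and T2W channels of one
#' preprocessed (resampled + normalized) unit and concatenates them with
#' `family_Feature_modality` names.
#'
#' @param t1w,t2w Preprocessed [image_volume()]s on a shared lattice.
#' @param mask The unit's [roi_mask()] on the same lattice.
#' @param bin_width Discretization bin width (default 3).
#' @param gldm_alpha GLDM dependence tolerance (default 0).
#' @param connectivity Zone/neighbour connectivity, 26 or 6.
#' @return Named numeric vector of length 186.
#' @export
compute_feature_vector <- function(t1w, t2w, mask, bin_width = 3,
                                   gldm_alpha = 0, connectivity = 26L) {
  stopifnot(inherits(t1w, "image_volume"), inherits(t2w, "image_volume"))
  if (!identical(dim(t1w$values), dim(t2w$values)) ||
      !identical(dim(t1w$values), dim(mask$labels)))
    stop("t1w, t2w and mask must share one lattice")
  f1 <- features_one_modality(t1w, mask, bin_width, gldm_alpha, connectivity)
  f2 <- features_one_modality(t2w, mask, bin_width, gldm_alpha, connectivity)
  out <- c(stats::setNames(f1, paste(names(f1), "t1w", sep = "_")),
           stats::setNames(f2, paste(names(f2), "t2w", sep = "_")))
  bad <- names(out)[!is.finite(out)]
  if (length(bad))
    stop("undefined feature value(s) on degenerate ROI: ",
         paste(bad, collapse = ", "))
  out
}

#' Voxel-wise local feature map
#'
#' Recomputes one texture feature in a cubic window centred at every ROI
#' voxel, producing a local map that can be overlaid on the anatomy (values
#' are 0 outside the ROI).
#'
#' @param vol A preprocessed [image_volume()].
#' @param mask An [roi_mask()].
#' @param feature_name Catalog name without modality suffix, e.g.
#'   `"gldm_LargeDependenceHighGrayLevelEmphasis"`.
#' @param window_radius Window half-width in voxels.
#' @param bin_width Discretization bin width inside each window.
#' @return An `image_volume` holding the map.
#' @export
render_feature_map <- function(vol, mask, feature_name, window_radius = 3L,
                               bin_width = 3) {
  stopifnot(inherits(vol, "image_volume"), inherits(mask, "roi_mask"))
  d <- dim(vol$values)
  if (window_radius > max(d))
    stop("window (radius ", window_radius, ") larger than the ROI extent")
  if (!feature_name %in% sub("_t1w$", "", feature_catalog("t1w")))
    stop("unknown feature: ", feature_name)
  sel <- which(mask$labels > 0L, arr.ind = TRUE)
  out <- array(0, dim = d)
  for (r in seq_len(nrow(sel))) {
    ctr <- sel[r, ]
    lo <- pmax(ctr - window_radius, 1L)
    hi <- pmin(ctr + window_radius, d)
    wv <- vol$values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    wvol <- image_volume(wv, vol$spacing, vol$modality)
    wmask <- roi_mask(array(1L, dim = dim(wv)), vol$spacing)
    f <- features_one_modality(wvol, wmask, bin_width = bin_width)
    out[ctr[1], ctr[2], ctr[3]] <- f[[feature_name]]
  }
  image_volume(out, vol$spacing, vol$modality)
}
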