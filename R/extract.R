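# Tighten a vertebra-level crop to one half-unit's bounding box (+1 voxel)
# so per-unit texture work runs on the smallest possible arrays.
unit_crop <- function(g, pos) {
  umask <- g$halves[[pos]]
  idx <- which(umask$labels > 0L, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - 1L, 1L)
  hi <- pmin(apply(idx, 2, max) + 1L, dim(umask$labels))
  sx <- lo[1]:hi[1]; sy <- lo[2]:hi[2]; sz <- lo[3]:hi[3]
  list(t1 = new_image_volume(g$t1$values[sx, sy, sz, drop = FALSE],
                             g$t1$spacing, "t1w"),
       t2 = new_image_volume(g$t2$values[sx, sy, sz, drop = FALSE],
                             g$t2$spacing, "t2w"),
       mask = new_roi_mask(umask$labels[sx, sy, sz, drop = FALSE],
                           umask$spacing, pos))
}

#' Extract per-unit feature tables from a cohort
#'
#' Runs the preprocessing chain (isotropic resampling, normalization,
#' per-ROI fixed-bin-width discretization) and the 186-feature catalog for
#' every vertebral unit, under three ROI conditions:
#'
#' * `main` - the 1.0 mm grid with the original unit mask;
#' * `contracted` - the same grid with the mask eroded by one voxel
#'   (segmentation-variability perturbation);
#' * `voxel` - a perturbed isotropic grid (default 1.1 mm) with the
#'   original mask (acquisition/reconstruction perturbation).
#'
#' The latter two exist solely to feed the ICC robustness screens.
#'
#' @param cohort A `cohort_dataset` (from [generate_cohort()] or
#'   [read_cohort()]).
#' @param config A [default_config()] list.
#' @return List with `main`, `contracted`, `voxel` (each a
#'   [feature_table()] with rows aligned to `manifest`) and `manifest`.
#' @export
extract_cohort_features <- function(cohort, config = default_config()) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  m <- cohort$manifest
  tabs <- list(main = NULL, contracted = NULL, voxel = NULL)
  rows <- lapply(tabs, function(x) vector("list", nrow(m)))
  for (p in cohort$patients) {
    pm <- which(m$patient_id == p$id)
    if (!length(pm)) next
    grids <- list()
    for (g in c("main", "voxel")) {
      mm <- if (g == "main") config$target_mm else config$perturbed_mm
      t1 <- normalize_volume(resample_isotropic(p$t1w, mm), config$scale)
      t2 <- normalize_volume(resample_isotropic(p$t2w, mm), config$scale)
      msk <- resample_mask(p$mask, mm)
      grids[[g]] <- list(t1 = t1, t2 = t2, mask = msk)
    }
    for (v in unique(m$vertebra_id[pm])) {
      # crop each grid to the vertebra bounding box before splitting, so
      # all per-unit work happens on small arrays
      cropped <- lapply(grids, function(g) {
        idx <- which(g$mask$labels == v, arr.ind = TRUE)
        lo <- pmax(apply(idx, 2, min) - 1L, 1L)
        hi <- pmin(apply(idx, 2, max) + 1L, dim(g$mask$labels))
        mk <- g$mask$labels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3],
                            drop = FALSE]
        mk[mk != v] <- 0L
        list(t1 = new_image_volume(g$t1$values[lo[1]:hi[1], lo[2]:hi[2],
                                               lo[3]:hi[3], drop = FALSE],
                                   g$t1$spacing, "t1w"),
             t2 = new_image_volume(g$t2$values[lo[1]:hi[1], lo[2]:hi[2],
                                               lo[3]:hi[3], drop = FALSE],
                                   g$t2$spacing, "t2w"),
             halves = split_vertebra(new_roi_mask(mk, g$mask$spacing),
                                     label = v, axis = 2L))
      })
      for (r in pm[m$vertebra_id[pm] == v]) {
        pos <- m$unit_position[r]
        cm <- unit_crop(cropped$main, pos)
        rows$main[[r]] <- compute_feature_vector(
          cm$t1, cm$t2, cm$mask,
          bin_width = config$bin_width, gldm_alpha = config$gldm_alpha,
          connectivity = config$connectivity)
        rows$contracted[[r]] <- compute_feature_vector(
          cm$t1, cm$t2, contract_mask(cm$mask, 1L, config$connectivity),
          bin_width = config$bin_width, gldm_alpha = config$gldm_alpha,
          connectivity = config$connectivity)
        cv <- unit_crop(cropped$voxel, pos)
        rows$voxel[[r]] <- compute_feature_vector(
          cv$t1, cv$t2, cv$mask,
          bin_width = config$bin_width, gldm_alpha = config$gldm_alpha,
          connectivity = config$connectivity)
      }
    }
  }
  lab <- m$fissure_label
  out <- lapply(rows, function(rl) feature_table(do.call(rbind, rl), lab))
  c(out, list(manifest = m))
}
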