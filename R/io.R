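#' Read / write image volumes and masks as NIfTI
#'
#' Volumes carry their voxel spacing (mm) in the NIfTI header. Arrays use
#' the package's canonical axis order (anterior-posterior, cranio-caudal,
#' left-right) with 0-based voxel indexing in the underlying C code; masks
#' are validated to hold non-negative integer labels.
#'
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @param modality `"t1w"` or `"t2w"`.
#' @return [read_volume()] an [image_volume()]; [read_mask()] an
#'   [roi_mask()].
#' @export
read_volume <- function(path, modality = c("t1w", "t2w")) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  # the header stores pixdim as float32; round away its representation error
  sp <- round(RNifti::pixdim(img)[1:3], 6)
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("NIfTI header of ", path, " lacks positive voxel spacing")
  vals <- as.array(img)
  attributes(vals) <- list(dim = dim(vals))
  image_volume(as_array3d(vals), sp, modality)
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  sp <- round(RNifti::pixdim(img)[1:3], 6)
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("NIfTI header of ", path, " lacks positive voxel spacing")
  vals <- as.array(img)
  attributes(vals) <- list(dim = dim(vals))
  vals <- as_array3d(vals)
  if (any(vals != round(vals)) || any(vals < 0))
    stop("mask ", path, " contains non-integer or negative labels")
  roi_mask(vals, sp)
}

#' @rdname read_volume
#' @param vol,mask Objects to write.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  vals <- vol$values
  attr(vals, "pixdim") <- vol$spacing
  RNifti::writeNifti(RNifti::asNifti(vals, datatype = "double"), path)
  invisible(path)
}

#' @rdname read_volume
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "roi_mask"))
  labs <- mask$labels
  attr(labs, "pixdim") <- mask$spacing
  RNifti::writeNifti(RNifti::asNifti(labs, datatype = "int16"), path)
  invisible(path)
}

manifest_columns <- c("patient_id", "vertebra_id", "unit_position", "level",
                      "mc_type", "ddd_grade", "fissure_label")

#' Read a vertebral-unit manifest
#'
#' Requires columns `patient_id`, `vertebra_id`, `unit_position`, `level`,
#' `mc_type`, `ddd_grade`; `fissure_label` is derived from the DDD grade
#' (1 iff grade 2-3) when absent, and validated against it when present.
#' Unknown columns pass through untouched.
#'
#' @param path CSV path.
#' @return Manifest data.frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(m) == 0L) stop("manifest is empty: ", path)
  required <- setdiff(manifest_columns, "fissure_label")
  missing <- setdiff(required, names(m))
  if (length(missing))
    stop("manifest lacks column(s): ", paste(missing, collapse = ", "))
  if (!all(m$unit_position %in% c("superior", "inferior")))
    stop("unit_position must be superior/inferior")
  if (!all(m$mc_type %in% 0:3)) stop("mc_type must be in 0..3")
  if (!all(m$ddd_grade %in% 0:3)) stop("ddd_grade must be in 0..3")
  derived <- as.integer(m$ddd_grade >= 2)
  if (!"fissure_label" %in% names(m)) {
    m$fissure_label <- derived
  } else if (!identical(as.integer(m$fissure_label), derived)) {
    stop("fissure_label inconsistent with ddd_grade (must be 1 iff grade 2-3)")
  }
  m
}

#' Write / read a feature table as CSV
#'
#' The CSV holds one unit per row: the fissure label followed by the named
#' feature columns. A header comment records the column metadata
#' (name, modality, family).
#'
#' @param t A [feature_table()].
#' @param path CSV path.
#' @return `write_feature_table`: the path, invisibly;
#'   `read_feature_table`: a `feature_table`.
#' @export
write_feature_table <- function(t, path) {
  stopifnot(inherits(t, "feature_table"))
  df <- data.frame(fissure_label = t$labels, t$features, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0L) stop("feature table is empty: ", path)
  if (!"fissure_label" %in% names(df)) stop("missing fissure_label column")
  feature_table(as.matrix(df[, setdiff(names(df), "fissure_label"),
                             drop = FALSE]),
                df$fissure_label)
}

#' Default pipeline configuration
#'
#' All tunable parameters of the analysis with their standard values:
#' isotropic grid 1.0 mm with a 1.1 mm perturbation for the voxel-size
#' robustness pass, normalization scale 100, fixed bin width 3,
#' ICC threshold 0.5, correlation threshold 0.9, five features kept per
#' model, 5-fold CV, Wald retention level 0.05.
#'
#' @param ... Named overrides of individual entries.
#' @return A named list (class `run_config`).
#' @export
default_config <- function(...) {
  cfg <- list(target_mm = 1.0, perturbed_mm = 1.1, scale = 100,
              bin_width = 3, gldm_alpha = 0, connectivity = 26L,
              icc_threshold = 0.5, r_threshold = 0.9,
              k_target = 5L, folds = 5L, alpha = 0.05,
              models = c("mlp", "rf", "knn"),
              mlp_maxit = 18L, mlp_decay = 1e-4,
              n_candidates = NULL, mc_invert = FALSE,
              seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  num <- c("target_mm", "perturbed_mm", "scale", "bin_width",
           "icc_threshold", "r_threshold", "k_target", "folds", "alpha")
  for (k in num) if (cfg[[k]] <= 0) stop("config ", k, " must be positive")
  structure(cfg, class = "run_config")
}

#' Read a configuration file (YAML or JSON)
#'
#' Keys mirror [default_config()]; unspecified keys take their defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A `run_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is needed to read YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(default_config, vals)
}
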