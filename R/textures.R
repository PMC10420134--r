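#' Texture matrix container
#'
#' @param family One of `"GLCM"`, `"GLRLM"`, `"GLSZM"`, `"GLDM"`, `"NGTDM"`.
#' @param counts Count matrix (gray level x second axis), a
#'   level x level x direction array (GLCM/GLRLM), or for NGTDM a list with
#'   `n_i` and `s_i`.
#' @param Nz Total count normalizer (zones, runs or voxels).
#' @param Np Number of ROI voxels.
#' @return Object of class `texture_matrix`.
#' @keywords internal
texture_matrix <- function(family, counts, Nz, Np) {
  structure(list(family = family, counts = counts, Nz = Nz, Np = Np),
            class = "texture_matrix")
}

#' @export
print.texture_matrix <- function(x, ...) {
  cat(sprintf("<texture_matrix %s: Nz=%s, Np=%s>\n", x$family, x$Nz, x$Np))
  invisible(x)
}

roi_voxel_count <- function(d) sum(d$levels > 0L)

#' Gray-level size-zone matrix
#'
#' `P(i, j)` counts connected zones of gray level `i` and size `j`, with
#' zones defined by 26-connectivity in 3D (a single-slice array degenerates
#' to 8-connectivity in-plane).
#'
#' @param d A [discretize_roi()] result.
#' @param connectivity 26 or 6.
#' @return A `texture_matrix` with `family = "GLSZM"`, `Nz` = number of
#'   zones, `Np` = ROI voxel count.
#' @export
build_glszm <- function(d, connectivity = 26L) {
  stopifnot(inherits(d, "discretized_roi"))
  connectivity <- match.arg(as.character(connectivity), c("26", "6"))
  P <- cpp_glszm(as.integer(d$levels), as.integer(dim(d$levels)),
                 d$n_levels, connectivity == "26")
  texture_matrix("GLSZM", P, sum(P), roi_voxel_count(d))
}

#' Gray-level dependence matrix
#'
#' For each ROI voxel of level `i`, the dependence `j` is one (the voxel
#' itself) plus the number of 26-neighbours inside the ROI whose level
#' differs by at most `alpha`.
#'
#' @inheritParams build_glszm
#' @param alpha Non-negative level-difference tolerance (default 0).
#' @return A `texture_matrix` with `family = "GLDM"` and `Nz = Np`.
#' @export
build_gldm <- function(d, alpha = 0, connectivity = 26L) {
  stopifnot(inherits(d, "discretized_roi"), alpha >= 0)
  connectivity <- match.arg(as.character(connectivity), c("26", "6"))
  P <- cpp_gldm(as.integer(d$levels), as.integer(dim(d$levels)),
                d$n_levels, alpha, connectivity == "26")
  texture_matrix("GLDM", P, sum(P), roi_voxel_count(d))
}

#' Neighbourhood gray-tone difference matrix
#'
#' Per gray level `i`: `n_i` ROI voxels and
#' `s_i = sum |i - mean(26-neighbour levels)|` over those voxels (voxels
#' without in-ROI neighbours contribute 0 to `s_i`).
#'
#' @inheritParams build_glszm
#' @return A `texture_matrix` with `family = "NGTDM"`; `counts` is a list
#'   with `n_i` and `s_i`.
#' @export
build_ngtdm <- function(d) {
  stopifnot(inherits(d, "discretized_roi"))
  res <- cpp_ngtdm(as.integer(d$levels), as.integer(dim(d$levels)), d$n_levels)
  texture_matrix("NGTDM", res, sum(res$n_i), roi_voxel_count(d))
}

#' Gray-level co-occurrence matrices
#'
#' Symmetric distance-1 co-occurrences along the 13 unique 3D directions;
#' features are computed per direction and averaged.
#'
#' @inheritParams build_glszm
#' @return A `texture_matrix` with a level x level x 13 count array.
#' @export
build_glcm <- function(d) {
  stopifnot(inherits(d, "discretized_roi"))
  P <- cpp_glcm(as.integer(d$levels), as.integer(dim(d$levels)), d$n_levels)
  texture_matrix("GLCM", P, sum(P), roi_voxel_count(d))
}

#' Gray-level run-length matrices
#'
#' Run counts `P(i, j)` (level `i`, run length `j`) along the 13 unique 3D
#' directions; features are computed per direction and averaged.
#'
#' @inheritParams build_glszm
#' @return A `texture_matrix` with a level x max-run x 13 count array.
#' @export
build_glrlm <- function(d) {
  stopifnot(inherits(d, "discretized_roi"))
  P <- cpp_glrlm(as.integer(d$levels), as.integer(dim(d$levels)), d$n_levels)
  texture_matrix("GLRLM", P, sum(P), roi_voxel_count(d))
}

#' Build the GLCM, GLRLM and NGTDM matrices in one call
#'
#' @inheritParams build_glszm
#' @return Named list of `texture_matrix` objects.
#' @export
build_remaining_families <- function(d) {
  list(glcm = build_glcm(d), glrlm = build_glrlm(d), ngtdm = build_ngtdm(d))
}

# ---- feature calculators --------------------------------------------------

#' GLSZM features
#'
#' The 16-feature size-zone catalog, e.g. SmallAreaLowGrayLevelEmphasis
#' `(1/Nz) sum P(i,j) / (i^2 j^2)` and LargeAreaHighGrayLevelEmphasis
#' `(1/Nz) sum P(i,j) i^2 j^2`.
#'
#' @param m A `texture_matrix` from [build_glszm()].
#' @return Named numeric vector of 16 features.
#' @export
glszm_features <- function(m) {
  stopifnot(inherits(m, "texture_matrix"), m$family == "GLSZM")
  if (m$Nz <= 0) stop("GLSZM has no zones (Nz = 0)")
  sz_features(m$counts, m$Nz, m$Np, prefix = "glszm",
              axis_names = c("Area", "Zone"))
}

#' GLDM features
#'
#' The 14-feature gray-level dependence catalog, e.g.
#' LargeDependenceHighGrayLevelEmphasis `(1/Nz) sum P(i,j) i^2 j^2`.
#'
#' @param m A `texture_matrix` from [build_gldm()].
#' @return Named numeric vector of 14 features.
#' @export
gldm_features <- function(m) {
  stopifnot(inherits(m, "texture_matrix"), m$family == "GLDM")
  if (m$Nz <= 0) stop("GLDM is empty (Nz = 0)")
  P <- m$counts
  Nz <- m$Nz
  i <- row(P); j <- col(P)
  p <- P / Nz
  pg <- rowSums(P); pd <- colSums(P)
  mu_i <- sum(p * i); mu_j <- sum(p * j)
  pz <- p[p > 0]
  c(gldm_SmallDependenceEmphasis = sum(P / j^2) / Nz,
    gldm_LargeDependenceEmphasis = sum(P * j^2) / Nz,
    gldm_GrayLevelNonUniformity = sum(pg^2) / Nz,
    gldm_DependenceNonUniformity = sum(pd^2) / Nz,
    gldm_DependenceNonUniformityNormalized = sum(pd^2) / Nz^2,
    gldm_GrayLevelVariance = sum(p * (i - mu_i)^2),
    gldm_DependenceVariance = sum(p * (j - mu_j)^2),
    gldm_DependenceEntropy = -sum(pz * log2(pz)),
    gldm_LowGrayLevelEmphasis = sum(P / i^2) / Nz,
    gldm_HighGrayLevelEmphasis = sum(P * i^2) / Nz,
    gldm_SmallDependenceLowGrayLevelEmphasis = sum(P / (i^2 * j^2)) / Nz,
    gldm_SmallDependenceHighGrayLevelEmphasis = sum(P * i^2 / j^2) / Nz,
    gldm_LargeDependenceLowGrayLevelEmphasis = sum(P * j^2 / i^2) / Nz,
    gldm_LargeDependenceHighGrayLevelEmphasis = sum(P * i^2 * j^2) / Nz)
}

# Shared size-zone / run-length arithmetic on one count matrix, computed on
# the nonzero entries only (GLSZM matrices are wide and sparse).
sz_features <- function(P, Nz, Np, prefix, axis_names) {
  nz <- which(P != 0, arr.ind = TRUE)
  w <- P[nz]
  i <- nz[, 1]; j <- nz[, 2]
  p <- w / Nz
  pg <- rowsum(w, i)                        # per-level totals (present only)
  ps <- rowsum(w, j)                        # per-size totals
  mu_i <- sum(p * i); mu_j <- sum(p * j)
  f <- c(sum(w / j^2) / Nz,                 # Small*Emphasis
         sum(w * j^2) / Nz,                 # Large*Emphasis
         sum(pg^2) / Nz,                    # GrayLevelNonUniformity
         sum(pg^2) / Nz^2,                  # ...Normalized
         sum(ps^2) / Nz,                    # Size/RunNonUniformity
         sum(ps^2) / Nz^2,                  # ...Normalized
         Nz / Np,                           # Zone/RunPercentage
         sum(p * (i - mu_i)^2),             # GrayLevelVariance
         sum(p * (j - mu_j)^2),             # Zone/RunVariance
         -sum(p * log2(p)),                 # Zone/RunEntropy
         sum(w / i^2) / Nz,                 # LowGrayLevel*Emphasis
         sum(w * i^2) / Nz,                 # HighGrayLevel*Emphasis
         sum(w / (i^2 * j^2)) / Nz,         # SmallLow
         sum(w * i^2 / j^2) / Nz,           # SmallHigh
         sum(w * j^2 / i^2) / Nz,           # LargeLow
         sum(w * i^2 * j^2) / Nz)           # LargeHigh
  if (prefix == "glszm") {
    names(f) <- paste0("glszm_", c(
      "SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
      "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
      "SizeZoneNonUniformityNormalized", "ZonePercentage",
      "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
      "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
      "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
      "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis"))
  } else {
    names(f) <- paste0("glrlm_", c(
      "ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
      "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
      "RunLengthNonUniformityNormalized", "RunPercentage",
      "GrayLevelVariance", "RunVariance", "RunEntropy",
      "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
      "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
      "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis"))
  }
  f
}

#' GLRLM features
#'
#' The 16-feature run-length catalog, computed per direction and averaged
#' over the 13 directions.
#'
#' @param m A `texture_matrix` from [build_glrlm()].
#' @return Named numeric vector of 16 features.
#' @export
glrlm_features <- function(m) {
  stopifnot(inherits(m, "texture_matrix"), m$family == "GLRLM")
  A <- m$counts
  f <- cpp_glrlm_features(as.integer(A), dim(A)[1], dim(A)[2], dim(A)[3],
                          as.numeric(m$Np))
  stats::setNames(rowMeans(f), paste0("glrlm_", c(
    "ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
    "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
    "RunLengthNonUniformityNormalized", "RunPercentage",
    "GrayLevelVariance", "RunVariance", "RunEntropy",
    "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
    "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
    "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis")))
}

#' GLCM features
#'
#' The 24-feature co-occurrence catalog (joint, difference, sum and
#' information-theoretic statistics plus MCC), computed on each direction's
#' symmetric normalized matrix and averaged over the 13 directions.
#'
#' @param m A `texture_matrix` from [build_glcm()].
#' @return Named numeric vector of 24 features.
#' @export
glcm_features <- function(m) {
  stopifnot(inherits(m, "texture_matrix"), m$family == "GLCM")
  A <- m$counts
  f <- cpp_glcm_features(as.integer(A), dim(A)[1], dim(A)[3])
  stats::setNames(rowMeans(f), paste0("glcm_", c(
    "Autocorrelation", "JointAverage", "ClusterProminence", "ClusterShade",
    "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
    "DifferenceEntropy", "DifferenceVariance", "Id", "Idm", "Idmn", "Idn",
    "Imc1", "Imc2", "InverseVariance", "JointEnergy", "JointEntropy",
    "MCC", "MaximumProbability", "SumAverage", "SumEntropy", "SumSquares")))
}

glcm_features_one <- function(p, kd_idx = NULL, ks_idx = NULL) {
  ng <- nrow(p)
  lv <- seq_len(ng)
  if (is.null(kd_idx))
    kd_idx <- as.vector(abs(.row(c(ng, ng)) - .col(c(ng, ng)))) + 1L
  if (is.null(ks_idx))
    ks_idx <- as.vector(.row(c(ng, ng)) + .col(c(ng, ng))) - 1L
  px <- rowSums(p); py <- colSums(p)
  mu_x <- sum(px * lv); mu_y <- sum(py * lv)
  sd_x <- sqrt(sum(px * (lv - mu_x)^2))
  sd_y <- sqrt(sum(py * (lv - mu_y)^2))
  # distributions of |i-j| (k = 0..ng-1) and i+j (k = 2..2 ng); every group
  # occurs in an ng x ng grid so rowsum returns them in order
  p_diff <- as.vector(rowsum(as.vector(p), kd_idx))
  p_sum <- as.vector(rowsum(as.vector(p), ks_idx))
  kd <- 0:(ng - 1)
  ks <- 2:(2 * ng)
  diff_avg <- sum(kd * p_diff)
  pz <- p[p > 0]
  HXY <- -sum(pz * log2(pz))
  HX <- -sum(px[px > 0] * log2(px[px > 0]))
  HY <- -sum(py[py > 0] * log2(py[py > 0]))
  # HXY1 and HXY2 both reduce to HX + HY for marginals of the same p, so
  # the information measures are functions of the mutual information
  mi <- max(HX + HY - HXY, 0)
  imc1 <- if (max(HX, HY) > 0) -mi / max(HX, HY) else 0
  imc2 <- sqrt(1 - exp(-2 * mi))
  autoc <- as.numeric(lv %*% p %*% lv)
  corr <- if (sd_x > 0 && sd_y > 0) (autoc - mu_x * mu_y) / (sd_x * sd_y) else 1
  ctr_s <- ks - mu_x - mu_y
  c(glcm_Autocorrelation = autoc,
    glcm_JointAverage = mu_x,
    glcm_ClusterProminence = sum(p_sum * ctr_s^4),
    glcm_ClusterShade = sum(p_sum * ctr_s^3),
    glcm_ClusterTendency = sum(p_sum * ctr_s^2),
    glcm_Contrast = sum(p_diff * kd^2),
    glcm_Correlation = corr,
    glcm_DifferenceAverage = diff_avg,
    glcm_DifferenceEntropy = -sum(p_diff[p_diff > 0] * log2(p_diff[p_diff > 0])),
    glcm_DifferenceVariance = sum((kd - diff_avg)^2 * p_diff),
    glcm_Id = sum(p_diff / (1 + kd)),
    glcm_Idm = sum(p_diff / (1 + kd^2)),
    glcm_Idmn = sum(p_diff / (1 + (kd / ng)^2)),
    glcm_Idn = sum(p_diff / (1 + kd / ng)),
    glcm_Imc1 = imc1,
    glcm_Imc2 = imc2,
    glcm_InverseVariance = sum(p_diff[-1] / kd[-1]^2),
    glcm_JointEnergy = sum(p^2),
    glcm_JointEntropy = HXY,
    glcm_MCC = glcm_mcc(p, px),
    glcm_MaximumProbability = max(p),
    glcm_SumAverage = sum(ks * p_sum),
    glcm_SumEntropy = -sum(p_sum[p_sum > 0] * log2(p_sum[p_sum > 0])),
    glcm_SumSquares = sum(px * (lv - mu_x)^2))
}

# Maximal correlation coefficient: sqrt of the second-largest eigenvalue of
# Q(i,j) = sum_k p(i,k) p(j,k) / (px(i) py(k)).  For a symmetric GLCM
# (px = py) Q is similar to the PSD matrix M = A A' with
# A = D^-1/2 p D^-1/2, whose top eigenvalue is 1 (eigenvector sqrt(px)).
glcm_mcc <- function(p, px) {
  keep <- px > 0
  if (sum(keep) < 2L) return(1)
  p2 <- p[keep, keep, drop = FALSE]
  pxk <- px[keep]
  sq <- sqrt(pxk)
  M <- (p2 %*% (t(p2) / pxk)) / tcrossprod(sq)
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  sqrt(min(max(ev[2], 0), 1))
}

#' NGTDM features
#'
#' Coarseness, Contrast, Busyness, Complexity and Strength from the
#' neighbourhood gray-tone difference vectors. A zero Coarseness denominator
#' (e.g. a constant ROI) is capped at `coarseness_cap`.
#'
#' @param m A `texture_matrix` from [build_ngtdm()].
#' @param coarseness_cap Value returned when `sum(p_i * s_i) == 0`
#'   (default 1e6, matching common radiomics practice).
#' @return Named numeric vector of 5 features.
#' @export
ngtdm_features <- function(m, coarseness_cap = 1e6) {
  stopifnot(inherits(m, "texture_matrix"), m$family == "NGTDM")
  n_i <- m$counts$n_i
  s_i <- m$counts$s_i
  Np <- sum(n_i)
  if (Np <= 0) stop("NGTDM is empty")
  lev <- seq_along(n_i)
  present <- n_i > 0
  p_i <- n_i / Np
  ngp <- sum(present)
  coarse_den <- sum(p_i * s_i)
  coarseness <- if (coarse_den > 0) min(1 / coarse_den, coarseness_cap) else coarseness_cap
  if (ngp > 1) {
    ip <- lev[present]; pp <- p_i[present]; sp <- s_i[present]
    dif2 <- outer(ip, ip, function(a, b) (a - b)^2)
    ppij <- outer(pp, pp, "+")
    contrast <- (sum(outer(pp, pp) * dif2) / (ngp * (ngp - 1))) * (sum(s_i) / Np)
    busy_den <- sum(abs(outer(ip * pp, ip * pp, "-")))
    busyness <- if (busy_den > 0) sum(pp * sp) / busy_den else 0
    psum <- outer(pp * sp, pp * sp, function(a, b) a + b)
    complexity <- sum(abs(outer(ip, ip, "-")) * psum / ppij) / Np
    strength <- if (sum(s_i) > 0) sum(ppij * dif2) / sum(s_i) else 0
  } else {
    contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
  }
  c(ngtdm_Coarseness = coarseness, ngtdm_Contrast = contrast,
    ngtdm_Busyness = busyness, ngtdm_Complexity = complexity,
    ngtdm_Strength = strength)
}

#' First-order intensity statistics
#'
#' The 18-feature first-order catalog. Intensity statistics use the raw
#' (normalized) ROI values; Entropy and Uniformity use the discretized level
#' histogram, following standard radiomics convention.
#'
#' @param vol A (normalized) [image_volume()].
#' @param mask An [roi_mask()].
#' @param d The matching [discretize_roi()] result (recomputed if `NULL`).
#' @param bin_width Bin width used if `d` must be recomputed.
#' @return Named numeric vector of 18 features.
#' @export
compute_first_order <- function(vol, mask, d = NULL, bin_width = 3) {
  stopifnot(inherits(vol, "image_volume"), inherits(mask, "roi_mask"))
  sel <- mask$labels > 0L
  if (!any(sel)) stop("empty ROI mask")
  x <- vol$values[sel]
  if (is.null(d)) d <- discretize_roi(vol, mask, bin_width = bin_width)
  h <- tabulate(d$levels[d$levels > 0L], nbins = d$n_levels)
  ph <- h / sum(h)
  ph <- ph[ph > 0]
  fo <- cpp_first_order(x, prod(vol$spacing))
  c(firstorder_Energy = fo[["Energy"]],
    firstorder_TotalEnergy = fo[["TotalEnergy"]],
    firstorder_Entropy = -sum(ph * log2(ph)),
    firstorder_Minimum = fo[["Minimum"]],
    firstorder_10Percentile = fo[["P10"]],
    firstorder_90Percentile = fo[["P90"]],
    firstorder_Maximum = fo[["Maximum"]],
    firstorder_Mean = fo[["Mean"]],
    firstorder_Median = fo[["Median"]],
    firstorder_InterquartileRange = fo[["IQR"]],
    firstorder_Range = fo[["Range"]],
    firstorder_MeanAbsoluteDeviation = fo[["MAD"]],
    firstorder_RobustMeanAbsoluteDeviation = fo[["rMAD"]],
    firstorder_RootMeanSquared = fo[["RMS"]],
    firstorder_Skewness = fo[["Skewness"]],
    firstorder_Kurtosis = fo[["Kurtosis"]],
    firstorder_Variance = fo[["Variance"]],
    firstorder_Uniformity = sum(ph^2))
}
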