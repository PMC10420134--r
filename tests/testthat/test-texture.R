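# The single-slice 3x3 grid used for the worked examples (in-plane
# 8-connectivity as the 2D degenerate of the 3D 26-neighbourhood):
#   1 1 2
#   1 2 2
#   3 3 3
worked_grid <- function() {
  g <- matrix(c(1, 1, 2,
                1, 2, 2,
                3, 3, 3), nrow = 3, byrow = TRUE)
  as_droi(array(as.integer(g), c(3, 3, 1)))
}

test_that("GLSZM construction and features match hand enumeration", {
  d <- worked_grid()
  m <- build_glszm(d)
  # three zones, each of size 3
  expect_equal(m$Nz, 3)
  expect_equal(m$Np, 9)
  expect_equal(m$counts[, 3], c(1L, 1L, 1L))
  expect_equal(sum(m$counts), 3L)
  f <- glszm_features(m)
  expect_equal(unname(f["glszm_SmallAreaLowGrayLevelEmphasis"]),
               (1 / 3) * (1 / 9 + 1 / 36 + 1 / 81), tolerance = 1e-12)
  expect_equal(unname(f["glszm_LargeAreaHighGrayLevelEmphasis"]), 42)
  expect_equal(unname(f["glszm_ZoneVariance"]), 0)     # all zones size 3
  expect_equal(unname(f["glszm_SizeZoneNonUniformity"]), 9 / 3)
  expect_equal(unname(f["glszm_ZonePercentage"]), 3 / 9)
  # constant ROI: one zone covering everything
  dc <- as_droi(array(1L, c(4, 3, 2)))
  mc <- build_glszm(dc)
  expect_equal(mc$Nz, 1)
  expect_equal(mc$counts[1, 24], 1L)
  # checkerboard under 6-connectivity: every voxel is its own zone
  cb <- array(1L + (as.integer(outer(outer(1:4, 1:4, "+"), 1:2, "+")) %% 2L),
              c(4, 4, 2))
  mcb <- build_glszm(as_droi(cb), connectivity = 6)
  expect_equal(mcb$Nz, 32)
  expect_true(all(which(mcb$counts > 0, arr.ind = TRUE)[, 2] == 1))
})

test_that("GLDM construction and features match per-voxel enumeration", {
  d <- worked_grid()
  m <- build_gldm(d, alpha = 0)
  expect_equal(m$counts[1, 3], 3L)
  expect_equal(m$counts[2, 3], 3L)
  expect_equal(m$counts[3, 2], 2L)
  expect_equal(m$counts[3, 3], 1L)
  expect_equal(m$Nz, 9)
  f <- gldm_features(m)
  expect_equal(unname(f["gldm_LargeDependenceHighGrayLevelEmphasis"]),
               (27 + 108 + 72 + 81) / 9, tolerance = 1e-12)
  # interior voxel of a constant cube attains dependence 27
  dc <- as_droi(array(1L, c(5, 5, 5)))
  mc <- build_gldm(dc)
  expect_equal(unname(mc$counts[1, 27]), 27L)  # the 3x3x3 interior voxels
  # large alpha: every voxel reaches its maximal neighbour count
  dr <- as_droi(random_levels(c(4, 4, 2), 4))
  ma <- build_gldm(dr, alpha = 100)
  m0 <- build_gldm(as_droi((dr$levels > 0) + 0L), alpha = 0)
  expect_equal(colSums(ma$counts), colSums(m0$counts))
  # single-voxel ROI: LDHGLE = i^2
  ds <- as_droi(array(c(0L, 2L, 0L, 0L), c(2, 2, 1)))
  expect_equal(unname(gldm_features(build_gldm(ds))["gldm_LargeDependenceHighGrayLevelEmphasis"]),
               4)
  # relabelling i -> 2i multiplies LDHGLE by 4
  d1 <- as_droi(random_levels(c(4, 4, 2), 3))
  d2 <- as_droi(d1$levels * 2L)
  expect_equal(4 * gldm_features(build_gldm(d1))[["gldm_LargeDependenceHighGrayLevelEmphasis"]],
               gldm_features(build_gldm(d2))[["gldm_LargeDependenceHighGrayLevelEmphasis"]])
})

test_that("texture matrices equal brute-force enumeration on random small ROIs", {
  set.seed(20)
  n_checked <- 0
  for (r in 1:110) {
    dims <- c(sample(3:5, 1), sample(3:5, 1), sample(1:3, 1))
    lev <- random_levels(dims, n_levels = sample(2:4, 1))
    if (!any(lev > 0)) next
    nl <- max(lev)
    d <- as_droi(lev)
    expect_equal(unname(build_glszm(d)$counts),
                 unname(oracle_glszm(lev, nl)))
    expect_equal(unname(build_gldm(d)$counts[, 1:27]),
                 unname(oracle_gldm(lev, nl))[, 1:27])
    # GLRLM / GLCM: directions may be ordered differently; compare the
    # direction sums and the sorted per-direction slices
    gr <- build_glrlm(d)$counts
    or <- oracle_glrlm(lev, nl)
    mx <- max(dim(gr)[2], dim(or)[2])
    pad <- function(a) {
      out <- array(0L, c(nl, mx, 13))
      out[, seq_len(dim(a)[2]), ] <- a
      out
    }
    gr <- pad(gr); or <- pad(or)
    expect_equal(apply(gr, 1:2, sum), apply(or, 1:2, sum))
    key <- function(a) sort(apply(a, 3, paste, collapse = ","))
    expect_equal(key(gr), key(or))
    gc <- build_glcm(d)$counts
    oc <- oracle_glcm(lev, nl)
    expect_equal(apply(gc, 1:2, sum), apply(oc, 1:2, sum))
    expect_equal(key(gc), key(oc))
    ng <- build_ngtdm(d)
    on <- oracle_ngtdm(lev, nl)
    expect_equal(as.vector(ng$counts$n_i), on$n_i)
    expect_equal(as.vector(ng$counts$s_i), on$s_i, tolerance = 1e-10)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 100)
})

test_that("NGTDM features handle the zero-contrast case", {
  dc <- as_droi(array(1L, c(3, 3, 3)))
  f <- ngtdm_features(build_ngtdm(dc))
  expect_equal(unname(f["ngtdm_Coarseness"]), 1e6)   # documented cap
  expect_equal(unname(f["ngtdm_Contrast"]), 0)
  expect_equal(unname(f["ngtdm_Strength"]), 0)
  # GLCM of a constant ROI has a single diagonal entry
  mg <- build_glcm(dc)
  expect_true(all(mg$counts[1, 1, ] > 0))
  expect_equal(sum(mg$counts > 0), 13L)
})

test_that("first-order statistics match their definitions", {
  v <- toy_volume(array(c(1, 2, 3, 4), c(4, 1, 1)))
  m <- full_mask(c(4, 1, 1))
  f <- compute_first_order(v, m)
  expect_equal(unname(f["firstorder_Mean"]), 2.5)
  expect_equal(unname(f["firstorder_Range"]), 3)
  expect_equal(unname(f["firstorder_Energy"]), 1 + 4 + 9 + 16)
  expect_equal(unname(f["firstorder_Skewness"]), 0)  # symmetric values
  fc <- compute_first_order(toy_volume(array(7, c(3, 3, 1))), full_mask(c(3, 3, 1)))
  expect_equal(unname(fc["firstorder_Variance"]), 0)
  expect_equal(unname(fc["firstorder_Entropy"]), 0)
  expect_equal(unname(fc["firstorder_Uniformity"]), 1)
})

test_that("the feature vector is the full 186-name catalog", {
  set.seed(21)
  dims <- c(7, 6, 5)
  t1 <- toy_volume(array(rnorm(prod(dims), 0, 20), dims), modality = "t1w")
  t2 <- toy_volume(array(rnorm(prod(dims), 0, 20), dims), modality = "t2w")
  mask <- roi_mask(array(rbinom(prod(dims), 1, 0.9), dims), c(1, 1, 1))
  fv <- compute_feature_vector(t1, t2, mask)
  expect_length(fv, 186)
  expect_true(all(is.finite(fv)))
  # 93/93 split by modality, and no shape or filtered-image features
  expect_equal(sum(grepl("_t1w$", names(fv))), 93)
  expect_equal(sum(grepl("_t2w$", names(fv))), 93)
  expect_false(any(grepl("shape|wavelet|log\\.", names(fv))))
  expect_equal(sort(names(fv)),
               sort(c(feature_catalog("t1w"), feature_catalog("t2w"))))
  # determinism: identical units give identical vectors
  fv2 <- compute_feature_vector(t1, t2, mask)
  expect_identical(fv, fv2)
})

test_that("direction-averaged features are invariant to 90-degree rotations", {
  set.seed(22)
  dims <- c(6, 6, 6)
  vol <- array(rnorm(prod(dims), 0, 15), dims)
  mask <- array(rbinom(prod(dims), 1, 0.85), dims)
  rot90z <- function(a) aperm(a, c(2, 1, 3))[dim(a)[2]:1, , , drop = FALSE]
  f1 <- features_one_modality(toy_volume(vol), roi_mask(mask, c(1, 1, 1)))
  f2 <- features_one_modality(toy_volume(rot90z(vol)),
                              roi_mask(rot90z(mask), c(1, 1, 1)))
  expect_equal(f1, f2, tolerance = 1e-10)
})

test_that("local feature maps recompute the feature per window", {
  dims <- c(7, 7, 3)
  const <- toy_volume(array(5, dims))
  mask <- full_mask(dims)
  mp <- render_feature_map(const, mask, "firstorder_Mean", window_radius = 1)
  expect_true(all(abs(mp$values[mask$labels > 0] - 5) < 1e-12))
  # window covering the whole ROI reproduces the global value
  set.seed(23)
  small <- c(3, 3, 2)
  v <- toy_volume(array(runif(18, 0, 30), small))
  m <- full_mask(small)
  g <- features_one_modality(v, m)[["gldm_LargeDependenceHighGrayLevelEmphasis"]]
  mp2 <- render_feature_map(v, m, "gldm_LargeDependenceHighGrayLevelEmphasis",
                            window_radius = 3)
  expect_true(all(abs(mp2$values[m$labels > 0] - g) < 1e-12))
  # a window larger than the ROI extent is rejected
  expect_error(render_feature_map(v, m, "firstorder_Mean", window_radius = 10),
               "larger than")
})
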