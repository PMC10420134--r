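test_that("trilinear resampling reproduces affine fields and scales geometry", {
  # linear ramp along each axis is reproduced exactly at interpolated points
  d <- c(8, 6, 5)
  ramp <- array(0, dim = d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3])
    ramp[i, j, k] <- 2 * i + 3 * j - k
  vol <- image_volume(ramp, c(1, 1, 4))
  out <- resample_isotropic(vol, 1.0)
  # physical position of output voxel (i,j,k) is ((i-1), (j-1), (k-1)) mm;
  # the ramp in physical coordinates is 2(x+1) + 3(y+1) - (z/4 + 1)
  do <- dim(out$values)
  expect_equal(do[3], (d[3] - 1) * 4 + 1)   # axial count ~ x4
  for (k in c(1, 5, do[3])) for (j in c(1, do[2])) for (i in c(1, do[1]))
    expect_equal(out$values[i, j, k],
                 2 * i + 3 * j - ((k - 1) / 4 + 1), tolerance = 1e-12)
  # resampling to the native spacing of an isotropic volume is the identity
  iso <- image_volume(array(rnorm(4 * 4 * 4), c(4, 4, 4)), c(1, 1, 1))
  expect_equal(resample_isotropic(iso, 1)$values, iso$values)
  # degenerate single-plane input is rejected
  flat <- image_volume(array(1:16 + 0, c(4, 4, 1)), c(1, 1, 4))
  expect_error(resample_isotropic(flat, 1), "single plane")
})

test_that("mask resampling is nearest-neighbour and preserves labels", {
  m <- roi_mask(array(sample(0:3, 6 * 6 * 4, replace = TRUE), c(6, 6, 4)),
                c(1, 1, 2))
  out <- resample_mask(m, 1)
  expect_true(all(out$labels %in% 0:3))
  expect_equal(out$spacing, c(1, 1, 1))
  expect_equal(dim(out$labels)[3], (4 - 1) * 2 + 1)
})

test_that("normalization is a truncated z-transform", {
  set.seed(1)
  x <- array(rnorm(1000, 50, 10), c(10, 10, 10))
  # plant a value far below the mean: must clip at -3 * scale
  x[1, 1, 1] <- 50 - 10 * 8
  v <- normalize_volume(image_volume(x, c(1, 1, 1)), scale = 100)
  expect_equal(min(v$values), -300)
  expect_lt(abs(mean(v$values)), 5)   # near-zero mean (clipping aside)
  expect_true(all(v$values >= -300 & v$values <= 300))
  # constant volume degenerates with a warning
  expect_warning(z <- normalize_volume(image_volume(array(7, c(3, 3, 3)),
                                                    c(1, 1, 1))),
                 "zero intensity variance")
  expect_true(all(z$values == 0))
})

test_that("normalize-then-discretize is invariant to affine intensity rescaling", {
  set.seed(2)
  x <- array(rnorm(5 * 5 * 5, 100, 25), c(5, 5, 5))
  m <- full_mask(c(5, 5, 5))
  run <- function(arr) {
    v <- normalize_volume(image_volume(arr, c(1, 1, 1)), 100)
    discretize_roi(v, m, bin_width = 3)$levels
  }
  expect_equal(run(x), run(3.7 * x + 55))
})

test_that("fixed-bin-width discretization follows the floor rule", {
  v <- toy_volume(array(c(0, 2.9, 3.0, 6.1), c(4, 1, 1)))
  m <- full_mask(c(4, 1, 1))
  d <- discretize_roi(v, m, bin_width = 3)
  expect_equal(as.vector(d$levels), c(1, 1, 2, 3))
  expect_equal(d$n_levels, 3)
  # constant ROI occupies a single level
  dc <- discretize_roi(toy_volume(array(5, c(2, 2, 2))), full_mask(c(2, 2, 2)))
  expect_equal(unique(as.vector(dc$levels)), 1L)
  expect_equal(dc$n_levels, 1L)
  # halving the bin width roughly doubles the occupied levels
  set.seed(3)
  vv <- toy_volume(array(runif(125, 0, 60), c(5, 5, 5)))
  n3 <- discretize_roi(vv, full_mask(c(5, 5, 5)), 3)$n_levels
  n15 <- discretize_roi(vv, full_mask(c(5, 5, 5)), 1.5)$n_levels
  expect_equal(n15 / n3, 2, tolerance = 0.1)
  # empty mask is an error naming the unit
  em <- roi_mask(array(0L, c(5, 5, 5)), c(1, 1, 1), "superior")
  expect_error(discretize_roi(vv, em), "superior")
})

test_that("vertebra splitting halves the ROI at the centroid slice", {
  # symmetric box: equal halves
  box <- array(0L, c(4, 6, 3)); box[2:3, 2:5, 1:3] <- 1L
  halves <- split_vertebra(roi_mask(box, c(1, 1, 1)), axis = 2)
  expect_equal(sum(halves$superior$labels > 0), sum(halves$inferior$labels > 0))
  # union = original, intersection = empty, on random masks
  set.seed(4)
  for (r in 1:100) {
    m <- array(0L, c(5, 7, 4))
    n_on <- sample(8:60, 1)
    m[sample(prod(dim(m)), n_on)] <- 1L
    idx <- which(m == 1L, arr.ind = TRUE)
    if (length(unique(idx[, 2])) < 2) next
    h <- split_vertebra(roi_mask(m, c(1, 1, 1)), axis = 2)
    s <- h$superior$labels; i <- h$inferior$labels
    expect_true(all((s > 0) + (i > 0) == (m > 0)))  # partition, exhaustively
    # the cut sits exactly at the voxel centroid: every superior slice is
    # at or above it, every inferior slice strictly below
    centroid <- mean(idx[, 2])
    expect_gte(min(which(apply(s > 0, 2, any))), centroid)
    expect_lt(max(which(apply(i > 0, 2, any))), centroid)
  }
  # centroid exactly on a slice: that slice goes to the superior half
  odd <- array(0L, c(2, 5, 2)); odd[, 1:5, ] <- 1L
  h <- split_vertebra(roi_mask(odd, c(1, 1, 1)), axis = 2)
  expect_equal(sort(unique(which(h$superior$labels > 0, arr.ind = TRUE)[, 2])),
               3:5)
  # single-slice vertebra cannot be split
  thin <- array(0L, c(3, 4, 3)); thin[, 2, ] <- 1L
  expect_error(split_vertebra(roi_mask(thin, c(1, 1, 1)), axis = 2),
               "fewer than 2 slices")
})

test_that("mask contraction is a 3D erosion", {
  cube <- array(0L, c(5, 5, 5)); cube[2:4, 2:4, 2:4] <- 1L
  m <- roi_mask(cube, c(1, 1, 1))
  e <- contract_mask(m, 1, 26)
  expect_equal(which(e$labels > 0), 63L)   # the centre voxel (3,3,3)
  # contracted mask is a subset of the original
  set.seed(5)
  for (r in 1:20) {
    mm <- array(0L, c(6, 6, 4))
    mm[2:5, 2:5, 2:3] <- rbinom(32, 1, 0.9)
    if (!any(mm > 0)) next
    ec <- tryCatch(contract_mask(roi_mask(mm, c(1, 1, 1))), error = function(e) NULL)
    if (is.null(ec)) next
    expect_true(all(mm[ec$labels > 0] > 0))
  }
  # two 1-voxel contractions equal one 2-voxel contraction
  big <- array(0L, c(9, 9, 9)); big[2:8, 2:8, 2:8] <- 1L
  bm <- roi_mask(big, c(1, 1, 1))
  twice <- contract_mask(contract_mask(bm, 1), 1)
  once2 <- contract_mask(bm, 2)
  expect_identical(twice$labels, once2$labels)
  # erosion that empties the mask errors
  single <- array(0L, c(3, 3, 3)); single[2, 2, 2] <- 1L
  expect_error(contract_mask(roi_mask(single, c(1, 1, 1))), "emptied")
})
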