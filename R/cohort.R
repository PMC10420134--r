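#' Parameters of a synthetic vertebral cohort
#'
#' Defines the statistical structure of a simulated lumbar-spine cohort:
#' paired T1W/T2W volumes, integer-labelled vertebral masks and a unit-level
#' manifest. Defaults emulate the study conditions the pipeline targets:
#' 61 patients with about three lumbar discs examined each (~177 discs, ~354
#' vertebral half-units), an 80/20 outer-fissure class imbalance, and Modic
#' changes in ~12% of units, arising only adjacent to fissured discs.
#'
#' @param n_patients Number of patients.
#' @param discs_per_patient Integer range (length 2) of examined discs per
#'   patient.
#' @param disc_count_prob Sampling probabilities over that range; the
#'   default puts the mean at 2.9 discs/patient, so 61 patients yield about
#'   177 discs and 354 vertebral units in expectation.
#' @param p_fissure Probability that a disc carries an outer annular fissure
#'   (DDD grade 2-3).
#' @param p_mc_given_fissure,p_mc_given_no_fissure Probability that a
#'   vertebral unit shows a Modic change given its adjacent disc's fissure
#'   status. The default `p_mc_given_no_fissure = 0` reproduces the
#'   100%-specificity regime of the MC marker.
#' @param voxel_spacing Native anisotropic spacing in mm
#'   (anterior-posterior, cranio-caudal, left-right); the default emulates
#'   sagittal acquisition with 4.0 mm slices + 0.4 mm gap.
#' @param vertebra_extent Vertebral body extent in mm along the same axes.
#' @param texture_effect Non-negative scale of the class-conditional texture
#'   difference; 0 makes the two classes' image distributions identical.
#' @param noise_sd Voxel-wise acquisition noise SD (raw intensity units).
#' @param seed Integer seed; all randomness derives from it.
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(n_patients = 61L,
                          discs_per_patient = c(2L, 4L),
                          disc_count_prob = c(0.3, 0.5, 0.2),
                          p_fissure = 0.8,
                          p_mc_given_fissure = 0.145,
                          p_mc_given_no_fissure = 0,
                          voxel_spacing = c(0.6, 0.6, 4.4),
                          vertebra_extent = c(30, 25, 26),
                          texture_effect = 1,
                          noise_sd = 2.5,
                          seed = 1L) {
  probs <- c(p_fissure, p_mc_given_fissure, p_mc_given_no_fissure)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (n_patients < 1) stop("n_patients must be at least 1")
  if (length(discs_per_patient) != 2L || any(discs_per_patient < 1) ||
      discs_per_patient[1] > discs_per_patient[2] || discs_per_patient[2] > 4)
    stop("discs_per_patient must be an increasing range within 1..4")
  n_counts <- discs_per_patient[2] - discs_per_patient[1] + 1L
  if (length(disc_count_prob) != n_counts || any(disc_count_prob < 0) ||
      sum(disc_count_prob) <= 0)
    stop("disc_count_prob must be ", n_counts,
         " non-negative weights over the disc-count range")
  if (any(voxel_spacing <= 0) || length(voxel_spacing) != 3L)
    stop("voxel_spacing must be three positive values (mm)")
  if (any(vertebra_extent <= 0) || length(vertebra_extent) != 3L)
    stop("vertebra_extent must be three positive values (mm)")
  if (texture_effect < 0) stop("texture_effect must be non-negative")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(n_patients = as.integer(n_patients),
                 discs_per_patient = as.integer(discs_per_patient),
                 disc_count_prob = disc_count_prob / sum(disc_count_prob),
                 p_fissure = p_fissure,
                 p_mc_given_fissure = p_mc_given_fissure,
                 p_mc_given_no_fissure = p_mc_given_no_fissure,
                 voxel_spacing = as.numeric(voxel_spacing),
                 vertebra_extent = as.numeric(vertebra_extent),
                 texture_effect = texture_effect,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_params")
}

# Separable Gaussian blur; kernel truncated at 3 sigma, edges padded by
# replication so the field keeps its variance near borders.
gauss_kernel <- function(sigma_vox) {
  if (sigma_vox < 0.3) return(1)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- stats::dnorm(seq(-r, r), sd = sigma_vox)
  k / sum(k)
}

blur1d <- function(m, kern) {
  if (length(kern) == 1L) return(m)
  n <- nrow(m)
  pad <- length(kern) %/% 2L
  mp <- rbind(m[rep(1L, pad), , drop = FALSE], m,
              m[rep(n, pad), , drop = FALSE])
  out <- matrix(0, n, ncol(m))
  for (k in seq_along(kern))
    out <- out + kern[k] * mp[k:(k + n - 1L), , drop = FALSE]
  out
}

blur3d <- function(arr, sigma_mm, spacing) {
  d <- dim(arr)
  for (ax in 1:3) {
    kern <- gauss_kernel(sigma_mm / spacing[ax])
    if (length(kern) == 1L) next
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    da <- dim(a)
    a <- blur1d(matrix(a, nrow = da[1]), kern)
    dim(a) <- da
    arr <- aperm(a, order(perm))
  }
  arr
}

# Smoothed unit-variance Gaussian random field on the native grid.
smooth_field <- function(d, sigma_mm, spacing) {
  f <- blur3d(array(stats::rnorm(prod(d)), dim = d), sigma_mm, spacing)
  s <- stats::sd(as.vector(f))
  if (s > 0) f / s else f
}

#' Generate a synthetic cohort of paired vertebral volumes
#'
#' Forward model: vertebral bodies are boxes of bright marrow on a dark
#' background, modulated by smoothed Gaussian random fields. The class
#' signal is the *coherence* of the T1W fat-island structure: every
#' half-vertebra unit receives heterogeneity of the same amplitude,
#' terraced into discrete plateaus of the same level quantum and rescaled
#' to the same spread, so the two classes' intensity histograms and broad
#' co-occurrence second moments are matched. What differs is the
#' coherence length of that structure -- away from fissures the plateaus
#' are large coherent fat islands, adjacent to a fissured disc the same
#' structure is finely fragmented -- so the class signal lives in the
#' equal-level neighbourhood counts and connected-patch sizes that the
#' GLDM dependence and GLSZM zone families read. `texture_effect` scales
#' the coherence difference; at 0 the classes' image distributions are
#' identical. On top of this, every unit (both classes alike) draws the
#' same exponential load of focal nuisance lesions -- a half-and-half mix
#' of small foci and large blobs -- which adds realistic within-class
#' texture variability without carrying class information. Fat islands
#' and foci are fat-contrast effects: visible on T1W, inconspicuous on
#' fluid-weighted T2W, so the planted signal is T1W-specific, as in
#' marrow imaging read for texture. The T2W channel is a monotone
#' (decreasing) transform of the shared latent background plus its own
#' smooth component and noise. Modic changes are drawn from the
#' class-conditional probabilities and painted as diffuse latent shifts
#' over the endplate-adjacent third of the unit (types 1 and 3 darken,
#' type 2 brightens the T1W channel).
#'
#' Axis convention: axis 1 anterior-posterior, axis 2 cranio-caudal
#' (increasing index = superior), axis 3 left-right (native slice
#' direction).
#'
#' @param params A [cohort_params()] object.
#' @return An object of class `cohort_dataset`: list with `patients` (each
#'   holding `id`, `t1w`, `t2w`, `mask`), `manifest` (one row per vertebral
#'   unit) and `params`. Each disc contributes exactly two units: the
#'   inferior half of the vertebra above it and the superior half of the
#'   vertebra below it.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(params$seed)
  sp <- params$voxel_spacing
  vdim <- pmax(round(params$vertebra_extent / sp), c(4L, 4L, 2L))
  gap_y <- max(2L, round(10 / sp[2]))          # ~10 mm disc space
  margin <- c(5L, 8L, 1L)
  disc_levels <- c("L1-L2", "L2-L3", "L3-L4", "L4-L5", "L5-S1")

  background <- 40; marrow <- 160
  base_amp <- 12
  het_amp <- 12                # amplitude of the T1W fat-island structure
  coher_hi <- 3.0              # coherence length (mm) away from fissures
  coher_lo <- 1.2              # coherence length (mm) next to a fissure
  terrace_step <- 1.0          # plateau quantum, in units of the field SD
  lesion_frac <- 0.12          # expected lesioned-voxel fraction at burden 1
  small_mean_vox <- 9          # mean voxels of a small focus (r 1-2, 1 slice)
  large_mean_vox <- 70         # mean voxels of a large blob (r 4-6, clipped)
  mc_types <- 1:3; mc_type_prob <- c(0.5, 0.35, 0.15)

  patients <- vector("list", params$n_patients)
  manifest <- list()
  for (p in seq_len(params$n_patients)) {
    pid <- sprintf("P%03d", p)
    n_discs <- sample(seq(params$discs_per_patient[1],
                          params$discs_per_patient[2]), 1L,
                      prob = params$disc_count_prob)
    n_vert <- n_discs + 1L
    start_lv <- sample.int(length(disc_levels) - n_discs + 1L, 1L)
    d <- c(vdim[1] + 2L * margin[1],
           n_vert * vdim[2] + (n_vert - 1L) * gap_y + 2L * margin[2],
           vdim[3] + 2L * margin[3])
    latent <- array(background, dim = d)
    t1_delta <- array(0, dim = d)   # T1W-specific focus responses
    mask <- array(0L, dim = d)
    base_field <- smooth_field(d, 2.0, sp)
    white_field <- array(stats::rnorm(prod(d)), dim = d)
    t2_field <- smooth_field(d, 2.0, sp)
    patient_jitter <- stats::rnorm(1, 0, 8)

    # vertebra v = 1 is the most cranial (highest axis-2 index)
    xr <- (margin[1] + 1L):(margin[1] + vdim[1])
    zr <- (margin[3] + 1L):(margin[3] + vdim[3])
    y_hi <- function(v) d[2] - margin[2] - (v - 1L) * (vdim[2] + gap_y)
    y_lo <- function(v) y_hi(v) - vdim[2] + 1L

    ddd <- ifelse(stats::runif(n_discs) < params$p_fissure,
                  sample(2:3, n_discs, replace = TRUE),
                  sample(0:1, n_discs, replace = TRUE))
    fiss <- as.integer(ddd >= 2)

    # in-plane disk offsets for the 1-6 voxel lesion radii
    disk_off <- lapply(1:6, function(r) {
      g <- expand.grid(dx = -r:r, dy = -r:r)
      g[g$dx^2 + g$dy^2 <= r^2, ]
    })

    paint_half <- function(yrange, fissured) {
      # Class signal: the *coherence* of the T1W fat-island structure.
      # Both classes get heterogeneity of the same amplitude, terraced
      # into discrete plateaus of the same level quantum and rescaled to
      # the same spread -- so histogram moments and broad co-occurrence
      # second moments are matched. What differs is the coherence
      # length: away from fissures the plateaus are large coherent fat
      # islands, next to a fissured disc the same structure is finely
      # fragmented. That difference lives in equal-level neighbourhood
      # counts and connected-patch sizes -- the GLDM dependence and
      # GLSZM zone statistics.
      coher <- max(0.5, coher_hi -
        (coher_hi - coher_lo) * params$texture_effect * fissured)
      h <- blur3d(white_field[xr, yrange, zr, drop = FALSE], coher, sp)
      s <- stats::sd(h); if (s > 0) h <- h / s
      hq <- terrace_step * (floor(h / terrace_step) + 0.5)
      hq <- hq - mean(hq)
      s <- stats::sd(hq); if (s > 0) hq <- hq / s
      val <- marrow + patient_jitter + stats::rnorm(1, 0, 5) +
        base_amp * base_field[xr, yrange, zr]
      db <- dim(val)
      # fat-island structure and focal lesions are fat-contrast effects:
      # dark/bright on T1W, inconspicuous on fluid-weighted T2W
      d1 <- het_amp * hq
      # Nuisance lesions, identically distributed in both classes: an
      # exponential lesion load spent on a half-and-half mix of small
      # foci and large blobs. They create realistic within-class texture
      # variability without carrying class information.
      burden <- stats::rexp(1, rate = 1)
      budget <- lesion_frac * burden * prod(db)
      mix_vox <- 0.5 * small_mean_vox + 0.5 * large_mean_vox
      n_les <- 1L + stats::rpois(1, budget / mix_vox)
      small <- stats::runif(n_les) < 0.5
      radii <- ifelse(small, sample(1:2, n_les, replace = TRUE),
                      sample(4:6, n_les, replace = TRUE))
      ctr <- cbind(sample.int(db[1], n_les, replace = TRUE),
                   sample.int(db[2], n_les, replace = TRUE),
                   sample.int(db[3], n_les, replace = TRUE))
      decs <- stats::runif(n_les, 30, 60)
      for (f in seq_len(n_les)) {
        off <- disk_off[[radii[f]]]
        xs <- ctr[f, 1] + off$dx
        ys <- ctr[f, 2] + off$dy
        ok <- xs >= 1L & xs <= db[1] & ys >= 1L & ys <= db[2]
        # thick-slice acquisition: lesions live on their native slice
        lin <- xs[ok] + db[1] * (ys[ok] - 1L + db[2] * (ctr[f, 3] - 1L))
        # fat-replacement foci: dark on T1W, inconspicuous on
        # fluid-weighted T2W
        d1[lin] <- d1[lin] - decs[f]
      }
      latent[xr, yrange, zr] <<- val
      t1_delta[xr, yrange, zr] <<- d1
    }

    units <- list()
    for (v in seq_len(n_vert)) {
      ylo <- y_lo(v); yhi <- y_hi(v)
      mask[xr, ylo:yhi, zr] <- v
      ymid <- floor((ylo + yhi) / 2L)           # lower slice of the cut
      sup_range <- (ymid + 1L):yhi
      inf_range <- ylo:ymid
      # superior half is adjacent to disc v-1 (above), inferior to disc v
      sup_fiss <- if (v >= 2L) fiss[v - 1L] else 0L
      inf_fiss <- if (v <= n_discs) fiss[v] else 0L
      paint_half(sup_range, sup_fiss)
      paint_half(inf_range, inf_fiss)
      if (v >= 2L)
        units[[length(units) + 1L]] <- list(v = v, pos = "superior",
                                            disc = v - 1L, yr = sup_range)
      if (v <= n_discs)
        units[[length(units) + 1L]] <- list(v = v, pos = "inferior",
                                            disc = v, yr = inf_range)
    }

    # Modic changes per unit, conditional on the adjacent disc
    rows <- list()
    for (u in units) {
      p_mc <- if (fiss[u$disc] == 1L) params$p_mc_given_fissure
              else params$p_mc_given_no_fissure
      mc <- if (stats::runif(1) < p_mc)
        sample(mc_types, 1L, prob = mc_type_prob) else 0L
      if (mc > 0L) {
        # diffuse shift over the third of the unit nearest the disc
        n_y <- length(u$yr)
        endplate <- if (u$pos == "inferior") u$yr[seq_len(max(1L, n_y %/% 3L))]
                    else u$yr[(n_y - max(1L, n_y %/% 3L) + 1L):n_y]
        shift <- switch(mc, `1` = -35, `2` = +35, `3` = -35)
        latent[xr, endplate, zr] <- latent[xr, endplate, zr] + shift
      }
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pid, vertebra_id = u$v, unit_position = u$pos,
        level = disc_levels[start_lv + u$disc - 1L],
        mc_type = mc, ddd_grade = ddd[u$disc],
        fissure_label = fiss[u$disc], stringsAsFactors = FALSE)
    }

    t1 <- latent + t1_delta + stats::rnorm(prod(d), 0, params$noise_sd)
    # T2W: monotone decreasing transform of the shared latent background
    # plus its own smooth field and noise; the fat-replacement foci are
    # T1W-specific and do not register here
    t2 <- 230 - 0.6 * (latent - background) + 10 * t2_field +
      stats::rnorm(prod(d), 0, params$noise_sd)
    patients[[p]] <- list(id = pid,
                          t1w = image_volume(array(t1, d), sp, "t1w"),
                          t2w = image_volume(array(t2, d), sp, "t2w"),
                          mask = roi_mask(mask, sp))
    manifest[[p]] <- do.call(rbind, rows)
  }
  manifest <- do.call(rbind, manifest)
  rownames(manifest) <- NULL
  structure(list(patients = patients, manifest = manifest, params = params),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<cohort_dataset: %d patients, %d discs, %d vertebral units (%.0f%% fissure-positive)>\n",
              length(x$patients),
              nrow(unique(m[, c("patient_id", "level")])), nrow(m),
              100 * mean(m$fissure_label)))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Volumes and masks are written as NIfTI (`.nii.gz`) with voxel spacing in
#' the header; the manifest as a CSV with columns `patient_id`,
#' `vertebra_id`, `unit_position`, `level`, `mc_type`, `ddd_grade`,
#' `fissure_label` (`fissure_label = 1` iff `ddd_grade` is 2 or 3).
#'
#' @param dataset A [generate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest CSV path.
#' @export
write_cohort <- function(dataset, dir) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory: ", dir)
  for (p in dataset$patients) {
    write_volume(p$t1w, file.path(dir, paste0("t1w_", p$id, ".nii.gz")))
    write_volume(p$t2w, file.path(dir, paste0("t2w_", p$id, ".nii.gz")))
    write_mask(p$mask, file.path(dir, paste0("mask_", p$id, ".nii.gz")))
  }
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(dataset$manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory holding the NIfTI volumes/masks and `manifest.csv`.
#' @return A `cohort_dataset`.
#' @export
read_cohort <- function(dir) {
  manifest <- read_manifest(file.path(dir, "manifest.csv"))
  ids <- unique(manifest$patient_id)
  patients <- lapply(ids, function(pid) {
    list(id = pid,
         t1w = read_volume(file.path(dir, paste0("t1w_", pid, ".nii.gz")), "t1w"),
         t2w = read_volume(file.path(dir, paste0("t2w_", pid, ".nii.gz")), "t2w"),
         mask = read_mask(file.path(dir, paste0("mask_", pid, ".nii.gz"))))
  })
  structure(list(patients = patients, manifest = manifest, params = NULL),
            class = "cohort_dataset")
}
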