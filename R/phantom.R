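#' Specification of a synthetic neonatal T2 phantom
#'
#' Describes one synthetic T2-weighted neonatal brain volume: the voxel grid,
#' per-tissue intensity statistics, the hyperintense DWMA lesions to embed in
#' periventricular white matter, and the Rician noise level. The anatomy is a
#' set of concentric ellipsoidal shells — a cortical grey-matter rim around a
#' white-matter interior containing two CSF-filled lateral ventricles — which
#' reproduces the qualitative appearance of an axially-acquired neonatal T2
#' scan without modelling cortical folding.
#'
#' On neonatal T2 images CSF is brightest, unmyelinated white matter is
#' brighter than cortical grey matter, and DWMA is brighter still. The DWMA
#' class mean defaults (`dwma = NA`) to the white-matter mean plus
#' `dwma_offset_sd` within-brain standard deviations, so lesions exceed the
#' 1.4-SD gold-standard threshold with margin. After composing the tissues,
#' intensities are rescaled so the mean cerebral (within-brain) intensity
#' equals `mean_cerebral_intensity`; the default 225 maps noise SDs
#' {10, 15, 20, 25, 30} to SNRs {22.5, 15, 11.25, 9, 7.5}.
#'
#' @param volume_shape Integer vector of 3 positive grid dimensions.
#' @param voxel_size Voxel edge lengths in mm per axis.
#' @param tissue_means Named intensity means for `csf`, `gm`, `wm`, `dwma`
#'   (arbitrary T2 units). `dwma = NA` resolves as described above.
#' @param tissue_sds Named within-class intensity SDs; `NULL` defaults to 2%
#'   of each class mean, which keeps the intensity classes cleanly separable
#'   on the noiseless image so that the 1.4-SD labeling rule recovers the
#'   simulated truth (image noise is then supplied by the Rician stage).
#' @param dwma_lesions List of lesion descriptors, each
#'   `list(center = c(x, y, z), radii = c(rx, ry, rz))` in voxel units;
#'   `NULL` gives three periventricular lesions scaled to the grid.
#' @param noise_sd Rician noise SD (same units as the intensities), >= 0.
#' @param seed Integer RNG seed; the whole phantom is a pure function of the
#'   spec including this seed.
#' @param mean_cerebral_intensity Calibration target for the within-brain
#'   mean intensity.
#' @param dwma_offset_sd DWMA mean offset above normal WM, in within-brain
#'   SD units, used when `tissue_means["dwma"]` is `NA`.
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()]
#' @export
phantom_spec <- function(volume_shape = c(96L, 96L, 20L),
                         voxel_size = c(1, 1, 2),
                         tissue_means = c(csf = 340, gm = 190, wm = 225,
                                          dwma = NA),
                         tissue_sds = NULL,
                         dwma_lesions = NULL,
                         noise_sd = 10,
                         seed = 1L,
                         mean_cerebral_intensity = 225,
                         dwma_offset_sd = 2.0) {
  volume_shape <- as.integer(volume_shape)
  if (length(volume_shape) != 3L || any(volume_shape <= 0L))
    abort("`volume_shape` must be 3 positive integers")
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    abort("`voxel_size` must be 3 positive lengths (mm)")
  needed <- c("csf", "gm", "wm", "dwma")
  if (!all(needed %in% names(tissue_means)))
    abort("`tissue_means` needs entries csf, gm, wm, dwma")
  tissue_means <- tissue_means[needed]
  if (!is.na(tissue_means["dwma"]) &&
      tissue_means["dwma"] <= tissue_means["wm"])
    abort("DWMA mean intensity must exceed the normal white-matter mean")
  if (is.null(tissue_sds)) {
    tissue_sds <- 0.02 * tissue_means
    tissue_sds["dwma"] <- NA  # resolved with the dwma mean
  } else {
    if (!all(needed %in% names(tissue_sds)))
      abort("`tissue_sds` needs entries csf, gm, wm, dwma")
    tissue_sds <- tissue_sds[needed]
    if (any(tissue_sds < 0, na.rm = TRUE)) abort("tissue SDs must be >= 0")
  }
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  if (is.null(dwma_lesions)) dwma_lesions <- default_lesions(volume_shape)
  for (les in dwma_lesions) {
    if (!all(c("center", "radii") %in% names(les)) ||
        length(les$center) != 3L || length(les$radii) != 3L ||
        any(les$radii <= 0))
      abort("each lesion needs center = c(x,y,z) and positive radii = c(rx,ry,rz)")
  }
  structure(
    list(volume_shape = volume_shape, voxel_size = as.numeric(voxel_size),
         tissue_means = tissue_means, tissue_sds = tissue_sds,
         dwma_lesions = dwma_lesions, noise_sd = noise_sd,
         seed = as.integer(seed),
         mean_cerebral_intensity = mean_cerebral_intensity,
         dwma_offset_sd = dwma_offset_sd),
    class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec> ", paste(x$volume_shape, collapse = " x "),
      " voxels, ", length(x$dwma_lesions), " DWMA lesion(s), noise SD ",
      x$noise_sd, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# Three periventricular/subcortical lesions, positioned relative to the
# brain centre and scaled with the grid (anterior, posterior-left,
# posterior-right of the lateral ventricles).
default_lesions <- function(volume_shape) {
  ctr <- (volume_shape + 1) / 2
  sc <- volume_shape / c(96, 96, 20)
  mk <- function(off, radii)
    list(center = ctr + off * sc, radii = radii * sc)
  list(
    mk(c(0, 15, 0),    c(7, 6, 3)),
    mk(c(-10, -13, 0), c(6, 5, 3)),
    mk(c(9, -11, -1), c(5, 5, 2))
  )
}

# Ellipsoidal tissue geometry. Returns logical masks on the spec grid.
phantom_geometry <- function(spec) {
  sh <- spec$volume_shape
  ctr <- (sh + 1) / 2
  brain_r <- c(0.36, 0.40, 0.43) * sh
  x <- seq_len(sh[1]) - ctr[1]
  y <- seq_len(sh[2]) - ctr[2]
  z <- seq_len(sh[3]) - ctr[3]
  # normalised squared radius on the brain ellipsoid
  rx2 <- (x / brain_r[1])^2
  ry2 <- (y / brain_r[2])^2
  rz2 <- (z / brain_r[3])^2
  rho2 <- outer(outer(rx2, ry2, `+`), rz2, `+`)
  brain <- rho2 <= 1
  inner <- rho2 <= 0.74^2          # white-matter compartment boundary
  vent <- array(FALSE, sh)
  for (sgn in c(-1, 1)) {
    vc <- c(sgn * 0.125 * sh[1], 0, 0)
    vr <- c(0.090 * sh[1], 0.036 * sh[2], 0.125 * sh[3])
    d2 <- outer(outer(((x - vc[1]) / vr[1])^2, ((y - vc[2]) / vr[2])^2, `+`),
                ((z - vc[3]) / vr[3])^2, `+`)
    vent <- vent | (d2 <= 1)
  }
  vent <- vent & inner
  list(brain = brain, gm = brain & !inner, wm = inner & !vent, csf = vent)
}

# Logical mask of one ellipsoidal lesion on the grid.
lesion_mask <- function(lesion, volume_shape) {
  x <- (seq_len(volume_shape[1]) - lesion$center[1]) / lesion$radii[1]
  y <- (seq_len(volume_shape[2]) - lesion$center[2]) / lesion$radii[2]
  z <- (seq_len(volume_shape[3]) - lesion$center[3]) / lesion$radii[3]
  outer(outer(x^2, y^2, `+`), z^2, `+`) <= 1
}

#' Generate a synthetic T2 phantom with known DWMA
#'
#' Composes the noiseless tissue volume from the spec (per-class Gaussian
#' intensities on the ellipsoidal anatomy, DWMA lesions embedded in the
#' white-matter shell), calibrates the within-brain mean intensity, and
#' corrupts the result with Rician noise via [add_rician_noise()]. The
#' ground-truth DWMA mask records exactly the lesion voxels.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom_volume`: a list with the noisy `t2`,
#'   the noiseless `t2_noiseless`, logical `brain_mask`, `wm_mask`,
#'   `gm_mask`, `csf_mask`, `dwma_truth`, the realised `dwma_mean`, and the
#'   generating `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(volume_shape = c(32, 32, 8), seed = 2))
#' sum(ph$dwma_truth)
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sh <- spec$volume_shape
  geo <- phantom_geometry(spec)
  m <- spec$tissue_means
  s <- spec$tissue_sds

  vol <- withr::with_seed(spec$seed, {
    v <- array(0, sh)
    for (cls in c("csf", "gm", "wm")) {
      idx <- which(geo[[cls]])
      v[idx] <- rnorm(length(idx), mean = m[[cls]], sd = s[[cls]])
    }
    v
  })

  brain_idx <- which(geo$brain)
  sd_c <- sqrt(mean((vol[brain_idx] - mean(vol[brain_idx]))^2))
  dwma_mean <- if (is.na(m[["dwma"]])) {
    m[["wm"]] + spec$dwma_offset_sd * sd_c
  } else m[["dwma"]]
  if (dwma_mean <= m[["wm"]])
    abort("DWMA mean intensity must exceed the normal white-matter mean")
  dwma_sd <- if (is.na(s[["dwma"]])) 0.02 * dwma_mean else s[["dwma"]]

  truth <- array(FALSE, sh)
  for (i in seq_along(spec$dwma_lesions)) {
    les <- lesion_mask(spec$dwma_lesions[[i]], sh)
    if (any(les & !geo$wm))
      abort(sprintf("lesion %d extends outside the white-matter mask", i))
    truth <- truth | les
  }
  les_idx <- which(truth)
  vol[les_idx] <- withr::with_seed(
    derive_seed(spec$seed, 101L),
    rnorm(length(les_idx), mean = dwma_mean, sd = dwma_sd))

  # calibrate mean cerebral tissue intensity (keeps background at 0)
  scale <- spec$mean_cerebral_intensity / mean(vol[brain_idx])
  vol[brain_idx] <- vol[brain_idx] * scale

  noisy <- if (spec$noise_sd > 0) {
    add_rician_noise(vol, spec$noise_sd, seed = derive_seed(spec$seed, 202L))
  } else vol

  structure(
    list(t2 = noisy, t2_noiseless = vol, brain_mask = geo$brain,
         wm_mask = geo$wm, gm_mask = geo$gm, csf_mask = geo$csf,
         dwma_truth = truth, dwma_mean = dwma_mean * scale, spec = spec),
    class = "phantom_volume")
}

#' @export
print.phantom_volume <- function(x, ...) {
  cat("<phantom_volume> ", paste(dim(x$t2), collapse = " x "),
      " voxels; brain ", sum(x$brain_mask), ", WM ", sum(x$wm_mask),
      ", DWMA ", sum(x$dwma_truth), " voxels; noise SD ",
      x$spec$noise_sd, "\n", sep = "")
  invisible(x)
}

#' Corrupt an intensity volume with Rician noise
#'
#' Magnitude-MRI noise: each voxel value A is replaced by
#' `sqrt((A + n1)^2 + n2^2)` with `n1`, `n2` independent zero-mean Gaussians
#' of SD `sigma`. On zero signal this reduces to a Rayleigh distribution
#' with mean `sigma * sqrt(pi / 2)`.
#'
#' @param volume Numeric array.
#' @param sigma Noise SD, >= 0. `sigma = 0` returns the input unchanged.
#' @param seed Integer seed; the corruption is deterministic given it.
#' @return Numeric array of the same shape, non-negative.
#' @export
add_rician_noise <- function(volume, sigma, seed = 1L) {
  if (sigma < 0) abort("`sigma` must be >= 0")
  if (sigma == 0) return(volume)
  withr::with_seed(as.integer(seed), {
    n1 <- rnorm(length(volume), sd = sigma)
    n2 <- rnorm(length(volume), sd = sigma)
    out <- sqrt((volume + n1)^2 + n2^2)
    dim(out) <- dim(volume)
    out
  })
}

#' Signal-to-noise ratio of a volume
#'
#' SNR is the mean cerebral tissue intensity divided by the noise SD.
#'
#' @param volume Numeric array.
#' @param cerebral_mask Logical array selecting cerebral tissue voxels.
#' @param sigma Noise SD, > 0.
#' @return A single dimensionless number.
#' @export
compute_snr <- function(volume, cerebral_mask, sigma) {
  cerebral_mask <- as_mask(cerebral_mask, "cerebral_mask")
  check_same_grid(volume, cerebral_mask)
  if (!any(cerebral_mask)) abort("`cerebral_mask` is empty")
  if (!is.numeric(sigma) || sigma <= 0) abort("`sigma` must be > 0")
  mean(volume[cerebral_mask]) / sigma
}

#' Generate a cohort of phantoms
#'
#' Produces `n_subjects` phantoms from one template spec, each with a
#' distinct seed derived from `seed` and small per-subject jitter of the
#' lesion centres (within +/- 1 voxel) and in-plane radii, emulating a
#' simulated multi-subject study.
#'
#' @param n_subjects Number of phantoms.
#' @param spec Template [phantom_spec()]; its `seed` is ignored.
#' @param seed Master seed for the cohort.
#' @return A named list of `phantom_volume` objects (`sim01`, `sim02`, ...).
#' @export
generate_cohort <- function(n_subjects = 10, spec = phantom_spec(),
                            seed = 1L) {
  wm <- phantom_geometry(spec)$wm
  fits_wm <- function(lesions) {
    all(purrr::map_lgl(lesions, function(les)
      !any(lesion_mask(les, spec$volume_shape) & !wm)))
  }
  purrr::map(seq_len(n_subjects), function(i) {
    si <- derive_seed(seed, i)
    # in-plane jitter only (the through-plane direction has the least
    # white-matter clearance); re-drawn deterministically while the jittered
    # lesion leaves white matter, falling back to the template placement
    lesions <- withr::with_seed(derive_seed(si, 7L), {
      cand <- spec$dwma_lesions
      for (attempt in 1:10) {
        cand <- purrr::map(spec$dwma_lesions, function(les) {
          les$center <- les$center + c(sample(-1:1, 2, replace = TRUE), 0)
          les$radii <- pmax(
            les$radii + c(0.5 * sample(-1:1, 2, replace = TRUE), 0), 1.5)
          les
        })
        if (fits_wm(cand)) break
        if (attempt == 10) cand <- spec$dwma_lesions
      }
      cand
    })
    sp <- spec
    sp$dwma_lesions <- lesions
    sp$seed <- si
    generate_phantom(sp)
  }) |>
    setNames(sprintf("sim%02d", seq_len(n_subjects)))
}
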