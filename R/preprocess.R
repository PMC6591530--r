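#' Bundle a T2 volume with its masks
#'
#' A subject record: the T2 intensity volume, its brain and white-matter
#' masks (from an upstream skull-stripping / tissue-segmentation pipeline,
#' consumed here as precomputed inputs), and optionally a gold-standard
#' DWMA mask.
#'
#' @param t2 Numeric 3D array.
#' @param brain_mask,wm_mask Logical 3D arrays; `wm_mask` must lie inside
#'   `brain_mask`.
#' @param gold_dwma Optional logical 3D array inside `wm_mask`.
#' @param subject_id Identifier string.
#' @param voxel_volume Volume of one voxel in mm^3.
#' @param normalized Whether `t2` is already z-score normalized.
#' @return An object of class `subject_image`.
#' @export
subject_image <- function(t2, brain_mask, wm_mask, gold_dwma = NULL,
                          subject_id = "subj", voxel_volume = 1,
                          normalized = FALSE) {
  brain_mask <- as_mask(brain_mask, "brain_mask")
  wm_mask <- as_mask(wm_mask, "wm_mask")
  check_same_grid(t2, brain_mask, wm_mask)
  if (any(wm_mask & !brain_mask))
    abort("`wm_mask` must lie inside `brain_mask`")
  if (!is.null(gold_dwma)) {
    gold_dwma <- as_mask(gold_dwma, "gold_dwma")
    check_same_grid(t2, gold_dwma)
    if (any(gold_dwma & !wm_mask))
      abort("`gold_dwma` must lie inside `wm_mask`")
  }
  structure(
    list(t2 = t2, brain_mask = brain_mask, wm_mask = wm_mask,
         gold_dwma = gold_dwma, subject_id = as.character(subject_id),
         voxel_volume = voxel_volume, normalized = isTRUE(normalized)),
    class = "subject_image")
}

#' @export
print.subject_image <- function(x, ...) {
  cat("<subject_image> ", x$subject_id, ": ",
      paste(dim(x$t2), collapse = " x "), " voxels; WM ", sum(x$wm_mask),
      if (!is.null(x$gold_dwma)) paste0(", gold DWMA ", sum(x$gold_dwma)),
      if (x$normalized) "; normalized", "\n", sep = "")
  invisible(x)
}

#' Z-score intensity normalization within the brain
#'
#' Centres and scales the in-brain intensities to mean 0 and (population)
#' SD 1; voxels outside the brain mask are set to 0. All downstream
#' intensity thresholds operate on this scale, which makes them invariant
#' to affine rescaling of the raw image.
#'
#' @param t2 Numeric 3D array.
#' @param brain_mask Logical 3D array with at least two voxels of
#'   non-identical intensity.
#' @return Numeric 3D array.
#' @export
zscore_normalize <- function(t2, brain_mask) {
  brain_mask <- as_mask(brain_mask, "brain_mask")
  check_same_grid(t2, brain_mask)
  idx <- which(brain_mask)
  if (length(idx) < 2) abort("`brain_mask` must contain at least 2 voxels")
  v <- t2[idx]
  mu <- mean(v)
  sigma <- sqrt(mean((v - mu)^2))
  if (sigma == 0) abort("degenerate image: zero intensity variance in brain")
  out <- array(0, dim(t2))
  out[idx] <- (v - mu) / sigma
  out
}

#' Normalize a subject in place
#'
#' @param subject A [subject_image()].
#' @return The subject with `t2` z-score normalized and `normalized = TRUE`.
#' @export
zscore_subject <- function(subject) {
  stopifnot(inherits(subject, "subject_image"))
  if (subject$normalized) return(subject)
  subject$t2 <- zscore_normalize(subject$t2, subject$brain_mask)
  subject$normalized <- TRUE
  subject
}

#' Threshold-based gold-standard DWMA mask
#'
#' Labels a white-matter voxel as DWMA iff its intensity is greater than or
#' equal to `alpha` SDs above the mean intensity of the cerebral tissues.
#' The cerebral statistics are computed over `brain_mask` by default (all
#' brain voxels; switchable to white matter only via `stats_over`). On a
#' z-score-normalized input this reduces to `value >= alpha`.
#'
#' @param normalized_t2 Numeric 3D array (z-score normalized; any intensity
#'   volume works since the statistics are recomputed).
#' @param wm_mask,brain_mask Logical 3D arrays on the same grid.
#' @param alpha SD multiplier; default 1.4.
#' @param stats_over `"brain"` (default) or `"wm"`: the voxel population
#'   whose mean/SD define the threshold.
#' @return Logical 3D array, a subset of `wm_mask`.
#' @export
gold_standard_dwma <- function(normalized_t2, wm_mask, brain_mask,
                               alpha = 1.4, stats_over = c("brain", "wm")) {
  stats_over <- match.arg(stats_over)
  wm_mask <- as_mask(wm_mask, "wm_mask")
  brain_mask <- as_mask(brain_mask, "brain_mask")
  check_same_grid(normalized_t2, wm_mask, brain_mask)
  if (!any(wm_mask)) abort("`wm_mask` is empty")
  ref <- if (stats_over == "brain") brain_mask else wm_mask
  v <- normalized_t2[ref]
  mu <- mean(v)
  sigma <- sqrt(mean((v - mu)^2))
  thr <- mu + alpha * sigma
  wm_mask & (normalized_t2 >= thr)
}

#' Remove small connected components from a binary mask
#'
#' Deterministic stand-in for the manual cleanup of isolated false-positive
#' voxels: deletes 26-connected components smaller than
#' `min_component_voxels`. Never adds voxels.
#'
#' @param mask Logical 3D array.
#' @param min_component_voxels Minimum component size to keep (>= 1).
#' @return Logical 3D array, a subset of `mask`.
#' @export
clean_mask <- function(mask, min_component_voxels = 5) {
  mask <- as_mask(mask)
  if (min_component_voxels < 1) abort("`min_component_voxels` must be >= 1")
  if (min_component_voxels == 1 || !any(mask)) return(mask)
  labels <- cpp_label_components(as.logical(mask), as.integer(dim(mask)))
  sizes <- tabulate(labels)
  keep <- which(sizes >= min_component_voxels)
  out <- array(labels %in% keep, dim(mask))
  out
}

#' Derive gold labels and a subject record from a phantom
#'
#' Runs the labeling pipeline on a phantom: z-score normalize the noiseless
#' volume, apply the `alpha`-SD threshold rule over white matter, clean
#' isolated components, and package the (noisy) T2 with its masks as a
#' [subject_image()].
#'
#' @param phantom A `phantom_volume`.
#' @param subject_id Identifier; defaults to the phantom seed.
#' @param alpha SD multiplier for the gold-standard rule.
#' @param min_component_voxels Cleanup threshold for [clean_mask()].
#' @param label_from `"noiseless"` (default) or `"noisy"`: which volume the
#'   gold-standard rule reads.
#' @return A `subject_image` with `gold_dwma` set.
#' @export
phantom_to_subject <- function(phantom, subject_id = NULL, alpha = 1.4,
                               min_component_voxels = 5,
                               label_from = c("noiseless", "noisy")) {
  stopifnot(inherits(phantom, "phantom_volume"))
  label_from <- match.arg(label_from)
  src <- if (label_from == "noiseless") phantom$t2_noiseless else phantom$t2
  norm_src <- zscore_normalize(src, phantom$brain_mask)
  gold <- gold_standard_dwma(norm_src, phantom$wm_mask, phantom$brain_mask,
                             alpha = alpha)
  gold <- clean_mask(gold, min_component_voxels)
  subject_image(
    t2 = phantom$t2, brain_mask = phantom$brain_mask,
    wm_mask = phantom$wm_mask, gold_dwma = gold,
    subject_id = subject_id %||% sprintf("phantom%d", phantom$spec$seed),
    voxel_volume = prod(phantom$spec$voxel_size))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
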