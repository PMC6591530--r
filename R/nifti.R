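#' Read a subject from NIfTI files
#'
#' @param t2,brain_mask,wm_mask,gold_dwma Paths to NIfTI-1 volumes
#'   (`gold_dwma` optional). Masks are binarised at > 0.
#' @param subject_id Identifier; defaults to the T2 file name.
#' @return A [subject_image()].
#' @export
read_subject_nifti <- function(t2, brain_mask, wm_mask, gold_dwma = NULL,
                               subject_id = NULL) {
  img <- RNifti::readNifti(t2)
  vx <- prod(utils::head(RNifti::pixdim(img), 3))
  subject_image(
    t2 = as.array(img),
    brain_mask = as.array(RNifti::readNifti(brain_mask)) > 0,
    wm_mask = as.array(RNifti::readNifti(wm_mask)) > 0,
    gold_dwma = if (!is.null(gold_dwma))
      as.array(RNifti::readNifti(gold_dwma)) > 0,
    subject_id = subject_id %||% sub("\\.nii(\\.gz)?$", "", basename(t2)),
    voxel_volume = if (is.finite(vx) && vx > 0) vx else 1)
}

#' Write a phantom to a directory of NIfTI files
#'
#' One file per volume (`t2`, `t2_noiseless`, the tissue masks,
#' `dwma_truth`) plus the generating spec as a plain-text `key=value`
#' provenance file.
#'
#' @param phantom A `phantom_volume`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the written paths.
#' @export
write_phantom_nifti <- function(phantom, dir, prefix = "phantom") {
  stopifnot(inherits(phantom, "phantom_volume"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  vols <- list(t2 = phantom$t2, t2_noiseless = phantom$t2_noiseless,
               brain_mask = phantom$brain_mask, wm_mask = phantom$wm_mask,
               gm_mask = phantom$gm_mask, csf_mask = phantom$csf_mask,
               dwma_truth = phantom$dwma_truth)
  for (nm in names(vols)) {
    p <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, nm))
    v <- vols[[nm]]
    if (is.logical(v)) storage.mode(v) <- "integer"
    RNifti::writeNifti(
      RNifti::asNifti(v, pixdim = phantom$spec$voxel_size), p)
    paths <- c(paths, p)
  }
  spec <- phantom$spec
  cfg <- c(
    sprintf("volume_shape=%s", paste(spec$volume_shape, collapse = ",")),
    sprintf("voxel_size=%s", paste(spec$voxel_size, collapse = ",")),
    sprintf("tissue_means=%s",
            paste(names(spec$tissue_means), spec$tissue_means,
                  sep = ":", collapse = ",")),
    sprintf("noise_sd=%g", spec$noise_sd),
    sprintf("seed=%d", spec$seed),
    sprintf("mean_cerebral_intensity=%g", spec$mean_cerebral_intensity),
    sprintf("dwma_offset_sd=%g", spec$dwma_offset_sd),
    sprintf("n_lesions=%d", length(spec$dwma_lesions)),
    purrr::imap_chr(spec$dwma_lesions, function(l, i)
      sprintf("lesion%d=center:%s;radii:%s", i,
              paste(round(l$center, 3), collapse = ","),
              paste(round(l$radii, 3), collapse = ","))))
  cfgp <- file.path(dir, sprintf("%s_spec.txt", prefix))
  writeLines(cfg, cfgp)
  invisible(c(paths, cfgp))
}

#' Write a predicted segmentation to NIfTI
#'
#' @param prediction A [predict_volume()] result.
#' @param prob_path,mask_path Output file paths.
#' @param voxel_size Voxel edge lengths in mm.
#' @return Invisibly, the paths.
#' @export
write_prediction_nifti <- function(prediction, prob_path, mask_path,
                                   voxel_size = c(1, 1, 1)) {
  RNifti::writeNifti(
    RNifti::asNifti(prediction$probability, pixdim = voxel_size), prob_path)
  m <- prediction$mask
  storage.mode(m) <- "integer"
  RNifti::writeNifti(RNifti::asNifti(m, pixdim = voxel_size), mask_path)
  invisible(c(prob_path, mask_path))
}

#' Save / load a trained model
#'
#' Checkpoints are a single RDS file holding the architecture spec, all
#' weights and batch-norm statistics, and the training configuration.
#'
#' @param model A `dwma_cnn` or `dwma_mlp`.
#' @param path Checkpoint file path.
#' @return `save_model()` the path, invisibly; `load_model()` the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)

#' Write an evaluation report as delimited text
#'
#' Tab-separated per-subject rows followed by a commented summary block.
#'
#' @param report A `dwma_eval`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "dwma_eval"))
  utils::write.table(report$per_subject, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  lines <- c(
    sprintf("# design: %s", report$design$kind),
    sprintf("# %s: mean %.6f sd %.6f", report$summary$metric,
            report$summary$mean, report$summary$sd))
  if (!is.null(report$agreement))
    lines <- c(lines, sprintf(
      "# dbr_agreement: mean_diff %.6e limits [%.6e, %.6e]",
      report$agreement$mean_difference, report$agreement$lower_limit,
      report$agreement$upper_limit))
  cat(lines, file = path, sep = "\n", append = TRUE)
  invisible(path)
}
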