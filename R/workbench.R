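#' Configuration of an end-to-end simulation study
#'
#' Ties the stages together: a phantom cohort, a sweep of Rician noise
#' levels, one or more patch-size architectures, a training recipe and a
#' validation design, all driven by a single master seed. Two named
#' presets ship with the package: `"paper_scale"` (10 phantoms on the
#' 96 x 96 x 20 grid, leave-one-subject-out, up to 20 epochs) and
#' `"test_scale"` (2 phantoms, 3 epochs) for smoke runs.
#'
#' @param n_subjects Number of phantoms in the cohort.
#' @param phantom Template [phantom_spec()] (its seed and noise SD are
#'   overridden per subject / per noise level).
#' @param noise_sds Rician noise SDs to sweep.
#' @param patch_sizes Architectures to compare (subset of 7, 9, 13, 17).
#' @param training A [training_config()].
#' @param design A `validation_design`.
#' @param alpha,min_component_voxels Gold-standard labelling parameters.
#' @param master_seed Single seed from which all per-stage seeds derive.
#' @param preset Optional `"paper_scale"` or `"test_scale"` shortcut.
#' @return An `experiment_config` object.
#' @export
experiment_config <- function(n_subjects = 10, phantom = phantom_spec(),
                              noise_sds = 10, patch_sizes = 13,
                              training = training_config(),
                              design = design_loso(),
                              alpha = 1.4, min_component_voxels = 5,
                              master_seed = 1L, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("paper_scale", "test_scale"))
    if (preset == "paper_scale") {
      n_subjects <- 10; training$max_epochs <- 20L
    } else {
      n_subjects <- 2; training$max_epochs <- 3L
      design <- design_holdout("sim01", "sim02")
    }
  }
  stopifnot(inherits(phantom, "phantom_spec"),
            inherits(training, "training_config"),
            inherits(design, "validation_design"))
  purrr::walk(patch_sizes, build_architecture)  # validate early
  if (any(noise_sds < 0)) abort("noise SDs must be >= 0")
  structure(
    list(n_subjects = n_subjects, phantom = phantom, noise_sds = noise_sds,
         patch_sizes = as.integer(patch_sizes), training = training,
         design = design, alpha = alpha,
         min_component_voxels = min_component_voxels,
         master_seed = as.integer(master_seed)),
    class = "experiment_config")
}

#' Run the phantom simulation study
#'
#' Generates the phantom cohort once (noiseless anatomy per subject seed),
#' then for every noise level corrupts the same anatomies with fresh
#' Rician noise, derives gold labels from the noiseless volumes with the
#' alpha-SD rule, and runs the validation design for every requested
#' architecture. Cells that fail are logged and skipped; the others
#' proceed.
#'
#' @param config An [experiment_config()].
#' @return Object of class `dwma_study`: `cells`, a tibble with one row
#'   per (noise_sd, patch_size) holding the `dwma_eval` report in a list
#'   column plus its headline means; `summary`, the [summarize_reports()]
#'   table; `errors`, a tibble of failed cells (if any); and the config.
#' @export
run_simulation_study <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  base <- config$phantom
  base$noise_sd <- 0  # anatomy first; noise applied per level below
  cohort <- generate_cohort(config$n_subjects, base,
                            seed = derive_seed(config$master_seed, 1L))
  cells <- list(); errors <- list()
  for (ni in seq_along(config$noise_sds)) {
    sigma <- config$noise_sds[ni]
    subjects <- purrr::imap(cohort, function(ph, id) {
      ph$spec$noise_sd <- sigma
      if (sigma > 0)
        ph$t2 <- add_rician_noise(
          ph$t2_noiseless, sigma,
          seed = derive_seed(config$master_seed, 2L, ni, match(id, names(cohort))))
      phantom_to_subject(ph, subject_id = id, alpha = config$alpha,
                         min_component_voxels = config$min_component_voxels)
    })
    for (psize in config$patch_sizes) {
      cfg <- config$training
      # same training seeds across noise levels: only the corruption differs
      cfg$seed <- derive_seed(config$master_seed, 3L, psize)
      res <- tryCatch(
        run_validation(subjects, config$design, cnn_factory(psize),
                       config = cfg, patch_size = psize),
        error = function(e) e)
      if (inherits(res, "error")) {
        errors[[length(errors) + 1]] <- tibble(
          noise_sd = sigma, patch_size = psize,
          message = conditionMessage(res))
        next
      }
      cells[[length(cells) + 1]] <- tibble(
        noise_sd = sigma, patch_size = psize,
        snr = config$phantom$mean_cerebral_intensity / max(sigma, 1e-12),
        report = list(res),
        mean_dice = res$summary$mean[res$summary$metric == "dice"],
        mean_balanced_accuracy =
          res$summary$mean[res$summary$metric == "balanced_accuracy"])
    }
  }
  cells <- dplyr::bind_rows(cells)
  structure(
    list(cells = cells,
         summary = if (nrow(cells)) summarize_reports(cells) else NULL,
         errors = dplyr::bind_rows(errors), config = config),
    class = "dwma_study")
}

#' Summary table of a simulation study
#'
#' One row per (noise level, architecture) with the mean and SD of Dice
#' and balanced accuracy over held-out subjects.
#'
#' @param cells Tibble with columns `noise_sd`, `patch_size` and a
#'   `report` list column of `dwma_eval` objects (as in a `dwma_study`).
#' @return A tibble.
#' @export
summarize_reports <- function(cells) {
  if (nrow(cells) == 0) abort("no reports to summarize")
  needed <- c("noise_sd", "patch_size", "report")
  if (!all(needed %in% names(cells)))
    abort("`cells` needs columns noise_sd, patch_size, report")
  purrr::pmap(cells[needed], function(noise_sd, patch_size, report) {
    s <- report$summary
    if (!all(c("dice", "balanced_accuracy") %in% s$metric))
      abort("report summary is missing the headline metrics")
    tibble(
      noise_sd = noise_sd, patch_size = patch_size,
      n_subjects = nrow(report$per_subject),
      dice_mean = s$mean[s$metric == "dice"],
      dice_sd = s$sd[s$metric == "dice"],
      balanced_accuracy_mean = s$mean[s$metric == "balanced_accuracy"],
      balanced_accuracy_sd = s$sd[s$metric == "balanced_accuracy"])
  }) |> dplyr::bind_rows()
}

#' @export
print.dwma_study <- function(x, ...) {
  cat("<dwma_study> ", nrow(x$cells), " cell(s), ",
      x$config$n_subjects, " phantom(s), design ", x$config$design$kind,
      "\n", sep = "")
  if (!is.null(x$summary)) print(x$summary)
  if (nrow(x$errors) > 0) {
    cat("failed cells:\n"); print(x$errors)
  }
  invisible(x)
}
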