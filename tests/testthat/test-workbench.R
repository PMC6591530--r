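small_study_config <- function(master_seed = 1, noise_sds = 10) {
  experiment_config(
    n_subjects = 2,
    phantom = phantom_spec(volume_shape = c(48L, 48L, 10L)),
    noise_sds = noise_sds, patch_sizes = 7,
    training = training_config(max_epochs = 2, max_train_patches = 4000,
                               batch_size = 128),
    design = design_holdout("sim01", "sim02"),
    master_seed = master_seed)
}

test_that("the simulation study runs end-to-end and is seed-deterministic", {
  st1 <- run_simulation_study(small_study_config(5))
  expect_s3_class(st1, "dwma_study")
  expect_equal(nrow(st1$errors), 0)
  expect_equal(nrow(st1$cells), 1)
  expect_true(st1$cells$mean_dice >= 0 && st1$cells$mean_dice <= 1)
  expect_equal(st1$summary$n_subjects, 1)

  st2 <- run_simulation_study(small_study_config(5))
  expect_identical(st1$summary, st2$summary)
  expect_identical(tidy(st1$cells$report[[1]]), tidy(st2$cells$report[[1]]))

  st3 <- run_simulation_study(small_study_config(6))
  expect_false(identical(st1$summary, st3$summary))
})

test_that("study cells sweep noise levels and architectures", {
  cfg <- small_study_config(3, noise_sds = c(10, 30))
  st <- run_simulation_study(cfg)
  expect_equal(nrow(st$cells), 2)
  expect_equal(st$cells$noise_sd, c(10, 30))
  expect_equal(st$cells$snr, 225 / c(10, 30))
  expect_s3_class(autoplot(st), "ggplot")
})

test_that("summaries match independent recomputation from per-subject rows", {
  st <- run_simulation_study(small_study_config(2))
  s <- summarize_reports(st$cells)
  r <- st$cells$report[[1]]
  expect_equal(s$dice_mean, mean(r$per_subject$dice))
  expect_equal(s$balanced_accuracy_mean, mean(r$per_subject$balanced_accuracy))
  expect_equal(nrow(s), nrow(st$cells))
  # a report of identical per-subject values has SD 0 (single row here -> NA)
  expect_error(summarize_reports(tibble::tibble()), "no reports")
  expect_error(summarize_reports(tibble::tibble(a = 1)), "needs columns")
})

test_that("experiment presets set the documented scales", {
  ec <- experiment_config(preset = "test_scale")
  expect_equal(ec$n_subjects, 2)
  expect_equal(ec$training$max_epochs, 3L)
  ep <- experiment_config(preset = "paper_scale")
  expect_equal(ep$n_subjects, 10)
  expect_equal(ep$training$max_epochs, 20L)
  expect_equal(ep$design$kind, "loso")
})

test_that("the CLI dispatcher wires the stages together", {
  tmp <- withr::local_tempdir()
  outdir <- file.path(tmp, "sim")
  dwma_cli(c("simulate", "--n-subjects", "1", "--noise-sd", "10",
             "--seed", "3", "--out", outdir))
  files <- list.files(outdir)
  expect_true("sim01_t2.nii.gz" %in% files)
  expect_true("sim01_dwma_truth.nii.gz" %in% files)
  expect_true("sim01_spec.txt" %in% files)

  prep <- file.path(tmp, "prep")
  dwma_cli(c("preprocess", "--t2", file.path(outdir, "sim01_t2.nii.gz"),
             "--brain-mask", file.path(outdir, "sim01_brain_mask.nii.gz"),
             "--wm-mask", file.path(outdir, "sim01_wm_mask.nii.gz"),
             "--out", prep))
  expect_true(file.exists(file.path(prep, "gold_dwma.nii.gz")))
  norm <- RNifti::readNifti(file.path(prep, "t2_normalized.nii.gz"))
  brain <- RNifti::readNifti(file.path(outdir, "sim01_brain_mask.nii.gz"))
  expect_equal(mean(norm[brain > 0]), 0, tolerance = 1e-6)

  expect_error(dwma_cli(c("nonsense")), "unknown command")
})
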