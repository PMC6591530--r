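# The full phantom simulation study (10 subjects, leave-one-subject-out,
# 13x13 CNN) is expensive; several acceptance properties read from the same
# run, so it is computed once per session and memoised.
.study_cache <- new.env(parent = emptyenv())

acceptance_study <- function() {
  if (is.null(.study_cache$study)) {
    cfg <- experiment_config(
      n_subjects = 10,
      phantom = phantom_spec(),            # 96 x 96 x 20, default lesions
      noise_sds = c(10, 30),               # SNR 22.5 and 7.5
      patch_sizes = 13,
      training = training_config(),        # batch 256, lr 0.1, <= 20 epochs
      design = design_loso(),
      master_seed = 1L)
    .study_cache$study <- run_simulation_study(cfg)
  }
  .study_cache$study
}

study_cell <- function(study, noise_sd) {
  i <- which(study$cells$noise_sd == noise_sd)
  stopifnot(length(i) == 1)
  study$cells[i, ]
}
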