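mk <- function(v, dims = c(4, 4, 2)) array(v, dims)

test_that("Dice matches hand-computed overlaps and is symmetric", {
  a <- mk(FALSE); a[1:4, 1, 1] <- TRUE                 # |A| = 4
  b <- mk(FALSE); b[2:4, 1, 1] <- TRUE; b[1:3, 2, 1] <- TRUE  # |B| = 6, |A^B| = 3
  expect_equal(dice(a, b), 0.6)
  expect_equal(dice(b, a), 0.6)
  expect_equal(dice(a, a), 1)
  disj <- mk(FALSE); disj[1, 4, 2] <- TRUE
  expect_equal(dice(a, disj), 0)
  expect_warning(d0 <- dice(mk(FALSE), mk(FALSE)), "empty")
  expect_equal(d0, 1)
  expect_error(dice(a, array(FALSE, c(4, 4, 3))), "grid")
})

test_that("balanced accuracy averages sensitivity and specificity", {
  expect_equal(balanced_accuracy(10, 10, 90, 90), 1)
  expect_equal(balanced_accuracy(0, 10, 90, 90), 0.5)   # all-majority prediction
  expect_equal(balanced_accuracy(9, 10, 80, 90), (9 / 10 + 80 / 90) / 2)
  # equals plain accuracy when per-class rates agree
  expect_equal(balanced_accuracy(8, 10, 72, 90), (8 + 72) / 100)
  expect_error(balanced_accuracy(1, 0, 5, 10), "undefined")
  expect_error(balanced_accuracy(11, 10, 5, 10), "tp")
})

test_that("DWMA-to-brain ratio is a plain voxel-count ratio", {
  brain <- mk(TRUE)
  d <- mk(FALSE); d[1:5] <- TRUE
  expect_equal(dbr(d, brain), 5 / 32)
  expect_equal(dbr(mk(FALSE), brain), 0)
  expect_equal(dbr(brain, brain), 1)
  outside <- mk(FALSE); outside[1] <- TRUE
  small_brain <- mk(TRUE); small_brain[1] <- FALSE
  expect_error(dbr(outside, small_brain), "outside")
})

test_that("Bland-Altman limits follow the 1.96-sample-SD closed form", {
  ba <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ba$mean_difference, 0)
  expect_equal(ba$lower_limit, 0); expect_equal(ba$upper_limit, 0)

  ba2 <- bland_altman(c(2, 1), c(1, 2))   # differences +1, -1
  expect_equal(ba2$mean_difference, 0)
  expect_equal(ba2$upper_limit, 1.96 * sqrt(2), tolerance = 1e-12)
  expect_equal(ba2$lower_limit, -1.96 * sqrt(2), tolerance = 1e-12)

  ba3 <- bland_altman(c(5, 6, 7) + 0.25, c(5, 6, 7))  # constant difference
  expect_equal(ba3$mean_difference, 0.25)
  expect_equal(ba3$lower_limit, 0.25); expect_equal(ba3$upper_limit, 0.25)
  expect_error(bland_altman(1, 1), "2 pairs")
})

test_that("model comparison is a paired two-sided t-test", {
  withr::with_seed(1, {
    a <- runif(10, 0.8, 0.9)
    b <- a - 0.1 + rnorm(10, 0, 0.003)   # large shift, small jitter
  })
  p <- compare_models(a, b)
  expect_lt(p, 0.001)
  expect_equal(compare_models(b, a), p)   # symmetric in its arguments
  expect_equal(p, t.test(a, b, paired = TRUE)$p.value)
  expect_warning(pd <- compare_models(a, a), "zero variance")
  expect_true(is.na(pd))
  expect_error(compare_models(a, b[1:5]), "equal length")
})

test_that("validation designs partition subjects without leakage", {
  ids <- sprintf("s%d", 1:10)
  folds <- dwmacnn:::design_folds(design_loso(), ids)
  expect_length(folds, 10)
  tested <- unlist(lapply(folds, `[[`, "test"))
  expect_setequal(tested, ids)           # every subject tested exactly once
  expect_length(tested, 10)
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0)
    expect_setequal(c(f$train, f$test), ids)
  }

  ids50 <- sprintf("s%02d", 1:50)
  folds10 <- dwmacnn:::design_folds(design_kfold(10, seed = 2), ids50)
  expect_length(folds10, 10)
  expect_true(all(vapply(folds10, function(f) length(f$test), integer(1)) == 5))
  expect_setequal(unlist(lapply(folds10, `[[`, "test")), ids50)

  expect_error(design_holdout(c("a", "b"), c("b")), "overlap")
})

test_that("run_validation aggregates per-subject metrics under a held-out design", {
  subs <- lapply(1:3, function(i) toy_subject(sprintf("t%d", i), seed = i))
  cfg <- training_config(batch_size = 32, max_epochs = 4, seed = 3)
  rep <- run_validation(subs, design_loso(), mlp_factory(hidden_sizes = c(16L)),
                        config = cfg, patch_size = 7)
  expect_s3_class(rep, "dwma_eval")
  expect_equal(nrow(rep$per_subject), 3)
  expect_setequal(rep$per_subject$subject_id, c("t1", "t2", "t3"))
  expect_true(all(rep$per_subject$dice >= 0 & rep$per_subject$dice <= 1))
  # summary equals independent recomputation from the per-subject rows
  expect_equal(rep$summary$mean[rep$summary$metric == "dice"],
               mean(rep$per_subject$dice))
  expect_equal(rep$summary$sd[rep$summary$metric == "balanced_accuracy"],
               sd(rep$per_subject$balanced_accuracy))
  # agreement block is the Bland-Altman of the DBR pairs
  expect_equal(rep$agreement,
               bland_altman(rep$per_subject$dbr_pred,
                            rep$per_subject$dbr_gold))
  # tidiers
  expect_identical(tidy(rep), rep$per_subject)
  g <- glance(rep)
  expect_equal(g$n_subjects, 3)
  expect_s3_class(autoplot(rep), "ggplot")
})
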