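test_that("z-score normalization centres and scales in-mask intensities", {
  t2 <- array(0, c(3, 1, 1))
  t2[, 1, 1] <- c(1, 2, 3)
  mask <- array(TRUE, c(3, 1, 1))
  z <- zscore_normalize(t2, mask)
  expect_equal(as.numeric(z), c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)

  withr::with_seed(1, {
    t2 <- array(rexp(1000, 0.01), c(10, 10, 10))
    mask <- array(runif(1000) > 0.3, c(10, 10, 10))
  })
  z <- zscore_normalize(t2, mask)
  expect_equal(mean(z[mask]), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(z[mask]^2)), 1, tolerance = 1e-9)
  expect_true(all(z[!mask] == 0))

  flat <- array(7, c(4, 4, 4))
  expect_error(zscore_normalize(flat, array(TRUE, c(4, 4, 4))), "degenerate")
})

test_that("gold-standard rule thresholds inclusively at alpha SD above the cerebral mean", {
  dims <- c(6, 6, 3)
  withr::with_seed(2, vals <- rnorm(40, 100, 15))
  t2 <- array(0, dims)
  brain <- array(FALSE, dims)
  brain[seq_len(40)] <- TRUE
  t2[brain] <- vals
  mu <- mean(vals); sigma <- sqrt(mean((vals - mu)^2))
  thr <- mu + 1.4 * sigma
  # two probe voxels in white matter only (outside the statistics mask):
  # one exactly at the threshold, one just below
  wm <- array(FALSE, dims)
  wm[5, 6, 3] <- TRUE; t2[5, 6, 3] <- thr
  wm[6, 6, 3] <- TRUE; t2[6, 6, 3] <- thr - 1e-9
  g <- gold_standard_dwma(t2, wm, brain, alpha = 1.4)
  expect_true(g[5, 6, 3])    # "greater than or equal to": inclusive
  expect_false(g[6, 6, 3])
})

test_that("gold-standard rule matches a brute-force oracle and is affine-invariant", {
  dims <- c(5, 5, 2)
  withr::with_seed(3, t2 <- array(rnorm(prod(dims), 50, 8), dims))
  brain <- array(TRUE, dims)
  wm <- array(FALSE, dims); wm[2:4, 2:4, ] <- TRUE
  g <- gold_standard_dwma(t2, wm, brain, alpha = 1.4)
  mu <- mean(t2); sigma <- sqrt(mean((t2 - mu)^2))
  oracle <- wm & (t2 >= mu + 1.4 * sigma)
  expect_identical(g, oracle)

  # any affine intensity rescaling leaves the labels unchanged
  expect_identical(gold_standard_dwma(3.7 * t2 + 120, wm, brain), g)

  # monotonicity: larger alpha never labels more voxels
  counts <- vapply(c(0.5, 1, 1.4, 2, 3),
                   function(a) sum(gold_standard_dwma(t2, wm, brain, a)),
                   integer(1))
  expect_true(all(diff(counts) <= 0))

  expect_error(gold_standard_dwma(t2, array(FALSE, dims), brain), "empty")
})

test_that("noiseless phantom labeling exactly recovers the simulated truth", {
  spec <- tiny_phantom_spec(seed = 6,
                            tissue_sds = c(csf = 0, gm = 0, wm = 0, dwma = 0))
  ph <- generate_phantom(spec)
  subj <- phantom_to_subject(ph)
  expect_equal(dice(subj$gold_dwma, ph$dwma_truth), 1)
  # and with the default within-class texture the margin still holds
  ph2 <- generate_phantom(tiny_phantom_spec(seed = 6))
  subj2 <- phantom_to_subject(ph2)
  expect_equal(dice(subj2$gold_dwma, ph2$dwma_truth), 1, tolerance = 0.01)
})

test_that("clean_mask removes exactly the small components", {
  dims <- c(12, 12, 4)
  mask <- array(FALSE, dims)
  mask[2:5, 2:5, 2:3] <- TRUE           # 32-voxel blob
  mask[9, 9, 1] <- TRUE                 # isolated voxel
  mask[11:12, 2, 4] <- TRUE             # 2-voxel island
  out <- clean_mask(mask, 5)
  expect_equal(sum(out), 32)
  expect_true(all(mask[out]))           # never adds voxels
  expect_identical(clean_mask(mask, 1), mask)
  expect_false(any(clean_mask(array(FALSE, dims), 5)))

  # against a brute-force flood-fill oracle on random masks
  for (s in 1:3) {
    withr::with_seed(s, m <- array(runif(6 * 6 * 3) < 0.25, c(6, 6, 3)))
    lab <- oracle_components(m)
    keep <- array(FALSE, dim(m))
    for (k in seq_len(max(lab)))
      if (sum(lab == k) >= 3) keep[lab == k] <- TRUE
    expect_identical(clean_mask(m, 3), keep)
  }
})

test_that("subject_image enforces mask nesting and grids", {
  dims <- c(6, 6, 2)
  t2 <- array(1, dims)
  brain <- array(TRUE, dims)
  wm <- array(FALSE, dims); wm[3:4, 3:4, ] <- TRUE
  bad_wm <- array(TRUE, c(6, 6, 3))
  expect_error(subject_image(t2, brain, bad_wm), "grid")
  gold_out <- array(TRUE, dims)
  expect_error(subject_image(t2, brain, wm, gold_out), "gold_dwma")
  s <- subject_image(t2, brain, wm)
  expect_s3_class(s, "subject_image")
  expect_false(s$normalized)
})
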