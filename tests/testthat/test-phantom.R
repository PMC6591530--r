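test_that("Rician corruption matches its definition and Rayleigh limit", {
  v <- array(5, c(4, 4, 2))
  expect_identical(add_rician_noise(v, 0), v)
  expect_error(add_rician_noise(v, -1), "sigma")

  # zero signal: Rayleigh limit, mean sigma*sqrt(pi/2), second moment 2 sigma^2
  sigma <- 7
  z <- add_rician_noise(array(0, c(50, 50, 50)), sigma, seed = 11)
  expect_true(all(z >= 0))
  expect_equal(mean(z), sigma * sqrt(pi / 2), tolerance = 0.01)
  expect_equal(mean(z^2), 2 * sigma^2, tolerance = 0.02)

  # determinism given the seed
  a <- add_rician_noise(v, 3, seed = 4)
  expect_identical(a, add_rician_noise(v, 3, seed = 4))
  expect_false(identical(a, add_rician_noise(v, 3, seed = 5)))
})

test_that("SNR is mean cerebral intensity over noise SD", {
  vol <- array(225, c(10, 10, 2))
  mask <- array(TRUE, c(10, 10, 2))
  expect_equal(compute_snr(vol, mask, 10), 22.5)
  expect_equal(compute_snr(vol, mask, 25), 9.0)
  expect_equal(compute_snr(array(4, c(2, 2, 2)), array(TRUE, c(2, 2, 2)), 4), 1)
  expect_error(compute_snr(vol, mask, 0), "sigma")
  expect_error(compute_snr(vol, array(FALSE, c(10, 10, 2)), 1), "empty")
})

test_that("phantom SNR calibration reproduces the noise-SD sweep", {
  ph <- generate_phantom(tiny_phantom_spec(seed = 2))
  expect_equal(mean(ph$t2_noiseless[ph$brain_mask]), 225)
  for (sdv in c(10, 15, 20, 25, 30))
    expect_equal(compute_snr(ph$t2_noiseless, ph$brain_mask, sdv), 225 / sdv)
  # measured on the corrupted image the ratio holds approximately
  noisy <- add_rician_noise(ph$t2_noiseless, 10, seed = 3)
  expect_equal(compute_snr(noisy, ph$brain_mask, 10), 22.5, tolerance = 0.01)
})

test_that("lesion voxels match a brute-force ellipsoid count and stay in WM", {
  les <- list(center = c(16, 21, 4), radii = c(4, 3, 1.5))
  spec <- tiny_phantom_spec(seed = 5, dwma_lesions = list(les))
  ph <- generate_phantom(spec)
  # brute-force loop over the grid
  cnt <- 0L
  for (x in 1:32) for (y in 1:32) for (z in 1:8) {
    if (((x - 16) / 4)^2 + ((y - 21) / 3)^2 + ((z - 4) / 1.5)^2 <= 1)
      cnt <- cnt + 1L
  }
  expect_identical(sum(ph$dwma_truth), cnt)
  expect_true(all(ph$wm_mask[ph$dwma_truth]))

  # lesion placed outside white matter is refused, naming the lesion
  bad <- tiny_phantom_spec(
    seed = 5, dwma_lesions = list(list(center = c(2, 2, 2),
                                       radii = c(3, 3, 2))))
  expect_error(generate_phantom(bad), "lesion 1")
})

test_that("phantom masks nest and partition as required", {
  ph <- generate_phantom(tiny_phantom_spec(seed = 7, noise_sd = 15))
  expect_true(all(ph$wm_mask[ph$dwma_truth]))
  expect_true(all(ph$brain_mask[ph$wm_mask]))
  # tissue classes are disjoint
  expect_equal(max(ph$wm_mask + ph$gm_mask + ph$csf_mask), 1)
  expect_true(all(ph$t2 >= 0))
  # empty lesion list gives an all-false truth mask
  ph0 <- generate_phantom(tiny_phantom_spec(seed = 7, dwma_lesions = list()))
  expect_false(any(ph0$dwma_truth))
})

test_that("identical specs give bit-identical phantoms; cohorts differ by subject", {
  spec <- tiny_phantom_spec(seed = 9, noise_sd = 12)
  expect_identical(generate_phantom(spec), generate_phantom(spec))

  co <- generate_cohort(10, tiny_phantom_spec(), seed = 3)
  expect_length(co, 10)
  seeds <- vapply(co, function(p) p$spec$seed, integer(1))
  expect_length(unique(seeds), 10)
  expect_false(identical(co[[1]]$t2, co[[2]]$t2))
  expect_identical(generate_cohort(3, tiny_phantom_spec(), seed = 3)[[2]],
                   co[[2]])
})

test_that("phantom_spec validates its invariants", {
  expect_error(phantom_spec(volume_shape = c(0, 10, 10)), "positive")
  expect_error(phantom_spec(noise_sd = -2), "noise_sd")
  expect_error(
    phantom_spec(tissue_means = c(csf = 340, gm = 190, wm = 225, dwma = 200)),
    "exceed")
})
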