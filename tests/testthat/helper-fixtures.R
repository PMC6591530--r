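# Shared fixtures, all built in code at test time.

# A small phantom spec that generates quickly; geometry scales with the grid.
tiny_phantom_spec <- function(seed = 1L, noise_sd = 0, ...) {
  phantom_spec(volume_shape = c(32L, 32L, 8L), seed = seed,
               noise_sd = noise_sd, ...)
}

# Linearly separable toy patch set: DWMA patches have a bright centre pixel,
# normal patches a dark one; background is mild noise. Separable by a single
# centre-pixel threshold.
toy_patch_set <- function(n_per_class = 120, patch_size = 7, seed = 1) {
  withr::with_seed(seed, {
    p2 <- patch_size^2
    ctr <- (p2 + 1) / 2
    n <- 2 * n_per_class
    X <- matrix(rnorm(p2 * n, sd = 0.3), p2, n)
    y <- rep(c(0L, 1L), each = n_per_class)
    X[ctr, y == 1] <- X[ctr, y == 1] + 2.5
    X[ctr, y == 0] <- X[ctr, y == 0] - 2.5
    ord <- sample(n)
    list(X = X[, ord], y = y[ord], patch_size = patch_size)
  })
}

# Balanced accuracy of hard 0/1 predictions against labels.
toy_balanced_accuracy <- function(pred, y) {
  balanced_accuracy(tp = sum(pred == 1 & y == 1), p = sum(y == 1),
                    tn = sum(pred == 0 & y == 0), n = sum(y == 0))
}

# A minimal labelled subject: a bright plate inside white matter on a small
# grid, playing the role of a gold-standard lesion.
toy_subject <- function(id = "toy", dims = c(16L, 16L, 4L), seed = 1) {
  withr::with_seed(seed, {
    t2 <- array(rnorm(prod(dims), 100, 2), dims)
    brain <- array(FALSE, dims)
    brain[3:14, 3:14, ] <- TRUE
    wm <- array(FALSE, dims)
    wm[5:12, 5:12, 2:3] <- TRUE
    gold <- array(FALSE, dims)
    gold[7:10, 7:10, 2] <- TRUE
    t2[gold] <- 140
    subject_image(t2, brain, wm, gold, subject_id = id)
  })
}

# Brute-force 3x3 valid cross-correlation + ReLU oracle. `patch` is a p x p
# matrix, `kernel3` a 3 x 3 matrix; returns an (p-2) x (p-2) matrix.
oracle_conv3x3_relu <- function(patch, kernel3) {
  p <- nrow(patch)
  out <- matrix(0, p - 2, p - 2)
  for (oh in seq_len(p - 2)) {
    for (ow in seq_len(p - 2)) {
      s <- 0
      for (kh in 1:3) for (kw in 1:3)
        s <- s + patch[oh + kh - 1, ow + kw - 1] * kernel3[kh, kw]
      out[oh, ow] <- max(0, s)
    }
  }
  out
}

# Brute-force connected-component labelling (26-connectivity) by flood fill.
oracle_components <- function(mask) {
  dims <- dim(mask)
  labels <- array(0L, dims)
  cur <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    labels[start] <- cur
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      co <- arrayInd(v, dims)
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        nb <- co + c(dx, dy, dz)
        if (any(nb < 1) || any(nb > dims)) next
        ni <- nb[1] + (nb[2] - 1) * dims[1] + (nb[3] - 1) * dims[1] * dims[2]
        if (mask[ni] && labels[ni] == 0L) {
          labels[ni] <- cur
          queue <- c(queue, ni)
        }
      }
    }
  }
  labels
}
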