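#' Baseline classifier configuration
#'
#' @param kind `"svm_linear"` or `"mlp"`.
#' @param c_grid Soft-margin candidates for the SVM; the default is the 11
#'   even powers of two from 2^-10 to 2^10.
#' @param hidden_sizes Hidden-layer widths of the MLP.
#' @param max_per_class Cap on training patches per class for the SVM
#'   (seeded subsample); quadratic-cost solvers do not scale to the full
#'   patch sets.
#' @param seed Integer seed.
#' @return A `baseline_config` object.
#' @export
baseline_config <- function(kind = c("svm_linear", "mlp"),
                            c_grid = 2^seq(-10, 10, by = 2),
                            hidden_sizes = c(64L, 10L),
                            max_per_class = 50000L,
                            seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "svm_linear" && length(c_grid) == 0)
    abort("`c_grid` must be non-empty")
  structure(list(kind = kind, c_grid = c_grid,
                 hidden_sizes = as.integer(hidden_sizes),
                 max_per_class = max_per_class, seed = as.integer(seed)),
            class = "baseline_config")
}

baseline_xy <- function(data, patch_size = NULL) {
  if (inherits(data, "patch_dataset")) {
    list(X = patch_matrix(data), y = data$centers$label,
         patch_size = data$patch_size)
  } else {
    list(X = data$X, y = data$y,
         patch_size = patch_size %||% data$patch_size %||%
           as.integer(sqrt(nrow(data$X))))
  }
}

svm_subsample <- function(X, y, max_per_class, seed) {
  keep <- withr::with_seed(as.integer(seed), {
    unlist(lapply(split(seq_along(y), y), function(ix) {
      if (length(ix) > max_per_class) sample(ix, max_per_class) else ix
    }), use.names = FALSE)
  })
  list(X = X[, keep, drop = FALSE], y = y[keep])
}

#' Linear-SVM baseline with soft-margin grid search
#'
#' Fits a linear-kernel soft-margin classifier on flattened patches for
#' every C in the grid and keeps the one whose DWMA detection performance
#' (Dice over patches) on `eval_data` is maximal. Note that selecting C on
#' the evaluation data is optimistic; pass an inner-validation set as
#' `eval_data` for an unbiased choice.
#'
#' @param train_data Labelled [patch_dataset] (or `list(X, y)`) with both
#'   classes.
#' @param eval_data Dataset scored to choose C.
#' @param config A [baseline_config()].
#' @return Object of class `dwma_svm`: the fitted `model`, `chosen_c`, and
#'   `scores` (tibble of per-C Dice, in grid order).
#' @export
train_svm_baseline <- function(train_data, eval_data,
                               config = baseline_config("svm_linear")) {
  tr <- baseline_xy(train_data)
  ev <- baseline_xy(eval_data)
  if (length(unique(tr$y)) < 2) abort("training data must contain both classes")
  if (length(config$c_grid) == 0) abort("`c_grid` must be non-empty")
  sub <- svm_subsample(tr$X, tr$y, config$max_per_class, config$seed)
  fits <- vector("list", length(config$c_grid))
  score <- numeric(length(config$c_grid))
  for (i in seq_along(config$c_grid)) {
    fits[[i]] <- e1071::svm(x = t(sub$X), y = factor(sub$y, levels = 0:1),
                            kernel = "linear", cost = config$c_grid[i],
                            scale = FALSE)
    pred <- as.integer(as.character(predict(fits[[i]], t(ev$X))))
    tp <- sum(pred == 1 & ev$y == 1)
    score[i] <- 2 * tp / (sum(pred == 1) + sum(ev$y == 1))
  }
  best <- which.max(score)
  structure(
    list(model = fits[[best]], chosen_c = config$c_grid[best],
         scores = tibble(c = config$c_grid, dice = score),
         patch_size = tr$patch_size),
    class = "dwma_svm")
}

#' @export
predict_patch_probs.dwma_svm <- function(model, X, ...) {
  pred <- predict(model$model, t(X))
  as.numeric(as.character(pred))  # hard 0/1 decisions
}

#' @export
print.dwma_svm <- function(x, ...) {
  cat("<dwma_svm> linear kernel, chosen C = ", format(x$chosen_c),
      " of ", nrow(x$scores), " candidates\n", sep = "")
  invisible(x)
}

#' Multilayer-perceptron baseline
#'
#' A fully-connected network on flattened patches (default hidden sizes
#' 64 and 10, ReLU activations, 2-way softmax output) trained with the
#' same mini-batch SGD + Nesterov recipe as the CNN. Stands in for a deep
#' neural network comparator without convolutional structure.
#'
#' @param train_data Labelled [patch_dataset] (or `list(X, y)`) with both
#'   classes.
#' @param config A [training_config()].
#' @param hidden_sizes Hidden-layer widths.
#' @return Object of class `dwma_mlp`.
#' @export
train_mlp_baseline <- function(train_data, config = training_config(),
                               hidden_sizes = c(64L, 10L)) {
  tr <- baseline_xy(train_data)
  if (inherits(train_data, "patch_dataset")) {
    rows <- cap_training_rows(train_data, config$max_train_patches,
                              derive_seed(config$seed, 31L))
    tr$X <- patch_matrix(train_data, rows)
    tr$y <- train_data$centers$label[rows]
  }
  layers <- c(
    purrr::map(hidden_sizes, ~ list(kind = "fully_connected",
                                    n_filters = as.integer(.x),
                                    has_bias = TRUE)),
    list(list(kind = "softmax", n_filters = 2L, has_bias = TRUE)))
  fit <- train_engine(layers, tr$patch_size, tr$X, tr$y, config)
  structure(
    list(state = fit$state, training_log = fit$training_log,
         hidden_sizes = hidden_sizes, patch_size = tr$patch_size,
         config = config, n_train = length(tr$y)),
    class = "dwma_mlp")
}

#' @export
predict_patch_probs.dwma_mlp <- function(model, X, ...) {
  cpp_predict(model$state, X, 2048L)[2, ]
}

#' @export
print.dwma_mlp <- function(x, ...) {
  cat("<dwma_mlp> hidden (", paste(x$hidden_sizes, collapse = ", "),
      "), input ", x$patch_size^2, "-d; trained ",
      length(x$training_log), " epoch(s)\n", sep = "")
  invisible(x)
}

#' @rdname model_factory
#' @export
mlp_factory <- function(...) {
  function(train_data, config) train_mlp_baseline(train_data, config, ...)
}

#' @rdname model_factory
#' @export
svm_factory <- function(...) {
  function(train_data, config) {
    cfg <- baseline_config("svm_linear", ...)
    cfg$seed <- config$seed
    # C chosen by inner split of the training subjects' patches
    n <- if (inherits(train_data, "patch_dataset")) {
      nrow(train_data$centers)
    } else length(train_data$y)
    inner <- withr::with_seed(cfg$seed, sample.int(n, max(2, round(n / 5))))
    tr <- baseline_xy(train_data)
    train_svm_baseline(
      list(X = tr$X[, -inner, drop = FALSE], y = tr$y[-inner],
           patch_size = tr$patch_size),
      list(X = tr$X[, inner, drop = FALSE], y = tr$y[inner],
           patch_size = tr$patch_size),
      cfg)
  }
}
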