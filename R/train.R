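#' Training hyper-parameters
#'
#' Defaults follow the training recipe used throughout the package:
#' mini-batch stochastic gradient descent with batch size 256, learning
#' rate 0.1, Nesterov momentum 0.9, at most 20 epochs, and early stopping
#' once three consecutive epochs return the same loss (operationalised as a
#' plateau within `loss_tolerance`).
#'
#' @param batch_size Mini-batch size m.
#' @param learning_rate Constant SGD learning rate.
#' @param max_epochs Epoch cap.
#' @param momentum Nesterov momentum coefficient in `[0, 1)`.
#' @param early_stop_patience Number of consecutive equal-loss epochs that
#'   triggers the stop.
#' @param loss_tolerance Two epoch losses within this absolute difference
#'   count as "the same"; exact floating-point equality would never fire.
#' @param bn_momentum Exponential running-average momentum for the
#'   batch-normalisation inference statistics.
#' @param max_train_patches Cap on training patches per fit; larger sets
#'   are subsampled (seeded, stratified, prevalence-preserving). `NULL`
#'   disables the cap.
#' @param seed Integer seed governing initialisation, shuffling and
#'   subsampling.
#' @return An object of class `training_config`.
#' @export
training_config <- function(batch_size = 256L, learning_rate = 0.1,
                            max_epochs = 20L, momentum = 0.9,
                            early_stop_patience = 3L, loss_tolerance = 1e-4,
                            bn_momentum = 0.99, max_train_patches = 25000L,
                            seed = 1L) {
  if (momentum < 0 || momentum >= 1) abort("`momentum` must be in [0, 1)")
  if (learning_rate <= 0) abort("`learning_rate` must be > 0")
  if (loss_tolerance < 0) abort("`loss_tolerance` must be >= 0")
  structure(
    list(batch_size = as.integer(batch_size), learning_rate = learning_rate,
         max_epochs = as.integer(max_epochs), momentum = momentum,
         early_stop_patience = as.integer(early_stop_patience),
         loss_tolerance = loss_tolerance, bn_momentum = bn_momentum,
         max_train_patches = max_train_patches, seed = as.integer(seed)),
    class = "training_config")
}

#' Has the epoch-loss log plateaued?
#'
#' TRUE when the last `patience` epoch losses lie pairwise within
#' `tolerance` of each other.
#'
#' @param losses Numeric vector of per-epoch losses.
#' @param tolerance Non-negative plateau tolerance.
#' @param patience Number of consecutive epochs considered.
#' @return Logical.
#' @export
loss_plateaued <- function(losses, tolerance = 1e-4, patience = 3L) {
  if (length(losses) < patience) return(FALSE)
  tail_losses <- utils::tail(losses, patience)
  (max(tail_losses) - min(tail_losses)) <= tolerance
}

# Shared engine loop: layer descriptors -> trained state + loss log.
train_engine <- function(layers, patch_size, X, y, config,
                         epsilon = 1e-5) {
  if (length(unique(y)) < 2)
    abort("training data must contain both classes")
  withr::with_seed(config$seed, {
    state <- cpp_init_net(layers, as.integer(patch_size), epsilon,
                          config$bn_momentum)
    log <- numeric(0)
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(ncol(X))
      res <- cpp_train_epoch(state, X, as.integer(y), ord,
                             config$batch_size, config$learning_rate,
                             config$momentum)
      state <- res$state
      if (!is.finite(res$loss))
        abort(sprintf("non-finite training loss at epoch %d", epoch))
      log <- c(log, res$loss)
      if (loss_plateaued(log, config$loss_tolerance,
                         config$early_stop_patience)) break
    }
    list(state = state, training_log = log)
  })
}

#' Train a patch CNN
#'
#' Minimises the cross-entropy loss by mini-batch SGD with Nesterov
#' momentum. Convolution and fully-connected weights are initialised
#' Glorot-uniform from the config seed; batch-norm scale/shift start at
#' 1/0. Training stops at `max_epochs` or when the epoch loss plateaus
#' (see [loss_plateaued()]).
#'
#' @param spec A [build_architecture()] result.
#' @param train_data A labelled [patch_dataset] with both classes present,
#'   or a list `list(X = features-by-patches matrix, y = 0/1 labels)`.
#' @param config A [training_config()].
#' @return An object of class `dwma_cnn`: `spec`, `state` (all weights and
#'   batch-norm statistics), `config`, `training_log` (per-epoch losses)
#'   and `n_train`.
#' @export
train_cnn <- function(spec, train_data, config = training_config()) {
  stopifnot(inherits(spec, "network_spec"))
  dat <- resolve_train_data(train_data, spec$patch_size, config)
  fit <- train_engine(engine_layers(spec), spec$patch_size, dat$X, dat$y,
                      config, epsilon = spec$epsilon)
  structure(
    list(spec = spec, state = fit$state, config = config,
         training_log = fit$training_log, n_train = length(dat$y)),
    class = "dwma_cnn")
}

resolve_train_data <- function(train_data, patch_size, config) {
  if (inherits(train_data, "patch_dataset")) {
    if (train_data$patch_size != patch_size)
      abort(sprintf("patch size mismatch: data %d vs network %d",
                    train_data$patch_size, patch_size))
    if (!"label" %in% names(train_data$centers))
      abort("training requires a labelled patch dataset")
    rows <- cap_training_rows(train_data, config$max_train_patches,
                              derive_seed(config$seed, 31L))
    list(X = patch_matrix(train_data, rows),
         y = train_data$centers$label[rows])
  } else if (is.list(train_data) && all(c("X", "y") %in% names(train_data))) {
    if (nrow(train_data$X) != patch_size^2)
      abort(sprintf("feature dimension %d does not match patch size %d",
                    nrow(train_data$X), patch_size))
    train_data
  } else {
    abort("`train_data` must be a patch_dataset or list(X, y)")
  }
}

#' @export
print.dwma_cnn <- function(x, ...) {
  cat("<dwma_cnn> patch ", x$spec$patch_size, " x ", x$spec$patch_size,
      ", ", nrow(x$spec$layers), " layers, ", count_parameters(x$spec),
      " parameters; trained ", length(x$training_log), " epoch(s) on ",
      x$n_train, " patches (final loss ",
      signif(utils::tail(x$training_log, 1), 4), ")\n", sep = "")
  invisible(x)
}

#' DWMA class probabilities for a patch matrix
#'
#' @param model A fitted classifier (`dwma_cnn`, `dwma_mlp` or `dwma_svm`).
#' @param X Numeric matrix, `patch_size^2` rows by one column per patch.
#' @param ... Unused.
#' @return Numeric vector of DWMA-class probabilities (or decision scores
#'   mapped to `[0, 1]` for the SVM), one per patch.
#' @export
predict_patch_probs <- function(model, X, ...) UseMethod("predict_patch_probs")

#' @export
predict_patch_probs.dwma_cnn <- function(model, X, ...) {
  if (nrow(X) != model$spec$patch_size^2)
    abort(sprintf("patch size mismatch: features %d vs network %d^2",
                  nrow(X), model$spec$patch_size))
  P <- cpp_predict(model$state, X, 1024L)
  P[2, ]  # class order (normal, dwma)
}

#' Segment a subject volume with a trained model
#'
#' Classifies every white-matter voxel from its centred patch. The
#' probability volume holds the DWMA-class softmax output; the binary mask
#' is the argmax decision (DWMA iff probability >= `threshold`). The
#' subject must have been normalized with the same pipeline as the
#' training data.
#'
#' @param model A fitted classifier with a [predict_patch_probs()] method.
#' @param subject A normalized [subject_image()].
#' @param threshold Decision threshold on the DWMA probability.
#' @return List with `probability` (numeric volume, 0 outside white
#'   matter) and `mask` (logical volume, subset of the white-matter mask).
#' @export
predict_volume <- function(model, subject, threshold = 0.5) {
  stopifnot(inherits(subject, "subject_image"))
  psize <- model_patch_size(model)
  pd <- extract_patches(subject, psize, labelled = FALSE)
  p <- predict_patch_probs(model, patch_matrix(pd))
  prob <- array(0, dim(subject$t2))
  prob[subject$wm_mask] <- p
  mask <- array(FALSE, dim(subject$t2))
  mask[subject$wm_mask] <- p >= threshold
  list(probability = prob, mask = mask)
}

model_patch_size <- function(model) UseMethod("model_patch_size")
#' @export
model_patch_size.dwma_cnn <- function(model) model$spec$patch_size
#' @export
model_patch_size.default <- function(model) model$patch_size

#' Model factories for the validation harness
#'
#' A model factory is a function `f(train_patch_dataset, training_config)`
#' returning a fitted classifier usable by [predict_volume()].
#' `cnn_factory(patch_size)` trains the matching [build_architecture()];
#' `mlp_factory()` and `svm_factory()` wrap the baselines.
#'
#' @param patch_size Patch side length.
#' @param ... Passed on to the underlying constructor.
#' @return A factory function.
#' @rdname model_factory
#' @export
cnn_factory <- function(patch_size, ...) {
  spec <- build_architecture(patch_size, ...)
  function(train_data, config) train_cnn(spec, train_data, config)
}
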