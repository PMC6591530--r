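#' Patch-size-specific deep CNN architectures
#'
#' Returns the fixed layer sequence for one of the four supported patch
#' sizes. Each network alternates 3x3 valid convolutions (stride 1, ReLU,
#' no bias), batch normalisation and 2x2 stride-1 max pooling, then a
#' 10-neuron fully-connected layer (ReLU, no bias), batch normalisation,
#' and a 2-way softmax. Biases are omitted wherever a batch-normalisation
#' layer follows, since its shift parameter absorbs them. The 7x7 and 9x9
#' networks have 9 layers (two conv blocks); the 13x13 and 17x17 networks
#' have 12 (three conv blocks).
#'
#' @param patch_size One of 7, 9, 13, 17.
#' @param epsilon Batch-normalisation fuzz constant.
#' @return An object of class `network_spec`: a list with `patch_size`,
#'   `epsilon`, `class_order = c("normal", "dwma")` and `layers`, a tibble
#'   with columns `kind`, `filter_size`, `n_filters`.
#' @examples
#' build_architecture(13)
#' @export
build_architecture <- function(patch_size, epsilon = 1e-5) {
  conv_filters <- switch(as.character(patch_size),
    "7"  = c(8L, 8L),
    "9"  = c(8L, 16L),
    "13" = c(8L, 8L, 16L),
    "17" = c(8L, 16L, 16L),
    abort("unsupported patch size; supported sizes are 7, 9, 13, 17"))
  rows <- list()
  for (nf in conv_filters) {
    rows <- c(rows, list(
      tibble(kind = "convolution", filter_size = 3L, n_filters = nf),
      tibble(kind = "batch_norm", filter_size = NA_integer_,
             n_filters = NA_integer_),
      tibble(kind = "max_pool", filter_size = 2L, n_filters = NA_integer_)))
  }
  rows <- c(rows, list(
    tibble(kind = "fully_connected", filter_size = 10L, n_filters = 10L),
    tibble(kind = "batch_norm", filter_size = NA_integer_,
           n_filters = NA_integer_),
    tibble(kind = "softmax", filter_size = 2L, n_filters = 2L)))
  structure(
    list(patch_size = as.integer(patch_size),
         epsilon = epsilon,
         class_order = c("normal", "dwma"),
         layers = dplyr::bind_rows(rows)),
    class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat("<network_spec> patch ", x$patch_size, " x ", x$patch_size, ", ",
      nrow(x$layers), " layers\n", sep = "")
  print(x$layers, n = nrow(x$layers))
  invisible(x)
}

#' Feature-map shape after every layer
#'
#' Traces the spatial arithmetic of a network: a valid 3x3 convolution
#' shrinks each side by 2, a 2x2 stride-1 max pool by 1; batch
#' normalisation preserves shape; the fully-connected stage flattens.
#'
#' @param spec A [build_architecture()] result.
#' @return Tibble with one row per layer: `layer`, `kind`, `channels`,
#'   `height`, `width`, `flat` (the flattened dimension `channels *
#'   height * width`).
#' @examples
#' forward_shape_trace(build_architecture(13))
#' @export
forward_shape_trace <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  c_ <- 1L; h <- spec$patch_size; w <- spec$patch_size
  out <- vector("list", nrow(spec$layers))
  for (i in seq_len(nrow(spec$layers))) {
    kind <- spec$layers$kind[i]
    if (kind == "convolution") {
      if (h < 3 || w < 3)
        abort(sprintf("layer %d shrinks the feature map below 1x1", i))
      c_ <- spec$layers$n_filters[i]; h <- h - 2L; w <- w - 2L
    } else if (kind == "max_pool") {
      if (h < 2 || w < 2)
        abort(sprintf("layer %d shrinks the feature map below 1x1", i))
      h <- h - 1L; w <- w - 1L
    } else if (kind %in% c("fully_connected", "softmax")) {
      c_ <- spec$layers$n_filters[i]; h <- 1L; w <- 1L
    }
    out[[i]] <- tibble(layer = i, kind = kind, channels = c_,
                       height = h, width = w, flat = c_ * h * w)
  }
  dplyr::bind_rows(out)
}

#' Count trainable parameters of an architecture
#'
#' Convolution weights (`out_c * in_c * 9`), fully-connected weights,
#' batch-norm scale/shift pairs, and the softmax weights and biases.
#'
#' @param spec A [build_architecture()] result.
#' @return Integer.
#' @export
count_parameters <- function(spec) {
  tr <- forward_shape_trace(spec)
  in_flat <- c(spec$patch_size^2, tr$flat[-nrow(tr)])
  in_chan <- c(1L, tr$channels[-nrow(tr)])
  total <- 0L
  for (i in seq_len(nrow(spec$layers))) {
    kind <- spec$layers$kind[i]
    if (kind == "convolution") {
      total <- total + tr$channels[i] * in_chan[i] * 9L
    } else if (kind == "batch_norm") {
      total <- total + 2L * tr$channels[i]
    } else if (kind == "fully_connected") {
      total <- total + tr$channels[i] * in_flat[i]
    } else if (kind == "softmax") {
      total <- total + tr$channels[i] * in_flat[i] + tr$channels[i]
    }
  }
  total
}

# Layer descriptors for the C++ engine.
engine_layers <- function(spec) {
  purrr::pmap(spec$layers, function(kind, filter_size, n_filters) {
    list(kind = kind,
         n_filters = if (is.na(n_filters)) 0L else as.integer(n_filters),
         has_bias = identical(kind, "softmax"))
  })
}
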