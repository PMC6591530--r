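#' Tidy evaluation reports and fitted models
#'
#' `tidy()` on a `dwma_eval` returns the per-subject metric rows; on a
#' `dwma_cnn` the per-layer architecture with parameter counts; on a
#' `dwma_study` the cell summary table. `glance()` gives the one-row
#' overview.
#'
#' @param x The object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.dwma_eval <- function(x, ...) x$per_subject

#' @rdname tidiers
#' @export
glance.dwma_eval <- function(x, ...) {
  s <- x$summary
  out <- tibble(
    n_subjects = nrow(x$per_subject),
    design = x$design$kind,
    dice_mean = s$mean[s$metric == "dice"],
    dice_sd = s$sd[s$metric == "dice"],
    balanced_accuracy_mean = s$mean[s$metric == "balanced_accuracy"],
    balanced_accuracy_sd = s$sd[s$metric == "balanced_accuracy"])
  if (!is.null(x$agreement)) {
    out$dbr_mean_difference <- x$agreement$mean_difference
    out$dbr_lower_limit <- x$agreement$lower_limit
    out$dbr_upper_limit <- x$agreement$upper_limit
  }
  out
}

#' @rdname tidiers
#' @export
tidy.dwma_cnn <- function(x, ...) {
  tr <- forward_shape_trace(x$spec)
  dplyr::mutate(tr, patch_size = x$spec$patch_size)
}

#' @rdname tidiers
#' @export
glance.dwma_cnn <- function(x, ...) {
  tibble(patch_size = x$spec$patch_size,
         n_layers = nrow(x$spec$layers),
         n_parameters = count_parameters(x$spec),
         epochs_trained = length(x$training_log),
         final_loss = utils::tail(x$training_log, 1),
         n_train = x$n_train)
}

#' @rdname tidiers
#' @export
tidy.dwma_study <- function(x, ...) x$summary

#' Plot an evaluation report
#'
#' Per-subject Dice and balanced accuracy as box plots (one box per
#' metric), mirroring how per-architecture detection performance is
#' usually displayed.
#'
#' @param object A `dwma_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dwma_eval <- function(object, ...) {
  df <- object$per_subject |>
    tidyr::pivot_longer(c("dice", "balanced_accuracy"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(width = 0.4, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "per-subject value") +
    ggplot2::theme_minimal()
}

#' Plot a study summary across noise levels
#'
#' Mean Dice and balanced accuracy per (noise SD, architecture) with
#' +/- 1 SD error bars.
#'
#' @param object A `dwma_study`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dwma_study <- function(object, ...) {
  df <- object$summary |>
    tidyr::pivot_longer(
      c("dice_mean", "balanced_accuracy_mean"),
      names_to = "metric", values_to = "mean") |>
    dplyr::mutate(
      sd = ifelse(.data$metric == "dice_mean", .data$dice_sd,
                  .data$balanced_accuracy_sd),
      metric = sub("_mean$", "", .data$metric),
      patch = factor(.data$patch_size))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$noise_sd, y = .data$mean,
                                   colour = .data$patch)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd)) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "Rician noise SD", y = "mean over held-out subjects",
                  colour = "patch size") +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot of DWMA-to-brain ratios
#'
#' @param report A `dwma_eval`.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(report) {
  stopifnot(inherits(report, "dwma_eval"))
  ba <- report$agreement
  df <- report$per_subject |>
    dplyr::mutate(avg = (.data$dbr_pred + .data$dbr_gold) / 2,
                  diff = .data$dbr_pred - .data$dbr_gold)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$avg, y = .data$diff)) +
    ggplot2::geom_point(shape = 8, colour = "blue") +
    ggplot2::geom_hline(yintercept = ba$mean_difference) +
    ggplot2::geom_hline(yintercept = c(ba$lower_limit, ba$upper_limit),
                        linetype = "dashed") +
    ggplot2::labs(x = "mean of predicted and gold DBR",
                  y = "predicted - gold DBR") +
    ggplot2::theme_minimal()
}
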