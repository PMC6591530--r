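#' Dice overlap between two binary masks
#'
#' `2 |A n B| / (|A| + |B|)`. Two empty masks are defined to agree
#' perfectly (returns 1 with a warning); the general case requires at
#' least one non-empty mask.
#'
#' @param mask_a,mask_b Logical arrays on the same grid.
#' @return Number in `[0, 1]`, symmetric in its arguments.
#' @export
dice <- function(mask_a, mask_b) {
  mask_a <- as_mask(mask_a, "mask_a"); mask_b <- as_mask(mask_b, "mask_b")
  check_same_grid(mask_a, mask_b)
  na <- sum(mask_a); nb <- sum(mask_b)
  if (na + nb == 0) {
    warn("both masks are empty; Dice defined as 1 (perfect agreement on absence)")
    return(1)
  }
  2 * sum(mask_a & mask_b) / (na + nb)
}

#' Balanced accuracy from confusion counts
#'
#' `(TP/P + TN/N) / 2`: the mean of sensitivity and specificity, robust to
#' class imbalance and equal to plain accuracy when the model performs
#' equally well on both classes.
#'
#' @param tp,tn True-positive and true-negative counts.
#' @param p,n Positive and negative class sizes (both >= 1).
#' @return Number in `[0, 1]`.
#' @export
balanced_accuracy <- function(tp, p, tn, n) {
  if (p < 1 || n < 1) abort("balanced accuracy undefined: P and N must be >= 1")
  if (tp < 0 || tp > p || tn < 0 || tn > n)
    abort("need 0 <= tp <= p and 0 <= tn <= n")
  (tp / p + tn / n) / 2
}

mask_metrics <- function(pred, gold, wm_mask) {
  p <- sum(gold & wm_mask); n <- sum(wm_mask & !gold)
  tp <- sum(pred & gold); tn <- sum(wm_mask & !pred & !gold)
  list(dice = dice(pred, gold),
       balanced_accuracy = balanced_accuracy(tp, p, tn, n))
}

#' DWMA-to-brain ratio
#'
#' DWMA volume divided by total brain volume; the voxel volume cancels.
#'
#' @param dwma_mask Logical array inside `brain_mask`.
#' @param brain_mask Non-empty logical array.
#' @return Number in `[0, 1]`.
#' @export
dbr <- function(dwma_mask, brain_mask) {
  dwma_mask <- as_mask(dwma_mask, "dwma_mask")
  brain_mask <- as_mask(brain_mask, "brain_mask")
  check_same_grid(dwma_mask, brain_mask)
  if (!any(brain_mask)) abort("`brain_mask` is empty")
  if (any(dwma_mask & !brain_mask)) abort("DWMA voxels outside the brain mask")
  sum(dwma_mask) / sum(brain_mask)
}

#' Bland-Altman agreement of paired measurements
#'
#' Mean difference of `predicted - gold` and the +/- 1.96 sample-SD limits
#' of agreement.
#'
#' @param predicted,gold Numeric vectors of equal length >= 2.
#' @return Tibble with `mean_difference`, `lower_limit`, `upper_limit`,
#'   `sd_difference`, `n`.
#' @export
bland_altman <- function(predicted, gold) {
  if (length(predicted) != length(gold))
    abort("`predicted` and `gold` must have equal length")
  if (length(predicted) < 2) abort("Bland-Altman needs at least 2 pairs")
  d <- predicted - gold
  md <- mean(d); s <- sd(d)
  tibble(mean_difference = md,
         lower_limit = md - 1.96 * s, upper_limit = md + 1.96 * s,
         sd_difference = s, n = length(d))
}

#' Paired t-test between per-subject metric lists
#'
#' Two-sided paired t-test on per-subject differences of the same metric
#' under two models. Zero-variance differences (identical lists) are
#' degenerate: returns `NA` with a warning.
#'
#' @param metric_a,metric_b Equal-length numeric vectors, same subjects in
#'   the same order.
#' @return The p-value.
#' @export
compare_models <- function(metric_a, metric_b) {
  if (length(metric_a) != length(metric_b))
    abort("metric vectors must have equal length")
  d <- metric_a - metric_b
  if (isTRUE(all.equal(sd(d), 0)) || sd(d) == 0) {
    warn("zero variance of paired differences; t-test degenerate, returning NA")
    return(NA_real_)
  }
  t.test(metric_a, metric_b, paired = TRUE)$p.value
}

#' Validation designs
#'
#' Constructors for the designs accepted by [run_validation()]:
#' k-fold cross-validation by subject, leave-one-subject-out, and an
#' explicit holdout split.
#'
#' @param k Number of folds.
#' @param seed Seed for the random fold assignment.
#' @param train_ids,test_ids Disjoint subject id vectors.
#' @return A `validation_design` object.
#' @rdname validation_design
#' @export
design_kfold <- function(k, seed = 1L) {
  structure(list(kind = "kfold", k = as.integer(k), seed = as.integer(seed)),
            class = "validation_design")
}
#' @rdname validation_design
#' @export
design_loso <- function() {
  structure(list(kind = "loso"), class = "validation_design")
}
#' @rdname validation_design
#' @export
design_holdout <- function(train_ids, test_ids) {
  if (length(intersect(train_ids, test_ids)) > 0)
    abort("holdout train and test ids overlap")
  structure(list(kind = "holdout", train_ids = train_ids,
                 test_ids = test_ids),
            class = "validation_design")
}

design_folds <- function(design, ids) {
  switch(design$kind,
    loso = purrr::map(seq_along(ids), function(i)
      list(train = ids[-i], test = ids[i])),
    kfold = {
      ft <- make_folds(ids, design$k, design$seed)
      purrr::map(seq_len(design$k), function(f) {
        te <- ft$subject_id[ft$fold == f]
        list(train = setdiff(ids, te), test = te)
      })
    },
    holdout = {
      missing <- setdiff(c(design$train_ids, design$test_ids), ids)
      if (length(missing) > 0)
        abort(paste("unknown subject id(s):", paste(missing, collapse = ", ")))
      list(list(train = design$train_ids, test = design$test_ids))
    },
    abort("unknown design kind"))
}

#' Run a subject-held-out validation study
#'
#' Trains a model per fold on the training side only and evaluates every
#' held-out subject: Dice and balanced accuracy of the predicted DWMA
#' mask against the gold standard over white matter, plus the predicted
#' and gold DWMA-to-brain ratios. Per-subject patches never cross the
#' train/test boundary.
#'
#' @param subjects Named list of [subject_image()]s with gold masks;
#'   z-score normalized automatically if not already.
#' @param design A `validation_design` (see [design_loso()]).
#' @param model_factory A factory `f(train_patch_dataset, config)`; see
#'   [cnn_factory()].
#' @param config A [training_config()].
#' @param patch_size Patch side length used for extraction.
#' @return An object of class `dwma_eval`: `per_subject` tibble
#'   (`subject_id`, `fold`, `dice`, `balanced_accuracy`, `dbr_pred`,
#'   `dbr_gold`), `summary` tibble (mean and SD per metric), `agreement`
#'   (Bland-Altman of the DBRs) and the `design`.
#' @export
run_validation <- function(subjects, design, model_factory,
                           config = training_config(), patch_size = 13) {
  if (length(subjects) < 2) abort("need at least 2 subjects")
  subjects <- purrr::map(subjects, zscore_subject)
  ids <- purrr::map_chr(subjects, "subject_id")
  if (anyDuplicated(ids)) abort("duplicate subject ids")
  names(subjects) <- ids
  per_subject_patches <- purrr::map(
    subjects, extract_patches, patch_size = patch_size)

  folds <- design_folds(design, ids)
  rows <- list()
  for (f in seq_along(folds)) {
    fold <- folds[[f]]
    if (length(intersect(fold$train, fold$test)) > 0)
      abort("subject appears on both sides of a fold")
    train_pd <- combine_patch_datasets(per_subject_patches[fold$train])
    fold_config <- config
    fold_config$seed <- derive_seed(config$seed, 1000L + f)
    model <- model_factory(train_pd, fold_config)
    for (sid in fold$test) {
      subj <- subjects[[sid]]
      pred <- predict_volume(model, subj)
      m <- mask_metrics(pred$mask, subj$gold_dwma, subj$wm_mask)
      rows[[length(rows) + 1]] <- tibble(
        subject_id = sid, fold = f, dice = m$dice,
        balanced_accuracy = m$balanced_accuracy,
        dbr_pred = dbr(pred$mask, subj$brain_mask),
        dbr_gold = dbr(subj$gold_dwma, subj$brain_mask))
    }
  }
  per_subject <- dplyr::bind_rows(rows)
  new_dwma_eval(per_subject, design)
}

new_dwma_eval <- function(per_subject, design) {
  summary <- per_subject |>
    tidyr::pivot_longer(c("dice", "balanced_accuracy", "dbr_pred",
                          "dbr_gold"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     .groups = "drop")
  agreement <- if (nrow(per_subject) >= 2) {
    bland_altman(per_subject$dbr_pred, per_subject$dbr_gold)
  } else NULL
  structure(list(per_subject = per_subject, summary = summary,
                 agreement = agreement, design = design),
            class = "dwma_eval")
}

#' @export
print.dwma_eval <- function(x, ...) {
  cat("<dwma_eval> ", nrow(x$per_subject), " held-out subject evaluations (",
      x$design$kind, ")\n", sep = "")
  s <- x$summary
  for (m in c("dice", "balanced_accuracy")) {
    r <- s[s$metric == m, ]
    cat("  ", format(m, width = 18), sprintf("%.4f (%.4f)", r$mean, r$sd),
        "\n", sep = "")
  }
  if (!is.null(x$agreement))
    cat("  DBR agreement: mean diff ",
        formatC(x$agreement$mean_difference, format = "e", digits = 2),
        ", limits [",
        formatC(x$agreement$lower_limit, format = "e", digits = 2), ", ",
        formatC(x$agreement$upper_limit, format = "e", digits = 2), "]\n",
        sep = "")
  invisible(x)
}
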