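#' Per-voxel patch samples grouped by subject
#'
#' A `patch_dataset` indexes one n-by-n axial in-plane patch per
#' white-matter voxel of its subjects. Patches are lazily indexed — only the
#' centre coordinates and the source volumes are stored — and materialized
#' on demand by [patch_matrix()], which is indistinguishable from holding
#' the full patch array in memory.
#'
#' @section Fields:
#' `centers` is a tibble with columns `subject_id`, `x`, `y`, `z` and
#' (when labelled) `label` (1 = DWMA centre voxel, 0 = normal white
#' matter); `patch_size` the odd side length; `volumes` a named list of
#' normalized source volumes.
#'
#' @name patch_dataset
NULL

new_patch_dataset <- function(centers, patch_size, volumes) {
  structure(list(centers = centers, patch_size = as.integer(patch_size),
                 volumes = volumes),
            class = "patch_dataset")
}

#' @export
print.patch_dataset <- function(x, ...) {
  cat("<patch_dataset> ", nrow(x$centers), " patches (",
      x$patch_size, " x ", x$patch_size, ") from ",
      length(x$volumes), " subject(s)", sep = "")
  if ("label" %in% names(x$centers))
    cat("; DWMA prevalence ",
        signif(mean(x$centers$label), 3), sep = "")
  cat("\n")
  invisible(x)
}

#' @export
length.patch_dataset <- function(x) nrow(x$centers)

#' Extract per-voxel patches from a subject
#'
#' Emits, for every white-matter voxel, the axial in-plane `patch_size` x
#' `patch_size` neighborhood centred on it (within the voxel's slice),
#' zero-padded where the neighborhood leaves the volume — zero being the
#' background value of a z-scored image. The label of a patch is the
#' gold-standard DWMA status of its centre voxel.
#'
#' @param subject A [subject_image()], normalized (see [zscore_subject()]).
#' @param patch_size Odd patch side length; the shipped architectures
#'   support 7, 9, 13 and 17.
#' @param labelled Attach centre-voxel labels from `gold_dwma` (default
#'   `TRUE`; requires the subject to carry a gold mask).
#' @return A [patch_dataset] with one patch per white-matter voxel.
#' @export
extract_patches <- function(subject, patch_size, labelled = TRUE) {
  stopifnot(inherits(subject, "subject_image"))
  patch_size <- as.integer(patch_size)
  if (patch_size %% 2L == 0L || patch_size < 1L)
    abort("`patch_size` must be a positive odd integer")
  if (labelled && is.null(subject$gold_dwma))
    abort("labels requested but the subject has no `gold_dwma` mask")
  idx <- which(subject$wm_mask, arr.ind = TRUE)
  centers <- tibble(
    subject_id = subject$subject_id,
    x = as.integer(idx[, 1]), y = as.integer(idx[, 2]),
    z = as.integer(idx[, 3]))
  if (labelled)
    centers$label <- as.integer(subject$gold_dwma[subject$wm_mask])
  vols <- setNames(list(subject$t2), subject$subject_id)
  new_patch_dataset(centers, patch_size, vols)
}

#' Materialize patches as a matrix
#'
#' @param dataset A [patch_dataset].
#' @param rows Optional integer row indices into `dataset$centers`.
#' @return Numeric matrix, `patch_size^2` rows by one column per patch
#'   (column-major pixel order within a patch).
#' @export
patch_matrix <- function(dataset, rows = NULL) {
  stopifnot(inherits(dataset, "patch_dataset"))
  cen <- dataset$centers
  if (!is.null(rows)) cen <- cen[rows, , drop = FALSE]
  out <- matrix(0, dataset$patch_size^2, nrow(cen))
  for (sid in unique(cen$subject_id)) {
    sel <- which(cen$subject_id == sid)
    vol <- dataset$volumes[[sid]]
    if (is.null(vol)) abort(sprintf("no source volume for subject '%s'", sid))
    out[, sel] <- cpp_extract_patches(
      vol, as.matrix(cen[sel, c("x", "y", "z")]), dataset$patch_size)
  }
  out
}

combine_patch_datasets <- function(datasets) {
  ps <- unique(purrr::map_int(datasets, "patch_size"))
  if (length(ps) != 1) abort("patch sizes differ across datasets")
  new_patch_dataset(
    dplyr::bind_rows(purrr::map(datasets, "centers")),
    ps,
    purrr::reduce(purrr::map(datasets, "volumes"), c))
}

#' Split subjects into leakage-free train/test patch sets
#'
#' All patches of a subject land on exactly one side of the split.
#'
#' @param subjects Named list of normalized [subject_image()]s (names are
#'   subject ids), or a list of labelled per-subject [patch_dataset]s.
#' @param train_ids,test_ids Disjoint character vectors of subject ids.
#' @param patch_size Patch side length (when `subjects` are images).
#' @return List with `train` and `test` [patch_dataset]s; each carries the
#'   per-class patch counts in attribute `class_counts`.
#' @export
assemble_split <- function(subjects, train_ids, test_ids, patch_size = 13) {
  if (length(intersect(train_ids, test_ids)) > 0)
    abort("`train_ids` and `test_ids` overlap; subject leakage")
  per_subject <- subject_patch_list(subjects, patch_size)
  missing <- setdiff(c(train_ids, test_ids), names(per_subject))
  if (length(missing) > 0)
    abort(paste("unknown subject id(s):", paste(missing, collapse = ", ")))
  out <- list(train = combine_patch_datasets(per_subject[train_ids]),
              test = combine_patch_datasets(per_subject[test_ids]))
  for (side in names(out)) {
    lab <- out[[side]]$centers$label
    attr(out[[side]], "class_counts") <-
      c(normal = sum(lab == 0), dwma = sum(lab == 1))
  }
  out
}

subject_patch_list <- function(subjects, patch_size) {
  if (all(purrr::map_lgl(subjects, inherits, "patch_dataset")))
    return(setNames(subjects,
                    purrr::map_chr(subjects, ~ .x$centers$subject_id[1])))
  pl <- purrr::map(subjects, extract_patches, patch_size = patch_size)
  setNames(pl, purrr::map_chr(pl, ~ .x$centers$subject_id[1]))
}

#' Assign subjects to cross-validation folds
#'
#' Seeded random partition of subject ids into `k` near-equal folds.
#'
#' @param ids Character vector of subject ids.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Tibble with columns `subject_id` and `fold`.
#' @export
make_folds <- function(ids, k, seed = 1L) {
  if (k < 2 || k > length(ids)) abort("`k` must be in [2, number of subjects]")
  fold <- withr::with_seed(as.integer(seed), {
    sample(rep(seq_len(k), length.out = length(ids)))
  })
  tibble(subject_id = ids, fold = fold)
}

# Seeded stratified subsample of training rows, preserving class prevalence
# (no rebalancing). Returns row indices into dataset$centers.
cap_training_rows <- function(dataset, max_patches, seed) {
  n <- nrow(dataset$centers)
  if (is.null(max_patches) || n <= max_patches) return(seq_len(n))
  lab <- dataset$centers$label
  frac <- max_patches / n
  withr::with_seed(as.integer(seed), {
    unlist(lapply(split(seq_len(n), lab), function(ix) {
      sample(ix, max(1L, round(length(ix) * frac)))
    }), use.names = FALSE)
  })
}
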