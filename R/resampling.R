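#' Stratified train/test split
#'
#' Splits row indices into train and test sides preserving class
#' proportions: per class, `round(test_fraction * n_class)` rows go to the
#' test side, so the per-class test proportion is within one row of
#' `test_fraction`. With `group_mode = "patient"`, whole patients are
#' assigned to one side (stratified at the patient level within class), so
#' correlated slices of one patient never straddle the split.
#'
#' @param labels class label per row.
#' @param test_fraction fraction of rows held out (default 0.2).
#' @param seed integer seed; the plan is a pure function of
#'   `(labels, test_fraction, seed, group_mode)`.
#' @param group_mode `"slice"` (default) or `"patient"`.
#' @param patient_ids required for `group_mode = "patient"`.
#' @return object of class `split_plan`: `train`, `test` (integer index
#'   vectors), plus the settings.
#' @export
stratified_split <- function(labels, test_fraction = 0.2, seed = 1L,
                             group_mode = c("slice", "patient"),
                             patient_ids = NULL) {
  group_mode <- match.arg(group_mode)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stopf("both classes must be present")
  if (any(table(labels) < 2)) stopf("each class needs >= 2 rows to split")
  test <- integer(0)
  with_seed(seed, {
    if (group_mode == "slice") {
      for (cl in classes) {
        idx <- which(labels == cl)
        n_test <- round(test_fraction * length(idx))
        test <- c(test, sample(idx, n_test))
      }
    } else {
      if (is.null(patient_ids)) stopf("patient_ids required in patient mode")
      for (cl in classes) {
        pats <- unique(patient_ids[labels == cl])
        n_test <- max(1L, round(test_fraction * length(pats)))
        chosen <- sample(pats, n_test)
        test <- c(test, which(labels == cl & patient_ids %in% chosen))
      }
    }
  })
  test <- sort(test)
  structure(list(train = setdiff(seq_along(labels), test), test = test,
                 test_fraction = test_fraction, stratified = TRUE,
                 group_mode = group_mode, seed = as.integer(seed)),
            class = "split_plan")
}

#' Stratified k-fold plan
#'
#' Assigns each row to one of `k` folds. Rows are shuffled within class and
#' dealt cyclically, the deal continuing across classes, so fold sizes
#' differ by at most one overall and per class.
#'
#' @param labels class label per (training) row.
#' @param k number of folds (default 10).
#' @param stratified deal within class (default TRUE).
#' @param seed integer seed.
#' @return object of class `fold_plan` with `folds` (integer vector in
#'   `1..k`), `k`, `seed`.
#' @export
kfold_plan <- function(labels, k = 10L, stratified = TRUE, seed = 1L) {
  labels <- as.character(labels)
  if (stratified && any(table(labels) < k))
    stopf("every class needs >= k = %d rows for stratified folds", k)
  if (!stratified && length(labels) < k) stopf("fewer rows than folds")
  folds <- integer(length(labels))
  with_seed(seed, {
    if (stratified) {
      pointer <- 0L
      for (cl in sort(unique(labels))) {
        idx <- sample(which(labels == cl))
        folds[idx] <- (pointer + seq_along(idx) - 1L) %% k + 1L
        pointer <- (pointer + length(idx)) %% k
      }
    } else {
      idx <- sample(seq_along(labels))
      folds[idx] <- (seq_along(idx) - 1L) %% k + 1L
    }
  })
  structure(list(folds = folds, k = as.integer(k), stratified = stratified,
                 seed = as.integer(seed)),
            class = "fold_plan")
}

#' SMOTE: synthetic minority oversampling
#'
#' Each synthetic observation is `x + lambda * (x_nn - x)`, where `x` is a
#' uniformly sampled minority row, `x_nn` one of its `k_neighbors` nearest
#' minority neighbors under Euclidean distance (ties broken by lowest row
#' index), and `lambda` is uniform on [0, 1]. Works in normalized feature
#' space; every synthetic value lies within the per-column minority range.
#'
#' @param x numeric matrix or data frame of minority-class feature rows
#'   (>= 2 rows).
#' @param n_synthetic number of synthetic rows to generate.
#' @param k_neighbors neighborhood size (default 5, capped at
#'   `nrow(x) - 1`).
#' @param seed integer seed.
#' @return matrix of `n_synthetic` synthetic rows.
#' @export
smote <- function(x, n_synthetic, k_neighbors = 5L, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) stopf("SMOTE needs at least 2 minority rows")
  k <- min(k_neighbors, n - 1L)
  d <- as.matrix(stats::dist(x))
  # k nearest neighbors per row, self excluded, distance ties by row index
  nn <- t(vapply(seq_len(n), function(i) {
    ord <- order(d[i, ], seq_len(n))
    setdiff(ord, i)[seq_len(k)]
  }, integer(k)))
  if (k == 1) nn <- matrix(nn, ncol = 1)
  with_seed(seed, {
    base <- sample.int(n, n_synthetic, replace = TRUE)
    pick <- sample.int(k, n_synthetic, replace = TRUE)
    lambda <- stats::runif(n_synthetic)
    xb <- x[base, , drop = FALSE]
    xn <- x[nn[cbind(base, pick)], , drop = FALSE]
    xb + lambda * (xn - xb)
  })
}

#' Balance a feature table by SMOTE
#'
#' Augments the minority class with synthetic rows until both classes match
#' the majority count. Synthetic rows get `slice_id` `"synthetic_<n>"`,
#' `patient_id` `"synthetic"`, and the whole table gains a logical
#' `synthetic` provenance column.
#'
#' @param tbl cleaned, normalized feature table with a `label` column.
#' @param k_neighbors,seed passed to [smote()].
#' @return the balanced table.
#' @export
balance_smote <- function(tbl, k_neighbors = 5L, seed = 1L) {
  cnt <- table(tbl$label)
  if (length(cnt) != 2) stopf("balance_smote needs exactly two classes")
  tbl$synthetic <- rep(FALSE, nrow(tbl))
  n_new <- max(cnt) - min(cnt)
  if (n_new == 0) return(tbl)
  minority <- names(cnt)[which.min(cnt)]
  fc <- feature_cols(tbl)
  synth <- smote(tbl[tbl$label == minority, fc, drop = FALSE],
                 n_synthetic = n_new, k_neighbors = k_neighbors, seed = seed)
  add <- tibble::tibble(slice_id = sprintf("synthetic_%04d", seq_len(n_new)),
                        patient_id = "synthetic", label = minority)
  for (j in seq_along(fc)) add[[fc[j]]] <- synth[, j]
  add$synthetic <- TRUE
  rbind(tbl[, c("slice_id", "patient_id", "label", fc, "synthetic")],
        add[, c("slice_id", "patient_id", "label", fc, "synthetic")])
}

#' Balance a feature table by random under-sampling
#'
#' The majority class is subsampled without replacement down to the
#' minority count; every minority row is retained, and no row is
#' synthesized.
#'
#' @param tbl feature table with a `label` column.
#' @param seed integer seed.
#' @return the balanced table (original row order preserved).
#' @export
undersample <- function(tbl, seed = 1L) {
  cnt <- table(tbl$label)
  if (length(cnt) != 2) stopf("undersample needs exactly two classes")
  majority <- names(cnt)[which.max(cnt)]
  keep_maj <- with_seed(seed,
    sample(which(tbl$label == majority), min(cnt)))
  keep <- sort(c(which(tbl$label != majority), keep_maj))
  tbl[keep, , drop = FALSE]
}
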