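#' One split-balance-train-evaluate pass over a feature table
#'
#' The single-run backbone of every experiment: stratified 80/20 split,
#' optional class balancing (`"smote"`, `"undersample"`, or `"none"`),
#' min-max normalization, random-forest (or any [model_spec()]) training,
#' and evaluation on the held-out rows.
#'
#' Two orders of operations are supported. The default, `order =
#' "split-first"`, splits before balancing and fits the normalization on
#' the training rows only, so no information about the test rows — real or
#' synthetic — reaches the classifier. `order = "balance-first"` balances the full
#' table first and normalizes on all rows before splitting; synthetic
#' points interpolated from eventual test rows can then land in the
#' training side, which typically inflates the measured accuracy. Both are
#' first-class so the two protocols can be compared.
#'
#' @param tbl cleaned (complete-case), un-normalized feature table.
#' @param strategy `"none"`, `"smote"`, or `"undersample"`.
#' @param model a [model_spec()].
#' @param test_fraction held-out fraction (default 0.2).
#' @param order `"split-first"` (default) or `"balance-first"`.
#' @param seed integer seed driving split, balancing and model.
#' @return list: `metrics` (per-class tibble), `counts`, `auc`,
#'   `accuracy`, `split`, `model`.
#' @export
run_once <- function(tbl, strategy = c("none", "smote", "undersample"),
                     model = model_spec("RF"), test_fraction = 0.2,
                     order = c("split-first", "balance-first"), seed = 1L) {
  strategy <- match.arg(strategy)
  order <- match.arg(order)
  fc <- feature_cols(tbl)
  if (order == "balance-first") {
    norm <- minmax_normalize(tbl)
    work <- norm$table
    if (strategy == "smote")
      work <- balance_smote(work, seed = derive_seed(seed, 2))
    else if (strategy == "undersample")
      work <- undersample(work, seed = derive_seed(seed, 2))
    split <- stratified_split(work$label, test_fraction,
                              seed = derive_seed(seed, 1))
    train <- work[split$train, , drop = FALSE]
    test <- work[split$test, , drop = FALSE]
  } else {
    split <- stratified_split(tbl$label, test_fraction,
                              seed = derive_seed(seed, 1))
    norm <- minmax_normalize(tbl, fit_rows = split$train)
    work <- norm$table
    train <- work[split$train, , drop = FALSE]
    test <- work[split$test, , drop = FALSE]
    if (strategy == "smote")
      train <- balance_smote(train, seed = derive_seed(seed, 2))
    else if (strategy == "undersample")
      train <- undersample(train, seed = derive_seed(seed, 2))
  }
  fc <- feature_cols(train)
  fit <- fit_model(model, train[, fc, drop = FALSE], train$label)
  pred <- predict_model(fit, test[, fc, drop = FALSE])
  counts <- confusion_counts(test$label, pred$labels)
  metrics <- class_metrics(counts)
  list(metrics = metrics, counts = counts,
       auc = roc_auc(pred$scores, factor(test$label))$auc,
       accuracy = metrics$accuracy[1], split = split, model = fit)
}

#' Repeated-run experiment
#'
#' Repeats [run_once()] `n_runs` times with seeds derived from the master
#' seed, returning one row per run with the test accuracy and the
#' per-class recalls. Feed the accuracy columns of two strategies to
#' [compare_runs()] for the paired statistical comparison.
#'
#' @param tbl cleaned feature table.
#' @param strategy,model,test_fraction,order as in [run_once()].
#' @param n_runs number of independent repetitions (default 100).
#' @param seed master seed.
#' @return tibble: run, accuracy, auc, recall_class0, recall_class1.
#' @export
run_experiment <- function(tbl, strategy = "none", n_runs = 100L,
                           model = model_spec("RF"), test_fraction = 0.2,
                           order = "split-first", seed = 1L) {
  rows <- lapply(seq_len(n_runs), function(r) {
    res <- run_once(tbl, strategy = strategy, model = model,
                    test_fraction = test_fraction, order = order,
                    seed = derive_seed(seed, 100, r))
    tibble::tibble(run = r, accuracy = res$accuracy, auc = res$auc,
                   recall_class0 = res$metrics$recall[1],
                   recall_class1 = res$metrics$recall[2])
  })
  do.call(rbind, rows)
}
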