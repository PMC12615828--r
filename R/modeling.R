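ALGORITHMS <- c("KNN", "LR", "RF", "DTC", "GaussianNB", "SVM", "ADA")

#' Specify a classifier
#'
#' The closed set of benchmarked algorithms: K-nearest neighbors (`KNN`),
#' logistic regression (`LR`), random forest (`RF`), decision tree
#' (`DTC`), Gaussian naive Bayes (`GaussianNB`), support vector machine
#' with radial kernel (`SVM`), and AdaBoost over depth-1 stumps (`ADA`).
#' Hyperparameters default to each backend's library defaults; for `RF`
#' the sklearn-style names `n_estimators`, `max_depth`,
#' `min_samples_split`, `min_samples_leaf`, `bootstrap` are accepted and
#' mapped onto ranger's `num.trees`, `max.depth`, `min.node.size`,
#' `min.bucket`, `replace`/`sample.fraction`.
#'
#' @param algorithm one of `r paste(ALGORITHMS, collapse = ", ")`.
#' @param hyperparameters named list.
#' @param seed integer seed recorded in the spec and used by stochastic
#'   learners.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(algorithm = "RF", hyperparameters = list(),
                       seed = 42L) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  structure(list(algorithm = algorithm, hyperparameters = hyperparameters,
                 seed = as.integer(seed)),
            class = "model_spec")
}

# SAMME-style AdaBoost over rpart stumps (no boosting package ships with
# the environment's R stack, and the weak-learner loop is ~25 lines)
adaboost_fit <- function(x, y, n_rounds = 50L, seed = 42L) {
  df <- data.frame(x, .y = y)
  w <- rep(1 / nrow(df), nrow(df))
  stumps <- list(); alphas <- numeric(0)
  with_seed(seed, for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = rpart::rpart.control(maxdepth = 1,
                                                       cp = -1, xval = 0,
                                                       minsplit = 2))
    pred <- stats::predict(fit, df, type = "class")
    err <- sum(w * (pred != y)) / sum(w)
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    w <- w * exp(alpha * ifelse(pred != y, 1, -1))
    w <- w / sum(w)
    stumps[[m]] <- fit; alphas[m] <- alpha
    if (err < 1e-9) break
  })
  list(stumps = stumps, alphas = alphas, levels = levels(y))
}

adaboost_score <- function(fit, x) {
  if (length(fit$stumps) == 0) return(rep(0.5, nrow(x)))
  margin <- rep(0, nrow(x))
  for (m in seq_along(fit$stumps)) {
    pred <- stats::predict(fit$stumps[[m]], data.frame(x), type = "class")
    margin <- margin + fit$alphas[m] * ifelse(pred == fit$levels[2], 1, -1)
  }
  # weighted-vote margin mapped to [0, 1]
  (margin / sum(fit$alphas) + 1) / 2
}

rf_args <- function(hp) {
  args <- list(num.trees = hp$n_estimators %||% 500L)
  md <- hp$max_depth
  if (!is.null(md) && !is.na(md)) args$max.depth <- md
  if (!is.null(hp$min_samples_split)) args$min.node.size <- hp$min_samples_split
  if (!is.null(hp$min_samples_leaf)) args$min.bucket <- hp$min_samples_leaf
  if (!is.null(hp$bootstrap)) {
    args$replace <- hp$bootstrap
    args$sample.fraction <- 1
  }
  args
}

#' Fit a classifier on a feature table
#'
#' @param spec a [model_spec()].
#' @param x data frame of (normalized) feature columns.
#' @param y class labels (coerced to a two-level factor; the second level
#'   is the positive class for scores).
#' @return object of class `clb_model` carrying the fitted backend and the
#'   training feature names.
#' @export
fit_model <- function(spec, x, y) {
  x <- as.data.frame(x)
  y <- factor(y)
  hp <- spec$hyperparameters
  fit <- switch(spec$algorithm,
    KNN = list(x = as.matrix(x), y = y, k = hp$k %||% 5L),
    LR = suppressWarnings(
      stats::glm(.y ~ ., data = data.frame(x, .y = y),
                 family = stats::binomial())),
    RF = do.call(ranger::ranger,
                 c(list(x = x, y = y, probability = TRUE, seed = spec$seed),
                   rf_args(hp))),
    DTC = rpart::rpart(.y ~ ., data = data.frame(x, .y = y),
                       method = "class"),
    GaussianNB = e1071::naiveBayes(x, y),
    SVM = e1071::svm(x, y, kernel = "radial", probability = TRUE),
    ADA = adaboost_fit(x, y, n_rounds = hp$n_rounds %||% 50L,
                       seed = spec$seed))
  structure(list(spec = spec, fit = fit, levels = levels(y),
                 features = names(x)),
            class = "clb_model")
}

#' Predict hard labels and class-1 scores
#'
#' Scores are the probability (or a probability-scaled decision value) of
#' the second factor level — the minority/positive class — and lie in
#' [0, 1]; row order is preserved.
#'
#' @param model a fitted [fit_model()] object.
#' @param newdata data frame with exactly the training feature columns.
#' @return list with `labels` (factor) and `scores` (numeric).
#' @export
predict_model <- function(model, newdata) {
  newdata <- as.data.frame(newdata)
  missing <- setdiff(model$features, names(newdata))
  if (length(missing) > 0)
    stopf("newdata lacks training feature column(s): %s",
          paste(missing, collapse = ", "))
  x <- newdata[, model$features, drop = FALSE]
  pos <- model$levels[2]
  scores <- switch(model$spec$algorithm,
    KNN = {
      pr <- class::knn(model$fit$x, as.matrix(x), model$fit$y,
                       k = model$fit$k, prob = TRUE)
      p <- attr(pr, "prob")
      ifelse(pr == pos, p, 1 - p)
    },
    LR = as.numeric(stats::predict(model$fit, data.frame(x),
                                   type = "response")),
    RF = stats::predict(model$fit, data = x)$predictions[, pos],
    DTC = stats::predict(model$fit, data.frame(x), type = "prob")[, pos],
    GaussianNB = stats::predict(model$fit, x, type = "raw")[, pos],
    SVM = {
      pr <- stats::predict(model$fit, x, probability = TRUE)
      attr(pr, "probabilities")[, pos]
    },
    ADA = adaboost_score(model$fit, x))
  labels <- factor(ifelse(scores > 0.5, pos, model$levels[1]),
                   levels = model$levels)
  list(labels = labels, scores = as.numeric(scores))
}

#' Ten-fold cross-validation benchmark of the seven classifiers
#'
#' For each algorithm and each fold of the plan: train on the other k-1
#' folds with library-default hyperparameters, score accuracy on the
#' held-out fold. A fold whose training side contains a single class is
#' skipped with a warning. The summary SD is the population standard
#' deviation of the per-fold accuracies.
#'
#' @param tbl cleaned, normalized feature table with a `label` column.
#' @param fold_plan a [kfold_plan()] over the rows of `tbl`.
#' @param algorithms subset of the seven (default: all).
#' @param seed seed forwarded to stochastic learners.
#' @return tibble of class `bench_result`: algorithm, mean_accuracy,
#'   sd_accuracy; per-fold accuracies in the `"fold_accuracies"` attribute
#'   (algorithms x folds matrix).
#' @export
crossval_bench <- function(tbl, fold_plan, algorithms = ALGORITHMS,
                           seed = 42L) {
  fc <- feature_cols(tbl)
  x <- tbl[, fc, drop = FALSE]
  y <- factor(tbl$label)
  k <- fold_plan$k
  per_fold <- matrix(NA_real_, length(algorithms), k,
                     dimnames = list(algorithms, NULL))
  for (a in seq_along(algorithms)) {
    spec <- model_spec(algorithms[a], seed = seed)
    for (f in seq_len(k)) {
      tr <- fold_plan$folds != f
      if (length(unique(y[tr])) < 2) {
        warnf("fold %d skipped for %s: single-class training side",
              f, algorithms[a])
        next
      }
      fit <- fit_model(spec, x[tr, , drop = FALSE], y[tr])
      pred <- predict_model(fit, x[!tr, , drop = FALSE])
      per_fold[a, f] <- mean(pred$labels == y[!tr])
    }
  }
  out <- tibble::tibble(
    algorithm = algorithms,
    mean_accuracy = unname(apply(per_fold, 1, mean, na.rm = TRUE)),
    sd_accuracy = unname(apply(per_fold, 1,
                               function(v) sd_pop(v[!is.na(v)]))))
  attr(out, "fold_accuracies") <- per_fold
  class(out) <- c("bench_result", class(out))
  out
}

#' The default random-forest tuning grid
#'
#' `n_estimators` 50/100/200/300, `max_depth` unlimited/10/20/30/40,
#' `min_samples_split` 2/5/10, `min_samples_leaf` 1/2/4, `bootstrap`
#' true/false — 360 configurations.
#'
#' @return named list of value vectors (`NA` encodes unlimited depth).
#' @export
grid_spec <- function() {
  list(n_estimators = c(50L, 100L, 200L, 300L),
       max_depth = c(NA, 10L, 20L, 30L, 40L),
       min_samples_split = c(2L, 5L, 10L),
       min_samples_leaf = c(1L, 2L, 4L),
       bootstrap = c(TRUE, FALSE))
}

#' Exhaustive grid search for the random forest
#'
#' Every configuration of the grid is scored by k-fold cross-validated
#' accuracy on the training table. Ties are broken by higher mean
#' accuracy, then lower fold SD, then first position in lexicographic grid
#' order (the order the ranges are printed in). The winner is refitted on
#' the full table.
#'
#' @param tbl cleaned, normalized training feature table.
#' @param fold_plan a [kfold_plan()] over its rows.
#' @param grid a [grid_spec()]-style named list.
#' @param seed model seed.
#' @return list: `best_params`, `model` (refit on all rows), `cv_score`,
#'   `cv_sd`, and `results` (one row per configuration).
#' @export
grid_search_rf <- function(tbl, fold_plan, grid = grid_spec(), seed = 42L) {
  fc <- feature_cols(tbl)
  x <- tbl[, fc, drop = FALSE]
  y <- factor(tbl$label)
  configs <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE,
                         stringsAsFactors = FALSE)
  # expand.grid varies the first column fastest; reorder so the *last*
  # listed hyperparameter varies fastest, i.e. lexicographic in the printed
  # order
  configs <- configs[do.call(order, configs[, seq_along(grid), drop = FALSE]), ]
  rownames(configs) <- NULL
  k <- fold_plan$k
  means <- numeric(nrow(configs)); sds <- numeric(nrow(configs))
  for (i in seq_len(nrow(configs))) {
    hp <- as.list(configs[i, ])
    spec <- model_spec("RF", hyperparameters = hp, seed = seed)
    accs <- numeric(0)
    for (f in seq_len(k)) {
      tr <- fold_plan$folds != f
      fit <- fit_model(spec, x[tr, , drop = FALSE], y[tr])
      pred <- predict_model(fit, x[!tr, , drop = FALSE])
      accs <- c(accs, mean(pred$labels == y[!tr]))
    }
    means[i] <- mean(accs); sds[i] <- sd_pop(accs)
  }
  best <- order(-means, sds, seq_len(nrow(configs)))[1]
  best_hp <- as.list(configs[best, ])
  model <- fit_model(model_spec("RF", hyperparameters = best_hp, seed = seed),
                     x, y)
  results <- tibble::as_tibble(configs)
  results$cv_accuracy <- means
  results$cv_sd <- sds
  list(best_params = best_hp, model = model,
       cv_score = means[best], cv_sd = sds[best], results = results)
}
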