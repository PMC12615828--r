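feature_cols <- function(tbl) intersect(feature_names(), names(tbl))

#' Drop rows with missing feature cells
#'
#' Rows containing any missing feature value (degenerate slices: zero
#' variance, undefined GLCM correlation, ...) are removed, mirroring the
#' elimination of null values before modeling. A per-column missingness
#' report is attached as the `"missingness"` attribute and printed as a
#' message.
#'
#' @param tbl feature table from [extract_cohort()].
#' @param quiet suppress the report message.
#' @return the table without incomplete rows.
#' @export
drop_missing <- function(tbl, quiet = FALSE) {
  fc <- feature_cols(tbl)
  miss <- vapply(tbl[fc], function(x) sum(is.na(x)), integer(1))
  report <- tibble::tibble(feature = fc, n_missing = unname(miss))
  keep <- stats::complete.cases(tbl[fc])
  if (!any(keep)) stopf("drop_missing: every row has a missing feature")
  if (!quiet && any(miss > 0))
    message(sprintf("dropping %d row(s) with missing values (%s)",
                    sum(!keep),
                    paste(sprintf("%s: %d", fc[miss > 0], miss[miss > 0]),
                          collapse = ", ")))
  out <- tbl[keep, , drop = FALSE]
  attr(out, "missingness") <- report
  out
}

#' Min-max normalization of the feature columns
#'
#' Each feature is rescaled as `(x - x_min) / (x_max - x_min)`, with the
#' extrema taken over `fit_rows` (all rows by default); the identical
#' transform is applied to the remaining rows, whose values may fall
#' outside `[0, 1]`. Features that are constant on the fitting rows carry
#' no information under this scaling and are dropped with a warning.
#' A z-score alternative (`method = "zscore"`) is available.
#'
#' @param tbl feature table.
#' @param fit_rows integer/logical row subset the parameters are estimated
#'   on (default: all rows). Fitting on training rows only avoids
#'   information leaking from the test side.
#' @param method `"minmax"` (default) or `"zscore"`.
#' @return list with `table` (transformed) and `params` (tibble: feature,
#'   min, max — or mean, sd).
#' @export
minmax_normalize <- function(tbl, fit_rows = NULL,
                             method = c("minmax", "zscore")) {
  method <- match.arg(method)
  fc <- feature_cols(tbl)
  if (is.null(fit_rows)) fit_rows <- seq_len(nrow(tbl))
  fit <- tbl[fit_rows, fc, drop = FALSE]
  if (nrow(fit) == 0) stopf("minmax_normalize: empty fitting subset")
  if (method == "minmax") {
    lo <- vapply(fit, min, numeric(1))
    hi <- vapply(fit, max, numeric(1))
    const <- hi <= lo
    params <- tibble::tibble(feature = fc, min = unname(lo), max = unname(hi))
  } else {
    mu <- vapply(fit, mean, numeric(1))
    sg <- vapply(fit, stats::sd, numeric(1))
    const <- sg == 0
    params <- tibble::tibble(feature = fc, mean = unname(mu), sd = unname(sg))
  }
  if (any(const)) {
    drop_f <- fc[const]
    warnf("dropping constant feature(s) on the fitting rows: %s",
          paste(drop_f, collapse = ", "))
    params <- params[!const, , drop = FALSE]
    tbl <- tbl[, setdiff(names(tbl), drop_f), drop = FALSE]
  }
  out <- apply_normalization(tbl, params)
  list(table = out, params = params)
}

#' Apply previously fitted normalization parameters
#'
#' @param tbl feature table containing the features named in `params`.
#' @param params the `params` tibble returned by [minmax_normalize()].
#' @return the transformed table.
#' @export
apply_normalization <- function(tbl, params) {
  for (i in seq_len(nrow(params))) {
    f <- params$feature[i]
    if (!f %in% names(tbl)) stopf("feature '%s' absent from table", f)
    if ("min" %in% names(params))
      tbl[[f]] <- (tbl[[f]] - params$min[i]) / (params$max[i] - params$min[i])
    else
      tbl[[f]] <- (tbl[[f]] - params$mean[i]) / params$sd[i]
  }
  tbl
}

#' Two-group one-way ANOVA F-test
#'
#' `F = MS_between / MS_within` with degrees of freedom (1, n - 2); for two
#' groups this equals the squared pooled two-sample t statistic. The
#' p-value comes from the F distribution.
#'
#' @param x numeric feature values.
#' @param g two-level grouping (class labels).
#' @return list with `f`, `p`, `df1`, `df2`.
#' @export
anova_f <- function(x, g) {
  g <- as.factor(g)
  if (nlevels(droplevels(g)) != 2)
    stopf("anova_f needs exactly two groups, got %d", nlevels(droplevels(g)))
  n_g <- table(g)
  if (any(n_g < 2)) stopf("anova_f: each group needs >= 2 observations")
  n <- length(x)
  gm <- mean(x)
  means <- tapply(x, g, mean)
  ssb <- sum(n_g * (means - gm)^2)
  ssw <- sum((x - means[g])^2)
  df2 <- n - 2L
  if (ssw == 0 && ssb == 0)
    return(list(f = NA_real_, p = NA_real_, df1 = 1L, df2 = df2))
  f <- (ssb / 1) / (ssw / df2)
  list(f = f, p = stats::pf(f, 1, df2, lower.tail = FALSE),
       df1 = 1L, df2 = df2)
}

#' F-test ranking of every feature
#'
#' @param tbl cleaned feature table.
#' @param rows optional row subset to compute the test on (e.g. training
#'   rows).
#' @return tibble: feature, f, p, ordered by increasing F.
#' @export
anova_rank <- function(tbl, rows = NULL) {
  if (!is.null(rows)) tbl <- tbl[rows, , drop = FALSE]
  fc <- feature_cols(tbl)
  res <- lapply(fc, function(f) anova_f(tbl[[f]], tbl$label))
  out <- tibble::tibble(feature = fc,
                        f = vapply(res, `[[`, numeric(1), "f"),
                        p = vapply(res, `[[`, numeric(1), "p"))
  out[order(out$f), , drop = FALSE]
}

#' Sequential-elimination ladder
#'
#' Ranks features by the ANOVA F-test and removes them one at a time from
#' least to most significant, retraining the classifier at each rung.
#' Row `i` of the ladder reports: the feature with the lowest F among the
#' `n_features` still present, its F-score and p-value, and the held-out
#' accuracy of the model trained on those `n_features` *before* the removal
#' — so the first row is the all-features baseline and the last row is the
#' single-best-feature model.
#'
#' By default F-scores are computed on the training rows only; `mode =
#' "full-table"` computes them on the full table (ranking before splitting).
#'
#' @param tbl cleaned, normalized feature table.
#' @param model a [model_spec()] retrained at each rung (default: random
#'   forest with library-default hyperparameters, seed 42).
#' @param split a [stratified_split()] plan; built from `seed` if omitted.
#' @param test_fraction,seed split parameters when `split` is `NULL`.
#' @param mode `"train-only"` (default) or `"full-table"`.
#' @return tibble of class `selection_ladder`: removed_feature, f_score,
#'   p_value, n_features, accuracy.
#' @export
sequential_elimination <- function(tbl, model = model_spec("RF", seed = 42L),
                                   split = NULL, test_fraction = 0.2,
                                   seed = 1L,
                                   mode = c("train-only", "full-table")) {
  mode <- match.arg(mode)
  fc <- feature_cols(tbl)
  if (length(fc) < 2) stopf("need at least two features")
  if (is.null(split))
    split <- stratified_split(tbl$label, test_fraction = test_fraction,
                              seed = seed)
  rank_rows <- if (mode == "full-table") NULL else split$train
  ranking <- anova_rank(tbl, rows = rank_rows)   # ascending F; fixed, since
  remaining <- ranking$feature                   # the test is univariate
  recs <- vector("list", length(remaining))
  for (i in seq_along(ranking$feature)) {
    fit <- fit_model(model, tbl[split$train, remaining, drop = FALSE],
                     tbl$label[split$train])
    pred <- predict_model(fit, tbl[split$test, remaining, drop = FALSE])
    acc <- mean(pred$labels == tbl$label[split$test])
    recs[[i]] <- tibble::tibble(removed_feature = ranking$feature[i],
                                f_score = ranking$f[i],
                                p_value = ranking$p[i],
                                n_features = length(remaining),
                                accuracy = acc)
    remaining <- setdiff(remaining, ranking$feature[i])
  }
  out <- do.call(rbind, recs)
  class(out) <- c("selection_ladder", class(out))
  out
}
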