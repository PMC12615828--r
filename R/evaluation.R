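#' One-vs-rest confusion counts for both classes
#'
#' Counts TP/TN/FP/FN treating each class in turn as positive; class 0 is
#' the first factor level ("IDC"), class 1 the second ("ILC"). The counts
#' of the two classes are mirror images (TP of one is TN of the other).
#'
#' @param truth,pred equal-length label vectors over the same two classes.
#' @return tibble of class `confusion_counts`: class, level, TP, TN, FP,
#'   FN, support.
#' @export
confusion_counts <- function(truth, pred) {
  if (length(truth) != length(pred))
    stopf("length mismatch: %d true vs %d predicted labels",
          length(truth), length(pred))
  lev <- levels(factor(as.character(truth)))
  if (length(lev) > 2) stopf("binary labels expected")
  if (length(lev) == 1) lev <- sort(unique(c(lev, as.character(pred))))
  truth <- factor(as.character(truth), levels = lev)
  pred <- factor(as.character(pred), levels = lev)
  rows <- lapply(1:2, function(ci) {
    pos <- lev[ci]
    tibble::tibble(class = ci - 1L, level = pos,
                   TP = sum(truth == pos & pred == pos),
                   TN = sum(truth != pos & pred != pos),
                   FP = sum(truth != pos & pred == pos),
                   FN = sum(truth == pos & pred != pos),
                   support = sum(truth == pos))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("confusion_counts", class(out))
  out
}

#' Build confusion counts directly from per-class totals
#'
#' Convenience for recomputing metrics from a printed confusion matrix:
#' give the number of correct predictions and the support of each class.
#'
#' @param correct0,support0 correctly classified / total class-0 rows.
#' @param correct1,support1 same for class 1.
#' @param levels class labels (default IDC/ILC).
#' @return a [confusion_counts()] tibble.
#' @export
confusion_from_totals <- function(correct0, support0, correct1, support1,
                                  levels = c("IDC", "ILC")) {
  truth <- rep(levels, c(support0, support1))
  pred <- c(rep(levels, c(correct0, support0 - correct0)),
            rep(rev(levels), c(correct1, support1 - correct1)))
  confusion_counts(truth, pred)
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' Accuracy is `(TP + TN) / (TP + TN + FP + FN)` (identical for both
#' one-vs-rest views); precision `TP / (TP + FP)`; recall
#' `TP / (TP + FN)`; F1 the harmonic mean of the two. A zero denominator
#' yields `NA` for that metric.
#'
#' @param counts a [confusion_counts()] tibble.
#' @return tibble: class, level, precision, recall, f1, support, accuracy.
#' @export
class_metrics <- function(counts) {
  safe_div <- function(a, b) ifelse(b == 0, NA_real_, a / b)
  pr <- safe_div(counts$TP, counts$TP + counts$FP)
  rc <- safe_div(counts$TP, counts$TP + counts$FN)
  f1 <- ifelse(is.na(pr) | is.na(rc) | pr + rc == 0, NA_real_,
               2 * pr * rc / (pr + rc))
  acc <- (counts$TP + counts$TN) /
    (counts$TP + counts$TN + counts$FP + counts$FN)
  tibble::tibble(class = counts$class, level = counts$level,
                 precision = pr, recall = rc, f1 = f1,
                 support = counts$support, accuracy = acc)
}

#' Harmonic mean of precision and recall
#'
#' @param precision,recall metric values in [0, 1].
#' @return the F1 score.
#' @export
f1_score <- function(precision, recall) {
  2 * precision * recall / (precision + recall)
}

#' Round metrics the way classification reports print them
#'
#' Precision/recall/F1 to two decimals; accuracy additionally as an
#' integer percent.
#'
#' @param metrics output of [class_metrics()].
#' @return the tibble with rounded columns plus `accuracy_pct`.
#' @export
format_metrics <- function(metrics) {
  metrics$precision <- round(metrics$precision, 2)
  metrics$recall <- round(metrics$recall, 2)
  metrics$f1 <- round(metrics$f1, 2)
  metrics$accuracy_pct <- round(metrics$accuracy * 100)
  metrics
}

#' ROC curve and AUC
#'
#' Sweeps every distinct score as a threshold, computing (FPR, TPR)
#' points, and integrates by the trapezoidal rule. [auc_rank()] gives the
#' equivalent rank-statistic (Mann-Whitney) formulation with midranked
#' ties; the two agree and serve as mutual cross-checks.
#'
#' @param scores class-1 scores, higher = more class-1.
#' @param truth labels; the second factor level is the positive class.
#' @return list: `points` (tibble fpr/tpr, decreasing threshold) and
#'   `auc`.
#' @export
roc_auc <- function(scores, truth) {
  truth <- factor(as.character(truth))
  if (nlevels(truth) != 2) stopf("ROC needs both classes present")
  pos <- truth == levels(truth)[2]
  n1 <- sum(pos); n0 <- sum(!pos)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(pos[ord]); fp <- cumsum(!pos[ord])
  last <- !duplicated(scores[ord], fromLast = TRUE)  # one point per threshold
  tpr <- c(0, tp[last] / n1); fpr <- c(0, fp[last] / n0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = tibble::tibble(fpr = fpr, tpr = tpr), auc = auc)
}

#' @rdname roc_auc
#' @export
auc_rank <- function(scores, truth) {
  truth <- factor(as.character(truth))
  if (nlevels(truth) != 2) stopf("AUC needs both classes present")
  pos <- truth == levels(truth)[2]
  r <- rank(scores)                       # midranks for ties
  n1 <- sum(pos); n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' Paired statistical comparison of two run-accuracy series
#'
#' Given paired per-run accuracies of two strategies (e.g. original vs
#' SMOTE over repeated splits), computes the paired t-test
#' (`t = mean(d) / (sd(d)/sqrt(R))`, sample SD), the Wilcoxon signed-rank
#' test (zero differences dropped, ties midranked; `W` is the smaller of
#' the two signed-rank sums; normal approximation with continuity
#' correction for more than 25 nonzero pairs, exact otherwise), and a
#' percentile bootstrap confidence interval of the mean difference.
#'
#' @param a,b equal-length accuracy vectors (difference `d = a - b`).
#' @param n_boot bootstrap resamples (default 10000).
#' @param conf_level CI level (default 0.95).
#' @param seed bootstrap seed.
#' @return object of class `run_comparison`.
#' @export
compare_runs <- function(a, b, n_boot = 10000L, conf_level = 0.95,
                         seed = 1L) {
  if (length(a) != length(b)) stopf("paired series must have equal length")
  if (length(a) < 2) stopf("need at least two paired runs")
  d <- a - b
  if (all(d == 0)) {
    warnf("all paired differences are zero: t undefined, W degenerate")
    tt <- list(statistic = NA_real_, p.value = NA_real_)
    w_stat <- NA_real_; w_p <- NA_real_
  } else {
    tt <- stats::t.test(a, b, paired = TRUE)
    nz <- sum(d != 0)
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, paired = TRUE, exact = nz <= 25,
                         correct = TRUE))
    v <- unname(wt$statistic)             # sum of positive ranks
    w_stat <- min(v, nz * (nz + 1) / 2 - v)
    w_p <- wt$p.value
  }
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot),
           function(i) mean(d[sample.int(length(d), replace = TRUE)]),
           numeric(1))
  })
  alpha <- (1 - conf_level) / 2
  ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha)))
  structure(list(mean_difference = mean(d),
                 t_statistic = unname(tt$statistic), t_p = tt$p.value,
                 w_statistic = w_stat, w_p = w_p,
                 ci_lower = ci[1], ci_upper = ci[2],
                 conf_level = conf_level, n_runs = length(a),
                 n_boot = n_boot, seed = as.integer(seed)),
            class = "run_comparison")
}

#' @export
print.run_comparison <- function(x, ...) {
  cat(sprintf("<run_comparison> R = %d runs\n", x$n_runs))
  cat(sprintf("  mean difference: %.4f  (%.0f%% bootstrap CI %.4f .. %.4f)\n",
              x$mean_difference, 100 * x$conf_level, x$ci_lower, x$ci_upper))
  cat(sprintf("  paired t: t = %.3f, p = %.3g\n", x$t_statistic, x$t_p))
  cat(sprintf("  Wilcoxon signed-rank: W = %.1f, p = %.3g\n",
              x$w_statistic, x$w_p))
  invisible(x)
}
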