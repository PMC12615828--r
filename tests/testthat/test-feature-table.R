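make_table <- function(n0 = 30, n1 = 20, seed = 1,
                       effects = c(a = 2, b = 1, c = 0)) {
  withr::with_seed(seed, {
    lab <- rep(c("IDC", "ILC"), c(n0, n1))
    tbl <- tibble::tibble(
      slice_id = sprintf("s%03d", seq_len(n0 + n1)),
      patient_id = sprintf("p%03d", seq_len(n0 + n1)),
      label = lab)
    shift <- as.numeric(lab == "ILC")
    tbl$mean <- stats::rnorm(n0 + n1) + effects["a"] * shift
    tbl$entropy <- stats::rnorm(n0 + n1) + effects["b"] * shift
    tbl$glcm_contrast <- stats::rnorm(n0 + n1) + effects["c"] * shift
    tbl
  })
}

test_that("drop_missing removes incomplete rows and reports counts", {
  tbl <- make_table(6, 4)
  tbl$glcm_correlation <- c(NA, NA, stats::rnorm(8))
  out <- suppressMessages(drop_missing(tbl))
  expect_equal(nrow(out), 8)
  rep_tbl <- attr(out, "missingness")
  expect_equal(rep_tbl$n_missing[rep_tbl$feature == "glcm_correlation"], 2L)
  expect_equal(sum(rep_tbl$n_missing), 2L)  # totals = removed occurrences

  clean <- make_table(6, 4)
  expect_equal(nrow(drop_missing(clean, quiet = TRUE)), 10)

  all_na <- tbl; all_na$mean <- NA_real_
  expect_error(suppressMessages(drop_missing(all_na)), "every row")
})

test_that("min-max normalization follows the endpoint formula", {
  tbl <- tibble::tibble(slice_id = c("a", "b", "c"), patient_id = "p",
                        label = c("IDC", "IDC", "ILC"),
                        mean = c(2, 4, 6))
  res <- minmax_normalize(tbl)
  expect_equal(res$table$mean, c(0, 0.5, 1))

  # fitted params extrapolate outside [0, 1] on new rows
  new <- tbl[1, ]; new$mean <- 8
  expect_equal(apply_normalization(new, res$params)$mean, 1.5)

  # refit on already-normalized values is the identity
  res2 <- minmax_normalize(res$table)
  expect_equal(res2$table$mean, res$table$mean)

  # constant features are dropped loudly
  tbl$entropy <- 5
  expect_warning(out <- minmax_normalize(tbl), "constant")
  expect_false("entropy" %in% names(out$table))

  # z-score alternative
  z <- minmax_normalize(tbl[, names(tbl) != "entropy"], method = "zscore")
  expect_equal(mean(z$table$mean), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z$table$mean), 1, tolerance = 1e-12)
})

test_that("two-group ANOVA F matches hand arithmetic and lm oracle", {
  res <- anova_f(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(res$f, 13.5)
  expect_equal(res$df1, 1L); expect_equal(res$df2, 4L)

  # identical group means -> F = 0
  expect_equal(anova_f(c(1, 2, 3, 1, 2, 3),
                       rep(c("a", "b"), each = 3))$f, 0)

  # agreement with the stats::lm F on random data, and affine invariance
  for (seed in 1:5) {
    x <- withr::with_seed(seed, stats::rnorm(40))
    g <- rep(c("a", "b"), 20)
    ours <- anova_f(x, g)
    ref <- stats::anova(stats::lm(x ~ g))
    expect_equal(ours$f, ref$`F value`[1])
    expect_equal(ours$p, ref$`Pr(>F)`[1])
    aff <- anova_f(3.7 * x - 11, g)
    expect_equal(aff$f, ours$f, tolerance = 1e-9)
  }

  expect_error(anova_f(1:4, rep("a", 4)), "two groups")
  degenerate <- anova_f(rep(5, 6), rep(c("a", "b"), 3))
  expect_true(is.na(degenerate$f))
})

test_that("a label-independent feature is eliminated first", {
  hits <- 0
  for (seed in 1:100) {
    tbl <- make_table(25, 25, seed = seed, effects = c(a = 1.5, b = 1, c = 0))
    first <- anova_rank(tbl)$feature[1]
    hits <- hits + (first == "glcm_contrast")
  }
  expect_gte(hits, 95)
})

test_that("the elimination ladder keeps its bookkeeping invariants", {
  tbl <- make_table(40, 30, seed = 3)
  norm <- minmax_normalize(tbl)$table
  ladder <- sequential_elimination(
    norm, model = model_spec("RF", list(n_estimators = 100L), seed = 42L),
    seed = 7L)
  expect_equal(nrow(ladder), 3)
  expect_equal(ladder$n_features, c(3L, 2L, 1L))
  expect_setequal(ladder$removed_feature,
                  c("mean", "entropy", "glcm_contrast"))
  expect_true(all(diff(ladder$f_score) >= 0))
  expect_true(all(ladder$accuracy >= 0 & ladder$accuracy <= 1))

  # full-table mode ranks before splitting; ladder structure is unchanged
  ladder_p <- sequential_elimination(
    norm, model = model_spec("RF", list(n_estimators = 100L), seed = 42L),
    seed = 7L, mode = "full-table")
  expect_equal(ladder_p$n_features, c(3L, 2L, 1L))
})

test_that("noise-only features classify at the majority frequency", {
  tbl <- make_table(60, 30, seed = 5, effects = c(a = 0, b = 0, c = 0))
  norm <- minmax_normalize(tbl)$table
  accs <- vapply(1:5, function(s) {
    run_once(tbl, "none", model = model_spec("RF", list(n_estimators = 100L)),
             seed = s)$accuracy
  }, numeric(1))
  maj <- 2 / 3
  se <- sqrt(maj * (1 - maj) / 18)   # 18 test rows per run
  expect_lt(abs(mean(accs) - maj), 3 * se)
})
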