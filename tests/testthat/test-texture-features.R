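test_that("first-order statistics match hand-computed values", {
  fo <- first_order(c(0, 0, 0, 4))
  expect_equal(fo$mean, 1)
  expect_equal(fo$standard_deviation, sqrt(3))
  expect_equal(fo$skewness, 2 / sqrt(3))
  expect_equal(fo$kurtosis, -2 / 3, tolerance = 1e-12)

  const <- first_order(c(7, 7, 7))
  expect_equal(const$mean, 7)
  expect_equal(const$standard_deviation, 0)
  expect_equal(const$entropy, 0)
  expect_true(is.na(const$skewness) && is.na(const$kurtosis))

  # two equiprobable bins -> 1 bit
  expect_equal(first_order(rep(c(0, 255), 10))$entropy, 1)
  expect_error(first_order(numeric(0)), "empty")
})

test_that("quantization uses equal-width bins over the masked range", {
  s <- masked_slice(matrix(c(0:255, rep(0, 0)), 16, 16), matrix(1L, 16, 16))
  q <- quantize(s, 8L)
  v <- q[match(c(0, 255, 128), s$intensities)]
  expect_equal(v, c(0L, 7L, 4L))
  expect_equal(sort(unique(as.integer(q))), 0:7)

  const <- quantize(masked_slice(matrix(9, 16, 16), matrix(1L, 16, 16)))
  expect_true(all(const == 0L))

  # a monotone transform that moves values within their bins (downward by
  # at most 1, never across the even-valued bin starts, extremes fixed)
  perm <- s
  v <- s$intensities
  perm$intensities <- ifelse(v == 255, 255, v - v %% 2)
  expect_identical(quantize(perm, 8L), q)
})

test_that("GLCM accumulation and properties match pair enumeration", {
  grid <- masked_slice(matrix(c(0L, 1L, 0L, 1L), 2, 2), matrix(1L, 2, 2))
  q <- quantize(grid, 2L)      # [[0,0],[1,1]] column-wise -> rows 0,1
  g <- compute_glcm(q, list(c(0L, 1L)), symmetric = TRUE, n_levels = 2L)
  expect_equal(g$P, matrix(c(0.5, 0, 0, 0.5), 2, 2))
  pr <- glcm_props(g)
  expect_equal(pr$glcm_contrast, 0)
  expect_equal(pr$glcm_energy, 0.5)
  expect_equal(pr$glcm_homogeneity, 1)
  expect_equal(pr$glcm_correlation, 1)

  # single asymmetric pair: P = [[0,1],[0,0]]
  q2 <- matrix(c(0L, NA, 1L, NA), 2, 2)   # one valid (0,1) horizontal pair
  g2 <- compute_glcm(q2, list(c(0L, 1L)), symmetric = FALSE, n_levels = 2L)
  expect_equal(g2$P, matrix(c(0, 0, 1, 0), 2, 2))
  pr2 <- glcm_props(g2)
  expect_equal(pr2$glcm_contrast, 1)
  expect_equal(pr2$glcm_energy, 1)
  expect_equal(pr2$glcm_homogeneity, 0.5)
  expect_true(is.na(pr2$glcm_correlation))

  # no valid pair under the mask -> dedicated error
  q3 <- matrix(c(0L, NA, NA, 1L), 2, 2)
  expect_error(compute_glcm(q3, list(c(0L, 1L))), class = "glcm_undefined")

  # normalization on random slices
  for (seed in 4:6) {
    r <- random_slice(seed)
    gg <- compute_glcm(quantize(r))
    expect_equal(sum(gg$P), 1, tolerance = 1e-12)
    expect_equal(gg$P, t(gg$P))
  }
})

test_that("energy and homogeneity reach 1 exactly in the degenerate cases", {
  s <- masked_slice(matrix(42, 16, 16), matrix(1L, 16, 16))
  pr <- glcm_props(compute_glcm(quantize(s)))
  expect_equal(pr$glcm_energy, 1)        # single occupied cell
  expect_equal(pr$glcm_homogeneity, 1)   # all mass on the diagonal
  expect_equal(pr$glcm_contrast, 0)

  # diagonal but two cells: homogeneity 1, energy < 1
  q <- matrix(rep(c(0L, 1L), 4), 2, 4)   # constant rows 0 and 1
  g <- glcm_props(compute_glcm(q, list(c(0L, 1L)), n_levels = 2L))
  expect_equal(g$glcm_homogeneity, 1)
  expect_lt(g$glcm_energy, 1)
})

test_that("local maps handle constants and checkerboards as enumerated", {
  const <- masked_slice(matrix(11, 16, 16), matrix(1L, 16, 16))
  loc <- local_feature_maps(const)
  expect_equal(loc$local_range, 0)
  expect_equal(loc$local_standard_deviation, 0)
  expect_equal(loc$local_entropy, 0)

  # checkerboard of 0/255: every 3x3 window holds both extremes
  chk <- outer(1:5, 1:5, function(r, c) ((r + c) %% 2) * 255L)
  s <- masked_slice(chk, matrix(1L, 5, 5))
  expect_equal(local_feature_maps(s)$local_range, 255)
})

test_that("extract_features composes the 12 features, NA where degenerate", {
  s <- masked_slice(matrix(99, 32, 32), matrix(1L, 32, 32))
  fv <- extract_features(s)
  expect_setequal(setdiff(names(fv), c("slice_id", "patient_id", "label")),
                  feature_names())
  expect_equal(fv$standard_deviation, 0)
  expect_equal(fv$entropy, 0)
  expect_equal(fv$local_range, 0)
  expect_equal(fv$glcm_contrast, 0)
  expect_equal(fv$glcm_energy, 1)
  expect_equal(fv$glcm_homogeneity, 1)
  expect_true(is.na(fv$skewness) && is.na(fv$kurtosis) &&
                is.na(fv$glcm_correlation))
})

test_that("adding a constant shifts the mean and nothing else", {
  r <- random_slice(21)
  r$intensities <- pmin(r$intensities, 200L)  # headroom for the shift
  shifted <- r
  shifted$intensities <- r$intensities + 10L  # multiple of the 8-bit bin width
  a <- extract_features(r); b <- extract_features(shifted)
  expect_equal(b$mean, a$mean + 10)
  for (f in c("standard_deviation", "skewness", "kurtosis", "entropy",
              "local_range", "local_standard_deviation", "local_entropy"))
    expect_equal(b[[f]], a[[f]], tolerance = 1e-12, label = f)
})
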