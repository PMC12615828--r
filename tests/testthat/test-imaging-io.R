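test_that("apply_mask returns the product grid and the row-major pixel list", {
  s <- masked_slice(matrix(c(5, 9, 7, 3), 2, 2),   # [[5,7],[9,3]] by rows
                    matrix(c(1, 0, 0, 1), 2, 2))
  res <- apply_mask(s)
  expect_equal(res$grid, matrix(c(5, 0, 0, 3), 2, 2))
  expect_equal(res$pixels, c(5, 3))

  full <- masked_slice(matrix(1:16, 4, 4), matrix(1L, 4, 4))
  expect_equal(apply_mask(full)$grid, full$intensities)
  expect_length(apply_mask(full)$pixels, 16)

  # masking the masked grid changes nothing (idempotence)
  s2 <- masked_slice(res$grid, s$mask)
  expect_equal(apply_mask(s2)$grid, res$grid)

  # conservation on random slices
  for (seed in 1:3) {
    r <- random_slice(seed)
    expect_length(apply_mask(r)$pixels, sum(r$mask))
  }
})

test_that("slice construction validates shapes, range and nonempty mask", {
  expect_error(masked_slice(matrix(0, 64, 64), matrix(1, 32, 32)),
               "64x64.*32x32")
  expect_error(masked_slice(matrix(300, 4, 4), matrix(1, 4, 4),
                            bit_depth = 8), "intensities outside")
  expect_error(masked_slice(matrix(1, 4, 4), matrix(0, 4, 4)), "QC")
  s <- masked_slice(matrix(40000, 4, 4), matrix(1, 4, 4), bit_depth = 16L)
  expect_equal(sum(s$mask), 16)
})

test_that("PNG write/read round-trips slices bit-exactly", {
  dir <- withr::local_tempdir()
  for (bd in c(8L, 16L)) {
    ext <- if (bd == 8L) "png" else "tiff"  # PNG writing is 8-bit only
    s <- random_slice(7, bit_depth = bd)
    ip <- file.path(dir, sprintf("img%d.%s", bd, ext))
    mp <- file.path(dir, sprintf("msk%d.%s", bd, ext))
    write_slice(s, ip, mp)
    s2 <- read_slice(ip, mp, slice_id = s$slice_id, bit_depth = bd)
    expect_identical(s2$intensities, s$intensities)
    expect_identical(s2$mask, s$mask)
  }
  expect_error(read_slice(file.path(dir, "absent.png"),
                          file.path(dir, "img8.png")), "does not exist")
  s8 <- random_slice(9)
  s8$bit_depth <- 16L
  expect_error(write_slice(s8, file.path(dir, "a.png"),
                           file.path(dir, "b.png")), "8-bit")
})

test_that("cohort write/read round-trips via manifest", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(synth_config(n_patients_per_class = c(2L, 1L),
                                     slices_per_patient = 2L,
                                     image_shape = c(32, 32)))
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_setequal(back$manifest$slice_id, co$manifest$slice_id)
  sid <- co$manifest$slice_id[1]
  expect_identical(back$slices[[sid]]$intensities,
                   co$slices[[sid]]$intensities)
  expect_identical(back$slices[[sid]]$label, co$slices[[sid]]$label)
})

test_that("qc_exclude follows area and fragmentation rules, mask-only", {
  blank <- matrix(0L, 40, 40)
  two <- blank
  two[2:11, 2:26] <- 1L    # 250 px, separated from
  two[25:34, 14:38] <- 1L  # another 250 px by >1 row
  s_two <- masked_slice(matrix(50, 40, 40), two)
  expect_equal(sort(oracle_component_sizes(two)), c(250, 250))
  expect_true(qc_exclude(s_two))                      # share 0.5 < 0.9

  small <- blank; small[5:10, 5:9] <- 1L              # 30 px
  expect_true(qc_exclude(masked_slice(matrix(50, 40, 40), small)))

  one <- blank; one[5:29, 5:24] <- 1L                 # 500 px contiguous
  s_one <- masked_slice(matrix(50, 40, 40), one)
  expect_false(qc_exclude(s_one))

  # intensity-invariance: decision depends only on the mask
  s_alt <- masked_slice(random_slice(3, c(40, 40))$intensities, one)
  expect_identical(qc_exclude(s_alt), qc_exclude(s_one))
})

test_that("component labeling agrees with a flood-fill oracle", {
  for (seed in 1:5) {
    m <- withr::with_seed(seed,
      matrix(as.integer(stats::runif(400) < 0.45), 20, 20))
    if (sum(m) == 0) next
    lab <- clbtexture:::label_components(m)
    expect_setequal(tabulate(lab[lab > 0]), oracle_component_sizes(m))
  }
})
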