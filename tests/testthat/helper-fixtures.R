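# shared fixtures, generated in code

# random masked slice: uniform random intensities, blobby random mask
random_slice <- function(seed, shape = c(32L, 32L), bit_depth = 8L,
                         coverage = 0.5) {
  withr::with_seed(seed, {
    img <- matrix(sample.int(2^bit_depth, prod(shape), replace = TRUE) - 1L,
                  shape[1], shape[2])
    repeat {
      mask <- matrix(as.integer(stats::runif(prod(shape)) < coverage),
                     shape[1], shape[2])
      if (sum(mask) >= 16) break
    }
    masked_slice(img, mask, slice_id = paste0("rand", seed),
                 bit_depth = bit_depth)
  })
}

# small two-class cohort config used across modeling tests
test_config <- function(n0 = 10L, n1 = 4L, spp = 4L, shape = c(48L, 48L),
                        smooth0 = 1.5, smooth1 = 3.5, seed = 1L) {
  synth_config(
    n_patients_per_class = c(n0, n1), slices_per_patient = spp,
    image_shape = shape,
    class_params = list(
      texture_params(mean_intensity = 120, noise_sd = 35,
                     smoothing_length = smooth0),
      texture_params(mean_intensity = 130, noise_sd = 35,
                     smoothing_length = smooth1)),
    mask_coverage = 0.3, seed = seed)
}

# cached feature table for the default test cohort (built once per run)
test_feature_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- generate_cohort(test_config())
      cache <<- drop_missing(extract_cohort(co$slices, min_area = 32L),
                             quiet = TRUE)
    }
    cache
  }
})
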