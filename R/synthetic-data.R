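#' Texture parameters for one phantom class
#'
#' The phantom generator draws white Gaussian noise, convolves it with a
#' Gaussian kernel of scale `smoothing_length`, and rescales to the requested
#' mean and spread. Larger `smoothing_length` means more spatial correlation,
#' hence lower GLCM contrast and higher homogeneity — the monotone dial the
#' two classes are separated on.
#'
#' @param mean_intensity mean gray level of the field.
#' @param noise_sd standard deviation of the field, gray levels. Zero gives
#'   a constant image.
#' @param smoothing_length Gaussian kernel scale in pixels; 0 = no smoothing
#'   (white noise).
#' @param anisotropy ratio >= 1; the column-direction kernel scale is
#'   `smoothing_length * anisotropy`.
#' @return an object of class `texture_params`.
#' @export
texture_params <- function(mean_intensity = 120, noise_sd = 30,
                           smoothing_length = 2, anisotropy = 1) {
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (smoothing_length < 0) stopf("smoothing_length must be >= 0")
  if (anisotropy < 1) stopf("anisotropy must be >= 1")
  structure(list(mean_intensity = mean_intensity, noise_sd = noise_sd,
                 smoothing_length = smoothing_length, anisotropy = anisotropy),
            class = "texture_params")
}

# separable Gaussian blur with edge renormalization (convolving a ones
# matrix with the same kernel), so edge pixels are proper averages
gauss_blur <- function(z, sigma_r, sigma_c) {
  blur_1d <- function(m, sigma, margin) {
    if (sigma <= 0) return(m)
    rad <- max(1L, ceiling(3 * sigma))
    w <- stats::dnorm(-rad:rad, sd = sigma)
    w <- w / sum(w)
    acc <- matrix(0, nrow(m), ncol(m))
    nrm <- matrix(0, nrow(m), ncol(m))
    n <- if (margin == 1) nrow(m) else ncol(m)
    for (k in seq_along(w)) {
      d <- k - rad - 1L
      src <- max(1, 1 - d):min(n, n - d)
      dst <- src + d
      if (margin == 1) {
        acc[dst, ] <- acc[dst, ] + w[k] * m[src, ]
        nrm[dst, ] <- nrm[dst, ] + w[k]
      } else {
        acc[, dst] <- acc[, dst] + w[k] * m[, src]
        nrm[, dst] <- nrm[, dst] + w[k]
      }
    }
    acc / nrm
  }
  blur_1d(blur_1d(z, sigma_r, 1L), sigma_c, 2L)
}

#' Generate one correlated Gaussian random texture field
#'
#' White Gaussian noise is smoothed with a separable Gaussian kernel, then
#' standardized empirically and mapped to `mean_intensity` +/- `noise_sd`,
#' quantized to integers and clipped to the bit-depth range. Deterministic
#' in `(params, shape, seed)`.
#'
#' @param params a [texture_params()].
#' @param shape `c(rows, cols)`, each >= 16.
#' @param seed integer seed.
#' @param bit_depth 8 or 16.
#' @return an integer matrix in `[0, 2^bit_depth - 1]`.
#' @export
generate_texture_field <- function(params, shape = c(128L, 128L), seed = 1L,
                                   bit_depth = 8L) {
  if (length(shape) != 2 || any(shape < 16))
    stopf("shape must be (rows, cols) with both >= 16, got (%s)",
          paste(shape, collapse = ", "))
  maxval <- 2^bit_depth - 1
  if (params$noise_sd == 0) {
    v <- min(max(round(params$mean_intensity), 0), maxval)
    return(matrix(v, shape[1], shape[2]))
  }
  z <- with_seed(seed, matrix(stats::rnorm(prod(shape)), shape[1], shape[2]))
  if (params$smoothing_length > 0)
    z <- gauss_blur(z, params$smoothing_length,
                    params$smoothing_length * params$anisotropy)
  z <- (z - mean(z)) / stats::sd(z)
  x <- round(params$mean_intensity + params$noise_sd * z)
  x[x < 0] <- 0
  x[x > maxval] <- maxval
  x
}

#' Generate a synthetic glandular mask of elliptical components
#'
#' The glandular ROI is modeled as a union of `n_components` disjoint
#' axis-aligned ellipses of (approximately) equal area; fragmented masks —
#' those that fail [qc_exclude()] — are obtained by asking for several
#' components. The realized coverage is within 20% of
#' `coverage_fraction`.
#'
#' @param shape `c(rows, cols)`.
#' @param coverage_fraction target masked fraction of the image, in (0, 1).
#' @param n_components number of disjoint elliptical components.
#' @param seed integer seed.
#' @return a 0/1 integer matrix.
#' @export
make_glandular_mask <- function(shape, coverage_fraction = 0.25,
                                n_components = 1L, seed = 1L) {
  rows <- shape[1]; cols <- shape[2]
  if (coverage_fraction <= 0 || coverage_fraction >= 1)
    stopf("coverage_fraction must be in (0, 1)")
  target <- coverage_fraction * rows * cols
  if (target < 64) stopf("infeasible coverage: %.0f px target (< 64)", target)
  area_each <- target / n_components
  r0 <- sqrt(area_each / pi)
  with_seed(seed, {
    for (attempt in 1:200) {
      centers <- matrix(0, n_components, 2)
      axes <- matrix(0, n_components, 2)
      ok <- TRUE
      for (i in seq_len(n_components)) {
        asp <- stats::runif(1, 0.75, 1.35)
        a <- r0 * sqrt(asp); b <- r0 / sqrt(asp)   # row, col semi-axes
        if (2 * a + 4 >= rows || 2 * b + 4 >= cols) { ok <- FALSE; break }
        placed <- FALSE
        for (try_c in 1:50) {
          cr <- stats::runif(1, a + 2, rows - a - 2)
          cc <- stats::runif(1, b + 2, cols - b - 2)
          sep <- TRUE
          if (i > 1) {
            for (j in 1:(i - 1)) {
              mind <- max(axes[j, ]) + max(a, b) + 2
              if (sqrt((cr - centers[j, 1])^2 + (cc - centers[j, 2])^2) <= mind)
                sep <- FALSE
            }
          }
          if (sep) { centers[i, ] <- c(cr, cc); axes[i, ] <- c(a, b)
                     placed <- TRUE; break }
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (!ok) next
      rr <- matrix(seq_len(rows), rows, cols)
      cc_idx <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
      mask <- matrix(0L, rows, cols)
      for (i in seq_len(n_components)) {
        inside <- ((rr - centers[i, 1]) / axes[i, 1])^2 +
                  ((cc_idx - centers[i, 2]) / axes[i, 2])^2 <= 1
        mask[inside] <- 1L
      }
      realized <- sum(mask)
      if (abs(realized - target) <= 0.2 * target) return(mask)
    }
  })
  stopf("infeasible coverage: could not place %d disjoint components at %.2f coverage",
        n_components, coverage_fraction)
}

#' Configuration of a synthetic cohort
#'
#' Describes a two-class cohort of per-patient slice stacks mirroring the
#' structure of a clinical breast-MRI collection: class 0 ("IDC") is the
#' majority, class 1 ("ILC") the minority, with a slice-count imbalance near
#' 1890:554 by default (the clinical cohort proportion, 77.3% vs 22.7%).
#'
#' `n_patients_per_class` may be length 2 (explicit patient counts per
#' class; the realized slice ratio then follows from the counts) or length 1
#' (majority-class patient count; the minority slice count is derived from
#' `imbalance_ratio`, the last minority patient receiving the remainder
#' slices).
#'
#' @param n_patients_per_class integer, length 1 or 2.
#' @param slices_per_patient slices per patient stack (default 6).
#' @param image_shape `c(rows, cols)`, default 128x128.
#' @param class_params list of two [texture_params()], class 0 and class 1;
#'   must differ in at least one field.
#' @param imbalance_ratio class0:class1 slice ratio used when
#'   `n_patients_per_class` has length 1 (default 1890/554).
#' @param bit_depth 8 or 16.
#' @param mask_coverage,mask_components glandular mask geometry.
#' @param seed master seed; all per-patient and per-slice seeds derive from
#'   it via [derive_seed()].
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_patients_per_class = c(20L, 6L),
                         slices_per_patient = 6L,
                         image_shape = c(128L, 128L),
                         class_params = list(
                           texture_params(mean_intensity = 120, noise_sd = 35,
                                          smoothing_length = 1.5),
                           texture_params(mean_intensity = 130, noise_sd = 35,
                                          smoothing_length = 3.5)),
                         imbalance_ratio = 1890 / 554,
                         bit_depth = 8L,
                         mask_coverage = 0.25,
                         mask_components = 1L,
                         seed = 1L) {
  if (any(n_patients_per_class < 1) || slices_per_patient < 1)
    stopf("all counts must be >= 1")
  if (any(image_shape < 16)) stopf("image_shape must be at least 16x16")
  if (imbalance_ratio <= 0) stopf("imbalance_ratio must be > 0")
  structure(list(n_patients_per_class = as.integer(n_patients_per_class),
                 slices_per_patient = as.integer(slices_per_patient),
                 image_shape = as.integer(image_shape),
                 class_params = class_params,
                 imbalance_ratio = imbalance_ratio,
                 bit_depth = as.integer(bit_depth),
                 mask_coverage = mask_coverage,
                 mask_components = as.integer(mask_components),
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic two-class cohort of masked slices
#'
#' Patients are drawn with per-patient offsets (a small shift of
#' `mean_intensity` and a multiplicative jitter of `smoothing_length`,
#' drawn once per patient) so slices within a patient are correlated,
#' emulating slice-level non-independence of clinical stacks. Each slice
#' gets its own texture field and glandular mask from derived seeds; the
#' whole cohort is a pure function of the configuration.
#'
#' @param config a [synth_config()].
#' @return list with `slices` (list of [masked_slice()]) and `manifest`
#'   (tibble: slice_id, patient_id, label).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  npc <- config$n_patients_per_class
  spp <- config$slices_per_patient
  if (length(npc) == 2) {
    slice_counts <- npc * spp
  } else {
    s0 <- npc * spp
    s1 <- max(1L, as.integer(round(s0 / config$imbalance_ratio)))
    npc <- c(npc, as.integer(ceiling(s1 / spp)))
    slice_counts <- c(s0, s1)
  }
  labels <- c("IDC", "ILC")
  slices <- list()
  rows <- character(); pids <- character(); labs <- character()
  for (cl in 1:2) {
    params <- config$class_params[[cl]]
    remaining <- slice_counts[cl]
    for (p in seq_len(npc[cl])) {
      pid <- sprintf("%s_p%03d", labels[cl], p)
      pseed <- derive_seed(config$seed, cl, p)
      off <- with_seed(pseed, list(
        dmean = stats::rnorm(1, 0, 4),
        fsmooth = exp(stats::rnorm(1, 0, 0.08))))
      pp <- params
      pp$mean_intensity <- params$mean_intensity + off$dmean
      pp$smoothing_length <- params$smoothing_length * off$fsmooth
      n_here <- min(spp, remaining)
      for (s in seq_len(n_here)) {
        sid <- sprintf("%s_s%02d", pid, s)
        fseed <- derive_seed(config$seed, cl, p, s, 1)
        mseed <- derive_seed(config$seed, cl, p, s, 2)
        img <- generate_texture_field(pp, config$image_shape, seed = fseed,
                                      bit_depth = config$bit_depth)
        msk <- make_glandular_mask(config$image_shape, config$mask_coverage,
                                   config$mask_components, seed = mseed)
        slices[[sid]] <- masked_slice(img, msk, slice_id = sid,
                                      patient_id = pid, label = labels[cl],
                                      bit_depth = config$bit_depth)
        rows <- c(rows, sid); pids <- c(pids, pid); labs <- c(labs, labels[cl])
      }
      remaining <- remaining - n_here
      if (remaining <= 0 && cl == 2) break
    }
  }
  list(slices = slices,
       manifest = tibble::tibble(slice_id = rows, patient_id = pids,
                                 label = labs))
}

#' Write a cohort to disk as image/mask pairs plus a manifest CSV
#'
#' 8-bit cohorts are written as PNG, 16-bit as TIFF.
#'
#' @param cohort output of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return the manifest tibble (with `image_path`, `mask_path` columns),
#'   invisibly; also written as `manifest.csv`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- cohort$manifest
  ext <- if (cohort$slices[[1]]$bit_depth == 8L) "png" else "tiff"
  man$image_path <- file.path(dir, sprintf("%s.%s", man$slice_id, ext))
  man$mask_path <- file.path(dir, sprintf("%s_mask.%s", man$slice_id, ext))
  for (i in seq_len(nrow(man))) {
    write_slice(cohort$slices[[man$slice_id[i]]],
                man$image_path[i], man$mask_path[i])
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}

#' Read a cohort previously written by [write_cohort()]
#'
#' @param dir directory containing `manifest.csv` and the PNG pairs.
#' @param bit_depth stored bit depth of the PNGs.
#' @return list with `slices` and `manifest`, as [generate_cohort()].
#' @export
read_cohort <- function(dir, bit_depth = 8L) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  slices <- lapply(seq_len(nrow(man)), function(i)
    read_slice(man$image_path[i], man$mask_path[i],
               slice_id = man$slice_id[i], patient_id = man$patient_id[i],
               label = man$label[i], bit_depth = bit_depth))
  names(slices) <- man$slice_id
  list(slices = slices, manifest = tibble::as_tibble(man))
}
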