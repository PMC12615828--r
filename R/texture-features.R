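#' Names of the 12 texture features
#'
#' Five first-order histogram statistics, three local-neighborhood
#' statistics, and four GLCM properties, in canonical order.
#'
#' @return character vector of length 12.
#' @export
feature_names <- function() {
  c("mean", "standard_deviation", "skewness", "kurtosis", "entropy",
    "local_entropy", "local_range", "local_standard_deviation",
    "glcm_contrast", "glcm_correlation", "glcm_energy", "glcm_homogeneity")
}

#' Extraction parameters
#'
#' Collects every tunable of the feature extractor: histogram bin count for
#' the entropies (256 bins spanning the full bit-depth range, log base 2),
#' local window sizes (9x9 for local entropy, 3x3 for local range and local
#' standard deviation), and GLCM settings (8 gray levels, offset (0,1),
#' symmetric accumulation, min-max quantization within the mask).
#'
#' @param n_levels GLCM gray levels.
#' @param offsets list of `c(drow, dcol)` GLCM displacement vectors.
#' @param symmetric count each pair in both directions.
#' @param n_bins histogram bins for entropy features.
#' @param w_entropy,w_range,w_std odd window sizes of the local features.
#' @return an object of class `feature_params`.
#' @export
feature_params <- function(n_levels = 8L, offsets = list(c(0L, 1L)),
                           symmetric = TRUE, n_bins = 256L,
                           w_entropy = 9L, w_range = 3L, w_std = 3L) {
  stopifnot(n_levels >= 2, n_bins >= 2,
            all(c(w_entropy, w_range, w_std) %% 2 == 1))
  structure(list(n_levels = as.integer(n_levels), offsets = offsets,
                 symmetric = symmetric, n_bins = as.integer(n_bins),
                 w_entropy = as.integer(w_entropy),
                 w_range = as.integer(w_range), w_std = as.integer(w_std)),
            class = "feature_params")
}

# histogram bin index over the full [0, 2^bit_depth - 1] range, 1-based
bin_index <- function(x, bit_depth, n_bins) {
  width <- 2^bit_depth / n_bins
  pmin(floor(x / width), n_bins - 1) + 1L
}

# Shannon entropy (bits) of a count vector
entropy_bits <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

#' First-order statistics of the masked intensity distribution
#'
#' Mean, population standard deviation, skewness, excess kurtosis, and
#' histogram entropy (256 bins over the bit-depth range, base-2 logarithm,
#' with 0*log(0) = 0) of the glandular pixels. All moments use the
#' population divisor N. When the standard deviation is zero the
#' standardized moments are undefined and skewness/kurtosis are `NA`.
#'
#' Note on kurtosis: the textbook fourth standardized moment minus 3 is
#' used. A squared-deviation variant sometimes seen in print is identically
#' -2 for every image (the mean squared standardized deviation is 1 by
#' construction) and therefore carries no information; it is kept internally
#' only as a documented degeneracy.
#'
#' @param pixels masked pixel list (numeric vector, N >= 1).
#' @param bit_depth 8 or 16.
#' @param n_bins entropy histogram bins.
#' @return named list: mean, standard_deviation, skewness, kurtosis,
#'   entropy.
#' @export
first_order <- function(pixels, bit_depth = 8L, n_bins = 256L) {
  n <- length(pixels)
  if (n < 1) stopf("first_order: empty pixel list")
  m <- mean(pixels)
  s <- sd_pop(pixels)
  if (s > 0) {
    z <- (pixels - m) / s
    skew <- mean(z^3)
    kurt <- mean(z^4) - 3
  } else {
    skew <- NA_real_
    kurt <- NA_real_
  }
  counts <- tabulate(bin_index(pixels, bit_depth, n_bins), nbins = n_bins)
  list(mean = m, standard_deviation = s, skewness = skew, kurtosis = kurt,
       entropy = entropy_bits(counts))
}

# the squared-deviation kurtosis as sometimes printed: identically -2
# whenever sd > 0, since mean(((x - m)/s)^2) == 1 with population divisors
kurtosis_as_printed <- function(pixels) {
  s <- sd_pop(pixels)
  if (s == 0) return(NA_real_)
  mean(((pixels - mean(pixels)) / s)^2) - 3
}

# stack of window values around each masked pixel: one row per masked pixel
# (row-major order), one column per window offset; NA where the neighbor is
# outside the grid or outside the mask. Center pixel included.
window_stack <- function(intensities, mask, w) {
  nr <- nrow(mask); nc <- ncol(mask)
  rad <- (w - 1L) %/% 2L
  pos <- which(t(mask) == 1)                 # row-major positions
  pr <- (pos - 1L) %/% nc + 1L               # row index
  pc <- (pos - 1L) %% nc + 1L                # col index
  offs <- expand.grid(dc = -rad:rad, dr = -rad:rad)
  out <- matrix(NA_real_, length(pos), nrow(offs))
  for (k in seq_len(nrow(offs))) {
    qr <- pr + offs$dr[k]
    qc <- pc + offs$dc[k]
    valid <- qr >= 1 & qr <= nr & qc >= 1 & qc <= nc
    idx <- (qc[valid] - 1L) * nr + qr[valid]  # column-major linear index
    v <- rep(NA_real_, length(pos))
    vals <- intensities[idx]
    vals[mask[idx] == 0] <- NA_real_
    v[valid] <- vals
    out[, k] <- v
  }
  out
}

#' Local-neighborhood texture features
#'
#' For every masked pixel, a statistic is computed over the intersection of
#' a square window centered on the pixel with the mask: entropy (9x9
#' window, 256-bin base-2 histogram), range (3x3), and standard deviation
#' (3x3, population divisor). Pixels whose window contains fewer than two
#' masked pixels (center included) do not contribute; the per-slice scalar
#' is the arithmetic mean of each map over its contributing pixels.
#'
#' @param slice a [masked_slice()].
#' @param params a [feature_params()].
#' @return named list: local_entropy, local_range,
#'   local_standard_deviation (each `NA` if no pixel contributes).
#' @export
local_feature_maps <- function(slice, params = feature_params()) {
  if (sum(slice$mask) < 4) stopf("local features need a masked area >= 4")
  img <- slice$intensities
  stat_over <- function(w, fun) {
    W <- window_stack(img, slice$mask, w)
    counts <- rowSums(!is.na(W))
    keep <- counts >= 2
    if (!any(keep)) return(NA_real_)
    mean(fun(W[keep, , drop = FALSE]))
  }
  rng <- stat_over(params$w_range, function(W) {
    apply(W, 1, function(v) { v <- v[!is.na(v)]; max(v) - min(v) })
  })
  lsd <- stat_over(params$w_std, function(W) {
    m1 <- rowMeans(W, na.rm = TRUE)
    m2 <- rowMeans(W^2, na.rm = TRUE)
    sqrt(pmax(m2 - m1^2, 0))
  })
  lent <- stat_over(params$w_entropy, function(W) {
    B <- matrix(bin_index(W, slice$bit_depth, params$n_bins),
                nrow(W), ncol(W))
    apply(B, 1, function(b) entropy_bits(tabulate(b[!is.na(b)],
                                                  nbins = params$n_bins)))
  })
  list(local_entropy = lent, local_range = rng,
       local_standard_deviation = lsd)
}

#' Quantize masked intensities to GLCM gray levels
#'
#' Linear binning of the masked intensity range `[min, max]` into
#' `n_levels` equal-width bins; the maximum maps to level `n_levels - 1`
#' and a constant region maps entirely to level 0. Pixels outside the mask
#' are `NA` in the returned grid.
#'
#' @param slice a [masked_slice()].
#' @param n_levels number of gray levels.
#' @return integer matrix of levels `0 .. n_levels - 1`, `NA` outside the
#'   mask.
#' @export
quantize <- function(slice, n_levels = 8L) {
  vals <- slice$intensities
  inside <- slice$mask == 1
  if (!any(inside)) stopf("quantize: empty mask")
  mn <- min(vals[inside]); mx <- max(vals[inside])
  q <- matrix(NA_integer_, nrow(vals), ncol(vals))
  if (mx == mn) {
    q[inside] <- 0L
  } else {
    lev <- floor((vals[inside] - mn) / (mx - mn) * n_levels)
    q[inside] <- as.integer(pmin(lev, n_levels - 1L))
  }
  q
}

#' Gray-level co-occurrence matrix over the masked region
#'
#' Counts co-occurring quantized level pairs at the given displacement
#' offsets, restricted to pixel pairs whose both ends lie inside the mask.
#' With `symmetric = TRUE` each pair (a, b) also counts as (b, a). Counts
#' are normalized to a joint distribution P, and the marginal means and
#' standard deviations over the level index (0-based) are recorded.
#'
#' @param qgrid quantized level grid from [quantize()] (`NA` outside mask).
#' @param offsets list of `c(drow, dcol)` displacements.
#' @param symmetric logical.
#' @param n_levels number of levels spanned by the matrix.
#' @return object of class `glcm`: `P` (n_levels x n_levels), `mu_i`,
#'   `mu_j`, `sigma_i`, `sigma_j`, `n_pairs`, plus the settings.
#' @export
compute_glcm <- function(qgrid, offsets = list(c(0L, 1L)), symmetric = TRUE,
                         n_levels = 8L) {
  nr <- nrow(qgrid); nc <- ncol(qgrid)
  counts <- matrix(0, n_levels, n_levels)
  n_pairs <- 0L
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    r_src <- max(1, 1 - dr):min(nr, nr - dr)
    c_src <- max(1, 1 - dc):min(nc, nc - dc)
    if (length(r_src) < 1 || length(c_src) < 1) next
    a <- qgrid[r_src, c_src, drop = FALSE]
    b <- qgrid[r_src + dr, c_src + dc, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    tab <- table(factor(a[ok], levels = 0:(n_levels - 1)),
                 factor(b[ok], levels = 0:(n_levels - 1)))
    counts <- counts + unclass(tab)
    n_pairs <- n_pairs + sum(ok)
  }
  if (n_pairs == 0)
    stop(structure(class = c("glcm_undefined", "error", "condition"),
                   list(message = "GLCM undefined: no valid pixel pair under the mask",
                        call = NULL)))
  if (symmetric) counts <- counts + t(counts)
  P <- counts / sum(counts)
  dimnames(P) <- NULL
  lev <- 0:(n_levels - 1)
  p_i <- rowSums(P); p_j <- colSums(P)
  mu_i <- sum(lev * p_i); mu_j <- sum(lev * p_j)
  structure(list(P = P,
                 mu_i = mu_i, mu_j = mu_j,
                 sigma_i = sqrt(sum((lev - mu_i)^2 * p_i)),
                 sigma_j = sqrt(sum((lev - mu_j)^2 * p_j)),
                 n_pairs = n_pairs, n_levels = n_levels,
                 offsets = offsets, symmetric = symmetric),
            class = "glcm")
}

#' GLCM texture properties
#'
#' Contrast `sum P_ij (i-j)^2`, correlation
#' `sum P_ij (i-mu_i)(j-mu_j)/(sigma_i sigma_j)` (reported `NA` when either
#' marginal is degenerate), energy `sum P_ij^2`, and homogeneity
#' `sum P_ij / (1 + (i-j)^2)`.
#'
#' @param g a [compute_glcm()] object.
#' @return named list: glcm_contrast, glcm_correlation, glcm_energy,
#'   glcm_homogeneity.
#' @export
glcm_props <- function(g) {
  lev <- 0:(g$n_levels - 1)
  I <- matrix(lev, g$n_levels, g$n_levels)
  J <- t(I)
  D2 <- (I - J)^2
  corr <- if (g$sigma_i == 0 || g$sigma_j == 0) NA_real_ else
    sum(g$P * (I - g$mu_i) * (J - g$mu_j)) / (g$sigma_i * g$sigma_j)
  list(glcm_contrast = sum(g$P * D2),
       glcm_correlation = corr,
       glcm_energy = sum(g$P^2),
       glcm_homogeneity = sum(g$P / (1 + D2)))
}

#' Extract the 12 texture features from one slice
#'
#' Runs the first-order, local-neighborhood and GLCM extractors and returns
#' a one-row tibble with identifiers and the 12 features in the order of
#' [feature_names()]. Degenerate features (zero variance, degenerate GLCM
#' marginal, no valid co-occurring pair) are `NA`.
#'
#' @param slice a [masked_slice()].
#' @param params a [feature_params()].
#' @return one-row tibble: slice_id, patient_id, label, then 12 features.
#' @export
extract_features <- function(slice, params = feature_params()) {
  px <- apply_mask(slice)$pixels
  fo <- first_order(px, slice$bit_depth, params$n_bins)
  loc <- local_feature_maps(slice, params)
  gl <- tryCatch({
    q <- quantize(slice, params$n_levels)
    glcm_props(compute_glcm(q, params$offsets, params$symmetric,
                            params$n_levels))
  }, glcm_undefined = function(e)
    list(glcm_contrast = NA_real_, glcm_correlation = NA_real_,
         glcm_energy = NA_real_, glcm_homogeneity = NA_real_))
  tibble::tibble(slice_id = slice$slice_id, patient_id = slice$patient_id,
                 label = slice$label, !!!fo, !!!loc, !!!gl)
}

#' Extract features for a whole cohort
#'
#' Applies [qc_exclude()] (unless disabled) and then [extract_features()]
#' to every surviving slice.
#'
#' @param slices list of [masked_slice()] (e.g. `cohort$slices`).
#' @param params a [feature_params()].
#' @param qc apply the ROI-discontinuity exclusion first (default TRUE).
#' @param min_area,min_largest_component_share QC thresholds, see
#'   [qc_exclude()].
#' @return tibble with one row per retained slice.
#' @export
extract_cohort <- function(slices, params = feature_params(), qc = TRUE,
                           min_area = 64L,
                           min_largest_component_share = 0.9) {
  if (qc) {
    keep <- !vapply(slices, qc_exclude, logical(1),
                    min_area = min_area,
                    min_largest_component_share = min_largest_component_share)
    slices <- slices[keep]
  }
  if (length(slices) == 0) stopf("no slice passed QC")
  do.call(rbind, lapply(slices, extract_features, params = params))
}
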