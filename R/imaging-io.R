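#' Construct a masked slice
#'
#' A `masked_slice` couples one 2-D grayscale intensity grid with a binary
#' glandular-ROI mask of identical shape, plus the identifiers the pipeline
#' tracks: slice id, patient id, and the histological class label
#' (class 0 = `"IDC"`, class 1 = `"ILC"`).
#'
#' @param intensities integer matrix of gray levels in
#'   `[0, 2^bit_depth - 1]`.
#' @param mask matrix of 0/1 with the same dimensions (any nonzero entry is
#'   coerced to 1).
#' @param slice_id,patient_id character identifiers.
#' @param label class label, `"IDC"` or `"ILC"`.
#' @param bit_depth 8 or 16.
#' @return an object of class `masked_slice`.
#' @export
masked_slice <- function(intensities, mask, slice_id = "slice",
                         patient_id = "patient", label = "IDC",
                         bit_depth = 8L) {
  if (!is.matrix(intensities) || !is.matrix(mask))
    stopf("intensities and mask must be matrices")
  if (!identical(dim(intensities), dim(mask)))
    stopf("shape mismatch: image is %dx%d but mask is %dx%d",
          nrow(intensities), ncol(intensities), nrow(mask), ncol(mask))
  if (!bit_depth %in% c(8L, 16L)) stopf("bit_depth must be 8 or 16")
  maxval <- 2^bit_depth - 1
  if (any(intensities < 0) || any(intensities > maxval))
    stopf("intensities outside [0, %d] for bit depth %d", maxval, bit_depth)
  if (!label %in% c("IDC", "ILC")) stopf("label must be 'IDC' or 'ILC'")
  mask <- (mask != 0) * 1L
  if (sum(mask) < 1) stopf("QC: mask of slice '%s' selects no pixels", slice_id)
  structure(
    list(slice_id = as.character(slice_id),
         patient_id = as.character(patient_id),
         label = label,
         intensities = round(intensities),
         mask = mask,
         bit_depth = as.integer(bit_depth)),
    class = "masked_slice")
}

#' @export
print.masked_slice <- function(x, ...) {
  cat(sprintf("<masked_slice> %s (patient %s, %s), %dx%d, %d-bit, ROI %d px\n",
              x$slice_id, x$patient_id, x$label,
              nrow(x$intensities), ncol(x$intensities), x$bit_depth,
              sum(x$mask)))
  invisible(x)
}

# read a grayscale PNG/TIFF into an integer matrix at the stored bit depth
read_gray <- function(path, bit_depth) {
  if (!file.exists(path)) stopf("cannot read '%s': file does not exist", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stopf("unsupported image format '.%s' (use PNG or TIFF)", ext))
  if (length(dim(arr)) == 3) arr <- arr[, , 1]  # first channel of non-gray file
  round(arr * (2^bit_depth - 1))
}

#' Read an image/mask pair into a masked slice
#'
#' Reads 8- or 16-bit grayscale PNG (or TIFF) images. The mask image is
#' binarized (any nonzero pixel becomes 1). Invariants are validated on
#' construction: matching shapes, intensities within the bit-depth range,
#' and a nonempty ROI.
#'
#' @param image_path,mask_path paths to the slice and its glandular mask.
#' @inheritParams masked_slice
#' @return a [masked_slice()].
#' @export
read_slice <- function(image_path, mask_path, slice_id = basename(image_path),
                       patient_id = "patient", label = "IDC", bit_depth = 8L) {
  img <- read_gray(image_path, bit_depth)
  msk <- read_gray(mask_path, bit_depth)
  masked_slice(img, (msk != 0) * 1L, slice_id = slice_id,
               patient_id = patient_id, label = label, bit_depth = bit_depth)
}

#' Write a masked slice as an image/mask pair
#'
#' 8-bit slices are stored as grayscale PNG; 16-bit slices as TIFF (PNG
#' writing is 8-bit only), chosen by the file extension. Round-trips with
#' [read_slice()] are bit-exact.
#'
#' @param slice a [masked_slice()].
#' @param image_path,mask_path output paths (`.png` for 8-bit, `.tif(f)`
#'   for 16-bit).
#' @return the slice, invisibly.
#' @export
write_slice <- function(slice, image_path, mask_path) {
  maxval <- 2^slice$bit_depth - 1
  write_one <- function(m, path) {
    ext <- tolower(tools::file_ext(path))
    if (ext == "png") {
      if (slice$bit_depth != 8L)
        stopf("PNG output supports 8-bit slices only; use .tiff for 16-bit")
      png::writePNG(m / maxval, path)
    } else if (ext %in% c("tif", "tiff")) {
      tiff::writeTIFF(m / maxval, path,
                      bits.per.sample = slice$bit_depth)
    } else stopf("unsupported output format '.%s'", ext)
  }
  write_one(slice$intensities, image_path)
  write_one(slice$mask * maxval, mask_path)
  invisible(slice)
}

#' Apply the glandular mask to a slice
#'
#' Returns both the masked grid (elementwise product of intensities and
#' mask, the conventional visualization product) and the masked pixel list
#' (intensities where mask is 1, in row-major order). All downstream
#' statistics are computed from the pixel list only, so the background zeros
#' introduced by the multiplication never enter any histogram.
#'
#' @param slice a [masked_slice()].
#' @return list with elements `grid` (matrix) and `pixels` (numeric vector
#'   of length `sum(mask)`).
#' @export
apply_mask <- function(slice) {
  grid <- slice$intensities * slice$mask
  tm <- t(slice$intensities)            # row-major traversal
  pixels <- tm[t(slice$mask) == 1]
  list(grid = grid, pixels = pixels)
}

# label 8-connected components of a binary matrix by iterative minimum-label
# propagation; returns an integer matrix, 0 = background
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0, nr, nc)
  inside <- mask != 0
  lab[inside] <- which(inside)
  shifts <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                 c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  shift_mat <- function(m, dr, dc) {
    out <- matrix(Inf, nr, nc)
    r_src <- max(1, 1 - dr):min(nr, nr - dr)
    c_src <- max(1, 1 - dc):min(nc, nc - dc)
    out[r_src + dr, c_src + dc] <- m[r_src, c_src]
    out
  }
  work <- matrix(Inf, nr, nc)
  work[inside] <- lab[inside]
  repeat {
    new <- work
    for (s in shifts) new <- pmin(new, shift_mat(work, s[1], s[2]))
    new[!inside] <- Inf
    if (identical(new, work)) break
    work <- new
  }
  lab[inside] <- match(work[inside], sort(unique(work[inside])))
  lab
}

#' Quality-control check for ROI discontinuity
#'
#' Flags outlier slices whose glandular ROI is too small or fragmented, the
#' exclusion step applied before feature extraction. A slice is excluded when
#' the masked area falls below `min_area` pixels, or when the largest
#' 8-connected component of the mask holds less than
#' `min_largest_component_share` of the total masked area. The decision
#' depends only on the mask, never on the intensities.
#'
#' @param slice a [masked_slice()].
#' @param min_area minimum masked pixel count (default 64).
#' @param min_largest_component_share minimum share of masked area in the
#'   largest connected component (default 0.9).
#' @return `TRUE` if the slice should be excluded.
#' @export
qc_exclude <- function(slice, min_area = 64L,
                       min_largest_component_share = 0.9) {
  area <- sum(slice$mask)
  if (area < min_area) return(TRUE)
  lab <- label_components(slice$mask)
  sizes <- tabulate(lab[lab > 0])
  max(sizes) / area < min_largest_component_share
}
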