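# naive, loop-based reference implementations kept deliberately independent
# of the package's vectorized code paths

oracle_bin <- function(x, bit_depth, n_bins = 256L) {
  width <- 2^bit_depth / n_bins
  pmin(floor(x / width), n_bins - 1)
}

oracle_entropy <- function(x, bit_depth, n_bins = 256L) {
  tab <- table(oracle_bin(x, bit_depth, n_bins))
  p <- as.numeric(tab) / length(x)
  -sum(p * log2(p))
}

oracle_first_order <- function(px, bit_depth = 8L) {
  n <- length(px)
  m <- sum(px) / n
  s <- sqrt(sum((px - m)^2) / n)
  list(mean = m, standard_deviation = s,
       skewness = if (s > 0) sum(((px - m) / s)^3) / n else NA_real_,
       kurtosis = if (s > 0) sum(((px - m) / s)^4) / n - 3 else NA_real_,
       entropy = oracle_entropy(px, bit_depth))
}

# local features by explicit double loop over every masked pixel
oracle_local <- function(slice, w_entropy = 9L, w_range = 3L, w_std = 3L) {
  img <- slice$intensities; mask <- slice$mask
  nr <- nrow(img); nc <- ncol(img)
  collect <- function(w, fun) {
    rad <- (w - 1) / 2
    vals <- c()
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      if (mask[r, c] == 0) next
      win <- c()
      for (dr in -rad:rad) for (dc in -rad:rad) {
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc && mask[rr, cc] == 1)
          win <- c(win, img[rr, cc])
      }
      if (length(win) >= 2) vals <- c(vals, fun(win))
    }
    if (length(vals) == 0) NA_real_ else mean(vals)
  }
  list(
    local_entropy = collect(w_entropy,
                            function(v) oracle_entropy(v, slice$bit_depth)),
    local_range = collect(w_range, function(v) max(v) - min(v)),
    local_standard_deviation = collect(w_std, function(v)
      sqrt(sum((v - mean(v))^2) / length(v))))
}

# GLCM by explicit pair enumeration
oracle_glcm_props <- function(slice, n_levels = 8L, offset = c(0L, 1L),
                              symmetric = TRUE) {
  img <- slice$intensities; mask <- slice$mask
  px <- img[mask == 1]
  mn <- min(px); mx <- max(px)
  q <- matrix(NA_integer_, nrow(img), ncol(img))
  for (r in seq_len(nrow(img))) for (c in seq_len(ncol(img))) {
    if (mask[r, c] == 1) {
      q[r, c] <- if (mx == mn) 0L else
        min(floor((img[r, c] - mn) / (mx - mn) * n_levels), n_levels - 1)
    }
  }
  counts <- matrix(0, n_levels, n_levels)
  for (r in seq_len(nrow(img))) for (c in seq_len(ncol(img))) {
    rr <- r + offset[1]; cc <- c + offset[2]
    if (rr < 1 || rr > nrow(img) || cc < 1 || cc > ncol(img)) next
    if (is.na(q[r, c]) || is.na(q[rr, cc])) next
    counts[q[r, c] + 1, q[rr, cc] + 1] <- counts[q[r, c] + 1, q[rr, cc] + 1] + 1
    if (symmetric)
      counts[q[rr, cc] + 1, q[r, c] + 1] <- counts[q[rr, cc] + 1, q[r, c] + 1] + 1
  }
  if (sum(counts) == 0) return(NULL)
  P <- counts / sum(counts)
  contrast <- 0; energy <- 0; homog <- 0
  mu_i <- 0; mu_j <- 0
  for (i in 1:n_levels) for (j in 1:n_levels) {
    mu_i <- mu_i + (i - 1) * P[i, j]
    mu_j <- mu_j + (j - 1) * P[i, j]
  }
  s_i <- 0; s_j <- 0; corr_num <- 0
  for (i in 1:n_levels) for (j in 1:n_levels) {
    contrast <- contrast + P[i, j] * (i - j)^2
    energy <- energy + P[i, j]^2
    homog <- homog + P[i, j] / (1 + (i - j)^2)
    s_i <- s_i + (i - 1 - mu_i)^2 * P[i, j]
    s_j <- s_j + (j - 1 - mu_j)^2 * P[i, j]
    corr_num <- corr_num + P[i, j] * (i - 1 - mu_i) * (j - 1 - mu_j)
  }
  corr <- if (s_i == 0 || s_j == 0) NA_real_ else corr_num / sqrt(s_i * s_j)
  list(glcm_contrast = contrast, glcm_correlation = corr,
       glcm_energy = energy, glcm_homogeneity = homog)
}

oracle_features <- function(slice) {
  pixels <- slice$intensities[slice$mask == 1]
  c(oracle_first_order(pixels, slice$bit_depth),
    oracle_local(slice),
    oracle_glcm_props(slice))
}

# pooled two-sample t statistic, squared: the classical identity oracle
oracle_t2 <- function(x, g) {
  g <- factor(g)
  x1 <- x[g == levels(g)[1]]; x2 <- x[g == levels(g)[2]]
  n1 <- length(x1); n2 <- length(x2)
  sp2 <- ((n1 - 1) * stats::var(x1) + (n2 - 1) * stats::var(x2)) /
    (n1 + n2 - 2)
  t <- (mean(x1) - mean(x2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  t^2
}

# AUC by exhaustive pair counting with half-credit for ties
oracle_auc_pairs <- function(scores, truth) {
  truth <- factor(as.character(truth))
  sp <- scores[truth == levels(truth)[2]]
  sn <- scores[truth == levels(truth)[1]]
  tot <- 0
  for (p in sp) for (q in sn)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(sp) * length(sn))
}

# flood-fill component labeling oracle (8-connectivity, recursive queue)
oracle_component_sizes <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  sizes <- integer(0)
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (mask[r0, c0] == 0 || seen[r0, c0]) next
    queue <- list(c(r0, c0)); seen[r0, c0] <- TRUE; size <- 0L
    while (length(queue) > 0) {
      cur <- queue[[1]]; queue <- queue[-1]; size <- size + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- cur[1] + dr; cc <- cur[2] + dc
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            mask[rr, cc] == 1 && !seen[rr, cc]) {
          seen[rr, cc] <- TRUE
          queue[[length(queue) + 1]] <- c(rr, cc)
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sizes
}
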