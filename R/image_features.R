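# Image feature battery: central-block crop, 36 colour channel moments over
# RGB / HSV / CIELAB, and 16 texture descriptors from the direction-averaged
# gray-level co-occurrence matrix.

#' Crop the central block of an image
#'
#' @param image An RGB array (`H x W x 3`, values in `[0, 1]`), e.g. an
#'   `image_sample`.
#' @param size Side of the square block in pixels (default 400).
#' @return A `size x size x 3` array. For odd residuals the extra row/column
#'   is taken from the bottom/right.
#' @export
crop_center_block <- function(image, size = 400L) {
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3) abort("`image` must be an H x W x 3 array.")
  if (d[1] < size || d[2] < size) {
    abort(sprintf("Image is %d x %d; cannot crop a %d x %d block.",
                  d[1], d[2], size, size))
  }
  r0 <- (d[1] - size) %/% 2
  c0 <- (d[2] - size) %/% 2
  block <- image[r0 + seq_len(size), c0 + seq_len(size), , drop = FALSE]
  attr(block, "grade") <- attr(image, "grade")
  block
}

#' Colour channel moment statistics (36 features)
#'
#' Converts the RGB block to HSV (hexcone transform, all channels in
#' `[0, 1]`) and CIELAB (sRGB, D65 white point; `L` in `[0, 100]`), then
#' computes per channel the mean, sample standard deviation (n-1 denominator),
#' skewness `m3 / m2^{3/2}` and kurtosis `m4 / m2^2` (normal = 3, not excess)
#' from central moments `m_k`. Channels with vanishing variance
#' (`m2 < 1e-12`) report 0 skewness and kurtosis.
#'
#' @param block An RGB array in `[0, 1]` (any spatial size).
#' @return Named numeric vector of 36 statistics, `<Channel>_<stat>` with
#'   channels `R,G,B,H,S,V,Ls,As,Bs` and stats `ave,std,skew,kurt`.
#' @export
color_statistics <- function(block) {
  d <- dim(block)
  if (length(d) != 3 || d[3] != 3) abort("`block` must be an H x W x 3 array.")
  rgb <- cbind(as.vector(block[, , 1]), as.vector(block[, , 2]),
               as.vector(block[, , 3]))

  hsv <- t(grDevices::rgb2hsv(t(rgb), maxColorValue = 1))
  lab <- grDevices::convertColor(rgb, from = "sRGB", to = "Lab")

  channels <- list(R = rgb[, 1], G = rgb[, 2], B = rgb[, 3],
                   H = hsv[, 1], S = hsv[, 2], V = hsv[, 3],
                   Ls = lab[, 1], As = lab[, 2], Bs = lab[, 3])

  out <- unlist(lapply(channels, channel_moments))
  names(out) <- as.vector(t(outer(names(channels),
                                  c("ave", "std", "skew", "kurt"),
                                  paste, sep = "_")))
  out
}

# mean, sd (n-1), skewness m3/m2^1.5, kurtosis m4/m2^2; degenerate -> 0
channel_moments <- function(x) {
  n <- length(x)
  mu <- mean(x)
  xc <- x - mu
  m2 <- mean(xc^2)
  s <- sqrt(sum(xc^2) / (n - 1))
  if (m2 < 1e-12) {
    c(mu, s, 0, 0)
  } else {
    c(mu, s, mean(xc^3) / m2^1.5, mean(xc^4) / m2^2)
  }
}

#' Gray-level co-occurrence matrix, direction-averaged
#'
#' Converts the block to grayscale (`0.2989 R + 0.5870 G + 0.1140 B`),
#' quantizes `[0, 1]` linearly into `levels` equal bins, counts co-occurring
#' gray-level pairs at unit distance in the four directions 0°, 45°, 90° and
#' 135° (out-of-bounds neighbours skipped), symmetrizes each directional
#' matrix as `P + t(P)`, averages the four, and normalizes to sum 1.
#'
#' @param block An RGB array in `[0, 1]`, or a grayscale matrix in `[0, 1]`.
#' @param levels Number of gray levels (default 8; must be >= 2).
#' @param normalize Normalize to probabilities (default `TRUE`).
#' @param directions Subset of `c("0", "45", "90", "135")` (degrees) to
#'   average over; default all four.
#' @return A `glcm` object: `levels x levels` matrix with attributes
#'   `levels`, `normalized`.
#' @export
compute_glcm <- function(block, levels = 8L, normalize = TRUE,
                         directions = c("0", "45", "90", "135")) {
  if (levels < 2) abort("`levels` must be at least 2.")
  gray <- if (length(dim(block)) == 3) {
    0.2989 * block[, , 1] + 0.5870 * block[, , 2] + 0.1140 * block[, , 3]
  } else {
    block
  }
  q <- quantize_gray(gray, levels)

  # offsets as (drow, dcol) at unit distance
  all_offsets <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L),
                      `90` = c(-1L, 0L), `135` = c(-1L, -1L))
  directions <- match.arg(directions, c("0", "45", "90", "135"),
                          several.ok = TRUE)
  offsets <- all_offsets[directions]
  acc <- matrix(0, levels, levels)
  for (off in offsets) {
    p <- glcm_one_offset(q, off[1], off[2], levels)
    acc <- acc + p + t(p)
  }
  acc <- acc / length(offsets)
  if (normalize) acc <- acc / sum(acc)
  structure(acc, class = c("glcm", "matrix", "array"),
            levels = levels, normalized = normalize)
}

# linear quantization of [0,1] into `levels` bins -> integer matrix in
# 1..levels
quantize_gray <- function(gray, levels) {
  q <- floor(gray * levels) + 1L
  q[q > levels] <- levels
  q[q < 1L] <- 1L
  q
}

# raw directed pair counts for one offset, vectorized via aligned submatrices
glcm_one_offset <- function(q, dr, dc, levels) {
  nr <- nrow(q); nc <- ncol(q)
  r1 <- max(1L, 1L - dr):min(nr, nr - dr)
  c1 <- max(1L, 1L - dc):min(nc, nc - dc)
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + dr, c1 + dc, drop = FALSE]
  counts <- tabulate((as.vector(a) - 1L) * levels + as.vector(b),
                     nbins = levels * levels)
  matrix(counts, nrow = levels, ncol = levels, byrow = TRUE)
}

#' Sixteen co-occurrence texture descriptors
#'
#' Computes the classical texture battery from a normalized symmetric GLCM
#' `p(i, j)` with 1-based level indices, logs base 2 and the convention
#' `0 * log 0 = 0`: entropy, energy (angular second moment), inertia
#' (contrast), correlation, homogeneity (`sum p / (1 + |i-j|)`),
#' dissimilarity, sum of squares (variance), sum average, sum variance, sum
#' entropy, difference variance, difference entropy, cluster shade, cluster
#' prominence, inverse difference moment (`sum p / (1 + (i-j)^2)`), and
#' maximum probability. Correlation is 0 by convention when the marginal
#' variance vanishes; sum variance is centred on the sum average.
#'
#' @param glcm A normalized symmetric matrix (e.g. from [compute_glcm()]).
#' @return Named numeric vector of 16 texture features.
#' @export
haralick16 <- function(glcm) {
  p <- unclass(glcm)
  ng <- nrow(p)
  if (abs(sum(p) - 1) > 1e-8) {
    abort("`glcm` must be normalized (entries summing to 1).")
  }

  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(p)                      # = py by symmetry
  mu <- sum(seq_len(ng) * px)
  sig2 <- sum((seq_len(ng) - mu)^2 * px)

  log2z <- function(x) ifelse(x > 0, log2(x), 0)

  # p_{x+y}(k), k = 2..2*ng ; p_{x-y}(k), k = 0..ng-1
  sums <- i + j
  diffs <- abs(i - j)
  pxy_sum <- vapply(2:(2 * ng), function(k) sum(p[sums == k]), numeric(1))
  pxy_diff <- vapply(0:(ng - 1), function(k) sum(p[diffs == k]), numeric(1))
  ks <- 2:(2 * ng)
  kd <- 0:(ng - 1)

  sum_average <- sum(ks * pxy_sum)
  diff_mean <- sum(kd * pxy_diff)

  c(
    Entropy = -sum(p * log2z(p)),
    Energy = sum(p^2),
    Inertia = sum((i - j)^2 * p),
    Correlation = if (sig2 < 1e-12) 0 else
      sum((i - mu) * (j - mu) * p) / sig2,
    Homogeneity = sum(p / (1 + abs(i - j))),
    Dissimilarity = sum(abs(i - j) * p),
    Sum_of_squares = sum((i - mu)^2 * p),
    Sum_average = sum_average,
    Sum_variance = sum((ks - sum_average)^2 * pxy_sum),
    Sum_entropy = -sum(pxy_sum * log2z(pxy_sum)),
    Difference_variance = sum((kd - diff_mean)^2 * pxy_diff),
    Difference_entropy = -sum(pxy_diff * log2z(pxy_diff)),
    Cluster_shade = sum((i + j - 2 * mu)^3 * p),
    Cluster_prominence = sum((i + j - 2 * mu)^4 * p),
    Inverse_difference_moment = sum(p / (1 + (i - j)^2)),
    Maximum_probability = max(p)
  )
}

#' Image feature table (52 features)
#'
#' Crops the central block of each image and extracts the 36 colour moments
#' and 16 texture descriptors, giving exactly 52 named columns.
#'
#' @param images List of `image_sample` arrays (or any RGB arrays).
#' @param labels Optional tibble with `sample_id`, `grade`; defaults to the
#'   grades carried by the images.
#' @param crop_size Central block side in pixels (default 400).
#' @param levels Gray levels for the co-occurrence matrix (default 8).
#' @return A feature table: tibble with `sample_id`, `grade` and 52 feature
#'   columns.
#' @export
image_feature_table <- function(images, labels = NULL, crop_size = 400L,
                                levels = 8L) {
  col_names <- c(
    as.vector(t(outer(c("R", "G", "B", "H", "S", "V", "Ls", "As", "Bs"),
                      c("ave", "std", "skew", "kurt"), paste, sep = "_"))),
    c("Entropy", "Energy", "Inertia", "Correlation", "Homogeneity",
      "Dissimilarity", "Sum_of_squares", "Sum_average", "Sum_variance",
      "Sum_entropy", "Difference_variance", "Difference_entropy",
      "Cluster_shade", "Cluster_prominence", "Inverse_difference_moment",
      "Maximum_probability"))

  if (!length(images)) {
    empty <- as_tibble(matrix(numeric(0), 0, 52, dimnames = list(NULL, col_names)))
    return(bind_cols(tibble(sample_id = character(0), grade = character(0)),
                     empty))
  }

  rows <- lapply(seq_along(images), function(k) {
    block <- tryCatch(crop_center_block(images[[k]], crop_size),
                      error = function(e) {
                        abort(sprintf("Image %d: %s", k, conditionMessage(e)))
                      })
    c(color_statistics(block), haralick16(compute_glcm(block, levels)))
  })
  mat <- do.call(rbind, rows)
  colnames(mat) <- col_names

  if (is.null(labels)) {
    grades <- vapply(images, function(im) attr(im, "grade") %||% NA_character_,
                     character(1))
    labels <- tibble(sample_id = sprintf("sample_%02d", seq_along(images)),
                     grade = grades)
  }
  out <- bind_cols(labels, as_tibble(mat))
  check_feature_table(out)
  out
}
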