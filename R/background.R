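# Automatic background-threshold detection and tissue masking.
#
# H&E background (glass, no tissue) is bright; tissue absorbs light. The
# threshold that splits the two is found per image, at low resolution, with
# Otsu's method on a blurred grayscale histogram. The mask itself is applied
# at the working (normalization) resolution.

#' Convert an RGB image to 8-bit grayscale luminance
#'
#' Uses ITU-R BT.601 luma weights (0.299, 0.587, 0.114), rounded half away
#' from zero to integers.
#'
#' @param image An [rgb_image].
#' @return An integer matrix \code{H x W} with values in \code{[0, 255]}.
#' @export
to_grayscale <- function(image) {
  stopifnot(inherits(image, "rgb_image"))
  px <- image$pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  ch <- function(k) matrix(px[, , k], h, w)   # keep H x W shape even when H = 1
  g <- round_half_away(0.299 * ch(1) + 0.587 * ch(2) + 0.114 * ch(3))
  storage.mode(g) <- "integer"
  g
}

# 1-D Gaussian kernel, truncated at radius ceiling(3*sigma), normalized.
gaussian_kernel <- function(sigma) {
  r <- ceiling(3 * sigma)
  k <- dnorm(-r:r, sd = sigma)
  k / sum(k)
}

# Separable Gaussian smoothing of a double matrix with symmetric (reflected)
# borders. Kept in doubles; callers round if they need integers.
gaussian_smooth <- function(mat, sigma) {
  k <- gaussian_kernel(sigma)
  r <- (length(k) - 1L) / 2L
  smooth_1d <- function(m) {
    # convolve columns of m with k, reflected borders
    n <- nrow(m)
    pad <- c(pmin(r:1, n), 1:n, pmax(n - seq_len(r) + 1L, 1L))
    mp <- m[pad, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (i in seq_along(k)) {
      out <- out + k[i] * mp[i:(i + n - 1L), , drop = FALSE]
    }
    out
  }
  t(smooth_1d(t(smooth_1d(mat))))
}

#' Gaussian blur of a grayscale image
#'
#' Convolution with a normalized 2-D Gaussian kernel truncated at radius
#' \code{ceiling(3*sigma)}, reflected borders, rounded half away from zero
#' back to integers. A constant image is unchanged.
#'
#' @param gray Integer matrix \code{H x W} in \code{[0, 255]}.
#' @param sigma Positive standard deviation in pixels.
#' @return Blurred integer matrix of the same shape.
#' @export
gaussian_blur <- function(gray, sigma) {
  if (!is.matrix(gray)) stainkit_error("parameter", "gray must be an H x W matrix")
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stainkit_error("parameter", "sigma must be a positive real")
  }
  g <- round_half_away(gaussian_smooth(gray + 0, sigma))
  storage.mode(g) <- "integer"
  g
}

#' Otsu threshold of a grayscale image
#'
#' Maximizes the between-class variance
#' \eqn{\omega_0(t)\,\omega_1(t)\,(\mu_0(t)-\mu_1(t))^2} over the 256-bin
#' histogram, with classes \code{{<= t}} and \code{{> t}}. Ties are broken
#' toward the smallest maximizing threshold. A single-valued (degenerate)
#' histogram returns that value with a warning.
#'
#' @param gray Integer matrix with values in \code{[0, 255]}.
#' @return Integer threshold in \code{[0, 255]}.
#' @export
otsu_threshold <- function(gray) {
  if (length(gray) == 0) stainkit_error("parameter", "image must be non-empty")
  v <- as.integer(gray)
  if (min(v) < 0 || max(v) > 255) stainkit_error("parameter", "gray values must lie in [0, 255]")
  counts <- tabulate(v + 1L, nbins = 256L)
  if (sum(counts > 0) == 1L) {
    val <- which(counts > 0) - 1L
    stainkit_warning("degenerate_histogram", sprintf(
      "image has a single gray value (%d); Otsu threshold is degenerate", val
    ))
    return(as.integer(val))
  }
  n <- sum(counts)
  p <- counts / n
  levels <- 0:255
  w0 <- cumsum(p)                       # P(class <= t)
  m0 <- cumsum(p * levels)              # unnormalized class-0 mean
  mT <- m0[256]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, 256)
  bcv[valid] <- (mT * w0[valid] - m0[valid])^2 / (w0[valid] * w1[valid])
  as.integer(which.max(bcv) - 1L)       # which.max returns the first maximum
}

#' Automatic background threshold
#'
#' The automatic threshold block: read the image at low resolution, convert
#' to grayscale, blur to separate the histogram modes, and take the Otsu
#' threshold. Computed per image because background brightness varies across
#' slides within a dataset.
#'
#' @param image An [rgb_image] at the working resolution.
#' @param downsample Integer factor (default 4) at which thresholding runs.
#' @param sigma Gaussian blur standard deviation at the low resolution
#'   (default 2 pixels); \code{NULL} or 0 skips the blur.
#' @return Integer threshold in \code{[0, 255]}.
#' @export
auto_threshold <- function(image, downsample = 4, sigma = 2) {
  stopifnot(inherits(image, "rgb_image"))
  if (downsample < 1) stainkit_error("parameter", "downsample must be >= 1")
  small <- downsample_image(image, as.integer(downsample))
  g <- to_grayscale(small)
  if (!is.null(sigma) && sigma > 0) g <- gaussian_blur(g, sigma)
  otsu_threshold(g)
}

#' Tissue mask at working resolution
#'
#' A pixel is tissue iff its grayscale luminance is strictly below the
#' background threshold; bright pixels (glass) are background and carry
#' negligible optical density.
#'
#' @param image An [rgb_image].
#' @param threshold Integer in \code{[0, 255]}.
#' @return An object of class \code{tissue_mask}: list with \code{mask}
#'   (logical \code{H x W}) and \code{tissue_count}.
#' @export
tissue_mask <- function(image, threshold) {
  stopifnot(inherits(image, "rgb_image"))
  threshold <- as.integer(threshold)
  if (is.na(threshold) || threshold < 0 || threshold > 255) {
    stainkit_error("parameter", "threshold must be an integer in [0, 255]")
  }
  m <- to_grayscale(image) < threshold
  structure(
    list(mask = m, tissue_count = sum(m), threshold = threshold),
    class = "tissue_mask"
  )
}

# Row-major (origin top-left) ordering of tissue pixels: returns column-major
# array indices of TRUE cells, ordered by row then column.
tissue_indices <- function(mask) {
  m <- mask$mask
  h <- nrow(m); w <- ncol(m)
  rm_idx <- which(t(m))                 # row-major traversal
  r <- (rm_idx - 1L) %/% w + 1L
  cc <- (rm_idx - 1L) %% w + 1L
  (cc - 1L) * h + r
}
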