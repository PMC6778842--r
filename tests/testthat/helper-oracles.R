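# Independent brute-force oracles and small fixture builders. Oracles are
# deliberately naive (loops, full sorts, textbook formulas) so they share no
# code path with the implementation they check.

# Exhaustive Otsu: between-class variance at every threshold t in 0..255,
# classes {<= t} and {> t}; smallest maximizing t.
otsu_bruteforce <- function(gray) {
  v <- as.integer(gray)
  best_t <- NA_integer_
  best <- -Inf
  n <- length(v)
  for (t in 0:255) {
    lo <- v[v <= t]
    hi <- v[v > t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / n
    w1 <- length(hi) / n
    bcv <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (bcv > best + 1e-12) {
      best <- bcv
      best_t <- t
    }
  }
  best_t
}

# Full-sort nearest-rank percentile.
percentile_fullsort <- function(x, q) {
  n <- length(x)
  k <- if (q == 0) 1L else as.integer(ceiling(q * n / 100))
  sort(x)[k]
}

# Textbook two-pass population covariance.
cov_twopass <- function(od) {
  n <- nrow(od)
  mu <- colMeans(od)
  centered <- sweep(od, 2, mu)
  crossprod(centered) / n
}

unit_vec <- function(v) v / sqrt(sum(v^2))

qc_names <- function() c("H_R", "H_G", "H_B", "E_R", "E_G", "E_B", "maxCh", "maxCe")

# Constant-color RGB image.
const_image <- function(h, w, rgb = c(255L, 255L, 255L)) {
  px <- array(0L, dim = c(h, w, 3L))
  for (k in 1:3) px[, , k] <- rgb[k]
  rgb_image(px)
}

# Uniform-random RGB image, reproducible.
rand_image <- function(h, w, seed = 1L, lo = 0L, hi = 255L) {
  set.seed(seed)
  rgb_image(array(sample(lo:hi, h * w * 3L, replace = TRUE), dim = c(h, w, 3L)))
}

# Grayscale image (equal channels) from a matrix of values.
gray_rgb_image <- function(mat) {
  rgb_image(array(rep(mat, 3L), dim = c(dim(mat), 3L)))
}

# Mean absolute per-channel difference over a pixel set (logical mask).
mean_channel_diff <- function(img_a, img_b, mask) {
  d <- 0
  npx <- sum(mask)
  for (k in 1:3) {
    d <- d + sum(abs(img_a$pixels[, , k][mask] - img_b$pixels[, , k][mask]))
  }
  d / (3 * npx)
}
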