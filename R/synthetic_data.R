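# Synthetic H&E image generator.
#
# Images are built from the same physical model the estimator inverts:
# per-pixel stain concentrations mix two known unit stain vectors linearly
# in optical-density space (Beer-Lambert), then map to 8-bit RGB through
# 255 * 10^(-OD). Background is bright but noisy (channel values 245-255)
# so the tissue/background histogram is realistically bimodal, and optional
# saturated-color artifact blobs reproduce the failure mode that the robust
# QC must catch. Every generated feature is recorded as ground truth.

# Conventional H&E OD directions, unit-normalized; fixture defaults only.
base_stain_pair <- function() {
  list(H = unit(c(0.65, 0.70, 0.29)), E = unit(c(0.07, 0.99, 0.11)))
}

#' Ground truth of a synthetic image
#'
#' @param H_true,E_true Unit stain vectors used for rendering.
#' @param maxCh_true,maxCe_true Positive 99th-percentile concentrations over
#'   tissue.
#' @param background_mask,artifact_mask Logical \code{H x W} matrices
#'   (disjoint).
#' @param seed Integer seed the image was generated from.
#' @return An object of class \code{ground_truth}.
#' @export
ground_truth <- function(H_true, E_true, maxCh_true, maxCe_true,
                         background_mask, artifact_mask = NULL, seed = NA_integer_) {
  H_true <- unit(as.numeric(H_true)); E_true <- unit(as.numeric(E_true))
  if (is.null(artifact_mask)) {
    artifact_mask <- matrix(FALSE, nrow(background_mask), ncol(background_mask))
  }
  if (any(artifact_mask & background_mask)) {
    stainkit_error("parameter", "artifact and background masks must be disjoint")
  }
  structure(
    list(H_true = H_true, E_true = E_true,
         maxCh_true = as.numeric(maxCh_true), maxCe_true = as.numeric(maxCe_true),
         background_mask = background_mask, artifact_mask = artifact_mask,
         seed = as.integer(seed)),
    class = "ground_truth"
  )
}

# Smooth random blob mask covering a target fraction of the frame: threshold
# low-pass-filtered noise at the matching quantile.
make_tissue_blob <- function(shape, fraction, seed) {
  with_seed(seed, {
    noise <- matrix(rnorm(prod(shape)), shape[1], shape[2])
    # correlation length capped: structure has a fixed physical scale,
    # larger frames show more of it, not bigger blobs
    field <- gaussian_smooth(noise, sigma = clip(min(shape) / 8, 4, 32))
    field >= stats::quantile(field, 1 - fraction, names = FALSE)
  })
}

#' Generate smooth random concentration fields
#'
#' Emulates the spatial structure that makes H&E estimable: a smooth mixing
#' field assigns each tissue region a hematoxylin/eosin balance — with both
#' near-pure-H regions (nuclei-like) and near-pure-E regions (stroma-like)
#' — and a smooth amplitude field with a positive floor sets the total stain
#' amount, keeping tissue clearly darker than background. Both fields are
#' low-pass-filtered Gaussian noise; each concentration field is rescaled so
#' its nearest-rank 99th percentile over tissue equals the stated maximum.
#' Deterministic per seed.
#'
#' @param shape \code{c(H, W)} in pixels.
#' @param maxCh_true,maxCe_true Target 99th-percentile concentrations.
#' @param tissue Logical \code{H x W} tissue mask (\code{NULL} = all tissue).
#' @param smoothness Gaussian sigma of the low-pass filter, in pixels;
#'   default \code{min(shape)/16} capped into \code{[2, 8]} (structure has a
#'   fixed scale; larger frames show more of it).
#' @param seed Integer seed.
#' @return List with matrices \code{C_h} and \code{C_e} (non-negative).
#' @export
make_concentration_fields <- function(shape, maxCh_true, maxCe_true,
                                      tissue = NULL, smoothness = NULL, seed = 1L) {
  if (maxCh_true <= 0 || maxCe_true <= 0) {
    stainkit_error("parameter", "true maxima must be positive")
  }
  if (is.null(tissue)) tissue <- matrix(TRUE, shape[1], shape[2])
  if (is.null(smoothness)) smoothness <- clip(min(shape) / 16, 2, 8)
  smooth_unit_field <- function() {
    # low-pass noise mapped through its own normal CDF: smooth, ~uniform [0,1]
    noise <- matrix(rnorm(prod(shape)), shape[1], shape[2])
    f <- gaussian_smooth(noise, smoothness)
    stats::pnorm(f / stats::sd(f))
  }
  with_seed(seed, {
    mix <- smooth_unit_field()
    mix <- clip((mix - 0.1) / 0.8, 0, 1)   # ~10% pure-H and ~10% pure-E tissue
    amp <- 0.35 + 0.65 * smooth_unit_field()
    rescale <- function(f, target) {
      p99 <- percentile(f[tissue], 99)
      if (p99 < 1e-12) return(matrix(target, shape[1], shape[2]))
      f * (target / p99)
    }
    list(C_h = rescale(amp * mix, maxCh_true),
         C_e = rescale(amp * (1 - mix), maxCe_true))
  })
}

#' Render a synthetic H&E image from ground truth
#'
#' Tissue pixel channels are \code{round(255 * 10^-(C_h H + C_e E))} (half
#' away from zero, clipped); background pixels are drawn uniformly in
#' \code{[245, 255]} per channel. Deterministic given the truth's seed.
#'
#' @param truth A [ground_truth] (its \code{seed} drives the background
#'   noise).
#' @param C_h,C_e Concentration matrices matching the mask shape.
#' @return An [rgb_image].
#' @export
render_image <- function(truth, C_h, C_e) {
  stopifnot(inherits(truth, "ground_truth"))
  bg <- truth$background_mask
  h <- nrow(bg); w <- ncol(bg)
  if (!all(dim(C_h) == c(h, w)) || !all(dim(C_e) == c(h, w))) {
    stainkit_error("parameter", "concentration fields must match the mask shape")
  }
  px <- array(0L, dim = c(h, w, 3L))
  n_bg <- sum(bg)
  bg_seed <- if (is.na(truth$seed)) 0L else truth$seed
  bg_vals <- with_seed(bg_seed + 7L,
                       matrix(sample(245:255, n_bg * 3L, replace = TRUE), ncol = 3L))
  for (k in 1:3) {
    od <- C_h * truth$H_true[k] + C_e * truth$E_true[k]
    plane <- clip(round_half_away(255 * 10^(-od)), 0, 255)
    plane[bg] <- bg_vals[, k]
    px[, , k] <- plane
  }
  rgb_image(px)
}

#' Inject saturated-color artifact blobs into a synthetic image
#'
#' Overwrites random discs of tissue with an artifact color (plus small
#' per-pixel jitter), emulating staining spots, dirt or ink. The total
#' covered tissue fraction lands within about 20\% of the request; the
#' truth's artifact mask is updated.
#'
#' @param image The rendered [rgb_image].
#' @param truth Its [ground_truth].
#' @param color RGB triple of the artifact; default saturated blue
#'   \code{c(40, 40, 230)}.
#' @param coverage Target fraction of tissue covered, in \code{(0, 0.5)}.
#' @param n_blobs Number of discs; default 3.
#' @param seed Integer seed.
#' @return List with the modified \code{image} and updated \code{truth}.
#' @export
inject_artifact <- function(image, truth, color = c(40, 40, 230),
                            coverage = 0.2, n_blobs = 3L, seed = 1L) {
  stopifnot(inherits(image, "rgb_image"), inherits(truth, "ground_truth"))
  if (coverage <= 0 || coverage >= 0.5) {
    stainkit_error("parameter", "coverage must lie in (0, 0.5)")
  }
  tissue <- !truth$background_mask
  n_tissue <- sum(tissue)
  if (n_tissue == 0L) stainkit_error("empty_tissue", "image has no tissue to overwrite")
  h <- nrow(tissue); w <- ncol(tissue)
  target_px <- coverage * n_tissue
  t_idx <- which(tissue)
  with_seed(seed, {
    centers <- t_idx[sample.int(length(t_idx), n_blobs, replace = n_blobs > length(t_idx))]
    rows <- matrix(rep(seq_len(h), w), h, w)
    cols <- matrix(rep(seq_len(w), each = h), h, w)
    blob_mask <- function(radius) {
      m <- matrix(FALSE, h, w)
      for (ci in centers) {
        cr <- (ci - 1L) %% h + 1L
        cc <- (ci - 1L) %/% h + 1L
        m <- m | ((rows - cr)^2 + (cols - cc)^2 <= radius^2)
      }
      m & tissue
    }
    # discs overlapping each other, the background or the frame edge shrink
    # the covered area, so grow the analytic radius until the target is met
    radius <- sqrt(target_px / (n_blobs * pi))
    art <- blob_mask(radius)
    while (sum(art) < 0.95 * target_px && radius < max(h, w)) {
      radius <- radius * 1.05
      art <- blob_mask(radius)
    }
    if (sum(art) < 0.8 * target_px) {
      stainkit_warning("coverage_unreachable",
                       "requested artifact coverage could not be reached; best effort applied")
    }
    px <- image$pixels
    npx <- h * w
    idx <- which(art)
    jitter <- matrix(sample(-5:5, length(idx) * 3L, replace = TRUE), ncol = 3L)
    for (k in 1:3) {
      px[idx + (k - 1L) * npx] <- clip(color[k] + jitter[, k], 0L, 255L)
    }
  })
  truth$artifact_mask <- art
  list(image = rgb_image(px, level_downsample = image$level_downsample),
       truth = truth)
}

# Rotate unit vector v by `angle` radians toward a random direction
# perpendicular to it.
jitter_vector <- function(v, angle) {
  if (angle <= 0) return(v)
  p <- rnorm(3)
  p <- p - sum(p * v) * v
  p <- unit(p)
  unit(cos(angle) * v + sin(angle) * p)
}

#' Generate one synthetic H&E image with ground truth
#'
#' Convenience wrapper: tissue blob, concentration fields, rendering and
#' (optionally) artifact injection, all driven by one seed.
#'
#' @param shape \code{c(H, W)}; default \code{c(128, 128)}.
#' @param H_true,E_true Unit stain vectors; default the conventional H&E OD
#'   directions.
#' @param maxCh_true,maxCe_true True robust maxima; defaults 1.9705, 1.0308.
#' @param tissue_fraction Fraction of the frame covered by tissue; default
#'   drawn uniformly in \code{[0.3, 0.6]}.
#' @param artifact Logical; add a saturated-blue artifact? Default FALSE.
#' @param artifact_coverage,artifact_color Passed to [inject_artifact()].
#' @param seed Integer seed; the image is fully reproducible from it.
#' @return List with \code{image} ([rgb_image]), \code{truth}
#'   ([ground_truth]), and the concentration fields \code{C_h}, \code{C_e}.
#' @export
synthesize_image <- function(shape = c(128L, 128L),
                             H_true = NULL, E_true = NULL,
                             maxCh_true = 1.9705, maxCe_true = 1.0308,
                             tissue_fraction = NULL, artifact = FALSE,
                             artifact_coverage = 0.2,
                             artifact_color = c(40, 40, 230), seed = 1L) {
  base <- base_stain_pair()
  if (is.null(H_true)) H_true <- base$H
  if (is.null(E_true)) E_true <- base$E
  if (is.null(tissue_fraction)) {
    tissue_fraction <- with_seed(seed + 11L, runif(1, 0.3, 0.6))
  }
  tissue <- make_tissue_blob(shape, tissue_fraction, seed + 1L)
  truth <- ground_truth(H_true, E_true, maxCh_true, maxCe_true,
                        background_mask = !tissue, seed = seed)
  fields <- make_concentration_fields(shape, maxCh_true, maxCe_true,
                                      tissue = tissue, seed = seed + 2L)
  img <- render_image(truth, fields$C_h, fields$C_e)
  if (artifact) {
    res <- inject_artifact(img, truth, color = artifact_color,
                           coverage = artifact_coverage, seed = seed + 3L)
    img <- res$image
    truth <- res$truth
  }
  list(image = img, truth = truth, C_h = fields$C_h, C_e = fields$C_e)
}

#' Generate a synthetic dataset
#'
#' \code{n_images} rendered images whose true stain vectors are jittered by
#' a bounded random rotation around a base pair; the first
#' \code{n_artifact_images} carry saturated-color artifact blobs. Fully
#' reproducible per seed.
#'
#' @param n_images Number of images.
#' @param n_artifact_images Number of artifact-carrying images
#'   (\code{<= n_images}).
#' @param shape \code{c(H, W)} per image; default \code{c(128, 128)}.
#' @param jitter_deg Maximum per-image stain rotation in degrees; default 10.
#' @param seed Integer master seed.
#' @param ... Further arguments passed to [synthesize_image()] (e.g.
#'   \code{artifact_coverage}, \code{artifact_color}, \code{maxCh_true}).
#' @return List of per-image lists (\code{image}, \code{truth}, \code{C_h},
#'   \code{C_e}), artifact images first.
#' @export
generate_dataset <- function(n_images, n_artifact_images = 0L,
                             shape = c(128L, 128L), jitter_deg = 10,
                             seed = 1L, ...) {
  if (n_artifact_images > n_images) {
    stainkit_error("parameter", "n_artifact_images must not exceed n_images")
  }
  base <- base_stain_pair()
  lapply(seq_len(n_images), function(i) {
    img_seed <- seed + 1000L * i
    hv <- base$H; ev <- base$E
    if (jitter_deg > 0) {
      ang <- with_seed(img_seed + 5L, runif(2, 0, jitter_deg * pi / 180))
      hv <- with_seed(img_seed + 6L, jitter_vector(base$H, ang[1]))
      ev <- with_seed(img_seed + 7L, jitter_vector(base$E, ang[2]))
    }
    synthesize_image(shape = shape, H_true = hv, E_true = ev,
                     artifact = i <= n_artifact_images, seed = img_seed, ...)
  })
}
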