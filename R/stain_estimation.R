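# Stain-vector and concentration estimation in optical-density space.
#
# The estimation follows the SVD-plane geometry of Macenko et al.: tissue
# pixels are mapped to optical density OD = -log10(I/255), the two leading
# principal directions of the OD cloud span a plane containing both stain
# vectors, and the robust angular extremes of the projected pixels identify
# hematoxylin and eosin. Robust maximum concentrations are high percentiles
# of the per-pixel stain coefficients. The implementation carries the
# optimizations that make this tractable on whole-slide images: a 256-entry
# OD look-up table, covariance assembled from component sums in one pass,
# selection-based (partial-sort) percentiles, and Monte Carlo pixel sampling.

#' Build the RGB-to-optical-density look-up table
#'
#' \code{table[v] = -log10(max(v, clamp_floor) / 255)} for \code{v} in
#' \code{0..255}. The clamp floor keeps OD finite at true channel zeros
#' (\code{-log10(1/255)} is about 2.4065).
#'
#' @param clamp_floor Integer in \code{[1, 255]}; channel values below it are
#'   treated as \code{clamp_floor}. Default 1.
#' @return An object of class \code{od_lut}: list with \code{table} (256
#'   non-negative reals, indexed by channel value + 1) and \code{clamp_floor}.
#' @export
build_od_lut <- function(clamp_floor = 1L) {
  clamp_floor <- as.integer(clamp_floor)
  if (is.na(clamp_floor) || clamp_floor < 1L || clamp_floor > 255L) {
    stainkit_error("parameter", "clamp_floor must be an integer in [1, 255]")
  }
  v <- 0:255
  structure(
    list(table = -log10(pmax(v, clamp_floor) / 255), clamp_floor = clamp_floor),
    class = "od_lut"
  )
}

#' Convert tissue pixels to an optical-density matrix
#'
#' One row per tissue pixel in row-major pixel order (origin top-left), each
#' channel mapped through the look-up table. OD conversion is performed on
#' non-background pixels only.
#'
#' @param image An [rgb_image].
#' @param mask A [tissue_mask].
#' @param lut An \code{od_lut} from [build_od_lut()].
#' @return Numeric matrix \code{N x 3} (columns R, G, B) of non-negative OD
#'   values; an all-background mask raises an empty-tissue error.
#' @export
rgb_to_od <- function(image, mask, lut = build_od_lut()) {
  stopifnot(inherits(image, "rgb_image"), inherits(mask, "tissue_mask"),
            inherits(lut, "od_lut"))
  if (mask$tissue_count < 1L) {
    stainkit_error("empty_tissue", "no tissue pixels under the background threshold")
  }
  idx <- tissue_indices(mask)
  npx <- length(image$pixels) / 3L
  od <- cbind(
    lut$table[image$pixels[idx] + 1L],
    lut$table[image$pixels[idx + npx] + 1L],
    lut$table[image$pixels[idx + 2L * npx] + 1L]
  )
  colnames(od) <- c("R", "G", "B")
  od
}

#' Monte Carlo pixel-sampling specification
#'
#' @param rate Sampling rate in \code{(0, 1]}; 1 disables sampling. The
#'   default 0.01 (1\%) is the rate used throughout the package.
#' @param seed Integer seed making the sample reproducible.
#' @return An object of class \code{sampling_spec}.
#' @export
sampling_spec <- function(rate = 0.01, seed = 1L) {
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0 || rate > 1) {
    stainkit_error("parameter", "sampling rate must lie in (0, 1]")
  }
  structure(list(rate = as.numeric(rate), seed = as.integer(seed)),
            class = "sampling_spec")
}

#' Sample tissue-pixel indices
#'
#' Uniform random subset without replacement of size
#' \code{max(1, round(rate * n_total))}; deterministic for a fixed seed.
#' \code{rate = 1} returns all indices in their original order, so the
#' sampled path reproduces the unsampled estimate bit-for-bit.
#'
#' @param n_total Number of tissue pixels (>= 1).
#' @param spec A [sampling_spec].
#' @return Integer vector of 1-based indices into the OD matrix rows.
#' @export
sample_pixels <- function(n_total, spec) {
  stopifnot(inherits(spec, "sampling_spec"))
  n_total <- as.integer(n_total)
  if (is.na(n_total) || n_total < 1L) stainkit_error("parameter", "n_total must be >= 1")
  if (spec$rate >= 1) return(seq_len(n_total))
  size <- max(1L, as.integer(round_half_away(spec$rate * n_total)))
  with_seed(spec$seed, sample.int(n_total, size, replace = FALSE))
}

#' Covariance of OD components from sums
#'
#' Population covariance assembled in a single pass over the pixels from the
#' component sums and products:
#' \eqn{\Sigma_{ij} = \frac{1}{N}\sum_p x_{p,i} x_{p,j}
#'      - \frac{1}{N^2}\left(\sum_p x_{p,i}\right)\left(\sum_p x_{p,j}\right)}.
#'
#' @param od Numeric \code{N x 3} OD matrix with \code{N >= 2}.
#' @return Symmetric \code{3 x 3} covariance matrix.
#' @export
covariance_from_sums <- function(od) {
  n <- nrow(od)
  if (is.null(n) || n < 2L) {
    stainkit_error("insufficient_pixels", "covariance requires at least 2 pixels")
  }
  s1 <- colSums(od)
  s2 <- crossprod(od)
  sigma <- s2 / n - tcrossprod(s1) / n^2
  (sigma + t(sigma)) / 2
}

#' Principal plane of the OD cloud
#'
#' Unit eigenvectors of the covariance for the two largest eigenvalues — the
#' plane the SVD of the OD tuples would span. Each eigenvector is sign-fixed
#' so the sum of its components is non-negative (OD stains point into the
#' positive octant).
#'
#' @param sigma Symmetric \code{3 x 3} covariance matrix with at least two
#'   eigenvalues above \code{1e-12}.
#' @return List with orthonormal 3-vectors \code{e1}, \code{e2} and the
#'   corresponding \code{eigenvalues}.
#' @export
principal_plane <- function(sigma) {
  eg <- eigen(sigma, symmetric = TRUE)
  if (eg$values[2] <= 1e-12) {
    stainkit_error("degenerate_plane",
                   "OD covariance has rank < 2 (single-stain or constant image)")
  }
  fix_sign <- function(v) if (sum(v) < 0) -v else v
  list(
    e1 = fix_sign(eg$vectors[, 1]),
    e2 = fix_sign(eg$vectors[, 2]),
    eigenvalues = eg$values
  )
}

#' Project OD pixels onto the principal plane and compute angles
#'
#' Each pixel's plane coordinates \code{(u, v) = (od . e1, od . e2)} are
#' normalized to unit length and summarized by the angle
#' \code{phi = atan2(v, u)}. Pixels whose in-plane norm falls below
#' \code{1e-12} are dropped and counted.
#'
#' @param od Numeric \code{N x 3} OD matrix.
#' @param basis List with orthonormal \code{e1}, \code{e2} (from
#'   [principal_plane()]).
#' @return List with \code{angles} (finite reals), \code{dropped} (count),
#'   and the basis.
#' @export
project_and_angles <- function(od, basis) {
  u <- od %*% basis$e1
  v <- od %*% basis$e2
  nrm <- sqrt(u^2 + v^2)
  keep <- nrm >= 1e-12
  if (!any(keep)) {
    stainkit_error("degenerate_projection", "all pixels project to the origin of the stain plane")
  }
  list(
    angles = atan2(v[keep], u[keep]),
    dropped = sum(!keep),
    e1 = basis$e1, e2 = basis$e2
  )
}

#' Nearest-rank percentile by selection
#'
#' The \code{k}-th smallest value with \code{k = ceiling(q*n/100)} (and
#' \code{k = 1} for \code{q = 0}), found by partial sorting (a selection
#' algorithm) rather than a full sort; the result equals the full-sort
#' percentile exactly.
#'
#' @param values Non-empty numeric vector.
#' @param q Percentile in \code{[0, 100]}.
#' @return The nearest-rank percentile value.
#' @export
percentile <- function(values, q) {
  n <- length(values)
  if (n == 0L) stainkit_error("parameter", "percentile of an empty list is undefined")
  if (!is.numeric(q) || length(q) != 1L || q < 0 || q > 100) {
    stainkit_error("parameter", "q must lie in [0, 100]")
  }
  k <- if (q == 0) 1L else as.integer(ceiling(q * n / 100))
  sort(values, partial = k)[k]
}

#' Robust angular extremes
#'
#' The \code{alpha}-th and \code{(100 - alpha)}-th percentiles of the
#' projected pixel angles; robust stand-ins for the extreme directions that
#' identify the two stains.
#'
#' @param proj Projection from [project_and_angles()].
#' @param alpha Percentile parameter in \code{(0, 50]}; default 1.
#' @return Numeric \code{c(phi_lo, phi_hi)}.
#' @export
robust_angle_extremes <- function(proj, alpha = 1) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 50) {
    stainkit_error("parameter", "alpha must lie in (0, 50]")
  }
  if (alpha == 50) {
    stainkit_warning("degenerate_extremes", "alpha = 50 collapses both extremes to the median")
  }
  c(percentile(proj$angles, alpha), percentile(proj$angles, 100 - alpha))
}

#' Map extreme angles back to OD stain vectors
#'
#' \code{v = cos(phi) e1 + sin(phi) e2} for each extreme, negative OD
#' components clamped to zero (stains cannot emit light), renormalized to
#' unit length.
#'
#' @param phi_lo,phi_hi Extreme angles (must differ).
#' @param basis List with orthonormal \code{e1}, \code{e2}.
#' @return List with unit 3-vectors \code{v_lo}, \code{v_hi}.
#' @export
angles_to_stain_vectors <- function(phi_lo, phi_hi, basis) {
  if (isTRUE(all.equal(phi_lo, phi_hi, tolerance = 0))) {
    stainkit_error("degenerate_stains", "extreme angles coincide; stains are indistinguishable")
  }
  one <- function(phi) {
    v <- cos(phi) * basis$e1 + sin(phi) * basis$e2
    v[v < 0] <- 0
    unit(v)
  }
  list(v_lo = one(phi_lo), v_hi = one(phi_hi))
}

#' Assign hematoxylin and eosin labels to the two stain vectors
#'
#' Hematoxylin absorbs red light more strongly than eosin, so the vector with
#' the larger red-channel OD component is labelled H. Equal red components
#' are broken by the larger blue OD (hematoxylin is the bluer stain), with a
#' warning.
#'
#' @param v_lo,v_hi Distinct unit 3-vectors.
#' @return List with unit vectors \code{H} and \code{E}; invariant to the
#'   argument order.
#' @export
assign_h_e <- function(v_lo, v_hi) {
  if (v_lo[1] > v_hi[1]) {
    list(H = v_lo, E = v_hi)
  } else if (v_hi[1] > v_lo[1]) {
    list(H = v_hi, E = v_lo)
  } else {
    stainkit_warning("he_tie", "equal red OD components; assigning H by larger blue OD")
    if (v_lo[3] >= v_hi[3]) list(H = v_lo, E = v_hi) else list(H = v_hi, E = v_lo)
  }
}

#' Per-pixel stain concentrations
#'
#' Least-squares solution of \code{od_pixel ~ C_h * H + C_e * E} via the
#' pseudo-inverse of the \code{3 x 2} stain matrix. Values may be negative
#' for pixels outside the stain cone; downstream normalization clamps them.
#'
#' @param od Numeric \code{N x 3} OD matrix.
#' @param H,E Linearly independent unit stain vectors.
#' @return Numeric \code{N x 2} matrix, columns \code{C_h}, \code{C_e}.
#' @export
concentrations <- function(od, H, E) {
  M <- cbind(H, E)
  if (kappa(M, exact = TRUE) > 1e8) {
    stainkit_error("ill_conditioned", "stain vectors are near-collinear; cannot unmix")
  }
  C <- od %*% M %*% solve(crossprod(M))
  colnames(C) <- c("C_h", "C_e")
  C
}

#' Robust maximum stain concentrations
#'
#' Per-stain \code{(100 - alpha)}-th percentile of the concentration
#' distribution — with the default \code{alpha = 1}, the 99th percentile —
#' used instead of the true maximum to resist outlier pixels.
#'
#' @param C Numeric \code{N x 2} concentration matrix.
#' @param alpha Percentile parameter; default 1.
#' @return Numeric \code{c(maxCh, maxCe)}.
#' @export
robust_max_concentrations <- function(C, alpha = 1) {
  c(percentile(C[, 1], 100 - alpha), percentile(C[, 2], 100 - alpha))
}

#' Per-image stain parameters
#'
#' Container for one image's estimate: unit H and E vectors in OD space and
#' the robust maximum concentrations.
#'
#' @param H,E Unit 3-vectors (renormalized on construction unless
#'   \code{renormalize = FALSE}, used when restoring serialized values).
#' @param maxCh,maxCe Positive robust maximum concentrations.
#' @param alpha Percentile parameter used for the robust statistics.
#' @param n_tissue,sample_size,dropped Optional bookkeeping recorded by
#'   [estimate_stain_parameters()].
#' @param renormalize Renormalize H and E to unit length (default TRUE).
#' @return An object of class \code{stain_parameters}.
#' @export
stain_parameters <- function(H, E, maxCh, maxCe, alpha = 1,
                             n_tissue = NA_integer_, sample_size = NA_integer_,
                             dropped = 0L, renormalize = TRUE) {
  H <- as.numeric(H); E <- as.numeric(E)
  if (length(H) != 3L || length(E) != 3L) {
    stainkit_error("parameter", "H and E must be 3-vectors")
  }
  if (renormalize) { H <- unit(H); E <- unit(E) }
  if (!all(is.finite(c(maxCh, maxCe))) || maxCh <= 0 || maxCe <= 0) {
    stainkit_error("parameter", "maxCh and maxCe must be positive")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 50) {
    stainkit_error("parameter", "alpha must lie in (0, 50)")
  }
  structure(
    list(H = H, E = E, maxCh = as.numeric(maxCh), maxCe = as.numeric(maxCe),
         alpha = as.numeric(alpha), n_tissue = as.integer(n_tissue),
         sample_size = as.integer(sample_size), dropped = as.integer(dropped)),
    class = "stain_parameters"
  )
}

#' @export
print.stain_parameters <- function(x, ...) {
  cat(sprintf(
    paste0("<stain_parameters>\n  H = (%.4f, %.4f, %.4f)\n  E = (%.4f, %.4f, %.4f)\n",
           "  maxCh = %.4f  maxCe = %.4f  (alpha = %g)\n"),
    x$H[1], x$H[2], x$H[3], x$E[1], x$E[2], x$E[3], x$maxCh, x$maxCe, x$alpha
  ))
  if (!is.na(x$n_tissue)) {
    cat(sprintf("  tissue pixels: %d, sampled: %d, dropped: %d\n",
                x$n_tissue, x$sample_size, x$dropped))
  }
  invisible(x)
}

#' Estimate stain parameters for one image
#'
#' Full estimation pipeline on a working-resolution image: tissue masking at
#' the given background threshold, OD conversion of (a Monte Carlo sample of)
#' the tissue pixels, covariance from sums, principal plane, robust angular
#' extremes, H/E assignment, and robust maximum concentrations. The sampled
#' subset drives the covariance, the angle percentiles, and the concentration
#' percentiles; with \code{rate = 1} the estimate is identical to the
#' unsampled computation.
#'
#' @param image An [rgb_image] at working resolution.
#' @param threshold Integer background threshold; \code{NULL} (default)
#'   computes it with [auto_threshold()].
#' @param sampling A [sampling_spec]; default 1\% sampling, seed 1.
#' @param alpha Robust percentile parameter in \code{(0, 50)}; default 1.
#' @param clamp_floor OD look-up clamp floor; default 1.
#' @param image_id Optional identifier attached to error messages.
#' @return A [stain_parameters] with tissue/sample bookkeeping and the
#'   threshold used attached as attribute \code{threshold}.
#' @export
estimate_stain_parameters <- function(image, threshold = NULL,
                                      sampling = sampling_spec(rate = 1),
                                      alpha = 1, clamp_floor = 1L,
                                      image_id = NULL) {
  stopifnot(inherits(image, "rgb_image"))
  tag <- function(e) {
    if (!is.null(image_id)) {
      e$message <- sprintf("[image %s] %s", image_id, e$message)
    }
    stop(e)
  }
  tryCatch(
    {
      if (is.null(threshold)) threshold <- auto_threshold(image)
      mask <- tissue_mask(image, threshold)
      if (mask$tissue_count < 1L) {
        stainkit_error("empty_tissue", "no tissue pixels under the background threshold")
      }
      lut <- build_od_lut(clamp_floor)
      od <- rgb_to_od(image, mask, lut)
      idx <- sample_pixels(nrow(od), sampling)
      ods <- od[idx, , drop = FALSE]
      sigma <- covariance_from_sums(ods)
      basis <- principal_plane(sigma)
      proj <- project_and_angles(ods, basis)
      phis <- robust_angle_extremes(proj, alpha)
      vs <- angles_to_stain_vectors(phis[1], phis[2], basis)
      he <- assign_h_e(vs$v_lo, vs$v_hi)
      C <- concentrations(ods, he$H, he$E)
      maxc <- robust_max_concentrations(C, alpha)
      p <- stain_parameters(
        H = he$H, E = he$E, maxCh = maxc[1], maxCe = maxc[2], alpha = alpha,
        n_tissue = mask$tissue_count, sample_size = length(idx),
        dropped = proj$dropped, renormalize = FALSE
      )
      attr(p, "threshold") <- as.integer(threshold)
      p
    },
    stainkit_error = function(e) tag(e)
  )
}
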