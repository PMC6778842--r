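test_that("OD look-up table matches the direct logarithm", {
  lut <- build_od_lut(1L)
  expect_identical(lut$table[255 + 1], 0)                      # -log10(1)
  expect_equal(lut$table[0 + 1], -log10(1 / 255))
  expect_identical(lut$table[0 + 1], lut$table[1 + 1])         # clamp at floor
  v <- 1:255
  expect_identical(lut$table[v + 1], -log10(v / 255))          # definitional
  lut20 <- build_od_lut(20L)
  expect_true(all(lut20$table[1:20] == -log10(20 / 255)))
  expect_error(build_od_lut(0L), class = "stainkit_parameter")
  expect_error(build_od_lut(256L), class = "stainkit_parameter")
})

test_that("RGB-to-OD conversion maps tissue pixels through the LUT", {
  px <- array(255L, dim = c(2L, 2L, 3L))
  px[1, 1, ] <- 26L
  img <- rgb_image(px)
  mask <- tissue_mask(img, 100)
  od <- rgb_to_od(img, mask)
  expect_equal(nrow(od), 1L)
  expect_equal(od[1, ], c(R = -log10(26 / 255), G = -log10(26 / 255), B = -log10(26 / 255)))

  # white pixel -> zero OD row (threshold 255 keeps every non-white pixel out)
  px[1, 1, ] <- 254L
  od <- rgb_to_od(rgb_image(px), tissue_mask(rgb_image(px), 255))
  expect_equal(unname(od[1, ]), rep(-log10(254 / 255), 3))

  expect_error(rgb_to_od(img, tissue_mask(img, 0)), class = "stainkit_empty_tissue")
})

test_that("pixel sampling is deterministic, correctly sized, and full at rate 1", {
  expect_identical(sample_pixels(10, sampling_spec(rate = 1)), 1:10)

  spec <- sampling_spec(rate = 0.01, seed = 123L)
  s1 <- sample_pixels(100000, spec)
  s2 <- sample_pixels(100000, spec)
  expect_identical(s1, s2)
  expect_length(s1, 1000L)
  expect_false(anyDuplicated(s1) > 0)

  s3 <- sample_pixels(100000, sampling_spec(rate = 0.01, seed = 124L))
  expect_false(identical(s1, s3))

  expect_length(sample_pixels(10, sampling_spec(rate = 0.001, seed = 1L)), 1L)
})

test_that("single-pass covariance equals the two-pass oracle", {
  od <- matrix(rep(c(0.3, 0.5, 0.7), each = 5), 5, 3)
  expect_equal(covariance_from_sums(od), matrix(0, 3, 3), ignore_attr = TRUE)

  od <- rbind(c(1, 0, 0), c(0, 1, 0))
  sig <- covariance_from_sums(od)
  expect_equal(unname(sig),
               matrix(c(0.25, -0.25, 0, -0.25, 0.25, 0, 0, 0, 0), 3, 3))

  set.seed(31)
  for (i in 1:5) {
    od <- matrix(runif(3000, 0, 2.4), 1000, 3)
    sig <- covariance_from_sums(od)
    oracle <- cov_twopass(od)
    expect_lt(max(abs(sig - oracle)) / max(abs(oracle)), 1e-10)
  }
  expect_error(covariance_from_sums(od[1, , drop = FALSE]),
               class = "stainkit_insufficient_pixels")
})

test_that("principal plane spans the leading eigen-directions with fixed signs", {
  basis <- principal_plane(diag(c(3, 2, 1)))
  expect_equal(basis$e1, c(1, 0, 0))
  expect_equal(basis$e2, c(0, 1, 0))

  # noise-free data in the span of two known vectors
  a <- c(0.65, 0.70, 0.29) / sqrt(sum(c(0.65, 0.70, 0.29)^2))
  b <- c(0.07, 0.99, 0.11) / sqrt(sum(c(0.07, 0.99, 0.11)^2))
  set.seed(5)
  w <- matrix(runif(400, 0, 2), 200, 2)
  od <- w %*% rbind(a, b)
  basis <- principal_plane(covariance_from_sums(od))
  expect_equal(abs(sum(basis$e1 * basis$e2)), 0, tolerance = 1e-10)
  for (v in list(a, b)) {
    in_plane <- sum(v * basis$e1) * basis$e1 + sum(v * basis$e2) * basis$e2
    expect_lt(angle_between(v, in_plane) * pi / 180, 1e-6)
  }

  # rank-1 covariance has no stain plane
  expect_error(principal_plane(tcrossprod(c(1, 2, 3))), class = "stainkit_degenerate_plane")
})

test_that("plane projection angles follow atan2 conventions", {
  basis <- list(e1 = c(1, 0, 0), e2 = c(0, 1, 0))
  od <- rbind(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0, 0, 1e-15))
  proj <- project_and_angles(od, basis)
  expect_equal(proj$angles, c(0, pi / 2, pi))
  expect_identical(proj$dropped, 1L)                 # near-zero projection dropped
  expect_error(project_and_angles(rbind(c(0, 0, 1e-14)), basis),
               class = "stainkit_degenerate_projection")
})

test_that("selection percentile equals the full-sort percentile exactly", {
  expect_identical(percentile(1:100, 99), 99L)
  expect_identical(percentile(5, 50), 5)
  expect_identical(percentile(5, 0), 5)
  set.seed(17)
  for (i in 1:25) {
    n <- sample(1:500, 1)
    x <- runif(n, -10, 10)
    for (q in c(0, sample(1:99, 12), 100)) {
      expect_identical(percentile(x, q), percentile_fullsort(x, q))
    }
  }
  expect_error(percentile(numeric(0), 50), class = "stainkit_parameter")
})

test_that("robust angle extremes are the alpha and 100-alpha percentiles", {
  set.seed(23)
  proj <- list(angles = runif(1e5, 0.2, 1.3))
  ex <- robust_angle_extremes(proj, alpha = 1)
  expect_equal(ex[1], 0.211, tolerance = 0.005)
  expect_equal(ex[2], 1.289, tolerance = 0.005)

  proj2 <- list(angles = rep(c(0.4, 0.9), each = 50))
  expect_equal(robust_angle_extremes(proj2, 1), c(0.4, 0.9))

  expect_warning(ex50 <- robust_angle_extremes(proj2, 50),
                 class = "stainkit_degenerate_extremes")
  expect_identical(ex50[1], ex50[2])
})

test_that("extreme angles map back to clamped unit stain vectors", {
  basis <- list(e1 = c(1, 0, 0), e2 = c(0, 1, 0))
  vs <- angles_to_stain_vectors(0, pi / 4, basis)
  expect_equal(vs$v_lo, c(1, 0, 0))
  expect_equal(vs$v_hi, c(sqrt(2) / 2, sqrt(2) / 2, 0))

  # negative components are clamped then renormalized
  vs <- angles_to_stain_vectors(-pi / 4, pi / 2, basis)
  expect_equal(vs$v_lo, c(1, 0, 0))

  expect_error(angles_to_stain_vectors(0.7, 0.7, basis),
               class = "stainkit_degenerate_stains")
})

test_that("H/E assignment keys on the red OD component and is order-invariant", {
  v1 <- c(0.65, 0.70, 0.29); v2 <- c(0.07, 0.99, 0.11)
  he <- assign_h_e(v1, v2)
  expect_equal(he$H, v1)
  expect_equal(he$E, v2)
  he_swapped <- assign_h_e(v2, v1)
  expect_identical(he, he_swapped)

  u1 <- c(0.5, 0.5, 0.9); u2 <- c(0.5, 0.9, 0.1)
  expect_warning(tie <- assign_h_e(u1, u2), class = "stainkit_he_tie")
  expect_equal(tie$H, u1)                            # larger blue wins H
})

test_that("concentration unmixing is exact on in-span OD rows", {
  H <- unname(c(0.65, 0.70, 0.29) / sqrt(sum(c(0.65, 0.70, 0.29)^2)))
  E <- unname(c(0.07, 0.99, 0.11) / sqrt(sum(c(0.07, 0.99, 0.11)^2)))
  od <- rbind(1.2 * H, 0 * H, 0.5 * H + 2.0 * E)
  C <- concentrations(od, H, E)
  expect_equal(unname(C[1, ]), c(1.2, 0), tolerance = 1e-10)
  expect_equal(unname(C[2, ]), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(C[3, ]), c(0.5, 2.0), tolerance = 1e-10)

  expect_error(concentrations(od, H, H * (1 + 1e-12)),
               class = "stainkit_ill_conditioned")
})

test_that("robust maximum concentrations are columnwise nearest-rank percentiles", {
  C <- cbind(1:100, rep(7, 100))
  mx <- robust_max_concentrations(C, alpha = 1)
  expect_identical(mx[1], 99)
  expect_identical(mx[2], 7)
  set.seed(29)
  C <- cbind(rnorm(321), rexp(321))
  mx <- robust_max_concentrations(C, alpha = 1)
  expect_identical(mx[1], percentile_fullsort(C[, 1], 99))
  expect_identical(mx[2], percentile_fullsort(C[, 2], 99))
})

test_that("full estimation recovers synthetic ground truth", {
  s <- synthesize_image(shape = c(256L, 256L), seed = 101)
  p <- estimate_stain_parameters(s$image, sampling = sampling_spec(rate = 1))
  expect_lt(angle_between(p$H, s$truth$H_true), 2)
  expect_lt(angle_between(p$E, s$truth$E_true), 2)
  expect_lt(abs(p$maxCh - s$truth$maxCh_true) / s$truth$maxCh_true, 0.05)
  expect_lt(abs(p$maxCe - s$truth$maxCe_true) / s$truth$maxCe_true, 0.05)

  # Monte Carlo sampling stays close to the full estimate
  ps <- estimate_stain_parameters(s$image, sampling = sampling_spec(rate = 0.01, seed = 8))
  err <- sampling_error(p, ps)
  expect_lt(err$odm_distance, 0.05)

  expect_error(estimate_stain_parameters(const_image(32, 32, c(255L, 255L, 255L)),
                                         threshold = 200),
               class = "stainkit_empty_tissue")

  # failures carry the image identifier
  expect_error(
    estimate_stain_parameters(const_image(32, 32, c(255L, 255L, 255L)),
                              threshold = 200, image_id = "blank.png"),
    "blank.png"
  )
})

test_that("estimation statistics are invariant to tissue-pixel order", {
  s <- synthesize_image(shape = c(96L, 96L), seed = 55)
  th <- auto_threshold(s$image)
  od <- rgb_to_od(s$image, tissue_mask(s$image, th))
  set.seed(60)
  odp <- od[sample.int(nrow(od)), ]
  expect_equal(covariance_from_sums(od), covariance_from_sums(odp))
  basis <- principal_plane(covariance_from_sums(od))
  a1 <- sort(project_and_angles(od, basis)$angles)
  a2 <- sort(project_and_angles(odp, basis)$angles)
  expect_equal(a1, a2)
  expect_identical(percentile(od[, 1], 99), percentile(odp[, 1], 99))
})

test_that("scaling all concentrations scales the robust maxima, not the vectors", {
  s1 <- synthesize_image(shape = c(128L, 128L), seed = 77,
                         maxCh_true = 1.0, maxCe_true = 0.6)
  s2 <- synthesize_image(shape = c(128L, 128L), seed = 77,
                         maxCh_true = 1.5, maxCe_true = 0.9)
  th <- 200L
  p1 <- estimate_stain_parameters(s1$image, threshold = th,
                                  sampling = sampling_spec(rate = 1))
  p2 <- estimate_stain_parameters(s2$image, threshold = th,
                                  sampling = sampling_spec(rate = 1))
  expect_equal(p2$maxCh / p1$maxCh, 1.5, tolerance = 0.05)
  expect_equal(p2$maxCe / p1$maxCe, 1.5, tolerance = 0.05)
  expect_lt(angle_between(p1$H, p2$H), 1)
  expect_lt(angle_between(p1$E, p2$E), 1)
})
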