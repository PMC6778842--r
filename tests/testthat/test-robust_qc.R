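fake_sidecar <- function(id, H = c(0.65, 0.70, 0.29), E = c(0.07, 0.99, 0.11),
                         maxCh = 1.9, maxCe = 1.0) {
  parameter_sidecar(
    id,
    stain_parameters(H = H, E = E, maxCh = maxCh, maxCe = maxCe, alpha = 1),
    threshold = 200, sampling_rate = 1, seed = 1L
  )
}

test_that("parameter collection builds one row per image and rejects duplicates", {
  scs <- list(fake_sidecar("a"), fake_sidecar("b", maxCh = 2.1), fake_sidecar("c"))
  qc <- collect_parameters(scs)
  expect_identical(nrow(qc$parameters), 3L)
  expect_identical(qc$parameters$image_id, c("a", "b", "c"))
  expect_equal(qc$parameters$maxCh, c(1.9, 2.1, 1.9))
  expect_equal(qc$parameters$H_R[1], scs[[1]]$H[1])

  expect_error(collect_parameters(list()), class = "stainkit_parameter")
  expect_error(collect_parameters(list(fake_sidecar("a"), fake_sidecar("a"))),
               class = "stainkit_parameter")
})

test_that("Tukey fences use nearest-rank quartiles", {
  scs <- lapply(1:9, function(i) fake_sidecar(paste0("img", i), maxCh = i))
  qc <- compute_bounds(collect_parameters(scs), method = "tukey", k = 1.5)
  b <- qc$bounds[qc$bounds$parameter == "maxCh", ]
  expect_equal(b$lower, -3)                          # Q1=3, Q3=7, IQR=4
  expect_equal(b$upper, 13)

  # all-equal parameter: zero-width bounds, no violations
  b_const <- qc$bounds[qc$bounds$parameter == "maxCe", ]
  expect_equal(b_const$lower, 1.0)
  expect_equal(b_const$upper, 1.0)
  flagged <- flag_outliers(qc)
  expect_false(any(flagged$outlier))
})

test_that("manual bounds pass through; statistical rules need three images", {
  scs <- list(fake_sidecar("a"), fake_sidecar("b"))
  qc <- collect_parameters(scs)
  expect_error(compute_bounds(qc, method = "tukey"), class = "stainkit_insufficient_data")

  manual <- data.frame(
    parameter = c("H_R", "H_G", "H_B", "E_R", "E_G", "E_B", "maxCh", "maxCe"),
    lower = rep(0, 8), upper = rep(3, 8)
  )
  qc <- compute_bounds(qc, method = "manual", manual = manual)
  expect_equal(qc$bounds$lower, rep(0, 8))
  expect_equal(qc$bounds$upper, rep(3, 8))
})

test_that("a single violated parameter flags the image", {
  scs <- c(lapply(1:7, function(i) fake_sidecar(paste0("g", i))),
           list(fake_sidecar("bad", maxCh = 19)))        # 10x the common value
  qc <- flag_outliers(compute_bounds(collect_parameters(scs)))
  expect_identical(which(qc$outlier), 8L)

  # violation in one stain component alone suffices
  scs2 <- c(lapply(1:7, function(i) {
    fake_sidecar(paste0("g", i), H = c(0.65, 0.70, 0.29 + 0.001 * i))
  }), list(fake_sidecar("bad", H = c(0.65, 0.70, 0.95))))
  qc2 <- flag_outliers(compute_bounds(collect_parameters(scs2)))
  expect_identical(which(qc2$outlier), 8L)

  # every image out of (manual) bounds: no good subset exists
  manual <- data.frame(parameter = qc_names(), lower = rep(100, 8), upper = rep(101, 8))
  qc3 <- compute_bounds(collect_parameters(scs), method = "manual", manual = manual)
  expect_error(flag_outliers(qc3), class = "stainkit_all_outliers")
})

test_that("flags are invariant to image order", {
  scs <- c(lapply(1:8, function(i) fake_sidecar(paste0("g", i), maxCh = 1.8 + 0.02 * i)),
           list(fake_sidecar("bad", maxCh = 12)))
  qc_fwd <- flag_outliers(compute_bounds(collect_parameters(scs)))
  set.seed(4)
  perm <- sample(length(scs))
  qc_perm <- flag_outliers(compute_bounds(collect_parameters(scs[perm])))
  expect_identical(qc_fwd$outlier[perm], qc_perm$outlier)
})

test_that("the representative set is the renormalized mean of good images", {
  scs <- c(lapply(1:7, function(i) fake_sidecar(paste0("g", i), maxCh = 1 + (i %% 2) * 2)),
           list(fake_sidecar("bad", maxCh = 40)))
  qc <- representative_set(flag_outliers(compute_bounds(collect_parameters(scs))))
  good_max <- qc$parameters$maxCh[!qc$outlier]
  expect_equal(qc$representative$maxCh, mean(good_max))
  expect_equal(sqrt(sum(qc$representative$H^2)), 1, tolerance = 1e-12)
  expect_equal(sqrt(sum(qc$representative$E^2)), 1, tolerance = 1e-12)

  # a single good image is its own representative
  one <- collect_parameters(list(fake_sidecar("solo", maxCh = 1.7)))
  manual <- data.frame(parameter = qc_names(), lower = rep(-10, 8), upper = rep(50, 8))
  one <- representative_set(flag_outliers(compute_bounds(one, "manual", manual = manual)))
  expect_equal(one$representative$maxCh, 1.7)
})

test_that("fast_rsn flags the artifact image and matches fast_sn when clean", {
  ds <- generate_dataset(8, n_artifact_images = 1, shape = c(96L, 96L), seed = 17)
  imgs <- lapply(ds, function(d) d$image)
  names(imgs) <- sprintf("img%02d", seq_along(imgs))

  res <- run_fast_rsn(imgs, sampling_rate = 1, seed = 2)
  expect_true(res$qc$outlier[1])                     # the artifact image
  expect_true(res$sidecars[[1]]$replaced)
  # replacement happens exactly for the flagged images
  replaced <- vapply(res$sidecars, function(s) s$replaced, TRUE)
  expect_identical(unname(replaced), res$qc$outlier)

  # clean dataset: zero flags and output identical to fast_sn
  clean <- lapply(ds[-1], function(d) d$image)
  names(clean) <- sprintf("img%02d", seq_along(clean))
  r_rsn <- run_fast_rsn(clean, sampling_rate = 1, seed = 2)
  expect_false(any(r_rsn$qc$outlier))
  r_sn <- run_fast_sn(clean, sampling_rate = 1, seed = 2)
  for (i in seq_along(clean)) {
    expect_identical(r_rsn$images[[i]]$pixels, r_sn$images[[i]]$pixels)
  }
})

test_that("fast_rsn_all applies one parameter set to every image", {
  ds <- generate_dataset(5, n_artifact_images = 1, shape = c(96L, 96L), seed = 23)
  imgs <- lapply(ds, function(d) d$image)
  names(imgs) <- sprintf("img%02d", seq_along(imgs))
  res <- run_fast_rsn_all(imgs, sampling_rate = 1, seed = 3)
  ref <- res$sidecars[[1]]
  for (sc in res$sidecars) {
    expect_identical(sc$H, ref$H)
    expect_identical(sc$E, ref$E)
    expect_identical(sc$maxCh, ref$maxCh)
    expect_identical(sc$maxCe, ref$maxCe)
    expect_true(sc$replaced)
  }
  # zero across-image variance of the applied parameters
  applied <- do.call(rbind, lapply(res$sidecars, function(s) c(s$H, s$E, s$maxCh, s$maxCe)))
  expect_true(all(apply(applied, 2, var) == 0))
})

test_that("robust QC needs at least two images", {
  s <- synthesize_image(shape = c(64L, 64L), seed = 1)
  expect_error(run_fast_rsn(list(a = s$image)), class = "stainkit_parameter")
})

test_that("sampling-error metrics follow their definitions", {
  p <- stain_parameters(H = c(0.65, 0.70, 0.29), E = c(0.07, 0.99, 0.11),
                        maxCh = 2.0, maxCe = 1.0)
  expect_equal(unlist(sampling_error(p, p)), c(odm_distance = 0,
                                               rel_err_maxCh = 0,
                                               rel_err_maxCe = 0))
  p2 <- stain_parameters(H = p$H, E = p$E, maxCh = 2.0 * 1.02, maxCe = 1.0,
                         renormalize = FALSE)
  expect_equal(sampling_error(p, p2)$rel_err_maxCh, 0.02)

  # a single perturbed coordinate gives that coordinate's distance
  H3 <- p$H; H3[2] <- H3[2] + 0.05
  p3 <- stain_parameters(H = H3, E = p$E, maxCh = 2.0, maxCe = 1.0,
                         renormalize = FALSE)
  expect_equal(sampling_error(p, p3)$odm_distance, 0.05)
})

test_that("QC reports serialize bounds, flags and the representative set", {
  scs <- lapply(1:5, function(i) fake_sidecar(paste0("img", i), maxCh = 1.8 + 0.05 * i))
  qc <- representative_set(flag_outliers(compute_bounds(collect_parameters(scs))))
  json_path <- withr::local_tempfile(fileext = ".json")
  csv_path <- withr::local_tempfile(fileext = ".csv")
  write_qc_report(qc, json_path, csv_path)
  rep <- jsonlite::fromJSON(json_path)
  expect_identical(nrow(rep$parameters), 5L)
  expect_identical(nrow(rep$bounds), 8L)
  expect_equal(rep$representative$maxCh, qc$representative$maxCh)
  tab <- utils::read.csv(csv_path)
  expect_identical(nrow(tab), 5L)
  expect_true("outlier" %in% names(tab))
})
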