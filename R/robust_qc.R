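# Dataset-level quality control: cross-check per-image stain parameters,
# flag poor-quality slides, build the representative parameter set, and run
# the robust normalization variants (fast_rsn, fast_rsn_all).
#
# The premise: artifacts (staining spots, dirt, ink) bias the estimated
# stain vectors toward the artifact color. Across one dataset the eight
# estimated parameters (H_R, H_G, H_B, E_R, E_G, E_B, maxCh, maxCe) of
# good-quality slides cluster tightly; a slide with at least one parameter
# outside its acceptable range is considered poor quality and is normalized
# with the mean parameters of the good-quality slides instead of its own.

qc_parameter_names <- c("H_R", "H_G", "H_B", "E_R", "E_G", "E_B", "maxCh", "maxCe")

#' Collect per-image stain parameters into a QC table
#'
#' One row per image with the eight cross-checked parameters, taken from
#' parameter sidecars (estimation run without the final normalization step).
#'
#' @param sidecars List of [parameter_sidecar] objects.
#' @return An object of class \code{qc_table}: list with \code{parameters}
#'   (data.frame, one row per image), and slots for \code{bounds},
#'   \code{outlier} flags and the \code{representative} parameter set filled
#'   in by the later QC steps.
#' @export
collect_parameters <- function(sidecars) {
  if (length(sidecars) < 1L) {
    stainkit_error("parameter", "at least one sidecar is required")
  }
  stopifnot(all(vapply(sidecars, inherits, TRUE, "parameter_sidecar")))
  ids <- vapply(sidecars, function(s) s$image_id, "")
  if (anyDuplicated(ids)) {
    stainkit_error("parameter", sprintf(
      "duplicate image identifier(s): %s", paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  rows <- do.call(rbind, lapply(sidecars, function(s) {
    data.frame(image_id = s$image_id,
               H_R = s$H[1], H_G = s$H[2], H_B = s$H[3],
               E_R = s$E[1], E_G = s$E[2], E_B = s$E[3],
               maxCh = s$maxCh, maxCe = s$maxCe,
               alpha = s$alpha, stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  structure(
    list(parameters = rows, bounds = NULL, outlier = NULL, representative = NULL),
    class = "qc_table"
  )
}

#' @export
print.qc_table <- function(x, ...) {
  cat(sprintf("<qc_table: %d image(s)>\n", nrow(x$parameters)))
  if (!is.null(x$outlier)) {
    cat(sprintf("  flagged poor-quality: %d\n", sum(x$outlier)))
  }
  invisible(x)
}

# Nearest-rank quartiles reuse the package percentile convention.
tukey_bounds <- function(v, k) {
  q1 <- percentile(v, 25)
  q3 <- percentile(v, 75)
  iqr <- q3 - q1
  c(q1 - k * iqr, q3 + k * iqr)
}

mad_bounds <- function(v, k) {
  med <- percentile(v, 50)
  m <- percentile(abs(v - med), 50)
  c(med - k * m, med + k * m)
}

#' Acceptable parameter ranges for a dataset
#'
#' Per-parameter lower and upper bounds. The default rule is Tukey fences
#' (\code{Q1 - k*IQR}, \code{Q3 + k*IQR}, quartiles by nearest rank,
#' \code{k = 1.5}), chosen because it is robust to the very outliers being
#' hunted. Alternatives: \code{median +- k*MAD}, or fixed manual bounds.
#'
#' @param table A [collect_parameters()] table.
#' @param method One of \code{"tukey"}, \code{"mad"}, \code{"manual"}.
#' @param k Fence multiplier for the statistical rules; default 1.5.
#' @param manual For \code{method = "manual"}: a data.frame with columns
#'   \code{parameter}, \code{lower}, \code{upper} covering all 8 parameters.
#' @return The table with its \code{bounds} slot set (data.frame with
#'   \code{parameter}, \code{lower}, \code{upper}).
#' @export
compute_bounds <- function(table, method = c("tukey", "mad", "manual"),
                           k = 1.5, manual = NULL) {
  stopifnot(inherits(table, "qc_table"))
  method <- match.arg(method)
  if (method == "manual") {
    if (is.null(manual) ||
        !all(c("parameter", "lower", "upper") %in% names(manual)) ||
        !setequal(manual$parameter, qc_parameter_names)) {
      stainkit_error("parameter",
                     "manual bounds need columns parameter/lower/upper covering all 8 parameters")
    }
    if (any(manual$lower > manual$upper)) {
      stainkit_error("parameter", "manual bounds must satisfy lower <= upper")
    }
    b <- manual[match(qc_parameter_names, manual$parameter),
                c("parameter", "lower", "upper")]
  } else {
    if (nrow(table$parameters) < 3L) {
      stainkit_error("insufficient_data", paste(
        "statistical bounds need at least 3 images;",
        "supply manual bounds for smaller datasets"
      ))
    }
    f <- if (method == "tukey") tukey_bounds else mad_bounds
    b <- do.call(rbind, lapply(qc_parameter_names, function(p) {
      lim <- f(table$parameters[[p]], k)
      data.frame(parameter = p, lower = lim[1], upper = lim[2],
                 stringsAsFactors = FALSE)
    }))
  }
  rownames(b) <- NULL
  table$bounds <- b
  table
}

#' Flag poor-quality images
#'
#' An image is an outlier iff at least one of its 8 parameters falls outside
#' its acceptable range. Non-flagged images form the good-quality subset.
#'
#' @param table A [qc_table] with bounds computed.
#' @return The table with its \code{outlier} slot set (logical per image).
#'   All images flagged raises an all-outliers error: no good-quality subset
#'   exists and the robust variants cannot proceed.
#' @export
flag_outliers <- function(table) {
  stopifnot(inherits(table, "qc_table"))
  if (is.null(table$bounds)) {
    stainkit_error("parameter", "compute bounds before flagging outliers")
  }
  p <- table$parameters
  viol <- vapply(seq_len(nrow(table$bounds)), function(j) {
    b <- table$bounds[j, ]
    v <- p[[b$parameter]]
    v < b$lower | v > b$upper
  }, logical(nrow(p)))
  flags <- if (nrow(p) == 1L) any(viol) else apply(viol, 1L, any)
  if (all(flags)) {
    stainkit_error("all_outliers",
                   "every image is flagged as poor quality; no good-quality subset exists")
  }
  table$outlier <- as.logical(flags)
  table
}

#' Representative parameter set of the good-quality images
#'
#' Component-wise arithmetic mean of the 8 parameters over non-outlier
#' images; the averaged H and E vectors are renormalized to unit length (the
#' mean of unit vectors is shorter than unit).
#'
#' @param table A [qc_table] with outlier flags set.
#' @return The table with its \code{representative} slot set to a
#'   [stain_parameters].
#' @export
representative_set <- function(table) {
  stopifnot(inherits(table, "qc_table"))
  if (is.null(table$outlier)) {
    stainkit_error("parameter", "flag outliers before computing the representative set")
  }
  good <- table$parameters[!table$outlier, , drop = FALSE]
  if (nrow(good) == 0L) {
    stainkit_error("all_outliers", "no good-quality images to average")
  }
  table$representative <- stain_parameters(
    H = c(mean(good$H_R), mean(good$H_G), mean(good$H_B)),
    E = c(mean(good$E_R), mean(good$E_G), mean(good$E_B)),
    maxCh = mean(good$maxCh), maxCe = mean(good$maxCe),
    alpha = good$alpha[1], renormalize = TRUE
  )
  table
}

# Shared engine for the robust variants: estimate everything, run QC, then
# normalize each image with its own or the representative parameters.
run_rsn_engine <- function(inputs, template, output_dir, sampling_rate, seed,
                           alpha, threshold, clamp_floor, bounds_method,
                           k, manual, replace_all, verbose) {
  batch <- resolve_inputs(inputs)
  n <- length(batch$images)
  if (n < 2L) stainkit_error("parameter", "robust QC needs at least 2 images")

  thresholds <- integer(n)
  params <- vector("list", n)
  masks <- vector("list", n)
  sidecars <- vector("list", n)
  for (i in seq_len(n)) {
    img <- batch$images[[i]]
    th <- if (is.null(threshold)) auto_threshold(img) else as.integer(threshold)
    sp <- sampling_spec(rate = sampling_rate, seed = seed + i - 1L)
    p <- estimate_stain_parameters(img, threshold = th, sampling = sp,
                                   alpha = alpha, clamp_floor = clamp_floor,
                                   image_id = batch$ids[i])
    thresholds[i] <- th
    params[[i]] <- p
    masks[[i]] <- tissue_mask(img, th)
    sidecars[[i]] <- parameter_sidecar(batch$ids[i], p, th, sampling_rate, sp$seed)
  }

  qc <- collect_parameters(sidecars)
  qc <- compute_bounds(qc, method = bounds_method, k = k, manual = manual)
  qc <- flag_outliers(qc)
  qc <- representative_set(qc)

  out_imgs <- vector("list", n)
  for (i in seq_len(n)) {
    use_rep <- replace_all || qc$outlier[i]
    p_use <- if (use_rep) qc$representative else params[[i]]
    out_imgs[[i]] <- normalize_image(batch$images[[i]], masks[[i]], p_use,
                                     template, clamp_floor)
    sidecars[[i]] <- parameter_sidecar(
      batch$ids[i],
      if (use_rep) {
        stain_parameters(p_use$H, p_use$E, p_use$maxCh, p_use$maxCe,
                         alpha = p_use$alpha,
                         n_tissue = params[[i]]$n_tissue,
                         sample_size = params[[i]]$sample_size,
                         renormalize = FALSE)
      } else p_use,
      thresholds[i], sampling_rate, seed + i - 1L,
      outlier = qc$outlier[i], replaced = use_rep
    )
    if (verbose) {
      message(sprintf("%s: %s%s", batch$ids[i],
                      if (qc$outlier[i]) "poor-quality" else "good",
                      if (use_rep) " (representative parameters applied)" else ""))
    }
    if (!is.null(output_dir)) {
      if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
      stem <- tools::file_path_sans_ext(batch$ids[i])
      write_image(out_imgs[[i]], file.path(output_dir, paste0(stem, "_normalized.png")))
      write_sidecar(sidecars[[i]], file.path(output_dir, paste0(stem, "_params.json")))
    }
  }
  names(out_imgs) <- batch$ids
  names(sidecars) <- batch$ids
  if (!is.null(output_dir)) {
    write_qc_report(qc, file.path(output_dir, "qc_report.json"))
  }
  invisible(list(images = out_imgs, sidecars = sidecars, qc = qc))
}

#' Robust batch normalization (fast_rsn)
#'
#' Estimates stain parameters for every image in the dataset, flags
#' poor-quality images whose parameters fall outside the acceptable ranges,
#' and normalizes: good images with their own parameters, flagged images
#' with the representative (mean good-quality) parameters. With zero flagged
#' images the output is identical to [run_fast_sn()].
#'
#' @inheritParams run_fast_sn
#' @param bounds_method Bound rule: \code{"tukey"} (default), \code{"mad"},
#'   or \code{"manual"}.
#' @param k Fence multiplier; default 1.5.
#' @param manual Manual bounds data.frame (see [compute_bounds()]).
#' @return Invisibly, a list with \code{images}, \code{sidecars} and the
#'   final \code{qc} table (bounds, flags, representative set).
#' @export
run_fast_rsn <- function(inputs, template = default_template(), output_dir = NULL,
                         sampling_rate = 0.01, seed = 1L, alpha = 1,
                         threshold = NULL, clamp_floor = 1L,
                         bounds_method = c("tukey", "mad", "manual"),
                         k = 1.5, manual = NULL, verbose = FALSE) {
  run_rsn_engine(inputs, template, output_dir, sampling_rate, seed, alpha,
                 threshold, clamp_floor, match.arg(bounds_method), k, manual,
                 replace_all = FALSE, verbose = verbose)
}

#' Robust batch normalization applying the representative set everywhere
#' (fast_rsn_all)
#'
#' Identical to [run_fast_rsn()] except that the representative parameters
#' are used to normalize every image, good and poor alike, giving the
#' dataset one uniform set of stain vectors.
#'
#' @inheritParams run_fast_rsn
#' @return As [run_fast_rsn()].
#' @export
run_fast_rsn_all <- function(inputs, template = default_template(), output_dir = NULL,
                             sampling_rate = 0.01, seed = 1L, alpha = 1,
                             threshold = NULL, clamp_floor = 1L,
                             bounds_method = c("tukey", "mad", "manual"),
                             k = 1.5, manual = NULL, verbose = FALSE) {
  run_rsn_engine(inputs, template, output_dir, sampling_rate, seed, alpha,
                 threshold, clamp_floor, match.arg(bounds_method), k, manual,
                 replace_all = TRUE, verbose = verbose)
}

#' Write a QC report
#'
#' JSON report with per-image parameters, the per-parameter bounds, outlier
#' flags and the representative set; optionally a flat CSV of the per-image
#' parameter table.
#'
#' @param qc A completed [qc_table].
#' @param path Output JSON path.
#' @param csv_path Optional CSV path for the parameter table.
#' @export
write_qc_report <- function(qc, path, csv_path = NULL) {
  stopifnot(inherits(qc, "qc_table"))
  rep <- qc$representative
  obj <- list(
    parameters = qc$parameters,
    bounds = qc$bounds,
    outlier = data.frame(image_id = qc$parameters$image_id,
                         outlier = qc$outlier %||% rep(NA, nrow(qc$parameters))),
    representative = if (!is.null(rep)) {
      list(H = rep$H, E = rep$E, maxCh = rep$maxCh, maxCe = rep$maxCe)
    }
  )
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, na = "null", dataframe = "rows"),
             path, useBytes = TRUE)
  if (!is.null(csv_path)) {
    tab <- qc$parameters
    if (!is.null(qc$outlier)) tab$outlier <- qc$outlier
    utils::write.csv(tab, csv_path, row.names = FALSE)
  }
  invisible(path)
}

#' Sampling-quality metrics
#'
#' Quantifies the impact of Monte Carlo pixel sampling on one image's
#' estimate: the Euclidean distance between the 6 stain-vector components of
#' the full and sampled estimates, and the relative error of each robust
#' maximum concentration.
#'
#' @param full [stain_parameters] from the unsampled (rate 1) estimation.
#' @param sampled [stain_parameters] from the sampled estimation of the same
#'   image.
#' @return List with \code{odm_distance}, \code{rel_err_maxCh},
#'   \code{rel_err_maxCe} (all non-negative).
#' @export
sampling_error <- function(full, sampled) {
  stopifnot(inherits(full, "stain_parameters"), inherits(sampled, "stain_parameters"))
  if (full$maxCh <= 0 || full$maxCe <= 0) {
    stainkit_error("parameter", "reference maxima must be positive")
  }
  list(
    odm_distance = sqrt(sum((c(full$H, full$E) - c(sampled$H, sampled$E))^2)),
    rel_err_maxCh = abs(full$maxCh - sampled$maxCh) / full$maxCh,
    rel_err_maxCe = abs(full$maxCe - sampled$maxCe) / full$maxCe
  )
}
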