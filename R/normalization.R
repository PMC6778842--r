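# Projection of images onto a reference H&E template and the batch
# normalization driver (fast_sn).

#' Reference H&E template
#'
#' Target stain matrix and maximum concentrations to which all images are
#' projected. The H and E vectors are renormalized to unit length on
#' construction.
#'
#' @param H,E Target unit stain vectors (3 OD components each).
#' @param maxCh,maxCe Target maximum concentrations (positive).
#' @return An object of class \code{reference_template}.
#' @export
reference_template <- function(H, E, maxCh, maxCe) {
  H <- unit(as.numeric(H)); E <- unit(as.numeric(E))
  if (length(H) != 3L || length(E) != 3L) {
    stainkit_error("parameter", "template stain vectors must be 3-vectors")
  }
  if (maxCh <= 0 || maxCe <= 0) {
    stainkit_error("parameter", "template maximum concentrations must be positive")
  }
  structure(list(H = H, E = E, maxCh = as.numeric(maxCh), maxCe = as.numeric(maxCe)),
            class = "reference_template")
}

#' Read a reference template from a YAML or JSON config file
#'
#' The file must define \code{H}, \code{E} (3 numbers each), \code{maxCh} and
#' \code{maxCe}, optionally nested under a \code{template:} key.
#'
#' @param path Path to the config file.
#' @return A [reference_template].
#' @export
read_template <- function(path) {
  if (!file.exists(path)) {
    stainkit_error("io", sprintf("template file '%s' does not exist", path))
  }
  ext <- tolower(tools::file_ext(path))
  x <- if (ext == "json") jsonlite::fromJSON(path) else yaml::read_yaml(path)
  if (!is.null(x$template)) x <- x$template
  missing <- setdiff(c("H", "E", "maxCh", "maxCe"), names(x))
  if (length(missing) > 0) {
    stainkit_error("parse", sprintf(
      "template '%s' is missing field(s): %s", path, paste(missing, collapse = ", ")
    ))
  }
  reference_template(x$H, x$E, x$maxCh, x$maxCe)
}

#' Default reference template
#'
#' The stain matrix and maximum concentrations of the public reference
#' Macenko implementation, shipped as a config file in
#' \code{inst/extdata/default_template.yaml}.
#'
#' @return A [reference_template].
#' @export
default_template <- function() {
  read_template(system.file("extdata", "default_template.yaml",
                            package = "stainkit", mustWork = TRUE))
}

#' Normalize tissue-pixel optical densities to a template
#'
#' Per pixel: unmix concentrations against the image's own stain vectors,
#' rescale each stain by \code{maxC_ref / maxC}, clamp negative
#' concentrations to zero, remix with the template's stain vectors, and map
#' back to 8-bit RGB via \code{round(255 * 10^(-od))} (half away from zero),
#' clipped to \code{[0, 255]}.
#'
#' @param od Numeric \code{N x 3} OD matrix of tissue pixels.
#' @param params The image's [stain_parameters].
#' @param template The [reference_template].
#' @return Integer \code{N x 3} matrix of normalized RGB values.
#' @export
normalize_pixels <- function(od, params, template) {
  stopifnot(inherits(params, "stain_parameters"),
            inherits(template, "reference_template"))
  if (params$maxCh <= 0 || params$maxCe <= 0) {
    stainkit_error("parameter", "image maximum concentrations must be positive")
  }
  C <- concentrations(od, params$H, params$E)
  C[, 1] <- C[, 1] * (template$maxCh / params$maxCh)
  C[, 2] <- C[, 2] * (template$maxCe / params$maxCe)
  C[C < 0] <- 0
  od_out <- C %*% t(cbind(template$H, template$E))
  out <- round_half_away(255 * 10^(-od_out))
  storage.mode(out) <- "integer"
  clip(out, 0L, 255L)
}

#' Normalize one image against a template
#'
#' Tissue pixels are replaced by their template projection; background pixels
#' are copied through unchanged (normalization, like OD conversion, operates
#' on non-background pixels only).
#'
#' @param image An [rgb_image].
#' @param mask A [tissue_mask] for the image.
#' @param params The image's [stain_parameters] (own or representative).
#' @param template The [reference_template].
#' @param clamp_floor OD look-up clamp floor; default 1.
#' @return A normalized [rgb_image] of the same size.
#' @export
normalize_image <- function(image, mask, params, template, clamp_floor = 1L) {
  stopifnot(inherits(image, "rgb_image"), inherits(mask, "tissue_mask"))
  if (mask$tissue_count == 0L) return(image)
  od <- rgb_to_od(image, mask, build_od_lut(clamp_floor))
  rgb_new <- normalize_pixels(od, params, template)
  px <- image$pixels
  idx <- tissue_indices(mask)
  npx <- length(px) / 3L
  px[idx] <- rgb_new[, 1]
  px[idx + npx] <- rgb_new[, 2]
  px[idx + 2L * npx] <- rgb_new[, 3]
  rgb_image(px, level_downsample = image$level_downsample)
}

# Resolve a batch input: character vector of paths, or a (possibly named)
# list of rgb_image objects. Returns list(images=, ids=).
resolve_inputs <- function(inputs) {
  if (is.character(inputs)) {
    ids <- basename(inputs)
    imgs <- lapply(inputs, read_image)
  } else if (is.list(inputs) && all(vapply(inputs, inherits, TRUE, "rgb_image"))) {
    imgs <- inputs
    ids <- names(inputs)
    if (is.null(ids) || any(ids == "")) {
      ids <- sprintf("image_%03d", seq_along(inputs))
    }
  } else {
    stainkit_error("parameter", "inputs must be file paths or a list of rgb_image objects")
  }
  if (anyDuplicated(ids)) stainkit_error("parameter", "duplicate image identifiers in batch")
  list(images = imgs, ids = ids)
}

#' Batch stain normalization (fast_sn)
#'
#' For each input image: determine the automatic background threshold,
#' estimate stain parameters (with Monte Carlo sampling), normalize against
#' the template, and (when \code{output_dir} is given) write the normalized
#' PNG and its JSON parameter sidecar. Per-image failures (e.g. an
#' all-background image) are recorded and the batch continues.
#'
#' @param inputs Character vector of image paths, or a named list of
#'   [rgb_image] objects.
#' @param template A [reference_template]; default [default_template()].
#' @param output_dir Optional directory for normalized images and sidecars.
#' @param sampling_rate Monte Carlo sampling rate; default 0.01.
#' @param seed Base sampling seed; image \code{i} uses \code{seed + i - 1}.
#' @param alpha Robust percentile parameter; default 1.
#' @param threshold Optional fixed background threshold overriding Otsu.
#' @param clamp_floor OD clamp floor; default 1.
#' @param verbose Print a per-image log line; default FALSE.
#' @return Invisibly, a list with \code{images} (normalized [rgb_image]s or
#'   NULL on failure), \code{sidecars}, and \code{status} (a data.frame of
#'   per-image outcomes).
#' @export
run_fast_sn <- function(inputs, template = default_template(), output_dir = NULL,
                        sampling_rate = 0.01, seed = 1L, alpha = 1,
                        threshold = NULL, clamp_floor = 1L, verbose = FALSE) {
  batch <- resolve_inputs(inputs)
  n <- length(batch$images)
  out_imgs <- vector("list", n)
  sidecars <- vector("list", n)
  status <- data.frame(image_id = batch$ids, ok = FALSE, error = NA_character_,
                       stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    img <- batch$images[[i]]
    id <- batch$ids[i]
    res <- tryCatch(
      {
        th <- if (is.null(threshold)) auto_threshold(img) else as.integer(threshold)
        sp <- sampling_spec(rate = sampling_rate, seed = seed + i - 1L)
        params <- estimate_stain_parameters(
          img, threshold = th, sampling = sp, alpha = alpha,
          clamp_floor = clamp_floor, image_id = id
        )
        mask <- tissue_mask(img, th)
        norm <- normalize_image(img, mask, params, template, clamp_floor)
        sc <- parameter_sidecar(id, params, th, sampling_rate, sp$seed)
        list(image = norm, sidecar = sc, threshold = th)
      },
      stainkit_error = function(e) e
    )
    if (inherits(res, "error")) {
      status$error[i] <- conditionMessage(res)
      if (verbose) message(sprintf("%s: FAILED (%s)", id, conditionMessage(res)))
      next
    }
    status$ok[i] <- TRUE
    out_imgs[[i]] <- res$image
    sidecars[[i]] <- res$sidecar
    if (verbose) {
      message(sprintf(
        "%s: threshold=%d N=%d sample=%d maxCh=%.3f maxCe=%.3f",
        id, res$threshold, res$sidecar$n_tissue, res$sidecar$sample_size,
        res$sidecar$maxCh, res$sidecar$maxCe
      ))
    }
    if (!is.null(output_dir)) {
      if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
      stem <- tools::file_path_sans_ext(id)
      write_image(res$image, file.path(output_dir, paste0(stem, "_normalized.png")))
      write_sidecar(res$sidecar, file.path(output_dir, paste0(stem, "_params.json")))
    }
  }
  names(out_imgs) <- batch$ids
  names(sidecars) <- batch$ids
  invisible(list(images = out_imgs, sidecars = sidecars, status = status))
}
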