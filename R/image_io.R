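# Raster image input/output, resolution-level selection, and JSON parameter
# sidecars. Images are 8-bit RGB arrays (H x W x 3, row = y, col = x,
# origin top-left, 0-based pixel coordinates in all user-facing docs).

#' Construct an 8-bit RGB image object
#'
#' The package's unit of input/output: an integer array of shape
#' \code{H x W x 3} with channel values in \code{[0, 255]}.
#'
#' @param pixels Numeric or integer array \code{H x W x 3}; values must lie in
#'   \code{[0, 255]} and be whole numbers.
#' @param level_downsample Positive real; 1 means native resolution.
#' @return An object of class \code{rgb_image}.
#' @export
rgb_image <- function(pixels, level_downsample = 1) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stainkit_error("parameter", "pixels must be an H x W x 3 array")
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stainkit_error("parameter", "channel values must lie in [0, 255]")
  }
  storage.mode(pixels) <- "integer"
  structure(
    list(
      pixels = pixels,
      width = dim(pixels)[2],
      height = dim(pixels)[1],
      level_downsample = as.numeric(level_downsample)
    ),
    class = "rgb_image"
  )
}

#' @export
print.rgb_image <- function(x, ...) {
  cat(sprintf(
    "<rgb_image %d x %d, 8-bit RGB, downsample %.3g>\n",
    x$width, x$height, x$level_downsample
  ))
  invisible(x)
}

#' @export
dim.rgb_image <- function(x) dim(x$pixels)

# [0,1] double plane stack from png/tiff -> integer HxWx3, alpha dropped,
# grayscale replicated.
decode_planes <- function(a, path) {
  if (is.matrix(a)) {
    a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  }
  if (length(dim(a)) != 3L) {
    stainkit_error("io", sprintf("'%s' does not decode as an 8-bit RGB image", path))
  }
  if (dim(a)[3] >= 4L) a <- a[, , 1:3, drop = FALSE]
  if (dim(a)[3] == 2L) a <- array(rep(a[, , 1], 3L), dim = c(dim(a)[1:2], 3L))
  round_half_away(a * 255)
}

#' Read a PNG or TIFF image
#'
#' Reads an 8-bit RGB raster (alpha, if present, is dropped; grayscale is
#' replicated across channels). Multi-level TIFFs expose their embedded
#' resolution levels; for single-level files a requested downsample factor is
#' synthesized by box averaging.
#'
#' @param path Path to a PNG or TIFF file.
#' @param level Optional 1-based resolution level (TIFF directories). When
#'   given, that stored level is returned as-is.
#' @param downsample Positive integer downsample factor relative to the base
#'   level. An embedded level whose dimensions match (within 1\%) is used when
#'   present; otherwise the base level is box-averaged by the factor with
#'   round-half-away-from-zero.
#' @return An [rgb_image].
#' @export
read_image <- function(path, level = NULL, downsample = 1) {
  if (!file.exists(path)) {
    stainkit_error("io", sprintf("cannot read image: '%s' does not exist", path))
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    levels <- list(png::readPNG(path))
  } else if (ext %in% c("tif", "tiff")) {
    levels <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(levels)) levels <- list(levels)
  } else {
    stainkit_error("io", sprintf("unsupported image format: '%s'", path))
  }
  if (!is.null(level)) {
    if (level < 1 || level > length(levels)) {
      stainkit_error("unsupported_level", sprintf(
        "requested level %d but '%s' has %d level(s)", level, path, length(levels)
      ))
    }
    base_w <- dim(levels[[1]])[2]
    px <- decode_planes(levels[[level]], path)
    return(rgb_image(px, level_downsample = base_w / dim(px)[2]))
  }
  downsample <- as.numeric(downsample)
  if (downsample < 1) {
    stainkit_error("parameter", "downsample must be >= 1")
  }
  base_dim <- dim(levels[[1]])
  if (downsample > 1) {
    # prefer an embedded level matching the requested factor
    for (lv in levels) {
      f <- base_dim[2] / dim(lv)[2]
      if (abs(f - downsample) / downsample < 0.01) {
        return(rgb_image(decode_planes(lv, path), level_downsample = downsample))
      }
    }
    if (downsample != round(downsample)) {
      stainkit_error("unsupported_level", sprintf(
        "no stored level matches downsample %.3g in '%s' and synthesis requires an integer factor",
        downsample, path
      ))
    }
    px <- decode_planes(levels[[1]], path)
    return(downsample_image(rgb_image(px), as.integer(downsample)))
  }
  rgb_image(decode_planes(levels[[1]], path))
}

#' Downsample an image by box averaging
#'
#' Non-overlapping \code{d x d} blocks are averaged per channel and rounded
#' half away from zero; edge blocks may be partial. A factor of 1 is the
#' identity.
#'
#' @param image An [rgb_image].
#' @param d Positive integer factor.
#' @return An [rgb_image] of size \code{ceiling(H/d) x ceiling(W/d)}.
#' @export
downsample_image <- function(image, d) {
  stopifnot(inherits(image, "rgb_image"))
  d <- as.integer(d)
  if (is.na(d) || d < 1L) stainkit_error("parameter", "downsample factor must be a positive integer")
  if (d == 1L) return(image)
  px <- image$pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  ri <- (seq_len(h) - 1L) %/% d + 1L
  ci <- (seq_len(w) - 1L) %/% d + 1L
  nh <- max(ri); nw <- max(ci)
  counts <- tabulate(ri, nh) %o% tabulate(ci, nw)
  out <- array(0L, dim = c(nh, nw, 3L))
  for (k in 1:3) {
    s <- rowsum(t(rowsum(px[, , k], ri)), ci)  # nw x nh sums
    out[, , k] <- round_half_away(t(s) / counts)
  }
  rgb_image(out, level_downsample = image$level_downsample * d)
}

#' Write an image to PNG or single-level TIFF
#'
#' The round trip \code{read_image(write_image(x))} is exact for 8-bit RGB.
#'
#' @param image An [rgb_image].
#' @param path Output path; format chosen by extension (.png, .tif/.tiff).
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "rgb_image"))
  if (!dir.exists(dirname(path))) {
    stainkit_error("io", sprintf("cannot write image: directory '%s' does not exist", dirname(path)))
  }
  a <- image$pixels / 255
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(a, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(a, path, bits.per.sample = 8L)
  } else {
    stainkit_error("io", sprintf("unsupported output format: '%s'", path))
  }
  invisible(path)
}

#' Per-image parameter sidecar
#'
#' Bundles everything the pipeline decided about one image: the estimated
#' stain parameters, the background threshold used, the sampling
#' configuration, and quality-control flags. Serializes losslessly to JSON.
#'
#' @param image_id Image identifier (typically the file name).
#' @param params A [stain_parameters] object.
#' @param threshold Integer background threshold in \code{[0, 255]}.
#' @param sampling_rate Sampling rate in \code{(0, 1]} used for estimation.
#' @param seed Integer sampling seed.
#' @param outlier Logical; was the image flagged as poor quality?
#' @param replaced Logical; were its parameters replaced by the representative
#'   set before normalization?
#' @return An object of class \code{parameter_sidecar}.
#' @export
parameter_sidecar <- function(image_id, params, threshold, sampling_rate, seed,
                              outlier = FALSE, replaced = FALSE) {
  stopifnot(inherits(params, "stain_parameters"))
  structure(
    list(
      image_id = as.character(image_id),
      H = as.numeric(params$H),
      E = as.numeric(params$E),
      maxCh = as.numeric(params$maxCh),
      maxCe = as.numeric(params$maxCe),
      alpha = as.numeric(params$alpha),
      threshold = as.integer(threshold),
      sampling_rate = as.numeric(sampling_rate),
      seed = as.integer(seed),
      n_tissue = as.integer(params$n_tissue %||% NA_integer_),
      sample_size = as.integer(params$sample_size %||% NA_integer_),
      outlier = isTRUE(outlier),
      replaced = isTRUE(replaced)
    ),
    class = "parameter_sidecar"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sidecar_required_fields <- c(
  "image_id", "H", "E", "maxCh", "maxCe", "alpha",
  "threshold", "sampling_rate", "seed", "outlier", "replaced"
)

#' Write a parameter sidecar as JSON
#'
#' Serialization is deterministic (two writes of the same sidecar are
#' byte-identical) and numeric fields keep full double precision.
#'
#' @param sidecar A [parameter_sidecar].
#' @param path Output path for the JSON file.
#' @export
write_sidecar <- function(sidecar, path) {
  stopifnot(inherits(sidecar, "parameter_sidecar"))
  json <- jsonlite::toJSON(unclass(sidecar), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, na = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Read a parameter sidecar from JSON
#'
#' @param path Path to a sidecar written by [write_sidecar()].
#' @return A [parameter_sidecar]; missing required fields raise a parse error
#'   naming the field.
#' @export
read_sidecar <- function(path) {
  if (!file.exists(path)) {
    stainkit_error("io", sprintf("sidecar '%s' does not exist", path))
  }
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  missing <- setdiff(sidecar_required_fields, names(x))
  if (length(missing) > 0) {
    stainkit_error("parse", sprintf(
      "sidecar '%s' is missing field(s): %s", path, paste(missing, collapse = ", ")
    ))
  }
  params <- stain_parameters(
    H = x$H, E = x$E, maxCh = x$maxCh, maxCe = x$maxCe, alpha = x$alpha,
    n_tissue = x$n_tissue %||% NA_integer_,
    sample_size = x$sample_size %||% NA_integer_,
    renormalize = FALSE
  )
  parameter_sidecar(
    image_id = x$image_id, params = params, threshold = x$threshold,
    sampling_rate = x$sampling_rate, seed = x$seed,
    outlier = x$outlier, replaced = x$replaced
  )
}
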