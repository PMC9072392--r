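#' Image patch container
#'
#' The unit all feature extractors consume: a 2D intensity array (or a
#' height x width x 3 array for RGB immunohistochemistry images) together
#' with its physical pixel size and a channel tag.
#'
#' @param pixels numeric matrix of non-negative intensities, or for
#'   \code{channel = "IHC_RGB"} an array with third dimension 3 holding
#'   values in \code{[0, 255]}.
#' @param pixel_size_um physical size of one pixel in micrometres; must be
#'   positive.
#' @param channel one of \code{"SHG"}, \code{"2PEF"}, \code{"IHC_RGB"}.
#' @return An object of class \code{shg_image}: a list with elements
#'   \code{pixels}, \code{pixel_size_um} and \code{channel}.
#' @examples
#' img <- image_patch(matrix(runif(64), 8, 8), pixel_size_um = 0.15)
#' dim(img$pixels)
#' @export
image_patch <- function(pixels, pixel_size_um,
                        channel = c("SHG", "2PEF", "IHC_RGB")) {
  channel <- match.arg(channel)
  check_scalar(pixel_size_um, "pixel_size_um", lower = 0, strict_lower = TRUE)
  if (channel == "IHC_RGB") {
    if (!(is.array(pixels) && length(dim(pixels)) == 3 && dim(pixels)[3] == 3))
      stop("IHC_RGB patches need a height x width x 3 array", call. = FALSE)
  } else {
    if (!is.matrix(pixels))
      stop(sprintf("'%s' patches need a 2D intensity matrix", channel),
           call. = FALSE)
  }
  if (!all(is.finite(pixels)) || any(pixels < 0))
    stop("pixel intensities must be finite and non-negative", call. = FALSE)
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 channel = channel),
            class = "shg_image")
}

#' @export
print.shg_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<shg_image> %s, %d x %d px (%.1f x %.1f um), %.4g um/px\n",
              x$channel, d[1], d[2],
              d[1] * x$pixel_size_um, d[2] * x$pixel_size_um,
              x$pixel_size_um))
  if (x$channel != "IHC_RGB") {
    cat(sprintf("  intensity range [%.4g, %.4g]\n",
                min(x$pixels), max(x$pixels)))
  }
  invisible(x)
}

#' @export
plot.shg_image <- function(x, ..., main = NULL) {
  main <- main %||% x$channel
  if (x$channel == "IHC_RGB") {
    rst <- grDevices::as.raster(x$pixels / 255)
    plot(c(0, ncol(x$pixels)), c(0, nrow(x$pixels)), type = "n", asp = 1,
         xlab = "col (px)", ylab = "row (px)", main = main)
    graphics::rasterImage(rst, 0, 0, ncol(x$pixels), nrow(x$pixels))
  } else {
    z <- t(x$pixels)[, nrow(x$pixels):1, drop = FALSE]
    graphics::image(z, col = grDevices::gray(seq(0, 1, length.out = 256)),
                    asp = nrow(x$pixels) / ncol(x$pixels), axes = FALSE,
                    main = main, ...)
  }
  invisible(x)
}

#' Read a micrograph from TIFF or PNG
#'
#' Grayscale images become \code{SHG} (or \code{2PEF}) patches with raw
#' integer intensities restored from the stored bit depth; 3-channel images
#' become \code{IHC_RGB} patches on the 0--255 scale. The pixel size is
#' taken from the TIFF resolution tags when present, otherwise from a JSON
#' sidecar file (same basename, extension \code{.json}, field
#' \code{pixel_size_um}) as written by \code{\link{write_image}}, otherwise
#' from \code{pixel_size_um}; if none is available an error is raised.
#'
#' @param path path to a \code{.tif}/\code{.tiff} or \code{.png} file.
#' @param pixel_size_um optional override/fallback pixel size in um/px.
#' @param channel channel tag for grayscale images.
#' @return An \code{\link{image_patch}}.
#' @export
read_image <- function(path, pixel_size_um = NULL, channel = "SHG") {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    px <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(px, "bits.per.sample") %||% 8L
    res_um <- .pixel_size_from_tags(px)
  } else if (ext == "png") {
    px <- png::readPNG(path)
    bits <- 8L
    res_um <- NULL
  } else {
    stop("unsupported image format: ", path, call. = FALSE)
  }
  sidecar <- .sidecar_path(path)
  if (is.null(res_um) && file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    res_um <- meta$pixel_size_um
    if (!is.null(meta$channel)) channel <- meta$channel
  }
  res_um <- res_um %||% pixel_size_um
  if (is.null(res_um))
    stop("no pixel size for ", path,
         ": none in TIFF tags or sidecar, and no override given",
         call. = FALSE)
  scale <- 2^bits - 1
  if (length(dim(px)) == 3) {
    if (dim(px)[3] == 4) px <- px[, , 1:3, drop = FALSE]  # drop alpha
    if (dim(px)[3] != 3)
      stop("unsupported colorspace in ", path, call. = FALSE)
    img <- round(px * 255)
    attributes(img) <- list(dim = dim(img))
    return(image_patch(img, res_um, "IHC_RGB"))
  }
  mat <- round(px * scale)
  attributes(mat) <- list(dim = dim(mat))
  image_patch(mat, res_um, channel)
}

.pixel_size_from_tags <- function(px) {
  xres <- attr(px, "x.resolution")
  unit <- attr(px, "resolution.unit") %||% "inch"
  if (is.null(xres) || !is.finite(xres) || xres <= 0) return(NULL)
  per_um <- switch(unit, cm = xres / 1e4, inch = xres / 25400, return(NULL))
  1 / per_um
}

.sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

#' Write a micrograph to TIFF with a JSON metadata sidecar
#'
#' \code{SHG}/\code{2PEF} patches are written as single-channel 16-bit TIFF
#' (intensities are rounded and clipped to 0--65535); \code{IHC_RGB} patches
#' as 8-bit RGB TIFF. Pixel size, channel and optionally scene ground truth
#' are stored in a sidecar JSON with the same basename, so that
#' \code{\link{read_image}} recovers the full patch.
#'
#' @param image an \code{\link{image_patch}}.
#' @param path output path, extension \code{.tif} recommended.
#' @param ground_truth optional \code{scene_truth} recorded in the sidecar.
#' @return \code{path}, invisibly.
#' @export
write_image <- function(image, path, ground_truth = NULL) {
  stopifnot(inherits(image, "shg_image"))
  if (image$channel == "IHC_RGB") {
    tiff::writeTIFF(pmin(pmax(image$pixels, 0), 255) / 255, path,
                    bits.per.sample = 8L)
  } else {
    tiff::writeTIFF(pmin(pmax(round(image$pixels), 0), 65535) / 65535, path,
                    bits.per.sample = 16L)
  }
  meta <- list(pixel_size_um = image$pixel_size_um, channel = image$channel)
  if (!is.null(ground_truth)) meta$ground_truth <- .truth_to_json(ground_truth)
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

.truth_to_json <- function(gt) {
  out <- unclass(gt)
  if (!is.null(out$vessel_mask)) {
    out$vessel_mask_true <- which(out$vessel_mask != 0) - 1L  # 0-based indices
    out$vessel_mask_dim <- dim(out$vessel_mask)
    out$vessel_mask <- NULL
  }
  if (!is.null(out$positive_mask)) {
    out$positive_mask_true <- which(out$positive_mask != 0) - 1L
    out$positive_mask_dim <- dim(out$positive_mask)
    out$positive_mask <- NULL
  }
  out
}
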