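# DAB positive-pixel classification and the expression index.

#' Classify DAB-positive pixels in an RGB IHC image
#'
#' Default method: color deconvolution. Per-channel optical densities
#' \code{OD = -log10((I + 1) / 256)} are projected onto the standard
#' hematoxylin/DAB/residual stain basis (Ruifrok--Johnston vectors) and a
#' pixel is called positive when its DAB optical density exceeds
#' \code{od_threshold}. Alternative method \code{"hsv"}: a hue/saturation
#' box classifier for brown pixels.
#'
#' @param image an \code{IHC_RGB} \code{\link{image_patch}} or a
#'   rows x cols x 3 array with values in 0--255 (or 0--1).
#' @param method \code{"deconvolution"} (default) or \code{"hsv"}.
#' @param od_threshold DAB optical-density threshold for the deconvolution
#'   method.
#' @param stain_vectors optional 3 x 3 matrix of unit optical-density stain
#'   vectors (rows: hematoxylin, DAB, residual) overriding the defaults.
#' @param hue_range,min_saturation parameters of the \code{"hsv"} method:
#'   hue window (degrees, 0--360) and minimum saturation for brown.
#' @return logical matrix marking positive pixels, with the classifier
#'   configuration attached as attribute \code{"config"}.
#' @export
classify_positive_pixels <- function(image,
                                     method = c("deconvolution", "hsv"),
                                     od_threshold = 0.15,
                                     stain_vectors = NULL,
                                     hue_range = c(10, 50),
                                     min_saturation = 0.15) {
  method <- match.arg(method)
  px <- if (inherits(image, "shg_image")) {
    if (image$channel != "IHC_RGB")
      stop("positive-pixel classification needs an IHC_RGB image, got ",
           image$channel, call. = FALSE)
    image$pixels
  } else image
  if (!(is.array(px) && length(dim(px)) == 3 && dim(px)[3] == 3))
    stop("input must be a 3-channel RGB image", call. = FALSE)
  if (max(px) <= 1) px <- px * 255
  nr <- dim(px)[1]; nc <- dim(px)[2]
  flat <- matrix(px, nr * nc, 3)

  if (method == "deconvolution") {
    vec <- stain_vectors %||% .stain_od_vectors()
    od <- -log10((flat + 1) / 256)
    conc <- od %*% solve(vec)  # per-pixel stain amounts (hema, dab, residual)
    mask <- matrix(conc[, 2] > od_threshold, nr, nc)
    cfg <- list(method = "deconvolution", od_threshold = od_threshold,
                stain_vectors = vec)
  } else {
    hsv <- grDevices::rgb2hsv(t(flat), maxColorValue = 255)
    hue <- hsv[1, ] * 360
    mask <- matrix(hue >= hue_range[1] & hue <= hue_range[2] &
                     hsv[2, ] >= min_saturation, nr, nc)
    cfg <- list(method = "hsv", hue_range = hue_range,
                min_saturation = min_saturation)
  }
  attr(mask, "config") <- cfg
  mask
}

#' Expression index of a positive-pixel mask
#'
#' IE = positive pixels / total pixels x 100, the percentage of DAB-positive
#' pixels in the micrograph.
#'
#' @param mask logical (or 0/1) matrix, e.g. from
#'   \code{\link{classify_positive_pixels}}.
#' @return An \code{ihc_result}: list with \code{positive_pixels},
#'   \code{total_pixels}, \code{ie} and \code{classifier_config}.
#' @examples
#' expression_index(matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2))$ie  # 25
#' @export
expression_index <- function(mask) {
  if (length(mask) == 0) stop("empty mask", call. = FALSE)
  if (!all(mask %in% c(0, 1)))
    stop("mask must be binary", call. = FALSE)
  pos <- sum(mask != 0)
  tot <- length(mask)
  structure(list(positive_pixels = pos,
                 total_pixels = tot,
                 ie = pos / tot * 100,
                 classifier_config = attr(mask, "config")),
            class = "ihc_result")
}

#' @export
print.ihc_result <- function(x, ...) {
  cat(sprintf("<ihc_result> IE = %.3f%% (%d / %d positive pixels)\n",
              x$ie, x$positive_pixels, x$total_pixels))
  if (!is.null(x$classifier_config))
    cat("  method:", x$classifier_config$method, "\n")
  invisible(x)
}

#' Quantify DAB expression in one IHC image
#'
#' Convenience wrapper: classify positive pixels, then compute the
#' expression index.
#'
#' @inheritParams classify_positive_pixels
#' @param ... passed to \code{\link{classify_positive_pixels}}.
#' @return An \code{ihc_result}.
#' @export
ihc_quantify <- function(image, ...) {
  expression_index(classify_positive_pixels(image, ...))
}
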