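# Fiber orientation index from the binarized 2D FFT magnitude.
#
# An isotropic fiber network gives a circular thresholded spectrum and
# OI = 0; perfectly parallel fibers give a collinear spectrum and OI = 1.

.fftshift2 <- function(x) {
  n <- nrow(x); m <- ncol(x)
  x[c((n %/% 2 + 1):n, 1:(n %/% 2)), c((m %/% 2 + 1):m, 1:(m %/% 2))]
}

#' Normalized FFT magnitude of a ROI
#'
#' The mean is subtracted before transforming (this suppresses the DC
#' component), an optional separable Hann taper is applied to damp the edge
#' cross, and the magnitude is center-shifted and divided by its maximum so
#' values lie in \code{[0, 1]}. A constant input has nothing left after mean
#' subtraction and yields an all-zero magnitude with the \code{degenerate}
#' flag set.
#'
#' @param roi_pixels 2D finite numeric matrix, or an
#'   \code{\link{image_patch}}.
#' @param window apply the Hann taper (default \code{TRUE}).
#' @return list with \code{magnitude} (matrix in \code{[0, 1]}, zero
#'   frequency at \code{(nrow/2 + 1, ncol/2 + 1)}), \code{degenerate} flag
#'   and \code{window}.
#' @export
fft_magnitude <- function(roi_pixels, window = TRUE) {
  x <- if (inherits(roi_pixels, "shg_image")) roi_pixels$pixels else roi_pixels
  if (!is.matrix(x) || !all(is.finite(x)))
    stop("ROI pixels must be a finite 2D matrix", call. = FALSE)
  x <- x - mean(x)
  if (all(x == 0)) {
    return(list(magnitude = matrix(0, nrow(x), ncol(x)),
                degenerate = TRUE, window = window))
  }
  if (window) {
    n <- nrow(x); m <- ncol(x)
    wr <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
    wc <- 0.5 * (1 - cos(2 * pi * (0:(m - 1)) / (m - 1)))
    x <- x * outer(wr, wc)
  }
  mg <- .fftshift2(Mod(stats::fft(x)))
  mx <- max(mg)
  if (mx == 0) {
    return(list(magnitude = mg, degenerate = TRUE, window = window))
  }
  list(magnitude = mg / mx, degenerate = FALSE, window = window)
}

#' Binarize a normalized spectrum magnitude
#'
#' Pixels with magnitude >= \code{threshold} (inclusive boundary) form the
#' mask whose shape carries the anisotropy information.
#'
#' @param magnitude output of \code{\link{fft_magnitude}}, or a bare matrix
#'   with values in \code{[0, 1]}.
#' @param threshold scalar strictly between 0 and 1; the conventional value
#'   is 0.38 of the spectrum maximum.
#' @return An object of class \code{spectrum_mask}: list with logical
#'   \code{mask}, \code{threshold} and the propagated \code{degenerate}
#'   flag.
#' @export
binarize_spectrum <- function(magnitude, threshold = 0.38) {
  check_scalar(threshold, "threshold", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  degenerate <- FALSE
  if (is.list(magnitude)) {
    degenerate <- isTRUE(magnitude$degenerate)
    magnitude <- magnitude$magnitude
  }
  structure(list(mask = magnitude >= threshold, threshold = threshold,
                 degenerate = degenerate),
            class = "spectrum_mask")
}

#' Equivalent-ellipse axes and orientation index of a spectrum mask
#'
#' Central second moments of the true-pixel point set are diagonalized; with
#' eigenvalues \code{lambda1 >= lambda2}, the equivalent-ellipse convention
#' gives long axis \code{4 sqrt(lambda1)} and short axis
#' \code{4 sqrt(lambda2)}, and \code{OI = 1 - short/long}. A collinear mask
#' (\code{lambda2 = 0}) gives OI = 1; a single-pixel mask carries no
#' anisotropy and gives OI = 0.
#'
#' @param spectrum_mask a \code{spectrum_mask} from
#'   \code{\link{binarize_spectrum}}, or a logical matrix.
#' @return An object of class \code{axis_estimate}: list with
#'   \code{short_axis_px}, \code{long_axis_px}, \code{oi} and
#'   \code{degenerate}.
#' @export
estimate_axes <- function(spectrum_mask) {
  mask <- if (inherits(spectrum_mask, "spectrum_mask")) spectrum_mask$mask
          else spectrum_mask
  pts <- which(mask != 0, arr.ind = TRUE)
  if (nrow(pts) == 0) stop("degenerate spectrum: empty mask", call. = FALSE)
  pr <- pts[, 1] - mean(pts[, 1])
  pc <- pts[, 2] - mean(pts[, 2])
  M <- matrix(c(mean(pr * pr), mean(pr * pc),
                mean(pr * pc), mean(pc * pc)), 2, 2)
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  l1 <- max(ev[1], 0); l2 <- max(ev[2], 0)
  long <- 4 * sqrt(l1); short <- 4 * sqrt(l2)
  oi <- if (l1 == 0) 0 else 1 - short / long
  structure(list(short_axis_px = short, long_axis_px = long,
                 oi = oi, degenerate = FALSE),
            class = "axis_estimate")
}

#' @export
print.axis_estimate <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("<axis_estimate> degenerate ROI (constant intensity), OI missing\n")
  } else {
    cat(sprintf("<axis_estimate> OI = %.4f (short %.2f px, long %.2f px)\n",
                x$oi, x$short_axis_px, x$long_axis_px))
  }
  invisible(x)
}

#' Orientation index of a ROI
#'
#' Composition of \code{\link{fft_magnitude}},
#' \code{\link{binarize_spectrum}} and \code{\link{estimate_axes}}:
#' \code{OI = 1 - short axis / long axis} of the spectrum magnitude
#' binarized at \code{threshold} of its maximum. A degenerate
#' (constant-intensity) ROI is flagged and its OI reported missing.
#'
#' @inheritParams fft_magnitude
#' @param threshold binarization threshold, default 0.38.
#' @return An \code{axis_estimate}; \code{oi} is \code{NA} for a degenerate
#'   ROI.
#' @examples
#' g <- outer(1:64, 1:64, function(r, c)
#'   exp(-((r - 32.5)^2 + (c - 32.5)^2) / 50))
#' orientation_index(g)$oi  # 0: radially symmetric
#' @export
orientation_index <- function(roi_pixels, threshold = 0.38, window = TRUE) {
  mg <- fft_magnitude(roi_pixels, window = window)
  if (mg$degenerate) {
    return(structure(list(short_axis_px = NA_real_, long_axis_px = NA_real_,
                          oi = NA_real_, degenerate = TRUE),
                     class = "axis_estimate"))
  }
  estimate_axes(binarize_spectrum(mg, threshold))
}
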