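# First-order histogram statistics and gray-level co-occurrence features.
#
# FOS are population moments of the intensity histogram (divide-by-n
# convention, non-excess kurtosis). SOS are the five classical Haralick
# scalars of a normalized, direction-averaged, symmetric GLCM.

#' First-order statistics of a ROI
#'
#' Population moments of the pixel-intensity histogram: mean, standard
#' deviation, skewness and (non-excess) kurtosis — a normal law has
#' kurtosis 3, a two-point symmetric law 1. On a constant ROI the standard
#' deviation is 0 and skewness/kurtosis are undefined, reported as
#' \code{NA}.
#'
#' @param roi_pixels finite numeric matrix (or \code{\link{image_patch}}).
#' @return An object of class \code{fos_features}: list with \code{mean},
#'   \code{std}, \code{skewness}, \code{kurtosis}, \code{n_pixels}.
#' @examples
#' f <- fos_features(matrix(c(0, 2, 0, 2), 2, 2))
#' c(f$mean, f$std, f$skewness, f$kurtosis)  # 1 1 0 1
#' @export
fos_features <- function(roi_pixels) {
  x <- if (inherits(roi_pixels, "shg_image")) roi_pixels$pixels else roi_pixels
  if (length(x) == 0) stop("empty ROI", call. = FALSE)
  if (!all(is.finite(x))) stop("non-finite pixel intensities", call. = FALSE)
  n <- length(x)
  mu <- sum(x) / n
  d <- x - mu
  v <- sum(d^2) / n
  s <- sqrt(v)
  skew <- if (s == 0) NA_real_ else (sum(d^3) / n) / s^3
  kurt <- if (s == 0) NA_real_ else (sum(d^4) / n) / v^2
  structure(list(mean = mu, std = s, skewness = skew, kurtosis = kurt,
                 n_pixels = n),
            class = "fos_features")
}

#' @export
print.fos_features <- function(x, ...) {
  cat(sprintf(
    "<fos_features> mean %.4g, sd %.4g, skewness %.4g, kurtosis %.4g (n = %d)\n",
    x$mean, x$std, x$skewness, x$kurtosis, x$n_pixels))
  invisible(x)
}

# offsets (drow, dcol) for the standard GLCM directions at distance d;
# rows grow downward, so 45 degrees looks up-right
.glcm_offsets <- function(directions, distance_px) {
  d <- as.integer(distance_px)
  lapply(directions, function(a) {
    switch(as.character(a),
           "0"   = c(0L, d),
           "45"  = c(-d, d),
           "90"  = c(-d, 0L),
           "135" = c(-d, -d),
           stop("unsupported GLCM direction: ", a, call. = FALSE))
  })
}

#' Gray-level co-occurrence matrix of a ROI
#'
#' Intensities are linearly rebinned to \code{n_levels} over the ROI's own
#' \code{[min, max]} range (a constant image maps every pixel to level 0),
#' co-occurrences are accumulated over all requested directions at the given
#' distance, symmetrized by adding the transpose, and normalized to sum 1.
#' Marginal means and standard deviations (over 0-based level indices) are
#' attached for the correlation feature.
#'
#' @param roi_pixels finite numeric matrix (or \code{\link{image_patch}}).
#' @param n_levels number of gray levels (>= 2), default 64.
#' @param distance_px pixel-pair distance, default 1.
#' @param directions subset of \code{c(0, 45, 90, 135)} degrees.
#' @param symmetric add the transposed counts (default \code{TRUE}).
#' @return An object of class \code{glcm}: list with the probability matrix
#'   \code{p} (\code{n_levels x n_levels}, sums to 1), the construction
#'   parameters and the marginals \code{mu_i}, \code{mu_j}, \code{sigma_i},
#'   \code{sigma_j}.
#' @export
compute_glcm <- function(roi_pixels, n_levels = 64, distance_px = 1,
                         directions = c(0, 45, 90, 135), symmetric = TRUE) {
  x <- if (inherits(roi_pixels, "shg_image")) roi_pixels$pixels else roi_pixels
  if (!is.matrix(x) || !all(is.finite(x)))
    stop("ROI pixels must be a finite 2D matrix", call. = FALSE)
  if (n_levels < 2) stop("'n_levels' must be >= 2", call. = FALSE)
  check_scalar(distance_px, "distance_px", lower = 1)
  n_levels <- as.integer(n_levels)

  rng <- range(x)
  lev <- if (rng[2] > rng[1]) {
    l <- floor((x - rng[1]) / (rng[2] - rng[1]) * n_levels)
    pmin(l, n_levels - 1L)
  } else matrix(0L, nrow(x), ncol(x))
  dim(lev) <- dim(x)

  counts <- matrix(0, n_levels, n_levels)
  total_pairs <- 0L
  for (off in .glcm_offsets(directions, distance_px)) {
    dr <- off[1]; dc <- off[2]
    rlo <- max(1L, 1L - dr); rhi <- min(nrow(x), nrow(x) - dr)
    clo <- max(1L, 1L - dc); chi <- min(ncol(x), ncol(x) - dc)
    if (rlo > rhi || clo > chi) next
    r1 <- rlo:rhi; c1 <- clo:chi
    a <- lev[r1, c1, drop = FALSE]
    b <- lev[r1 + dr, c1 + dc, drop = FALSE]
    if (length(a) == 0) next
    idx <- as.integer(a) * n_levels + as.integer(b) + 1L
    tab <- tabulate(idx, nbins = n_levels * n_levels)
    counts <- counts + matrix(tab, n_levels, n_levels, byrow = TRUE)
    total_pairs <- total_pairs + length(a)
  }
  if (total_pairs == 0L)
    stop("image too small for the requested GLCM offsets", call. = FALSE)
  if (symmetric) counts <- counts + t(counts)
  p <- counts / sum(counts)

  i <- 0:(n_levels - 1)
  p_i <- rowSums(p); p_j <- colSums(p)
  mu_i <- sum(i * p_i); mu_j <- sum(i * p_j)
  sigma_i <- sqrt(sum((i - mu_i)^2 * p_i))
  sigma_j <- sqrt(sum((i - mu_j)^2 * p_j))
  structure(list(p = p, n_levels = n_levels, distance_px = distance_px,
                 directions = directions, symmetric = symmetric,
                 mu_i = mu_i, mu_j = mu_j,
                 sigma_i = sigma_i, sigma_j = sigma_j),
            class = "glcm")
}

#' @export
print.glcm <- function(x, ...) {
  cat(sprintf(
    "<glcm> %d levels, distance %g px, directions {%s}%s; %d nonzero cells\n",
    x$n_levels, x$distance_px, paste(x$directions, collapse = ", "),
    if (x$symmetric) ", symmetric" else "", sum(x$p > 0)))
  invisible(x)
}

#' Second-order (Haralick) statistics of a GLCM
#'
#' The five scalars: energy (angular second moment), inertia (contrast),
#' correlation, inverse difference moment (homogeneity) and entropy in
#' natural-log units with the convention \code{0 * ln 0 = 0}. The
#' correlation of a zero-variance GLCM (single-entry matrix, as for a
#' uniform image) is defined as 0.
#'
#' @param glcm a \code{glcm} from \code{\link{compute_glcm}}.
#' @return An object of class \code{sos_features}: list with
#'   \code{energy}, \code{inertia}, \code{correlation}, \code{idm},
#'   \code{entropy}.
#' @examples
#' g <- compute_glcm(matrix(5, 16, 16))
#' sos_features(g)  # energy 1, inertia 0, idm 1, entropy 0, correlation 0
#' @export
sos_features <- function(glcm) {
  if (!inherits(glcm, "glcm")) stop("'glcm' must be a glcm object",
                                    call. = FALSE)
  p <- glcm$p
  n <- glcm$n_levels
  i <- matrix(0:(n - 1), n, n)
  j <- t(i)
  energy <- sum(p^2)
  inertia <- sum((i - j)^2 * p)
  idm <- sum(p / (1 + (i - j)^2))
  nz <- p > 0
  entropy <- -sum(p[nz] * log(p[nz])) + 0  # + 0 avoids IEEE negative zero
  correlation <- if (glcm$sigma_i == 0 || glcm$sigma_j == 0) 0 else
    sum((i - glcm$mu_i) * (j - glcm$mu_j) * p) / (glcm$sigma_i * glcm$sigma_j)
  structure(list(energy = energy, inertia = inertia,
                 correlation = correlation, idm = idm, entropy = entropy),
            class = "sos_features")
}

#' @export
print.sos_features <- function(x, ...) {
  cat(sprintf(paste0(
    "<sos_features> energy %.4g, inertia %.4g, correlation %.4g, ",
    "idm %.4g, entropy %.4g\n"),
    x$energy, x$inertia, x$correlation, x$idm, x$entropy))
  invisible(x)
}
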