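# Selection of square analysis regions near vessel walls.
#
# Coordinates are 0-based internally documented as (row, col) with origin at
# the top-left; in R matrices this corresponds to 1-based [row, col] indexing,
# which is what the data frames below store.

#' Euclidean distance map to the vessel wall
#'
#' For every pixel, the Euclidean distance in micrometres to the nearest
#' vessel (lumen) pixel; pixels inside the vessel hold 0. Computed with the
#' exact distance transform of \pkg{EBImage}.
#'
#' @param vessel_mask logical or 0/1 matrix marking the vessel lumen; must
#'   contain at least one vessel pixel.
#' @param pixel_size_um pixel size in um/px.
#' @return numeric matrix of distances in micrometres.
#' @examples
#' m <- matrix(0, 8, 8); m[1, 1] <- 1
#' vessel_distance_map(m, 1)[4, 5]  # 3-4-5 triangle: 5 um
#' @export
vessel_distance_map <- function(vessel_mask, pixel_size_um) {
  check_scalar(pixel_size_um, "pixel_size_um", lower = 0, strict_lower = TRUE)
  if (!all(vessel_mask %in% c(0, 1)))
    stop("vessel_mask must be binary", call. = FALSE)
  if (!any(vessel_mask != 0))
    stop("no vessel present: vessel_mask is empty", call. = FALSE)
  m <- matrix(as.numeric(vessel_mask == 0), nrow(vessel_mask),
              ncol(vessel_mask))
  d <- EBImage::distmap(m, metric = "euclidean")
  as.matrix(d) * pixel_size_um
}

#' Select square ROIs near the vessel wall
#'
#' Places axis-aligned square regions of side \code{side_um} so that every
#' ROI center lies within \code{max_distance_um} of the vessel wall and no
#' ROI pixel falls inside the vessel lumen; returned ROIs are pairwise
#' non-overlapping. Placement is greedy over a seeded random ordering of a
#' half-side-stride candidate grid, so the same seed and inputs always give
#' the same set. When \code{vessel_mask} is \code{NULL} and
#' \code{whole_image = TRUE}, the distance rule is dropped and the whole
#' image is tiled instead (pure synthetic runs).
#'
#' @param image an \code{\link{image_patch}} or intensity matrix.
#' @param vessel_mask lumen mask as in \code{\link{vessel_distance_map}},
#'   or \code{NULL}.
#' @param side_um ROI side in micrometres (default 150).
#' @param max_distance_um maximal center-to-wall distance in micrometres
#'   (default 500).
#' @param min_count,max_count desired number of ROIs; a warning is recorded
#'   when fewer than \code{min_count} fit, and at most \code{max_count} are
#'   returned.
#' @param seed integer seed for the placement order.
#' @param pixel_size_um pixel size, required when \code{image} is a bare
#'   matrix.
#' @param whole_image allow whole-image tiling when no vessel mask exists.
#' @return An object of class \code{roi_set}: list with a data frame
#'   \code{rois} (columns \code{id}, \code{row}, \code{col} — 1-based
#'   top-left corner — \code{side_px}, \code{side_um}, \code{center_row},
#'   \code{center_col}, \code{vessel_distance_um}), the image dimensions,
#'   \code{pixel_size_um}, \code{seed} and any \code{warnings}.
#' @export
select_rois <- function(image, vessel_mask = NULL, side_um = 150,
                        max_distance_um = 500, min_count = 50,
                        max_count = 80, seed, pixel_size_um = NULL,
                        whole_image = is.null(vessel_mask)) {
  if (missing(seed)) stop("'seed' must be given", call. = FALSE)
  if (inherits(image, "shg_image")) {
    pixel_size_um <- image$pixel_size_um
    px <- image$pixels
  } else {
    px <- image
    if (is.null(pixel_size_um))
      stop("'pixel_size_um' is required for a bare matrix", call. = FALSE)
  }
  check_scalar(side_um, "side_um", lower = 0, strict_lower = TRUE)
  nr <- nrow(px); nc <- ncol(px)
  side_px <- as.integer(round(side_um / pixel_size_um))
  if (side_px > min(nr, nc))
    stop(sprintf("ROI side (%d px) exceeds image size (%d x %d px)",
                 side_px, nr, nc), call. = FALSE)
  if (is.null(vessel_mask) && !whole_image)
    stop("no vessel mask given and whole-image tiling disabled",
         call. = FALSE)

  dmap <- NULL
  lumen_csum <- NULL
  if (!is.null(vessel_mask)) {
    if (!identical(dim(vessel_mask), dim(px)))
      stop("vessel_mask shape differs from the image", call. = FALSE)
    dmap <- vessel_distance_map(vessel_mask, pixel_size_um)
    # 2D prefix sums for O(1) "any lumen pixel inside rectangle" queries
    m01 <- matrix(as.numeric(vessel_mask != 0), nr, nc)
    cs <- t(apply(apply(m01, 2, cumsum), 1, cumsum))  # cs[i,j]: rows<=i, cols<=j
    lumen_csum <- rbind(0, cbind(0, cs))
  }

  stride <- max(1L, side_px %/% 2L)
  cand_r <- unique(c(seq(1L, nr - side_px + 1L, by = stride)))
  cand_c <- unique(c(seq(1L, nc - side_px + 1L, by = stride)))
  cand <- expand.grid(row = cand_r, col = cand_c, KEEP.OUT.ATTRS = FALSE)

  feasible <- vapply(seq_len(nrow(cand)), function(i) {
    .roi_feasible(cand$row[i], cand$col[i], side_px, dmap, lumen_csum,
                  max_distance_um)
  }, logical(1))
  cand <- cand[feasible, , drop = FALSE]

  chosen <- with_seed(seed, {
    ord <- if (nrow(cand) > 0) sample.int(nrow(cand)) else integer(0)
    acc <- matrix(0L, 0, 2)
    for (i in ord) {
      r <- cand$row[i]; c <- cand$col[i]
      if (nrow(acc) > 0) {
        ovl <- abs(acc[, 1] - r) < side_px & abs(acc[, 2] - c) < side_px
        if (any(ovl)) next
      }
      acc <- rbind(acc, c(r, c))
      if (nrow(acc) >= max_count) break
    }
    acc
  })

  warnings <- character(0)
  if (nrow(chosen) < min_count) {
    msg <- sprintf("only %d ROIs fit (requested at least %d)",
                   nrow(chosen), min_count)
    warnings <- msg
    warning(msg, call. = FALSE)
  }
  n <- nrow(chosen)
  ctr_r <- chosen[, 1] + (side_px - 1) / 2
  ctr_c <- chosen[, 2] + (side_px - 1) / 2
  dist_um <- if (!is.null(dmap) && n > 0) {
    dmap[cbind(round(ctr_r), round(ctr_c))]
  } else rep(NA_real_, n)
  rois <- data.frame(
    id = if (n > 0) sprintf("roi%03d", seq_len(n)) else character(0),
    row = as.integer(chosen[, 1]), col = as.integer(chosen[, 2]),
    side_px = rep(side_px, n), side_um = rep(side_px * pixel_size_um, n),
    center_row = ctr_r, center_col = ctr_c,
    vessel_distance_um = dist_um,
    stringsAsFactors = FALSE)
  structure(list(rois = rois, image_dim = c(nr, nc),
                 pixel_size_um = pixel_size_um, side_um = side_um,
                 max_distance_um = if (is.null(dmap)) NA_real_
                                   else max_distance_um,
                 whole_image = is.null(dmap), seed = seed,
                 warnings = warnings),
            class = "roi_set")
}

# feasibility of one candidate: center close enough to the wall, and no
# lumen pixel inside the square
.roi_feasible <- function(r, c, side_px, dmap, lumen_csum, max_distance_um) {
  if (is.null(dmap)) return(TRUE)
  ctr <- c(round(r + (side_px - 1) / 2), round(c + (side_px - 1) / 2))
  if (dmap[ctr[1], ctr[2]] > max_distance_um) return(FALSE)
  r2 <- r + side_px - 1L; c2 <- c + side_px - 1L
  n_lumen <- lumen_csum[r2 + 1L, c2 + 1L] - lumen_csum[r, c2 + 1L] -
    lumen_csum[r2 + 1L, c] + lumen_csum[r, c]
  n_lumen == 0
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d ROIs of %.4g um side (%d px) on a %d x %d image\n",
              nrow(x$rois), x$side_um, x$rois$side_px[1] %||% NA_integer_,
              x$image_dim[1], x$image_dim[2]))
  if (x$whole_image) cat("  whole-image tiling (no vessel mask)\n")
  else cat(sprintf("  center-to-wall distance <= %.4g um\n",
                   x$max_distance_um))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Extract the pixels of one ROI
#'
#' @param image an \code{\link{image_patch}} or matrix.
#' @param roi one row of the \code{rois} data frame of a \code{roi_set}.
#' @return An \code{\link{image_patch}} for image input, else a matrix.
#' @export
extract_roi <- function(image, roi) {
  px <- if (inherits(image, "shg_image")) image$pixels else image
  rows <- roi$row:(roi$row + roi$side_px - 1L)
  cols <- roi$col:(roi$col + roi$side_px - 1L)
  if (max(rows) > nrow(px) || max(cols) > ncol(px))
    stop("ROI exceeds image bounds", call. = FALSE)
  sub <- px[rows, cols, drop = FALSE]
  if (inherits(image, "shg_image"))
    image_patch(sub, image$pixel_size_um, image$channel)
  else sub
}
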