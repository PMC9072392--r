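# Synthetic DAB-stained immunohistochemistry images with exact ground truth.

# Ruifrok & Johnston optical-density unit vectors for hematoxylin and DAB;
# the third vector completes an orthogonal-ish basis for the residual channel.
.stain_od_vectors <- function() {
  h <- c(0.650, 0.704, 0.286)
  d <- c(0.268, 0.570, 0.776)
  r <- c(h[2] * d[3] - h[3] * d[2],
         h[3] * d[1] - h[1] * d[3],
         h[1] * d[2] - h[2] * d[1])
  rbind(hematoxylin = h / sqrt(sum(h^2)),
        dab = d / sqrt(sum(d^2)),
        residual = r / sqrt(sum(r^2)))
}

#' Generate a synthetic IHC micrograph
#'
#' Produces an RGB image in which exactly
#' \code{round(positive_fraction * n_pixels)} pixels carry the DAB-brown
#' stain class and the remainder the hematoxylin counterstain class. Colors
#' are built through the Beer--Lambert law from standard optical-density
#' stain vectors with a per-pixel jitter of the stain amount, so the scene
#' is a controlled test bed for \code{\link{classify_positive_pixels}}.
#'
#' @param shape_px image shape \code{c(rows, cols)}.
#' @param positive_fraction fraction of DAB-positive pixels in \code{[0, 1]}.
#' @param stain_amounts mean optical-density amounts
#'   \code{c(positive, negative)} applied along the DAB and hematoxylin
#'   vectors respectively.
#' @param jitter_sd relative standard deviation of the per-pixel stain
#'   amount (the "color jitter").
#' @param pixel_size_um pixel size in um/px.
#' @param seed integer seed.
#' @return list with \code{image} (an \code{IHC_RGB}
#'   \code{\link{image_patch}}, values 0--255) and \code{truth} (a
#'   \code{scene_truth} with the exact logical \code{positive_mask} and
#'   \code{positive_fraction}).
#' @examples
#' sc <- generate_ihc_image(c(64, 64), positive_fraction = 0.25, seed = 1)
#' sum(sc$truth$positive_mask)  # exactly round(0.25 * 64^2)
#' @export
generate_ihc_image <- function(shape_px = c(500, 500),
                               positive_fraction,
                               stain_amounts = c(positive = 0.8,
                                                 negative = 0.6),
                               jitter_sd = 0.1,
                               pixel_size_um = 0.5,
                               seed) {
  if (missing(seed)) stop("'seed' must be given", call. = FALSE)
  check_scalar(positive_fraction, "positive_fraction", lower = 0, upper = 1)
  nr <- as.integer(shape_px[1]); nc <- as.integer(shape_px[2])
  npx <- nr * nc
  n_pos <- round(positive_fraction * npx)

  with_seed(seed, {
    pos_idx <- if (n_pos > 0) sample.int(npx, n_pos) else integer(0)
    mask <- matrix(FALSE, nr, nc)
    mask[pos_idx] <- TRUE
    vec <- .stain_od_vectors()
    amount <- pmax(rnorm(npx, 1, jitter_sd), 0.2)
    amount <- amount * ifelse(as.vector(mask), stain_amounts[["positive"]],
                              stain_amounts[["negative"]])
    stain <- matrix(vec["hematoxylin", ], npx, 3, byrow = TRUE)
    if (n_pos > 0)
      stain[as.vector(mask), ] <- matrix(vec["dab", ], n_pos, 3,
                                         byrow = TRUE)
    od <- stain * amount
    rgbv <- round(255 * 10^(-od))
    img <- array(0, dim = c(nr, nc, 3))
    img[, , 1] <- rgbv[, 1]; img[, , 2] <- rgbv[, 2]; img[, , 3] <- rgbv[, 3]
    truth <- structure(list(
      fibers = NULL,
      orientation_mean_deg = NA_real_,
      orientation_concentration = NA_real_,
      vessel_mask = NULL,
      positive_mask = mask,
      positive_fraction = positive_fraction,
      n_positive = n_pos,
      seed = seed), class = "scene_truth")
    list(image = image_patch(img, pixel_size_um, "IHC_RGB"), truth = truth)
  })
}
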