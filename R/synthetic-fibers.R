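# Synthetic SHG-like fiber scenes with exact ground truth.
#
# Fibers are straight segments with a Gaussian cross-profile; orientations
# follow an axial von Mises law (von Mises on the doubled angle, the standard
# model for undirected fiber data). All generators are pure functions of
# (parameters, seed).

#' Sample axial fiber orientations
#'
#' Draws angles in degrees on \code{[0, 180)} from an axial von Mises law:
#' the doubled angle follows a von Mises distribution with mean
#' \code{2 * mean_deg} and concentration \code{kappa}. \code{kappa = 0}
#' gives the uniform law on \code{[0, 180)}; large \code{kappa} concentrates
#' the fibers around \code{mean_deg}.
#'
#' @param n number of draws.
#' @param mean_deg mean orientation in degrees.
#' @param kappa non-negative concentration parameter.
#' @return numeric vector of \code{n} angles in \code{[0, 180)}.
#' @export
raxial_vonmises <- function(n, mean_deg, kappa) {
  check_scalar(kappa, "kappa", lower = 0)
  if (kappa < 1e-10) return(runif(n, 0, 180))
  # Best & Fisher (1979) rejection sampler for the von Mises distribution
  mu <- 2 * mean_deg * pi / 180
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (u[2] < cc * (2 - cc) || u[2] <= cc * exp(1 - cc)) {
      i <- i + 1L
      psi <- (mu + sign(u[3] - 0.5) * acos(pmin(pmax(f, -1), 1))) %% (2 * pi)
      out[i] <- psi * 90 / pi  # halve the doubled angle
    }
  }
  out %% 180
}

# add one Gaussian-profile segment to img (modified in place via return);
# width_px is the full width at half maximum of the cross-profile
.render_fiber <- function(img, r0, c0, angle_deg, length_px, width_px, peak) {
  nr <- nrow(img); nc <- ncol(img)
  sigma <- width_px / (2 * sqrt(2 * log(2)))
  th <- angle_deg * pi / 180
  dr <- -sin(th); dc <- cos(th)  # rows grow downward; angle ccw from +x
  r1 <- r0 + length_px * dr; c1 <- c0 + length_px * dc
  m <- ceiling(3 * sigma)
  rlo <- max(1L, floor(min(r0, r1)) - m); rhi <- min(nr, ceiling(max(r0, r1)) + m)
  clo <- max(1L, floor(min(c0, c1)) - m); chi <- min(nc, ceiling(max(c0, c1)) + m)
  if (rlo > rhi || clo > chi) return(img)
  rs <- rlo:rhi; cs <- clo:chi
  R <- matrix(rs, length(rs), length(cs))
  C <- matrix(cs, length(rs), length(cs), byrow = TRUE)
  vr <- r1 - r0; vc <- c1 - c0
  l2 <- vr * vr + vc * vc
  t <- if (l2 > 0) pmin(pmax(((R - r0) * vr + (C - c0) * vc) / l2, 0), 1) else 0
  d2 <- (R - r0 - t * vr)^2 + (C - c0 - t * vc)^2
  img[rs, cs] <- img[rs, cs] + peak * exp(-d2 / (2 * sigma^2))
  img
}

.apply_noise <- function(img, noise_model) {
  type <- noise_model$type %||% "none"
  switch(type,
    none = img,
    gaussian = {
      sd <- noise_model$sd
      check_scalar(sd, "noise sd", lower = 0)
      pmax(img + rnorm(length(img), 0, sd), 0)
    },
    poisson = matrix(rpois(length(img), pmax(img, 0)), nrow(img), ncol(img)),
    stop("unknown noise_model type: '", type, "'", call. = FALSE)
  )
}

#' Generate a synthetic SHG-like fiber image
#'
#' Renders \code{n_fibers} straight collagen-like fibers with a Gaussian
#' cross-profile on a constant background, with orientations drawn from the
#' axial von Mises law of \code{\link{raxial_vonmises}}, fiber start points
#' uniform over the image, lengths from \code{length_law}, and optional
#' additive noise. The defaults emulate a 150 x 150 um^2 SHG tile of dense
#' fibrotic lung parenchyma (1000 x 1000 px at 0.15 um/px).
#'
#' @param shape_px integer vector \code{c(rows, cols)}, each >= 32.
#' @param n_fibers number of fibers (>= 0).
#' @param orientation_mean_deg mean fiber orientation in degrees.
#' @param orientation_concentration axial von Mises concentration
#'   \code{kappa >= 0}; 0 = isotropic.
#' @param length_law list \code{list(type = "uniform", min, max)} in px.
#' @param width_px fiber full width at half maximum in px.
#' @param peak_intensity added intensity at the fiber core.
#' @param background constant background intensity.
#' @param noise_model list with \code{type} one of \code{"none"},
#'   \code{"gaussian"} (field \code{sd}) or \code{"poisson"}; the default is
#'   Gaussian with sd = 5\% of \code{peak_intensity}.
#' @param pixel_size_um pixel size in um/px.
#' @param seed integer seed; the generator is a pure function of
#'   (parameters, seed).
#' @return list with elements \code{image} (an \code{\link{image_patch}})
#'   and \code{truth} (a \code{scene_truth}: fiber table, orientation law
#'   parameters, seed).
#' @examples
#' sc <- generate_fiber_image(shape_px = c(128, 128), n_fibers = 10,
#'                            orientation_concentration = 4, seed = 1)
#' sc$truth$fibers[1:3, ]
#' @export
generate_fiber_image <- function(shape_px = c(1000, 1000),
                                 n_fibers = 60,
                                 orientation_mean_deg = 90,
                                 orientation_concentration = 0,
                                 length_law = list(type = "uniform",
                                                   min = 200, max = 800),
                                 width_px = 5,
                                 peak_intensity = 150,
                                 background = 10,
                                 noise_model = list(type = "gaussian",
                                                    sd = 0.05 * peak_intensity),
                                 pixel_size_um = 0.15,
                                 seed) {
  if (missing(seed)) stop("'seed' must be given", call. = FALSE)
  if (length(shape_px) != 2 || any(shape_px < 32))
    stop("'shape_px' must be two integers >= 32", call. = FALSE)
  check_scalar(n_fibers, "n_fibers", lower = 0)
  check_scalar(orientation_concentration, "orientation_concentration",
               lower = 0)
  check_scalar(width_px, "width_px", lower = 1)
  check_scalar(pixel_size_um, "pixel_size_um", lower = 0, strict_lower = TRUE)
  if (!identical(length_law$type %||% "uniform", "uniform"))
    stop("only length_law type 'uniform' is supported", call. = FALSE)

  with_seed(seed, {
    nr <- as.integer(shape_px[1]); nc <- as.integer(shape_px[2])
    img <- matrix(background, nr, nc)
    n_fibers <- as.integer(n_fibers)
    angles <- raxial_vonmises(n_fibers, orientation_mean_deg,
                              orientation_concentration)
    fibers <- data.frame(
      start_row = runif(n_fibers, 1, nr),
      start_col = runif(n_fibers, 1, nc),
      orientation_deg = angles,
      length_px = pmax(runif(n_fibers, length_law$min, length_law$max), 1),
      width_px = rep(width_px, n_fibers),
      peak_intensity = rep(peak_intensity, n_fibers)
    )
    for (k in seq_len(n_fibers)) {
      img <- .render_fiber(img, fibers$start_row[k], fibers$start_col[k],
                           fibers$orientation_deg[k], fibers$length_px[k],
                           width_px, peak_intensity)
    }
    img <- .apply_noise(img, noise_model)
    truth <- structure(list(
      fibers = fibers,
      orientation_mean_deg = orientation_mean_deg,
      orientation_concentration = orientation_concentration,
      background = background,
      noise_model = noise_model,
      vessel_mask = NULL, positive_fraction = NULL,
      seed = seed), class = "scene_truth")
    list(image = image_patch(img, pixel_size_um, "SHG"), truth = truth)
  })
}

#' Generate a synthetic perivascular vessel scene
#'
#' Builds an SHG-like scene with a circular low-intensity vessel lumen, a
#' fiber-dense annular wall of tangentially oriented fibers, and sparser
#' background parenchyma fibers, mirroring how collagen surrounds the blood
#' vessel wall in lung tissue. The returned ground truth carries the lumen
#' mask used by \code{\link{select_rois}}.
#'
#' @param shape_px image shape \code{c(rows, cols)}.
#' @param vessel_center_px lumen center \code{c(row, col)}; default image
#'   center.
#' @param vessel_radius_px lumen radius in px.
#' @param wall_thickness_px thickness of the fiber-dense wall annulus in px;
#'   0 disables wall fibers.
#' @param collagen_params list of rendering parameters:
#'   \code{wall_fiber_density} (fibers per 1000 px^2 of annulus),
#'   \code{n_background_fibers}, \code{width_px}, \code{peak_intensity},
#'   \code{background}, \code{lumen_intensity}, \code{noise_model},
#'   \code{background_concentration}.
#' @param pixel_size_um pixel size in um/px.
#' @param seed integer seed.
#' @return list(image, truth) as in \code{\link{generate_fiber_image}};
#'   \code{truth$vessel_mask} is a logical matrix marking the lumen.
#' @export
generate_vessel_scene <- function(shape_px = c(1000, 1000),
                                  vessel_center_px = NULL,
                                  vessel_radius_px = 80,
                                  wall_thickness_px = 40,
                                  collagen_params = list(),
                                  pixel_size_um = 0.15,
                                  seed) {
  if (missing(seed)) stop("'seed' must be given", call. = FALSE)
  nr <- as.integer(shape_px[1]); nc <- as.integer(shape_px[2])
  ctr <- vessel_center_px %||% c((nr + 1) / 2, (nc + 1) / 2)
  if (vessel_radius_px + wall_thickness_px > min(ctr[1] - 1, nr - ctr[1],
                                                 ctr[2] - 1, nc - ctr[2],
                                                 na.rm = TRUE) + 1)
    stop("vessel (lumen + wall) does not fit inside the image", call. = FALSE)
  p <- utils::modifyList(list(
    wall_fiber_density = 3,      # fibers per 1000 px^2 of wall annulus
    n_background_fibers = 30,
    background_concentration = 0,
    width_px = 5,
    peak_intensity = 150,
    background = 10,
    lumen_intensity = 2,
    noise_model = list(type = "gaussian", sd = 7.5)
  ), collagen_params)

  with_seed(seed, {
    img <- matrix(p$background, nr, nc)
    D <- sqrt(outer((1:nr - ctr[1])^2, (1:nc - ctr[2])^2, `+`))
    lumen <- D <= vessel_radius_px

    # background parenchyma fibers
    nbg <- as.integer(p$n_background_fibers)
    bg_ang <- raxial_vonmises(nbg, 90, p$background_concentration)
    bg <- data.frame(
      start_row = runif(nbg, 1, nr), start_col = runif(nbg, 1, nc),
      orientation_deg = bg_ang,
      length_px = runif(nbg, 100, 400),
      width_px = p$width_px, peak_intensity = p$peak_intensity)

    # wall fibers: tangential segments in the annulus
    wall <- NULL
    if (wall_thickness_px > 0) {
      area <- pi * ((vessel_radius_px + wall_thickness_px)^2 -
                      vessel_radius_px^2)
      nw <- max(0L, as.integer(round(p$wall_fiber_density * area / 1000)))
      phi <- runif(nw, 0, 2 * pi)
      rad <- sqrt(runif(nw, vessel_radius_px^2,
                        (vessel_radius_px + wall_thickness_px)^2))
      tang <- (phi * 180 / pi + 90) %% 180
      wall <- data.frame(
        start_row = ctr[1] - rad * sin(phi),
        start_col = ctr[2] + rad * cos(phi),
        orientation_deg = (tang + rnorm(nw, 0, 5)) %% 180,
        length_px = runif(nw, 40, 120),
        width_px = p$width_px, peak_intensity = p$peak_intensity)
    }
    fibers <- rbind(bg, wall)
    for (k in seq_len(nrow(fibers))) {
      img <- .render_fiber(img, fibers$start_row[k], fibers$start_col[k],
                           fibers$orientation_deg[k], fibers$length_px[k],
                           fibers$width_px[k], fibers$peak_intensity[k])
    }
    img[lumen] <- p$lumen_intensity
    img <- .apply_noise(img, p$noise_model)
    truth <- structure(list(
      fibers = fibers,
      orientation_mean_deg = NA_real_,
      orientation_concentration = p$background_concentration,
      background = p$background,
      noise_model = p$noise_model,
      vessel_mask = lumen,
      vessel_center_px = ctr,
      vessel_radius_px = vessel_radius_px,
      wall_thickness_px = wall_thickness_px,
      positive_fraction = NULL,
      seed = seed), class = "scene_truth")
    list(image = image_patch(img, pixel_size_um, "SHG"), truth = truth)
  })
}

#' @export
print.scene_truth <- function(x, ...) {
  cat("<scene_truth>\n")
  cat(sprintf("  fibers: %d; orientation kappa = %s; seed = %s\n",
              if (is.null(x$fibers)) 0L else nrow(x$fibers),
              format(x$orientation_concentration), format(x$seed)))
  if (!is.null(x$vessel_mask))
    cat(sprintf("  vessel lumen: %d px\n", sum(x$vessel_mask)))
  if (!is.null(x$positive_fraction))
    cat(sprintf("  IHC positive fraction: %.4f\n", x$positive_fraction))
  invisible(x)
}
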