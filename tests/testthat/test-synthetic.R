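# Synthetic scene generators: determinism, ground-truth consistency,
# orientation law, vessel geometry, IHC pixel counts.

test_that("empty scene is exactly the background constant", {
  sc <- generate_fiber_image(shape_px = c(64, 64), n_fibers = 0,
                             noise_model = list(type = "none"),
                             background = 7, seed = 1)
  expect_true(all(sc$image$pixels == 7))
  expect_equal(nrow(sc$truth$fibers), 0)
})

test_that("generators are pure functions of (parameters, seed)", {
  a <- generate_fiber_image(shape_px = c(96, 96), n_fibers = 12, seed = 42)
  b <- generate_fiber_image(shape_px = c(96, 96), n_fibers = 12, seed = 42)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth$fibers, b$truth$fibers)
  c <- generate_fiber_image(shape_px = c(96, 96), n_fibers = 12, seed = 43)
  expect_false(identical(a$image$pixels, c$image$pixels))

  v1 <- generate_vessel_scene(shape_px = c(256, 256), vessel_radius_px = 30,
                              wall_thickness_px = 15, seed = 7)
  v2 <- generate_vessel_scene(shape_px = c(256, 256), vessel_radius_px = 30,
                              wall_thickness_px = 15, seed = 7)
  expect_identical(v1$image$pixels, v2$image$pixels)

  i1 <- generate_ihc_image(c(60, 60), 0.3, seed = 5)
  i2 <- generate_ihc_image(c(60, 60), 0.3, seed = 5)
  expect_identical(i1$image$pixels, i2$image$pixels)
})

test_that("generator leaves the caller's RNG stream untouched", {
  set.seed(123)
  r1 <- runif(1)
  set.seed(123)
  invisible(generate_fiber_image(shape_px = c(64, 64), n_fibers = 3,
                                 seed = 9))
  expect_identical(runif(1), r1)
})

test_that("kappa = 0 gives uniform orientations on [0, 180)", {
  sc <- generate_fiber_image(shape_px = c(64, 64), n_fibers = 500,
                             orientation_concentration = 0, seed = 17)
  ang <- sc$truth$fibers$orientation_deg
  expect_true(all(ang >= 0 & ang < 180))
  counts <- table(cut(ang, breaks = seq(0, 180, by = 15)))
  gof <- suppressWarnings(chisq.test(as.vector(counts)))
  expect_gt(gof$p.value, 0.01)
})

test_that("large kappa concentrates orientations around the mean", {
  sc <- generate_fiber_image(shape_px = c(64, 64), n_fibers = 300,
                             orientation_mean_deg = 40,
                             orientation_concentration = 32, seed = 11)
  dev <- sc$truth$fibers$orientation_deg - 40
  dev <- (dev + 90) %% 180 - 90  # axial wrap
  expect_lt(sd(dev), 15)
  expect_lt(abs(mean(dev)), 5)
})

test_that("invalid generator arguments are rejected with the parameter name", {
  expect_error(generate_fiber_image(shape_px = c(16, 64), seed = 1),
               "shape_px")
  expect_error(generate_fiber_image(shape_px = c(64, 64),
                                    orientation_concentration = -1, seed = 1),
               "orientation_concentration")
  expect_error(generate_fiber_image(shape_px = c(64, 64),
                                    noise_model = list(type = "salt"),
                                    seed = 1),
               "noise_model")
  expect_error(generate_fiber_image(shape_px = c(64, 64), n_fibers = 1),
               "seed")
})

test_that("vessel scene has a dense wall and a lumen mask", {
  sc <- generate_vessel_scene(shape_px = c(512, 512), vessel_radius_px = 60,
                              wall_thickness_px = 40,
                              collagen_params = list(
                                noise_model = list(type = "none")),
                              seed = 3)
  tr <- sc$truth
  expect_identical(dim(tr$vessel_mask), dim(sc$image$pixels))
  ctr <- tr$vessel_center_px
  D <- sqrt(outer((1:512 - ctr[1])^2, (1:512 - ctr[2])^2, `+`))
  expect_identical(unname(tr$vessel_mask), unname(D <= 60))
  # collagen density in the wall annulus exceeds the far field
  wall <- D > 60 & D <= 100
  far <- D > 200
  expect_gt(mean(sc$image$pixels[wall]) / mean(sc$image$pixels[far]), 1)
})

test_that("zero wall thickness gives a plain lumen disk and no wall fibers", {
  sc <- generate_vessel_scene(shape_px = c(256, 256), vessel_radius_px = 40,
                              wall_thickness_px = 0,
                              collagen_params = list(n_background_fibers = 5),
                              seed = 8)
  expect_equal(nrow(sc$truth$fibers), 5)  # background fibers only
  expect_equal(sum(sc$truth$vessel_mask),
               sum(sqrt(outer((1:256 - 128.5)^2, (1:256 - 128.5)^2,
                              `+`)) <= 40))
})

test_that("vessel larger than the image is rejected", {
  expect_error(generate_vessel_scene(shape_px = c(128, 128),
                                     vessel_radius_px = 100,
                                     wall_thickness_px = 10, seed = 1),
               "fit")
})

test_that("IHC ground truth obeys the exact rounding rule", {
  expect_equal(sum(generate_ihc_image(c(40, 40), 0, seed = 1)
                   $truth$positive_mask), 0)
  expect_equal(sum(generate_ihc_image(c(40, 40), 1, seed = 1)
                   $truth$positive_mask), 1600)
  expect_equal(sum(generate_ihc_image(c(100, 100), 0.25, seed = 1)
                   $truth$positive_mask), 2500)
  expect_equal(sum(generate_ihc_image(c(30, 30), 1 / 3, seed = 1)
                   $truth$positive_mask), round(900 / 3))
  expect_error(generate_ihc_image(c(40, 40), 1.2, seed = 1),
               "positive_fraction")
})

test_that("noise models behave as declared", {
  base <- generate_fiber_image(shape_px = c(64, 64), n_fibers = 0,
                               background = 100,
                               noise_model = list(type = "none"), seed = 2)
  g <- generate_fiber_image(shape_px = c(64, 64), n_fibers = 0,
                            background = 100,
                            noise_model = list(type = "gaussian", sd = 5),
                            seed = 2)
  expect_equal(sd(as.vector(g$image$pixels)), 5, tolerance = 0.15)
  p <- generate_fiber_image(shape_px = c(64, 64), n_fibers = 0,
                            background = 100,
                            noise_model = list(type = "poisson"), seed = 2)
  expect_true(all(p$image$pixels == round(p$image$pixels)))
  expect_equal(mean(p$image$pixels), 100, tolerance = 1)
  expect_true(all(base$image$pixels == 100))
})
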