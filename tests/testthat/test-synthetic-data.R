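test_that("equal seeds give bit-identical phantoms, movies and time-lapses", {
  a <- generate_well_phantom(phantom_spec(seed = 11))
  b <- generate_well_phantom(phantom_spec(seed = 11))
  expect_identical(a$stack$pixels, b$stack$pixels)
  c1 <- generate_confluency_movie(18, seed = 5, n_frames = 6)
  c2 <- generate_confluency_movie(18, seed = 5, n_frames = 6)
  expect_identical(c1$stack$pixels, c2$stack$pixels)
  f1 <- generate_fucci_timelapse(n_cells = 10, n_frames = 3, seed = 9)
  f2 <- generate_fucci_timelapse(n_cells = 10, n_frames = 3, seed = 9)
  expect_identical(f1$stack$pixels, f2$stack$pixels)
  expect_identical(f1$truth, f2$truth)
})

test_that("plate composition follows largest-remainder allocation", {
  p <- generate_plate(100, seed = 3, n_slices = 3)
  cls <- table(vapply(p, function(x) x$truth$class, ""))
  expect_equal(unname(cls[["planar"]]), 91)
  expect_equal(unname(cls[["meniscus"]]), 6)
  expect_equal(unname(cls[["concave"]]), 3)
  all_planar <- generate_plate(8, composition = c(planar = 1), seed = 1,
                               n_slices = 3)
  expect_true(all(vapply(all_planar, function(x) x$truth$class, "") ==
                    "planar"))
  expect_error(generate_plate(0), class = "gelplate_validation")
  expect_error(generate_plate(10, composition = c(planar = 0.7)),
               class = "gelplate_validation")
})

test_that("phantom ground truth is volumetrically consistent", {
  sp <- phantom_spec("planar", seed = 2)
  ph <- generate_well_phantom(sp)
  tr <- ph$truth
  vol_map <- sum(tr$height_map_um) * sp$pixel_size_um^2
  vol_nominal <- sp$gel_height_um * pi *
    (tr$footprint_px * sp$pixel_size_um)^2
  expect_lt(abs(vol_map - vol_nominal) / vol_nominal, 0.02)
})

test_that("gel taller than the stack is rejected", {
  expect_error(phantom_spec(gel_height_um = 500, n_slices = 4,
                            z_step_um = 30),
               class = "gelplate_validation")
})

test_that("logistic growth truth follows the Hill-suppressed rate", {
  m0 <- generate_confluency_movie(0, r0 = 0.08, seed = 1, n_frames = 3)
  expect_equal(m0$truth$rate, 0.08)                 # Hill identity at dose 0
  mh <- generate_confluency_movie(18, ic50_true = 18, r0 = 0.08, seed = 1,
                                  n_frames = 3)
  expect_equal(mh$truth$rate, 0.04)                 # half-point
  # recurrence check
  C <- m0$truth$confluency_true
  expect_equal(C[2], C[1] + 0.08 * C[1] * (1 - C[1]))
})

test_that("rendered coverage tracks the true fraction within 1 point", {
  mv <- generate_confluency_movie(0, r0 = 0.08, n_frames = 20, seed = 4)
  expect_lt(max(abs(mv$truth$confluency_rendered -
                      mv$truth$confluency_true)), 0.01)
})

test_that("FUCCI truth honours fragment fraction and bleed-through", {
  fu <- generate_fucci_timelapse(n_cells = 30, n_frames = 2,
                                 fragment_fraction = 0.1, seed = 3)
  frac <- mean(fu$truth$fragmented[fu$truth$frame == 1])
  expect_equal(frac, 0.1, tolerance = 1e-9)
  # fragmented nuclei are below half the mean area
  t1 <- fu$truth[fu$truth$frame == 1, ]
  expect_true(all(t1$area_px[t1$fragmented] <
                    0.5 * mean(t1$area_px)))
  # bleed-through adds cyan onto tubulin
  f0 <- generate_fucci_timelapse(n_cells = 10, n_frames = 1, seed = 7,
                                 bleedthrough = 0)
  f3 <- generate_fucci_timelapse(n_cells = 10, n_frames = 1, seed = 7,
                                 bleedthrough = 0.3)
  d <- f3$stack$pixels[1, 2, , ] - f0$stack$pixels[1, 2, , ]
  expect_equal(d, 0.3 * f0$stack$pixels[1, 3, , ], tolerance = 1e-12)
})

test_that("dry height map is gel plus background plus seeded noise", {
  prof <- data.frame(r_um = c(0, 200, 300), h_um = c(20, 20, 0))
  g0 <- generate_dry_height_map(prof, noise_sd = 0, seed = 1)
  expect_equal(g0$map$heights, g0$truth$gel_um, tolerance = 1e-12)
  gq <- generate_dry_height_map(prof,
                                background_poly2 = c(5, 0.1, 0, 1e-3, 0, 1e-3),
                                noise_sd = 0, seed = 1)
  expect_equal(gq$map$heights - min(gq$truth$gel_um + gq$truth$background_um, 0),
               gq$truth$gel_um + gq$truth$background_um, tolerance = 1e-9)
  expect_error(generate_dry_height_map(prof, background_poly2 = 1:3),
               class = "gelplate_validation")
})

test_that("stacks round-trip through the TIFF writer within float precision", {
  ph <- generate_well_phantom(phantom_spec(seed = 5, n_slices = 3))
  tmp <- tempfile(fileext = ".tif")
  on.exit(unlink(c(tmp, paste0(tmp, ".json"))))
  write_stack(ph$stack, tmp)
  back <- read_stack(tmp)
  expect_identical(back$axes, ph$stack$axes)
  expect_identical(back$channel_names, ph$stack$channel_names)
  expect_lt(max(abs(back$pixels - ph$stack$pixels)) /
              max(ph$stack$pixels), 1e-6)
  expect_equal(back$z_step_um, ph$stack$z_step_um)
})
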