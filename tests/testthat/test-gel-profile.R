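test_that("column height is the first-to-last slice distance times z-step", {
  arr <- array(0, c(12, 8, 8))
  arr[4:11, 3:6, 3:6] <- 1          # signal in slices 4..11
  arr[6, 7, 7] <- 1                 # single-slice column
  hm <- extract_height_map(arr, z_step_um = 2)
  expect_equal(hm$heights[4, 4], (11 - 4) * 2)
  expect_equal(hm$heights[7, 7], 0)               # first == last convention
  hm_inc <- extract_height_map(arr, z_step_um = 2, inclusive = TRUE)
  expect_equal(hm_inc$heights[4, 4], (11 - 4 + 1) * 2)
  expect_error(extract_height_map(arr * 0, z_step_um = 2),
               class = "gelplate_empty_map")
})

test_that("planar phantom heights are recovered within one z-step", {
  for (H in c(10, 30, 50)) {
    ph <- generate_well_phantom(phantom_spec(
      gel_height_um = H, z_step_um = 2, n_slices = 28,
      bead_density = 1.5e-2, pixel_size_um = 5,
      noise = default_noise_off, seed = 31))
    st <- ph$stack
    arr <- st$pixels[, 2, , ]       # gel channel
    hm <- extract_height_map(arr, z_step_um = 2)
    med <- median(hm$heights[hm$heights > 0])
    expect_lte(abs(med - H), 2)
  }
})

test_that("moving average uses a shrinking centred window", {
  moving_avg_oracle <- function(x, w) {
    left <- floor((w - 1) / 2); right <- w - 1 - left
    sapply(seq_along(x), function(i)
      mean(x[max(1, i - left):min(length(x), i + right)]))
  }
  x <- c(10, 20, 30, 40)
  got <- gelplate:::moving_avg(x, 4)
  expect_equal(got, moving_avg_oracle(x, 4))
  expect_equal(got, c(20, 25, 30, 35))
  expect_equal(gelplate:::moving_avg(rep(7, 9), 5), rep(7, 9))
  # a step smooths into a ramp of the window width
  st <- gelplate:::moving_avg(c(rep(0, 10), rep(1, 10)), 5)
  expect_equal(sum(st > 0.01 & st < 0.99), 4)
})

test_that("radial profiles keep constants and need a wide enough footprint", {
  m <- height_map(matrix(12, 40, 40), pixel_size_um = 1)
  pr <- radial_profile(m)
  expect_equal(pr$height_um, rep(12, 40))
  small <- height_map(
    { h <- matrix(0, 40, 40); h[18:22, 18:22] <- 5; h },
    pixel_size_um = 1)
  expect_error(radial_profile(small), class = "gelplate_validation")
})

test_that("two-plane thickness summarizes FOVs as mean and SD", {
  s <- two_plane_thickness(c(32, 28, 30, 31, 29), 0)
  expect_equal(s$mean_um, 30)
  expect_equal(s$flatness_sd_um, sd(c(32, 28, 30, 31, 29)))
  expect_equal(s$n_fov, 5)
  expect_equal(two_plane_thickness(5, 5)$mean_um, 0)
  expect_error(two_plane_thickness(1, 2), class = "gelplate_validation")
})

test_that("quadratic detrending recovers the gel and is idempotent", {
  prof <- data.frame(r_um = c(0, 250, 350), h_um = c(22, 22, 0))
  g <- generate_dry_height_map(prof,
                               background_poly2 = c(8, 0.05, -0.03,
                                                    8e-4, 2e-4, 6e-4),
                               noise_sd = 0.3, seed = 5)
  cor1 <- detrend_dry_map(g$map, g$truth$substrate_mask)
  ctr <- round(dim(cor1$heights) / 2)
  expect_lt(abs(cor1$heights[ctr[1], ctr[2]] - 22), 3 * 0.3 + 0.1)
  expect_lt(abs(mean(cor1$heights[g$truth$substrate_mask])), 0.05)
  cor2 <- detrend_dry_map(cor1, g$truth$substrate_mask)
  expect_lt(max(abs(cor2$heights - cor1$heights)), 1e-9)
  # noise-free, background-free input is untouched
  g0 <- generate_dry_height_map(prof, noise_sd = 0, seed = 1)
  cor0 <- detrend_dry_map(g0$map, g0$truth$substrate_mask)
  expect_lt(max(abs(cor0$heights - g0$map$heights)), 1e-9)
  # pure background with no gel corrects to ~0
  flatprof <- data.frame(r_um = c(0, 1), h_um = c(0, 0))
  gb <- generate_dry_height_map(flatprof,
                                background_poly2 = c(3, 0.1, 0.1, 1e-3,
                                                     0, 1e-3),
                                noise_sd = 0, seed = 1)
  corb <- detrend_dry_map(gb$map, matrix(TRUE, 128, 128))
  expect_lt(max(abs(corb$heights)), 1e-6)
  expect_error(detrend_dry_map(g$map, g$truth$substrate_mask & FALSE),
               class = "gelplate_validation")
})

test_that("cross cuts measure thickness and planar fraction", {
  flat <- height_map(
    { h <- matrix(0, 101, 101)
      yy <- matrix(1:101, 101, 101); xx <- t(yy)
      h[sqrt((yy - 51)^2 + (xx - 51)^2) <= 40] <- 15; h },
    pixel_size_um = 2)
  cc <- cross_cuts(flat)
  expect_equal(cc$thickness_um, 15, tolerance = 1e-9)
  expect_gt(cc$flatness_pct, 95)
  # hemisphere: planar only within R sin(3 deg)
  R <- 80
  hemi <- height_map(
    { yy <- matrix(1:161, 161, 161); xx <- t(yy)
      rr <- sqrt((yy - 81)^2 + (xx - 81)^2)
      h <- ifelse(rr <= R, sqrt(pmax(R^2 - rr^2, 0)), 0); h },
    pixel_size_um = 1)
  cc2 <- cross_cuts(hemi)
  expect_lt(abs(cc2$flatness_pct - 100 * sin(pi / 60)), 0.9)
  # concave phantom: centre below rim
  prof <- data.frame(r_um = c(0, 150, 250, 300),
                     h_um = c(8, 12, 20, 0))
  gc <- generate_dry_height_map(prof, noise_sd = 0, seed = 1)
  cut <- cross_cuts(gc$map)$x_cut
  centre <- cut$height_um[which.min(abs(cut$pos_um))]
  expect_lt(centre, max(cut$height_um))
})

test_that("swelling ratio is hydrated over dry", {
  expect_equal(swelling_ratio(27, 4), 6.75)
  expect_equal(swelling_ratio(10, 10), 1)
  expect_equal(swelling_ratio(30, 7.3), 30 / 7.3)
  expect_error(swelling_ratio(10, 0), class = "gelplate_validation")
})
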