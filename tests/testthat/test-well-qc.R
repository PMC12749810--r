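test_that("noise-free phantoms classify perfectly by class", {
  for (cls in c("planar", "concave", "meniscus", "empty")) {
    ph <- generate_well_phantom(phantom_spec(cls, noise = default_noise_off,
                                             seed = 21))
    rec <- classify_well(ph$stack)
    want <- c(planar = "planar", concave = "concave", meniscus = "bad",
              empty = "empty")[[cls]]
    expect_equal(rec$qc_class, want)
    if (want == "bad") expect_gt(rec$wall_overlap_px, 0)
    if (want %in% c("planar", "concave"))
      expect_equal(rec$wall_overlap_px, 0)
  }
})

test_that("preprocessing recentres an offset well to within ~1 px", {
  ph <- generate_well_phantom(phantom_spec(center_offset_px = c(15, -10),
                                           noise = default_noise_off,
                                           seed = 4))
  pre <- preprocess_well(ph$stack)
  wm <- wall_mask(pre$wall_mip)
  idx <- which(wm, arr.ind = TRUE)
  ctr <- colMeans(idx)
  mid <- (dim(pre$wall_mip) + 1) / 2
  expect_lt(max(abs(ctr - mid)), 1.5)
  # already-centred phantom is a near-identity
  ph0 <- generate_well_phantom(phantom_spec(noise = default_noise_off,
                                            seed = 4))
  pre0 <- preprocess_well(ph0$stack)
  expect_lt(max(abs(pre0$center - (dim(ph0$stack$pixels)[3] + 1) / 2)), 1.5)
})

test_that("classification is invariant to global intensity scaling", {
  ph <- generate_well_phantom(phantom_spec("concave", seed = 8))
  st2 <- ph$stack
  st2$pixels <- st2$pixels * 3.7
  r1 <- classify_well(ph$stack)
  r2 <- classify_well(st2)
  expect_equal(r1$qc_class, r2$qc_class)
  expect_equal(r1$wall_overlap_px, r2$wall_overlap_px)
})

test_that("isolated hot pixels do not perturb the wall mask", {
  ph <- generate_well_phantom(phantom_spec(noise = default_noise_off,
                                           seed = 13))
  pre <- preprocess_well(ph$stack)
  clean <- wall_mask(pre$wall_mip)
  dirty_mip <- pre$wall_mip
  set.seed(99)
  hot <- sample(length(dirty_mip), 50)
  dirty_mip[hot] <- max(dirty_mip) * 1.5
  dirty <- wall_mask(dirty_mip)
  expect_lt(sum(xor(clean, dirty)) / sum(clean), 0.01)
})

test_that("wall mask overlaps the true ring closely (IoU >= 0.9)", {
  sp <- phantom_spec(noise = default_noise_off, seed = 2)
  ph <- generate_well_phantom(sp)
  pre <- preprocess_well(ph$stack)
  wm <- wall_mask(pre$wall_mip)
  side <- nrow(pre$wall_mip)
  ctr <- (side + 1) / 2
  yy <- matrix(seq_len(side), side, side)
  xx <- t(yy)
  rr <- sqrt((yy - ctr)^2 + (xx - ctr)^2)
  truth <- rr >= sp$well_radius_px - 6 & rr <= sp$well_radius_px + 6
  iou <- sum(wm & truth) / sum(wm | truth)
  expect_gte(iou, 0.9)
})

test_that("wall-contact detection counts the AND overlap", {
  m0 <- matrix(FALSE, 10, 10)
  g <- m0; g[3:6, 3:6] <- TRUE
  w1 <- m0; w1[5:9, 5:9] <- TRUE
  ct <- detect_wall_contact(g, w1, min_overlap = 1)
  expect_equal(ct$overlap_px, 4)
  expect_true(ct$contact)
  expect_false(detect_wall_contact(g, w1, min_overlap = 5)$contact)
  expect_false(detect_wall_contact(m0, w1)$contact)
  expect_error(detect_wall_contact(g, matrix(FALSE, 5, 5)),
               class = "gelplate_validation")
})

test_that("plate QC aggregates fractions and tolerates failing wells", {
  plate <- generate_plate(12, composition = c(planar = 0.5, bad = 0.25,
                                              concave = 0.25), seed = 6)
  rep <- qc_plate(plate)
  expect_equal(sum(rep$class_fractions), 100, tolerance = 0.1)
  truth <- vapply(plate, function(x)
    c(planar = "planar", meniscus = "bad", concave = "concave")[[
      x$truth$class]], "")
  expect_gte(mean(rep$records$qc_class == truth), 11 / 12)
  expect_s4_class(rep$tile_image, "Image")
  # a broken stack is recorded as an error, not a crash
  plate[[1]]$stack <- "not a stack"
  rep2 <- qc_plate(plate)
  expect_equal(rep2$records$qc_class[1], "error")
})
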