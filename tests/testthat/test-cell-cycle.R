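make_two_nuclei_frame <- function(cyan_a, mag_a, cyan_b, mag_b, bg = 0.1) {
  arr <- array(bg, c(4, 40, 40))
  labels <- matrix(0L, 40, 40)
  labels[8:12, 8:12] <- 1L
  labels[25:29, 25:29] <- 2L
  arr[3, 8:12, 8:12] <- cyan_a;  arr[4, 8:12, 8:12] <- mag_a
  arr[3, 25:29, 25:29] <- cyan_b; arr[4, 25:29, 25:29] <- mag_b
  list(frame = arr, labels = labels)
}

test_that("the four-way FUCCI rule classifies background-subtracted means", {
  f <- make_two_nuclei_frame(0.1, 0.1, 0.8, 0.8)
  rec <- classify_nuclei(f$frame, f$labels, cyan_thr = 0.2,
                         magenta_thr = 0.2)
  expect_equal(rec$cycle_class, c("EG1", "T"))
  f2 <- make_two_nuclei_frame(0.8, 0.1, 0.1, 0.8)
  rec2 <- classify_nuclei(f2$frame, f2$labels, cyan_thr = 0.2,
                          magenta_thr = 0.2)
  expect_equal(rec2$cycle_class, c("G1", "SG2M"))
  # adding a constant to every channel changes nothing
  f3 <- f2; f3$frame <- f3$frame + 0.3
  expect_equal(classify_nuclei(f3$frame, f3$labels, cyan_thr = 0.2,
                               magenta_thr = 0.2)$cycle_class,
               rec2$cycle_class)
  expect_equal(nrow(classify_nuclei(f$frame, f$labels * 0L,
                                    cyan_thr = 0.2, magenta_thr = 0.2)), 0)
})

test_that("zero-noise synthetic time-lapses classify with 100% accuracy", {
  fu <- generate_fucci_timelapse(n_cells = 25, n_frames = 5, seed = 12)
  arr <- fu$stack$pixels
  for (t in 1:5) {
    fr <- array(arr[t, , , ], dim(arr)[2:4])
    labs <- array(fu$labels[t, , ], dim(arr)[3:4])
    rec <- classify_nuclei(fr, labs)
    tru <- fu$truth[fu$truth$frame == t, ]
    m <- merge(rec, tru, by.x = "label_id", by.y = "cell")
    expect_equal(mean(m$cycle_class.x == m$cycle_class.y), 1)
  }
})

test_that("mitotic thresholds are substrate-specific", {
  # one nucleus whose tubulin exceeds its surroundings by exactly 30%
  arr <- array(0, c(4, 40, 40))
  arr[2, , ] <- 0.5                   # cytoplasm tubulin level
  arr[2, 8:12, 8:12] <- 0.65          # relative excess 0.3
  labels <- matrix(0L, 40, 40); labels[8:12, 8:12] <- 1L
  on_plastic <- detect_mitotic(arr, labels, "plastic")
  on_gel <- detect_mitotic(arr, labels, "hydrogel")
  expect_true(on_plastic$mitotic)
  expect_false(on_gel$mitotic)
  # nucleus equal to background is never mitotic
  arr[2, 8:12, 8:12] <- 0.5
  expect_false(detect_mitotic(arr, labels, "plastic")$mitotic)
})

test_that("mitotic recall stays >= 99% after bleed-through correction", {
  fu <- generate_fucci_timelapse(n_cells = 24, n_frames = 3,
                                 mitotic_fraction = 0.25,
                                 bleedthrough = 0.3, seed = 6)
  arr <- fu$stack$pixels
  hits <- 0; total <- 0; false_pos <- 0
  for (t in 1:3) {
    fr <- array(arr[t, , , ], dim(arr)[2:4])
    labs <- array(fu$labels[t, , ], dim(arr)[3:4])
    mit <- detect_mitotic(fr, labs, "hydrogel", bleed_coeff = 0.3)
    tru <- fu$truth[fu$truth$frame == t, ]
    m <- merge(mit, tru, by.x = "label_id", by.y = "cell")
    hits <- hits + sum(m$mitotic.x & m$mitotic.y)
    total <- total + sum(m$mitotic.y)
    false_pos <- false_pos + sum(m$mitotic.x & !m$mitotic.y)
  }
  expect_gte(hits / total, 0.99)
  expect_equal(false_pos, 0)
})

test_that("fragmentation exclusion uses a strict inequality", {
  recs <- data.frame(label_id = 1:3, area_px = c(100, 99, 40))
  out <- fragmentation_filter(recs, control_mean_area = 100)
  expect_equal(out$excluded_fragmented, c(FALSE, TRUE, TRUE))
  none <- fragmentation_filter(recs, 100, exclusion_fraction = 0)
  expect_false(any(none$excluded_fragmented))
  fu <- generate_fucci_timelapse(n_cells = 30, n_frames = 1,
                                 fragment_fraction = 0.1, seed = 8)
  labs <- array(fu$labels[1, , ], dim(fu$labels)[2:3])
  rec <- classify_nuclei(array(fu$stack$pixels[1, , , ],
                               dim(fu$stack$pixels)[2:4]), labs)
  flt <- fragmentation_filter(rec, mean(rec$area_px),
                              exclusion_fraction = 0.5)
  expect_equal(sum(flt$excluded_fragmented), 3)   # the 10% fragmented cells
})

test_that("M-phase fold change matches hand-computed contingency counts", {
  recs <- data.frame(
    condition = rep(c("vehicle", "drug"), each = 100),
    mitotic = c(rep(TRUE, 2), rep(FALSE, 98), rep(TRUE, 8), rep(FALSE, 92)))
  out <- mphase_fold_change(recs, "vehicle")
  expect_equal(out$fold[out$condition == "drug"], 4)
  expect_equal(out$fold[out$condition == "vehicle"], 1)
  same <- mphase_fold_change(
    data.frame(condition = rep(c("vehicle", "x"), each = 50),
               mitotic = rep(c(TRUE, FALSE, TRUE, FALSE), c(5, 45, 5, 45))),
    "vehicle")
  expect_equal(same$fold, c(1, 1))
  novehicle <- data.frame(condition = rep(c("vehicle", "drug"), each = 10),
                          mitotic = rep(c(FALSE, TRUE), each = 10))
  expect_error(mphase_fold_change(novehicle, "vehicle"),
               class = "gelplate_undefined_fold")
})

test_that("tracking links drifting cells, closes gaps, keeps strangers apart", {
  drift <- data.frame(frame = 1:10, label_id = 1,
                      y = seq(10, 55, 5), x = 10)
  tr <- link_tracks(drift, pixel_size_um = 1)
  expect_equal(length(unique(tr$tracks$track_id)), 1)
  # disappear for 2 frames, reappear within 50 um
  gap <- data.frame(frame = c(1, 2, 5, 6), label_id = 1,
                    y = c(10, 12, 20, 22), x = 10)
  trg <- link_tracks(gap, pixel_size_um = 1, max_gap_frames = 3)
  expect_equal(length(unique(trg$tracks$track_id)), 1)
  # a 4-frame gap is not closed
  toolong <- data.frame(frame = c(1, 6), label_id = 1, y = c(10, 12), x = 10)
  expect_equal(length(unique(link_tracks(toolong,
                                         pixel_size_um = 1)$tracks$track_id)),
               2)
  # two cells 200 um apart never merge
  two <- data.frame(frame = rep(1:5, 2), label_id = rep(1:2, each = 5),
                    y = c(rep(10, 5), rep(210, 5)), x = 10)
  tr2 <- link_tracks(two, pixel_size_um = 1)
  expect_equal(length(unique(tr2$tracks$track_id)), 2)
  expect_error(link_tracks(drift), class = "gelplate_validation")
})

test_that("every detection lands in exactly one track within distance", {
  set.seed(4)
  det <- do.call(rbind, lapply(1:6, function(f)
    data.frame(frame = f, label_id = 1:8,
               y = runif(8, 0, 180), x = runif(8, 0, 180))))
  tr <- link_tracks(det, pixel_size_um = 1)$tracks
  expect_equal(nrow(tr), nrow(det))
  expect_false(any(duplicated(tr[c("frame", "label_id")])))
  by_track <- split(tr, tr$track_id)
  for (b in by_track) {
    if (nrow(b) < 2) next
    d <- sqrt(diff(b$y)^2 + diff(b$x)^2)
    expect_true(all(d <= 50 + 1e-9))
  }
})

test_that("pure-magenta scenes segment into the expected nucleus count", {
  fu <- generate_fucci_timelapse(n_cells = 20, n_frames = 1,
                                 mitotic_fraction = 1, seed = 10)
  labs <- segment_nuclei(array(fu$stack$pixels[1, , , ],
                               dim(fu$stack$pixels)[2:4]))
  expect_equal(length(unique(labs[labs > 0])), 20)
})
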