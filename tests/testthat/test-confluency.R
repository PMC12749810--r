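test_that("segmentation handles blank and saturated frames", {
  blank <- segment_cells_phase(matrix(0, 48, 48))
  expect_equal(mean(blank), 0)
  expect_true(isTRUE(attr(blank, "degenerate")))
  sat <- matrix(1, 64, 64)
  set.seed(2); sat[sample(64 * 64, 40)] <- 0   # a few dark defects
  expect_gte(mean(segment_cells_phase(sat)), 0.99)
})

test_that("known coverage is recovered within 2 percentage points", {
  mv <- generate_confluency_movie(0, c0 = 0.25, n_frames = 2, seed = 17)
  m <- segment_cells_phase(array(mv$stack$pixels[1, , ], c(96, 96)))
  expect_lt(abs(mean(m) - mv$truth$confluency_true[1]), 0.02)
})

test_that("segmentation is invariant to global intensity scaling", {
  mv <- generate_confluency_movie(0, n_frames = 2, seed = 23)
  fr <- array(mv$stack$pixels[1, , ], c(96, 96))
  expect_identical(segment_cells_phase(fr), segment_cells_phase(fr * 2.5))
})

test_that("trace smoothing, normalization and flags behave per the rules", {
  tr <- structure(list(times_h = 0:3, raw_pct = c(10, 20, 30, 40),
                       smoothed_pct = NULL, normalized = NULL,
                       flags = c("ok", "ok", "ok", "review")),
                  class = "confluency_trace")
  sm <- smooth_trace(tr, window = 4)
  expect_equal(sm$smoothed_pct, c(20, 25, 30, 35))
  expect_true(all(sm$smoothed_pct >= min(tr$raw_pct) &
                    sm$smoothed_pct <= max(tr$raw_pct)))
  nm <- normalize_trace(sm)
  expect_equal(nm$normalized[1], 1)
  expect_true(all(diff(nm$normalized) > 0))       # ordering preserved
  cst <- structure(list(times_h = 0:2, raw_pct = rep(12, 3),
                        smoothed_pct = NULL, normalized = NULL,
                        flags = rep("ok", 3)), class = "confluency_trace")
  expect_equal(normalize_trace(cst)$normalized, rep(1, 3))
  zero <- structure(list(times_h = 0, raw_pct = 0, smoothed_pct = NULL,
                         normalized = NULL, flags = "ok"),
                    class = "confluency_trace")
  expect_error(normalize_trace(zero), class = "gelplate_normalization")
})

test_that("a measured trace matches the generator truth end to end", {
  # slow growth: the window-4 edge bias (~1.5 frames of growth) stays small
  mv <- generate_confluency_movie(0, r0 = 0.025, c0 = 0.08, n_frames = 25,
                                  seed = 3)
  tr <- normalize_trace(smooth_trace(confluency_trace(mv$stack)))
  truth_ratio <- mv$truth$confluency_true[25] / mv$truth$confluency_true[1]
  expect_lt(abs(tr$normalized[25] - truth_ratio) / truth_ratio, 0.05)
  expect_true(all(tr$flags == "ok"))              # stays below 30%
})

test_that("the 4PL fit inverts noiseless samples exactly", {
  d <- c(0.5, 2, 8, 18, 40, 160)
  y <- 1 + (9 - 1) / (1 + (d / 18)^2)
  f <- fit_dose_response(d, y, n_boot = 0)
  expect_true(f$converged)
  expect_lt(abs(f$ic50 - 18) / 18, 1e-6)
  expect_lt(abs(f$hill - 2), 1e-6)
  expect_lt(abs(f$top - 9), 1e-6)
})

test_that("flat responses are flagged as non-converged", {
  f <- fit_dose_response(c(0, 1, 10, 100), rep(5, 4), n_boot = 0)
  expect_false(f$converged)
  expect_true(is.na(f$ic50))
})

test_that("the bootstrap CI brackets the point estimate", {
  d <- rep(c(0.5, 2, 8, 18, 40, 160), each = 3)
  set.seed(1)
  y <- 1 + 8 / (1 + (d / 18)^2) + rnorm(length(d), 0, 0.2)
  f <- fit_dose_response(d, pmax(y, 0.1), n_boot = 60, seed = 2)
  expect_true(f$converged)
  expect_true(f$ic50_ci[1] <= f$ic50 && f$ic50 <= f$ic50_ci[2])
})

test_that("the logistic-rate readout is exact for logistic growth", {
  r <- 0.06; c0 <- 0.05; n <- 30
  logit <- function(p) log(p / (1 - p))
  ct <- c0
  for (t in 1:(n - 1)) ct <- ct + r * ct * (1 - ct)
  est <- logistic_rate(c0, ct, n)
  expect_lt(abs(est - r) / r, 0.05)   # discrete-vs-continuous map error only
})
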