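pars <- default_params()
w <- pars$well; fl <- pars$fluid; wet <- pars$wetting

simple_protocol <- function(v_disp, v_asp = v_disp) {
  dispense_protocol(data.frame(action = c("dispense", "aspirate"),
                               volume = c(v_disp, v_asp)))
}

test_that("the contact line stays pinned during initial aspiration", {
  prot <- dispense_protocol(data.frame(action = c("dispense", "aspirate"),
                                       volume = c(12e-9, 4e-9)))
  sim <- simulate_protocol(prot, w, fl, wet, volume_step = 0.4e-9)
  tr <- sim$trajectory
  asp <- tr[seq(which.max(tr$volume) + 1, nrow(tr)), ]
  rc_at_max <- tr$contact_radius[which.max(tr$volume)]
  # all aspiration states above the receding angle stay pinned at rc
  live <- asp[asp$apparent_angle > wet$theta_receding + 1e-6, ]
  expect_true(all(live$pinned))
  expect_equal(unique(live$contact_radius), rc_at_max, tolerance = 1e-9)
})

test_that("without hysteresis the final state is path-independent", {
  wet_nohyst <- wetting_params(theta_advancing = 50, theta_receding = 50,
                               theta_wall = 60)
  one <- simulate_protocol(
    dispense_protocol(data.frame(action = "dispense", volume = 12e-9)),
    w, fl, wet_nohyst, volume_step = 0.12e-9)
  two <- simulate_protocol(
    dispense_protocol(data.frame(action = c("dispense", "dispense"),
                                 volume = c(6e-9, 6e-9))),
    w, fl, wet_nohyst, volume_step = 0.12e-9)
  expect_equal(one$coverage, two$coverage, tolerance = 0.01)
})

test_that("an empty protocol yields an empty-well result", {
  sim <- simulate_protocol(
    dispense_protocol(data.frame(action = character(),
                                 volume = numeric())), w, fl, wet)
  expect_true(sim$empty)
  expect_equal(sim$coverage, 0)
  expect_equal(sim$flatness, 0)
  expect_false(sim$wall_contact_ever)
})

test_that("24 uL dispensing wets the wall; 12 uL does not", {
  s24 <- simulate_protocol(
    dispense_protocol(data.frame(action = "dispense", volume = 24e-9)),
    w, fl, wet)
  expect_true(s24$wall_contact_ever)
  expect_true(s24$final_profile$wall_contact)
  s12 <- simulate_protocol(
    dispense_protocol(data.frame(action = "dispense", volume = 12e-9)),
    w, fl, wet)
  expect_false(s12$wall_contact_ever)
})

test_that("volume step must be smaller than every protocol step", {
  expect_error(
    simulate_protocol(simple_protocol(12e-9), w, fl, wet,
                      volume_step = 13e-9),
    class = "gelplate_validation")
})

test_that("halving the volume step changes final flatness by < 0.5 pp", {
  s1 <- simulate_protocol(simple_protocol(12e-9), w, fl, wet,
                          volume_step = 0.12e-9)
  s2 <- simulate_protocol(simple_protocol(12e-9), w, fl, wet,
                          volume_step = 0.06e-9)
  expect_lt(abs(s1$flatness - s2$flatness), 0.5)
})

test_that("a sweep without perturbations reproduces the nominal run", {
  sw <- robustness_sweep(12e-9, dV_fraction = 0, dR_offsets = numeric(),
                         well = w, fluid = fl, wetting = wet,
                         volume_step = 0.24e-9)
  nominal <- simulate_protocol(simple_protocol(12e-9), w, fl, wet,
                               volume_step = 0.24e-9)
  expect_equal(nrow(sw), 1)
  expect_equal(sw$flatness, nominal$flatness, tolerance = 1e-9)
  expect_equal(sw$coverage, nominal$coverage, tolerance = 1e-9)
  expect_equal(sw$wall_contact, nominal$wall_contact_ever)
})

test_that("the residual volume matches the target film thickness", {
  sim <- simulate_protocol(simple_protocol(12e-9), w, fl, wet,
                           film_um = 30)
  rc <- sim$final_profile$contact_radius
  expect_equal(sim$final_profile$volume, pi * rc^2 * 30e-6,
               tolerance = 1e-6)
})
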