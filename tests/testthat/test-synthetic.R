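test_that("trial profiles hit their amplitude exactly at ground-truth level", {
  tr <- simulate_trial(movement_profile("ABD"))
  expect_equal(max(tr$x_deg), 160.9)
  expect_equal(min(tr$x_deg), 0)
  expect_equal(max(abs(tr$z_deg)), 0)
  # zero amplitude: constant identity orientation
  tr0 <- simulate_trial(movement_profile("ABD", amplitude_deg = 0))
  expect_true(all(tr0$x_deg == 0 & tr0$z_deg == 0 & tr0$y_deg == 0))
  r <- rotations(tr0)
  expect_equal(r[, , 1], diag(3))
  # signs follow the channel conventions
  expect_lte(min(simulate_trial(movement_profile("ADD"))$x_deg), -38)
  expect_lte(min(simulate_trial(movement_profile("HFLEX"))$y_deg), -114)
  expect_error(movement_profile("ABD", duration_s = -1), "positive")
})

test_that("PNF engages all three channels between its start and end poses", {
  tr <- simulate_trial(movement_profile("PNF"))
  expect_equal(tr$x_deg[1], -50.1)
  expect_equal(tr$z_deg[1], 143.8)
  expect_equal(tr$y_deg[1], -14.4)
  expect_equal(max(tr$x_deg), 19.2)
  expect_equal(min(tr$z_deg), -27.3)
  expect_equal(max(tr$y_deg), 55.8)
})

test_that("rendering is deterministic under a fixed seed", {
  tr <- simulate_trial(movement_profile("HEXT"))
  m <- wearable_model()
  expect_identical(render_stream(tr, m, seed = 5),
                   render_stream(tr, m, seed = 5))
  s1 <- render_stream(tr, m, seed = 5)
  s2 <- render_stream(tr, m, seed = 6)
  expect_false(identical(s1$x_deg, s2$x_deg))
})

test_that("a null error model reproduces the decomposed ground truth", {
  tr <- simulate_trial(movement_profile("ABD"))
  s <- render_stream(tr, null_model(147, gyro = TRUE))
  expect_equal(s$rate_hz, 147)
  # extraction recovers the amplitude within resampling error
  s2 <- remove_offset(resample_series(s))
  rom <- compute_rom(s2, segment_phases(s2))
  expect_equal(rom, 160.9, tolerance = 0.1)
})

test_that("amplitude scaling attenuates extracted ROM proportionally", {
  tr <- simulate_trial(movement_profile("ABD"))
  rom_of <- function(model) {
    s <- remove_offset(resample_series(render_stream(tr, model)))
    compute_rom(s, segment_phases(s))
  }
  rom1 <- rom_of(null_model(147))
  rom07 <- rom_of(system_error_model(147, amplitude_scale = c(0.7, 1, 1)))
  expect_equal(rom07, 0.7 * rom1, tolerance = 1e-6)
  expect_equal(rom07, 112.6, tolerance = 0.2)
})

test_that("static offsets cancel in ranges but shift raw angles", {
  tr <- simulate_trial(movement_profile("HEXT"))
  s0 <- render_stream(tr, null_model(147))
  s10 <- render_stream(tr, system_error_model(
    147, static_offset_deg = c(10, 0, 0)))
  expect_equal(s10$x_deg, s0$x_deg + 10)
  extract <- function(s) {
    s <- remove_offset(resample_series(s))
    ph <- segment_phases(s)
    c(compute_rom(s, ph), compute_mav(s, ph)["mav_pooled"],
      compute_pav(s, ph, force = TRUE))
  }
  expect_equal(extract(s0), extract(s10), tolerance = 1e-9)
})

test_that("mean extracted ROM is unbiased under additive angle noise", {
  tr <- simulate_trial(movement_profile("ABD"))
  m <- system_error_model(147, amplitude_scale = c(0.8, 1, 1),
                          noise_sd_deg = 1, gyro = TRUE)
  roms <- vapply(1:100, function(i) {
    s <- remove_offset(resample_series(render_stream(tr, m, seed = i)))
    compute_rom(s, segment_phases(s))
  }, numeric(1))
  expect_equal(mean(roms), 0.8 * 160.9, tolerance = 0.5)
})

test_that("misalignment introduces cross-talk without destroying ROM", {
  tr <- simulate_trial(movement_profile("ABD"))
  m <- system_error_model(147, misalignment_deg = c(0, 3, 3))
  s <- remove_offset(resample_series(render_stream(tr, m)))
  rom <- compute_rom(s, segment_phases(s, channel = "x"))
  expect_equal(rom, 160.9, tolerance = 5)
  # the inactive channels now pick up movement
  expect_gt(diff(range(s$z_deg)), 1)
})

test_that("cohort draws are reproducible and respect truncation", {
  spec <- cohort_spec(n_subjects = 24, movements = c("ABD", "PNF"))
  p1 <- draw_cohort_profiles(spec, seed = 3)
  p2 <- draw_cohort_profiles(spec, seed = 3)
  expect_identical(p1, p2)
  amps <- vapply(p1, function(p) p$ABD$pose["x", "end"], numeric(1))
  expect_true(all(amps >= 160.9 - 3 * 10.9 & amps <= 160.9 + 3 * 10.9))
  expect_gt(stats::sd(amps), 0)
  # PNF draws stay positive on the side their pose prescribes
  zs <- vapply(p1, function(p) p$PNF$pose["z", "start"], numeric(1))
  expect_true(all(zs > 0))
})

test_that("simulated cohorts pair two streams over one ground truth", {
  trials <- simulate_cohort(cohort_spec(n_subjects = 2, movements = "VEXT"),
                            ref_model = reference_model(noise_sd_deg = 0),
                            wear_model = wearable_model(),
                            seed = 11)
  expect_length(trials, 2)
  tr <- trials[[1]]
  expect_equal(tr$reference$rate_hz, 500)
  expect_equal(tr$wearable$rate_hz, 147)
  expect_true(has_velocity(tr$wearable))
  expect_false(has_velocity(tr$reference))
  # reference stream with zero noise equals the ground truth at its rate
  expect_equal(tr$reference$z_deg, tr$truth$z_deg, tolerance = 1e-12)
})
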