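# Trapezoidal test profile: flat, constant-velocity rise, hold, fall.
trapezoid_series <- function(rate = 200, lead = 1, rise = 1, hold = 1,
                             amp = 100) {
  t <- seq(0, lead + rise + hold + rise + 0.5, by = 1 / rate)
  a <- numeric(length(t))
  up <- t >= lead & t < lead + rise
  a[up] <- amp * (t[up] - lead) / rise
  a[t >= lead + rise & t < lead + rise + hold] <- amp
  dn <- t >= lead + rise + hold & t < lead + 2 * rise + hold
  a[dn] <- amp * (1 - (t[dn] - lead - rise - hold) / rise)
  one_channel_series(a, rate)
}

test_that("velocity-threshold segmentation finds constructed boundaries", {
  s <- trapezoid_series()
  ph <- segment_phases(s)
  expect_s3_class(ph, "movement_phases")
  expect_equal(ph$channel, "x")
  # onset at t = 1.0 s, i.e. sample 201, within one sample
  expect_lte(abs(ph$outward[1] - 201), 1)
  # reverse starts after the 1 s hold, t = 3.0 s
  expect_lte(abs(ph$reverse[1] - 601), 1)
  expect_true(ph$baseline[2] < ph$outward[1])
  expect_true(ph$outward[2] < ph$reverse[1])
  # flat series: no movement
  expect_error(segment_phases(one_channel_series(rep(2, 500), 200)),
               "no movement detected")
})

test_that("ROM is the excursion from baseline to terminal position", {
  s <- trapezoid_series(amp = 150)
  ph <- segment_phases(s)
  expect_equal(compute_rom(s, ph), 150, tolerance = 1e-9)
  # constant shift leaves ROM unchanged (offset invariance)
  s2 <- s; s2$x_deg <- s2$x_deg + 10
  expect_equal(compute_rom(s2, segment_phases(s2)), 150, tolerance = 1e-9)
  # negative-going movement: magnitude reported
  s3 <- s; s3$x_deg <- -s3$x_deg
  expect_equal(compute_rom(s3, segment_phases(s3)), 150, tolerance = 1e-9)
})

test_that("synthetic single-plane trials recover their reference amplitude", {
  tr <- simulate_trial(movement_profile("ABD"))
  s <- remove_offset(resample_series(render_stream(tr, null_model(147))))
  expect_equal(compute_rom(s, segment_phases(s)), 160.9, tolerance = 0.1)
})

test_that("TROM is the sum of opposing terminal ranges", {
  expect_equal(compute_trom(30, 40), 70)
  expect_equal(compute_trom(0, 12.5), 12.5)
  expect_error(compute_trom(-1, 5), "non-negative")
  # additivity on a synthetic opposing pair
  roms <- vapply(c("ER", "IR"), function(m) {
    tr <- simulate_trial(movement_profile(m))
    s <- remove_offset(resample_series(render_stream(tr, null_model(147))))
    compute_rom(s, segment_phases(s))
  }, numeric(1))
  expect_equal(unname(compute_trom(roms[1], roms[2])), sum(roms))
  expect_equal(sum(roms), 65.3 + 65.0, tolerance = 0.2)
})

test_that("peak angular velocity matches profile mechanics", {
  # constant-velocity trapezoid: +/- amp/rise
  s <- trapezoid_series(amp = 90, rise = 1)
  ph <- segment_phases(s)
  pav <- compute_pav(s, ph)
  expect_equal(unname(pav["pav_max"]), 90, tolerance = 1)
  expect_equal(unname(pav["pav_min"]), -90, tolerance = 1)
  # minimum-jerk profile: peak velocity 1.875 A / T, against a dense
  # numerical oracle
  A <- 120; T_ <- 2
  tr <- simulate_trial(movement_profile("ABD", amplitude_deg = A,
                                        duration_s = T_), rate_hz = 2000)
  v_dense <- max(abs(diff(tr$x_deg)) * 2000)
  expect_equal(v_dense, 1.875 * A / T_, tolerance = 0.001 * 1.875 * A / T_)
  s <- render_stream(tr, null_model(200))
  pav <- compute_pav(s, segment_phases(s))
  expect_equal(unname(pav["pav_max"]), 1.875 * A / T_,
               tolerance = 0.005 * 1.875 * A / T_)
  # zero-amplitude trial: no movement to segment
  tr0 <- simulate_trial(movement_profile("ABD", amplitude_deg = 0))
  expect_error(segment_phases(render_stream(tr0, null_model(200))),
               "no movement")
})

test_that("PAV is reported for single-plane movements only by default", {
  tr <- simulate_trial(movement_profile("ER"))
  s <- render_stream(tr, null_model(200))
  ph <- segment_phases(s)
  expect_error(compute_pav(s, ph), "not reported")
  expect_silent(compute_pav(s, ph, force = TRUE))
})

test_that("MAV windows average absolute velocity as specified", {
  # constant-velocity phases: every window reads the plateau velocity
  s <- trapezoid_series(amp = 100, rise = 2)  # 50 deg/s
  ph <- segment_phases(s)
  mav <- compute_mav(s, ph)
  expect_equal(unname(mav), rep(50, 5), tolerance = 2.5)
  # symmetric profile, window_frac = 0.5: both halves of a phase agree
  tr <- simulate_trial(movement_profile("ABD"))
  s <- render_stream(tr, null_model(200))
  ph <- segment_phases(s)
  mav <- compute_mav(s, ph, window_frac = 0.5)
  expect_equal(unname(mav["mav_out_early"]), unname(mav["mav_out_late"]),
               tolerance = 0.5)
  # early windows are slower than the mid-phase for bell-shaped velocity
  mav25 <- compute_mav(s, ph, window_frac = 0.25)
  v <- abs(series_channel(angular_velocity(s), "x", "velocity"))
  mid <- mean(v[ph$outward[1]:ph$outward[2]])
  expect_lt(mav25[["mav_out_early"]], mid)
  expect_error(compute_mav(s, ph, window_frac = 0.001), "3 samples")
})

test_that("PNF extraction splits start and end pose excursions per channel", {
  tr <- simulate_trial(movement_profile("PNF"))
  s <- resample_series(render_stream(tr, null_model(147)))
  out <- extract_outcomes(s, subject = 1)
  expect_equal(nrow(out), 6)
  expect_setequal(out$movement,
                  c("PNF-X start", "PNF-X end", "PNF-Z start", "PNF-Z end",
                    "PNF-Y start", "PNF-Y end"))
  get <- function(m) out$rom_deg[out$movement == m]
  expect_equal(get("PNF-X start"), 50.1, tolerance = 0.3)
  expect_equal(get("PNF-X end"), 19.2, tolerance = 0.3)
  expect_equal(get("PNF-Z start"), 143.8, tolerance = 0.3)
  expect_equal(get("PNF-Z end"), 27.3, tolerance = 0.3)
  expect_true(all(is.na(out$pav_min_deg_s)))
  expect_true(all(out$mav_deg_s > 0))
})

test_that("PAV and MAV scale linearly with amplitude at fixed duration", {
  vals <- vapply(c(40, 80), function(A) {
    tr <- simulate_trial(movement_profile("HEXT", amplitude_deg = A,
                                          duration_s = 1))
    s <- render_stream(tr, null_model(200))
    ph <- segment_phases(s)
    c(compute_pav(s, ph)["pav_max"], compute_mav(s, ph)["mav_pooled"])
  }, numeric(2))
  expect_equal(unname(vals[, 2] / vals[, 1]), c(2, 2), tolerance = 0.02)
})
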