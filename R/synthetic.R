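# Movement battery defaults.
#
# Amplitudes (degrees) and their between-subject SDs are the reference-system
# per-movement means +/- SDs of the emulated study cohort; phase durations are
# chosen so that the minimum-jerk peak velocity (1.875 * amplitude / duration)
# matches the reference-system peak angular velocity of the same cohort where
# one was reported, and a comfortable self-paced value otherwise.
#
# Channel mapping and signs (intrinsic XZ'Y''):
#   X: + abduction / - adduction
#   Z: + vertical flexion / - vertical extension
#   Y: + external rotation, horizontal extension / - internal rotation,
#      horizontal flexion
# The complex PNF pattern starts away from neutral (vertical flexion /
# adduction / internal rotation) and ends on the opposite side of all three
# channels (vertical extension / abduction / external rotation).
.battery <- list(
  ABD   = list(channel = "x", start = 0,     end =  160.9,
               sd_start = 0,    sd_end = 10.9, duration_s = 1.875 * 160.9 / 90.5),
  ADD   = list(channel = "x", start = 0,     end =  -39.0,
               sd_start = 0,    sd_end = 12.9, duration_s = 1.875 * 39.0 / 91.3),
  HFLEX = list(channel = "y", start = 0,     end = -114.5,
               sd_start = 0,    sd_end = 10.5, duration_s = 1.875 * 114.5 / 107.9),
  HEXT  = list(channel = "y", start = 0,     end =   30.9,
               sd_start = 0,    sd_end = 10.6, duration_s = 1.875 * 30.9 / 111.2),
  VFLEX = list(channel = "z", start = 0,     end =  157.0,
               sd_start = 0,    sd_end = 11.3, duration_s = 1.875 * 157.0 / 98.6),
  VEXT  = list(channel = "z", start = 0,     end =  -37.7,
               sd_start = 0,    sd_end = 10.0, duration_s = 1.875 * 37.7 / 93.6),
  ER    = list(channel = "y", start = 0,     end =   65.3,
               sd_start = 0,    sd_end = 12.8, duration_s = 1.4),
  IR    = list(channel = "y", start = 0,     end =  -65.0,
               sd_start = 0,    sd_end = 11.5, duration_s = 1.4),
  PNF   = list(channel = c("x", "z", "y"),
               start = c(x = -50.1, z = 143.8, y = -14.4),
               end   = c(x =  19.2, z = -27.3, y =  55.8),
               sd_start = c(x = 8.6,  z = 31.4, y = 11.9),
               sd_end   = c(x = 14.8, z = 38.7, y = 22.7),
               duration_s = 3.0)
)

# Opposing-movement pairs whose terminal ranges sum to a total arc (TROM);
# for PNF the arc is within-trial (start pose + end pose per channel).
.trom_pairs <- list(
  `ABD/ADD`     = c("ABD", "ADD"),
  `HFLEX/HEXT`  = c("HFLEX", "HEXT"),
  `VFLEX/VEXT`  = c("VFLEX", "VEXT"),
  `ER/IR`       = c("ER", "IR")
)

#' The simulated movement battery
#'
#' Nine active shoulder movement conditions: four single-plane opposing
#' pairs (abduction/adduction, horizontal flexion/extension, vertical
#' flexion/extension, external/internal rotation) and one complex
#' multiplanar pattern (PNF) engaging all three Euler channels.
#'
#' @return data.frame with one row per movement and active channel:
#'   `movement`, `channel`, `start_deg`, `end_deg`, `sd_start_deg`,
#'   `sd_end_deg`, `duration_s`, `pav_reported` (whether peak angular
#'   velocity is an outcome for this movement).
#' @export
movement_battery <- function() {
  rows <- lapply(names(.battery), function(m) {
    b <- .battery[[m]]
    data.frame(movement = m, channel = b$channel,
               start_deg = unname(b$start), end_deg = unname(b$end),
               sd_start_deg = unname(b$sd_start),
               sd_end_deg = unname(b$sd_end),
               duration_s = b$duration_s,
               pav_reported = !(m %in% c("ER", "IR", "PNF")))
  })
  do.call(rbind, rows)
}

#' Define one movement profile
#'
#' A profile fixes, per Euler channel, the signed start and end angles of
#' one trial, the phase duration, the hold at the terminal position, and
#' the angular trajectory shape. The trial is: lead-in at the start pose,
#' smooth outward phase to the terminal pose, hold, smooth reverse phase
#' back, tail at the start pose. Both smooth phases have zero velocity and
#' (for the minimum-jerk shape) zero acceleration at their boundaries.
#'
#' @param movement Movement abbreviation from [movement_battery()].
#' @param amplitude_deg Optional override. For single-plane movements a
#'   single non-negative magnitude (the conventional sign is applied); for
#'   PNF a named vector such as `c(x_start = , x_end = , z_start = , ...)`
#'   of magnitudes.
#' @param duration_s Duration of each smooth phase, seconds (> 0).
#' @param hold_s Hold at the terminal pose, seconds.
#' @param lead_s,tail_s Quiet time at the start pose before the outward and
#'   after the reverse phase, seconds.
#' @param shape `"minimum_jerk"` (default) or `"raised_cosine"`.
#' @return A `movement_profile` object.
#' @export
movement_profile <- function(movement, amplitude_deg = NULL,
                             duration_s = NULL, hold_s = 0.5,
                             lead_s = 1.0, tail_s = 0.5,
                             shape = c("minimum_jerk", "raised_cosine")) {
  shape <- match.arg(shape)
  movement <- match.arg(movement, names(.battery))
  b <- .battery[[movement]]
  if (is.null(duration_s)) duration_s <- b$duration_s
  if (duration_s <= 0) stop("duration_s must be positive")
  if (hold_s < 0 || lead_s < 0 || tail_s < 0)
    stop("hold_s, lead_s and tail_s must be non-negative")
  # signed start/end per channel, rows x, z, y
  pose <- matrix(0, 3, 2, dimnames = list(c("x", "z", "y"),
                                          c("start", "end")))
  if (movement == "PNF") {
    for (ch in c("x", "z", "y")) {
      pose[ch, "start"] <- b$start[[ch]]
      pose[ch, "end"] <- b$end[[ch]]
    }
    if (!is.null(amplitude_deg)) {
      if (is.null(names(amplitude_deg)))
        stop("PNF amplitudes must be a named vector, e.g. c(x_start = 50)")
      if (any(amplitude_deg < 0)) stop("amplitudes must be non-negative")
      for (nm in names(amplitude_deg)) {
        p <- strsplit(nm, "_", fixed = TRUE)[[1]]
        if (length(p) != 2 || !(p[1] %in% c("x", "z", "y")) ||
            !(p[2] %in% c("start", "end")))
          stop("unknown PNF amplitude name: ", nm)
        pose[p[1], p[2]] <- sign(pose[p[1], p[2]]) * amplitude_deg[[nm]]
      }
    }
  } else {
    amp <- if (is.null(amplitude_deg)) abs(b$end) else amplitude_deg
    if (length(amp) != 1 || amp < 0)
      stop("single-plane amplitude must be one non-negative number")
    pose[b$channel, "end"] <- sign(b$end) * amp
  }
  structure(list(movement = movement, pose = pose,
                 duration_s = duration_s, hold_s = hold_s,
                 lead_s = lead_s, tail_s = tail_s, shape = shape),
            class = "movement_profile")
}

# Normalized trajectory s(tau): 0 -> 1 with zero endpoint velocity.
profile_shape <- function(tau, shape) {
  switch(shape,
         minimum_jerk = 10 * tau^3 - 15 * tau^4 + 6 * tau^5,
         raised_cosine = (1 - cos(pi * tau)) / 2,
         stop("unknown shape: ", shape))
}

#' Simulate one ground-truth movement trial
#'
#' Evaluates the profile's angular trajectory on a uniform grid, producing
#' the true humerus-relative-to-thorax orientation over the trial. The
#' ground-truth range of motion equals the profile amplitude exactly.
#'
#' @param profile A [movement_profile()].
#' @param rate_hz Master sampling rate of the ground truth (default 500).
#' @param seed Unused placeholder kept for interface symmetry with the
#'   stochastic generators; trials are deterministic given the profile.
#' @return A `rotation_series`: uniformly sampled true Euler channels plus
#'   the sampling rate and movement label. Rotation matrices are
#'   materialized on demand via [rotations()].
#' @export
simulate_trial <- function(profile, rate_hz = 500, seed = NULL) {
  stopifnot(inherits(profile, "movement_profile"), rate_hz > 0)
  p <- profile
  total <- p$lead_s + p$duration_s + p$hold_s + p$duration_s + p$tail_s
  t <- seq(0, total, by = 1 / rate_hz)
  # normalized position along start -> end, per sample
  s <- numeric(length(t))
  out0 <- p$lead_s
  out1 <- out0 + p$duration_s
  rev0 <- out1 + p$hold_s
  rev1 <- rev0 + p$duration_s
  i <- t >= out0 & t < out1
  s[i] <- profile_shape((t[i] - out0) / p$duration_s, p$shape)
  s[t >= out1 & t < rev0] <- 1
  i <- t >= rev0 & t < rev1
  s[i] <- 1 - profile_shape((t[i] - rev0) / p$duration_s, p$shape)
  ch <- lapply(c("x", "z", "y"), function(c_)
    p$pose[c_, "start"] + (p$pose[c_, "end"] - p$pose[c_, "start"]) * s)
  structure(list(rate_hz = rate_hz, t0_s = 0,
                 x_deg = ch[[1]], z_deg = ch[[2]], y_deg = ch[[3]],
                 movement = p$movement, profile = p),
            class = "rotation_series")
}

#' @export
print.rotation_series <- function(x, ...) {
  cat(sprintf("<rotation_series> [%s]: %d samples @ %g Hz\n",
              x$movement, length(x$x_deg), x$rate_hz))
  invisible(x)
}

#' Rotation matrices of a ground-truth series
#' @param rs A `rotation_series` from [simulate_trial()].
#' @return `3 x 3 x n` array of rotation matrices.
#' @export
rotations <- function(rs) {
  stopifnot(inherits(rs, "rotation_series"))
  r <- rotation_from_euler(rs$x_deg, rs$z_deg, rs$y_deg)
  if (is.matrix(r)) array(r, dim = c(3, 3, 1)) else r
}

#' Define a measurement-system error model
#'
#' Parameterizes how a measurement system corrupts the true segment
#' orientation, at the angle level: a fixed frame misalignment (sensor
#' tilt/rotation on the skin), per-channel amplitude scaling (soft-tissue
#' artifact attenuating or inflating excursions), per-channel static
#' offsets, integrated-white-noise drift (accumulated sensor error and
#' slow magnetic disturbance), and additive white noise.
#'
#' @param rate_hz Native sampling rate of the system, Hz.
#' @param static_offset_deg Length-3 (x, z, y) constant angle offsets,
#'   degrees.
#' @param misalignment_deg Length-3 rotation vector (degrees) of the fixed
#'   sensor-frame tilt; applied to the angle vector as small-angle
#'   cross-talk mixing between channels.
#' @param amplitude_scale Length-3 positive per-channel gains.
#' @param drift_rate_deg_s Random-walk rate: the drift SD after `t` seconds
#'   is `drift_rate_deg_s * sqrt(t)` degrees.
#' @param noise_sd_deg SD of additive white angle noise, degrees.
#' @param gyro Whether the system carries gyroscope angular-velocity
#'   channels (the wearable does; the optical reference does not).
#' @param label System label stamped on rendered streams.
#' @return A `system_error_model` object.
#' @export
system_error_model <- function(rate_hz,
                               static_offset_deg = c(0, 0, 0),
                               misalignment_deg = c(0, 0, 0),
                               amplitude_scale = c(1, 1, 1),
                               drift_rate_deg_s = 0,
                               noise_sd_deg = 0,
                               gyro = FALSE,
                               label = "system") {
  stopifnot(rate_hz > 0, length(static_offset_deg) == 3,
            length(misalignment_deg) == 3, length(amplitude_scale) == 3,
            all(amplitude_scale > 0), drift_rate_deg_s >= 0,
            noise_sd_deg >= 0)
  structure(list(rate_hz = rate_hz,
                 static_offset_deg = as.numeric(static_offset_deg),
                 misalignment_deg = as.numeric(misalignment_deg),
                 amplitude_scale = as.numeric(amplitude_scale),
                 drift_rate_deg_s = drift_rate_deg_s,
                 noise_sd_deg = noise_sd_deg, gyro = gyro, label = label),
            class = "system_error_model")
}

#' Default optical-reference error model (500 Hz, near-perfect)
#' @param ... Overrides passed to [system_error_model()].
#' @return A `system_error_model`.
#' @export
reference_model <- function(...) {
  args <- utils::modifyList(
    list(rate_hz = 500, noise_sd_deg = 0.02, gyro = FALSE,
         label = "reference"), list(...))
  do.call(system_error_model, args)
}

#' Default wearable error model (147 Hz, mild realistic errors)
#' @param ... Overrides passed to [system_error_model()].
#' @return A `system_error_model`.
#' @export
wearable_model <- function(...) {
  args <- utils::modifyList(
    list(rate_hz = 147, static_offset_deg = c(2, 2, 2),
         misalignment_deg = c(2, 2, 2), amplitude_scale = c(0.95, 0.95, 0.95),
         drift_rate_deg_s = 0.05, noise_sd_deg = 0.5, gyro = TRUE,
         label = "wearable"), list(...))
  do.call(system_error_model, args)
}

#' Render a ground-truth trial through a measurement system
#'
#' Resamples the true orientation to the system's native rate, applies the
#' fixed sensor misalignment as small-angle cross-talk (the misalignment
#' rotation applied to the angle vector), then per-channel amplitude
#' scaling and static offsets, then random-walk drift, and finally
#' additive white noise.
#' Gyroscope velocity channels, when the system carries them, are the
#' finite-difference derivative of the distorted angles before the white
#' noise term (gyroscope noise is negligible next to angle noise at these
#' rates). With an all-zero error model and matching rate the output equals
#' the Euler decomposition of the ground truth.
#'
#' @param rs A `rotation_series` from [simulate_trial()].
#' @param model A [system_error_model()].
#' @param seed Integer seed for the stochastic terms (drift, noise);
#'   `NULL` leaves the RNG state alone.
#' @return An [angle_series()] at `model$rate_hz`.
#' @export
render_stream <- function(rs, model, seed = NULL) {
  stopifnot(inherits(rs, "rotation_series"),
            inherits(model, "system_error_model"))
  if (length(rs$x_deg) < 2L) stop("ground-truth series is empty")
  if (!is.null(seed)) set.seed(seed)
  src_t <- rs$t0_s + (seq_along(rs$x_deg) - 1L) / rs$rate_hz
  t <- seq(src_t[1], src_t[length(src_t)], by = 1 / model$rate_hz)
  # ground truth is band-limited by construction; plain interpolation
  a <- lapply(list(rs$x_deg, rs$z_deg, rs$y_deg), function(ch)
    stats::approx(src_t, ch, xout = t)$y)
  names(a) <- c("x", "z", "y")
  if (any(model$misalignment_deg != 0)) {
    # small-angle cross-talk: the sensor-frame tilt rotates the angle
    # vector (axis order x, y, z), mixing a little of each movement into
    # the other channels. Composing the misalignment in rotation space
    # instead would fold the XZ'Y'' decomposition of sagittal excursions
    # beyond 90 degrees (near-gimbal passage), which no measurement
    # pipeline reporting these movements can have done.
    rmis <- rotation_from_rotvec(model$misalignment_deg)
    av <- rmis %*% rbind(a$x, a$y, a$z)
    a <- list(x = av[1, ], z = av[3, ], y = av[2, ])
  }
  n <- length(t)
  dt <- 1 / model$rate_hz
  for (i in 1:3) {
    ch <- channel_names[i]
    a[[ch]] <- a[[ch]] * model$amplitude_scale[i] + model$static_offset_deg[i]
    if (model$drift_rate_deg_s > 0)
      a[[ch]] <- a[[ch]] +
        cumsum(stats::rnorm(n, 0, model$drift_rate_deg_s * sqrt(dt)))
  }
  v <- if (model$gyro)
    lapply(a, fd_velocity, rate_hz = model$rate_hz)
  if (model$noise_sd_deg > 0)
    for (ch in channel_names)
      a[[ch]] <- a[[ch]] + stats::rnorm(n, 0, model$noise_sd_deg)
  angle_series(model$rate_hz, a$x, a$z, a$y,
               vx = v$x, vz = v$z, vy = v$y, t0_s = t[1],
               system = model$label, movement = rs$movement)
}

#' Define a simulated cohort
#'
#' @param n_subjects Number of subjects (>= 2; default 24, the emulated
#'   study cohort size).
#' @param movements Character vector of movement abbreviations (default:
#'   the full battery).
#' @param amplitude_sd_scale Multiplier on the battery's per-movement
#'   between-subject amplitude SDs (1 = defaults; 0 = identical subjects).
#' @param duration_sd_frac Between-subject SD of the phase-duration
#'   multiplier (self-selected pace), as a fraction; multipliers are
#'   truncated to \[0.6, 1.5\].
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_subjects = 24, movements = names(.battery),
                        amplitude_sd_scale = 1, duration_sd_frac = 0.15) {
  stopifnot(n_subjects >= 2, all(movements %in% names(.battery)),
            amplitude_sd_scale >= 0, duration_sd_frac >= 0)
  structure(list(n_subjects = n_subjects, movements = movements,
                 amplitude_sd_scale = amplitude_sd_scale,
                 duration_sd_frac = duration_sd_frac),
            class = "cohort_spec")
}

# Normal draw truncated to [lo, hi] (inverse-CDF; deterministic under seed).
rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

# Deterministic sub-seed derivation, kept below 2^31.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 7919 + as.double(i) * 104729) %% 2147483629 + 1)
}

#' Draw per-subject movement profiles for a cohort
#'
#' Subject amplitudes are normal around the battery defaults, truncated at
#' 3 SD and floored at 0.5 degrees so ranges stay positive; each subject
#' gets a movement-specific pace multiplier on the phase duration.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; draws are reproducible given `(spec, seed)`.
#' @return Nested list: `profiles[[subject]][[movement]]` of
#'   [movement_profile()] objects.
#' @export
draw_cohort_profiles <- function(spec, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  lapply(seq_len(spec$n_subjects), function(s) {
    out <- lapply(spec$movements, function(m) {
      b <- .battery[[m]]
      draw_amp <- function(mean_deg, sd_deg) {
        sd_deg <- sd_deg * spec$amplitude_sd_scale
        mean_mag <- abs(mean_deg)
        amp <- rtruncnorm1(1, mean_mag, sd_deg,
                           max(0.5, mean_mag - 3 * sd_deg),
                           mean_mag + 3 * sd_deg)
        max(0.5, amp)
      }
      if (m == "PNF") {
        amp <- c(
          x_start = draw_amp(b$start[["x"]], b$sd_start[["x"]]),
          x_end   = draw_amp(b$end[["x"]],   b$sd_end[["x"]]),
          z_start = draw_amp(b$start[["z"]], b$sd_start[["z"]]),
          z_end   = draw_amp(b$end[["z"]],   b$sd_end[["z"]]),
          y_start = draw_amp(b$start[["y"]], b$sd_start[["y"]]),
          y_end   = draw_amp(b$end[["y"]],   b$sd_end[["y"]]))
      } else {
        amp <- draw_amp(b$end, b$sd_end)
      }
      pace <- min(1.5, max(0.6, stats::rnorm(1, 1, spec$duration_sd_frac)))
      movement_profile(m, amplitude_deg = amp,
                       duration_s = b$duration_s * pace)
    })
    names(out) <- spec$movements
    out
  })
}

#' Simulate a paired two-system cohort
#'
#' For every subject and movement, one ground-truth trial is generated and
#' rendered through both measurement systems, producing the paired data the
#' agreement statistics consume.
#'
#' @param spec A [cohort_spec()].
#' @param ref_model,wear_model [system_error_model()]s for the reference
#'   and wearable systems (defaults: [reference_model()],
#'   [wearable_model()]).
#' @param seed Integer seed; output is reproducible given all arguments.
#' @param master_rate_hz Sampling rate of the shared ground truth.
#' @return List of trials; each element has `subject`, `movement`, `truth`
#'   (`rotation_series`), `reference` and `wearable` ([angle_series()]).
#' @export
simulate_cohort <- function(spec = cohort_spec(),
                            ref_model = reference_model(),
                            wear_model = wearable_model(),
                            seed = 1, master_rate_hz = 500) {
  profiles <- draw_cohort_profiles(spec, seed)
  trials <- list()
  k <- 0L
  for (s in seq_len(spec$n_subjects)) {
    for (m in spec$movements) {
      k <- k + 1L
      truth <- simulate_trial(profiles[[s]][[m]], rate_hz = master_rate_hz)
      trials[[k]] <- list(
        subject = s, movement = m, truth = truth,
        reference = render_stream(truth, ref_model,
                                  seed = derive_seed(seed, 2L * k)),
        wearable = render_stream(truth, wear_model,
                                 seed = derive_seed(seed, 2L * k + 1L)))
    }
  }
  trials
}
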