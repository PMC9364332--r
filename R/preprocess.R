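#' Resample an angle series onto a uniform target grid
#'
#' Linear interpolation onto a uniform grid at `target_hz` spanning the
#' original time range. When downsampling, a zero-phase 4th-order
#' Butterworth low-pass (default cutoff 50 Hz, capped below the target
#' Nyquist) is applied first to prevent aliasing; upsampling needs no
#' filter. Velocity channels, when present, are resampled the same way.
#'
#' @param s An [angle_series()].
#' @param target_hz Target sampling rate, Hz (default 200, the common
#'   analysis timebase).
#' @param antialias Apply the low-pass before downsampling (default TRUE).
#' @param cutoff_hz Anti-alias cutoff, Hz.
#' @return An [angle_series()] at `target_hz`.
#' @export
resample_series <- function(s, target_hz = 200, antialias = TRUE,
                            cutoff_hz = 50) {
  stopifnot(inherits(s, "angle_series"), target_hz > 0)
  if (length(s) < 2L) stop("need at least 2 samples to resample")
  src_t <- series_time(s)
  chans <- c("x_deg", "z_deg", "y_deg",
             if (has_velocity(s)) c("vx", "vz", "vy"))
  down <- target_hz < s$rate_hz
  filt <- NULL
  if (down && antialias) {
    wc <- min(cutoff_hz, 0.45 * target_hz) / (s$rate_hz / 2)
    if (wc < 1) filt <- signal::butter(4, wc, type = "low")
  }
  t <- seq(src_t[1], src_t[length(src_t)], by = 1 / target_hz)
  out <- lapply(chans, function(ch) {
    a <- s[[ch]]
    if (!is.null(filt)) {
      # filtfilt starts from zero state; remove the line through the
      # endpoints first so edge transients vanish on offset signals
      trend <- seq(a[1], a[length(a)], length.out = length(a))
      a <- trend + signal::filtfilt(filt, a - trend)
    }
    stats::approx(src_t, a, xout = t)$y
  })
  names(out) <- chans
  angle_series(target_hz, out$x_deg, out$z_deg, out$y_deg,
               vx = out$vx, vz = out$vz, vy = out$vy,
               t0_s = t[1], system = s$system, movement = s$movement)
}

# Channel with the largest angle excursion (used for sync and segmentation).
dominant_channel <- function(s) {
  rng <- vapply(channel_names, function(ch) {
    a <- series_channel(s, ch)
    diff(range(a))
  }, numeric(1))
  channel_names[which.max(rng)]
}

crop_series <- function(s, from, to) {
  idx <- from:to
  angle_series(s$rate_hz, s$x_deg[idx], s$z_deg[idx], s$y_deg[idx],
               vx = s$vx[idx], vz = s$vz[idx], vy = s$vy[idx],
               t0_s = s$t0_s + (from - 1L) / s$rate_hz,
               system = s$system, movement = s$movement)
}

#' Synchronize two angle series by cross-correlation
#'
#' Estimates the lag of `b` relative to `a` by maximizing the normalized
#' cross-correlation of the dominant channel's angular velocity, then crops
#' both series to their common window. When the correlation peak is below
#' 0.2 (e.g. flat, featureless streams) a warning is issued and zero lag is
#' applied.
#'
#' @param a,b [angle_series()] at the same rate.
#' @param max_lag_s Largest lag searched, seconds.
#' @return A `synced_pair`: list with elements `a`, `b` (cropped to equal
#'   length), `lag_s` (positive means `b` started later), and `peak_cor`.
#' @export
synchronize <- function(a, b, max_lag_s = 2) {
  stopifnot(inherits(a, "angle_series"), inherits(b, "angle_series"))
  if (abs(a$rate_hz - b$rate_hz) > 1e-9)
    stop("both series must share one sampling rate; resample first")
  rate <- a$rate_hz
  va <- series_channel(angular_velocity(a), dominant_channel(a), "velocity")
  vb <- series_channel(angular_velocity(b), dominant_channel(a), "velocity")
  max_lag <- min(as.integer(round(max_lag_s * rate)),
                 length(va) - 2L, length(vb) - 2L)
  # FFT cross-correlation of the demeaned velocities; z[k] aligns va[j + L]
  # with vb[j] at lag L = k - length(vb)
  va0 <- va - mean(va)
  vb0 <- vb - mean(vb)
  denom <- sqrt(sum(va0^2) * sum(vb0^2))
  lag <- 0L
  peak <- NA_real_
  if (denom > 0) {
    z <- stats::convolve(va0, vb0, conj = TRUE, type = "open")
    lags_all <- seq_along(z) - length(vb)
    keep <- abs(lags_all) <= max_lag
    cand <- lags_all[keep][which.max(z[keep])]
    # Pearson correlation over the actual overlap at the candidate lag
    if (cand >= 0) {
      n <- min(length(va) - cand, length(vb))
      peak <- suppressWarnings(
        stats::cor(va[(1 + cand):(cand + n)], vb[1:n]))
    } else {
      n <- min(length(va), length(vb) + cand)
      peak <- suppressWarnings(
        stats::cor(va[1:n], vb[(1 - cand):(n - cand)]))
    }
    if (is.finite(peak) && peak >= 0.2) lag <- cand
  }
  if (lag == 0L && (!is.finite(peak) || peak < 0.2))
    warning("cross-correlation peak below 0.2; applying zero lag")
  # lag > 0: a leads b by `lag` samples; drop a's head / b's tail
  if (lag >= 0) {
    n <- min(length(a) - lag, length(b))
    a2 <- crop_series(a, 1L + lag, lag + n)
    b2 <- crop_series(b, 1L, n)
  } else {
    n <- min(length(a), length(b) + lag)
    a2 <- crop_series(a, 1L, n)
    b2 <- crop_series(b, 1L - lag, n - lag)
  }
  structure(list(a = a2, b = b2, lag_s = -lag / rate, peak_cor = peak),
            class = "synced_pair")
}

#' Remove baseline angle offsets
#'
#' Subtracts, per channel, the mean over an initial baseline window, so
#' the series starts at zero. Kinematic ranges and velocities are invariant
#' to this; it mirrors retrospective offset removal between two systems
#' whose calibration poses differ slightly. Idempotent.
#'
#' @param s An [angle_series()].
#' @param baseline_window_s Length of the initial baseline window, seconds
#'   (default 0.5). Must be at most half the series duration.
#' @return The series with zero-mean baseline; the removed offsets are
#'   attached as attribute `"offset_deg"`.
#' @export
remove_offset <- function(s, baseline_window_s = 0.5) {
  stopifnot(inherits(s, "angle_series"), baseline_window_s > 0)
  n <- length(s)
  w <- as.integer(round(baseline_window_s * s$rate_hz))
  if (w < 1L || 2L * w > n)
    stop("baseline window must be positive and at most half the series")
  off <- c(x = mean(s$x_deg[1:w]), z = mean(s$z_deg[1:w]),
           y = mean(s$y_deg[1:w]))
  s$x_deg <- s$x_deg - off[["x"]]
  s$z_deg <- s$z_deg - off[["z"]]
  s$y_deg <- s$y_deg - off[["y"]]
  attr(s, "offset_deg") <- off
  s
}
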