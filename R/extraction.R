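# Run-length helper: first index where `cond` holds for >= k consecutive
# samples, searching at or after `from`. Returns NA if none.
first_sustained <- function(cond, k, from = 1L) {
  n <- length(cond)
  if (from > n) return(NA_integer_)
  cond[seq_len(from - 1L)] <- FALSE
  r <- rle(cond)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= k)
  if (!length(hit)) NA_integer_ else starts[hit[1]]
}

#' Segment a trial into baseline, outward and reverse phases
#'
#' Automated movement fragmentation by velocity threshold: movement onset
#' is the first sample where the absolute angular velocity of the active
#' channel exceeds `threshold_frac` of its peak, sustained for at least
#' `sustain_s`; the outward phase ends when the velocity falls back below
#' the threshold (sustained), the terminal dwell spans the hold at
#' end-range, and the reverse phase is detected symmetrically. The baseline
#' window precedes the onset.
#'
#' @param s An [angle_series()] with velocity channels (see
#'   [angular_velocity()]).
#' @param channel Active channel, `"x"`, `"z"` or `"y"`; default: the
#'   channel with the largest excursion.
#' @param threshold_frac Velocity threshold as a fraction of the peak
#'   absolute velocity (default 0.05).
#' @param sustain_s Minimum time the threshold condition must hold
#'   (default 0.1 s), which rejects isolated noise crossings.
#' @param baseline_window_s Length of the baseline window before onset.
#' @return A `movement_phases` object: list with integer index pairs
#'   `baseline`, `outward`, `dwell` (terminal hold), `reverse`, plus the
#'   `channel` used.
#' @export
segment_phases <- function(s, channel = NULL, threshold_frac = 0.05,
                           sustain_s = 0.1, baseline_window_s = 0.5) {
  stopifnot(inherits(s, "angle_series"))
  s <- angular_velocity(s)
  if (is.null(channel)) channel <- dominant_channel(s)
  v <- abs(series_channel(s, channel, "velocity"))
  vmax <- max(v)
  thr <- threshold_frac * vmax
  if (vmax <= 0 || !any(v > thr))
    stop("no movement detected on channel ", channel)
  k <- max(1L, as.integer(round(sustain_s * s$rate_hz)))
  onset <- first_sustained(v > thr, k)
  if (is.na(onset)) stop("no movement detected on channel ", channel)
  out_end <- first_sustained(v < thr, k, from = onset + 1L)
  if (is.na(out_end))
    stop("outward phase does not end within the trial")
  rev_start <- first_sustained(v > thr, k, from = out_end)
  if (is.na(rev_start))
    stop("no reverse phase detected")
  rev_end <- first_sustained(v < thr, k, from = rev_start + 1L)
  if (is.na(rev_end)) rev_end <- length(v) + 1L
  bw <- as.integer(round(baseline_window_s * s$rate_hz))
  # the threshold onset trails the true movement start; keep the baseline
  # clear of that sub-threshold early motion by a phase-proportional margin
  margin <- as.integer(round(0.1 * (out_end - onset)))
  b1 <- max(1L, onset - 1L - margin)
  b0 <- max(1L, b1 - bw + 1L)
  phases <- list(baseline = c(b0, b1),
                 outward = c(onset, out_end - 1L),
                 dwell = c(out_end, rev_start - 1L),
                 reverse = c(rev_start, rev_end - 1L),
                 channel = channel)
  structure(phases, class = "movement_phases")
}

#' @export
print.movement_phases <- function(x, ...) {
  cat(sprintf(
    "<movement_phases> [%s] baseline %d-%d, outward %d-%d, dwell %d-%d, reverse %d-%d\n",
    x$channel, x$baseline[1], x$baseline[2], x$outward[1], x$outward[2],
    x$dwell[1], x$dwell[2], x$reverse[1], x$reverse[2]))
  invisible(x)
}

# Signed terminal angle. Preferred estimator: the mean angle over the
# central part of the terminal dwell, trimming a margin proportional to the
# outward-phase length off both dwell ends. The edges of the
# threshold-based dwell still belong to the smooth approach/departure,
# where the angle has not quite reached end-range and would bias the range
# low; the trimmed centre is the static hold, so its mean is unbiased and
# averages out additive noise. Falls back to the full dwell mean, then to
# the signed extremum of the movement (earliest sample on ties) when the
# dwell is too short to average.
terminal_angle <- function(s, ph, channel, min_dwell = 5L,
                           trim_frac = 0.08) {
  a <- series_channel(s, channel)
  d <- ph$dwell
  trim <- as.integer(round(trim_frac *
                             (ph$outward[2] - ph$outward[1] + 1L)))
  if (d[2] - trim - (d[1] + trim) + 1L >= min_dwell)
    return(mean(a[(d[1] + trim):(d[2] - trim)]))
  if (d[2] - d[1] + 1L >= min_dwell) return(mean(a[d[1]:d[2]]))
  idx <- ph$outward[1]:ph$reverse[2]
  seg <- a[idx]
  base <- mean(a[ph$baseline[1]:ph$baseline[2]])
  seg[which.max(abs(seg - base))]
}

#' Range of motion of one movement phase
#'
#' Absolute angular excursion from the baseline (starting) position to the
#' terminal position, in degrees. The terminal position is the mean angle
#' over the central part of the terminal dwell (the static hold, after
#' trimming phase-proportional margins off the dwell edges), an estimator
#' that is both unbiased at end-range and robust to additive measurement
#' noise; with no usable dwell it falls back to the full dwell mean and
#' then to the signed extremum of the movement (earliest sample on ties).
#'
#' @param s An [angle_series()].
#' @param phases A [segment_phases()] result.
#' @param channel Channel to read; defaults to the segmentation channel.
#' @param min_dwell Minimum dwell samples for the dwell-mean estimator.
#' @return Non-negative ROM in degrees.
#' @export
compute_rom <- function(s, phases, channel = phases$channel,
                        min_dwell = 5L) {
  a <- series_channel(s, channel)
  base <- mean(a[phases$baseline[1]:phases$baseline[2]])
  abs(terminal_angle(s, phases, channel, min_dwell) - base)
}

#' Total range of motion of an opposing-movement pair
#'
#' Sum of the two terminal ranges about the shared starting position, e.g.
#' the external + internal rotation arc.
#'
#' @param rom_a,rom_b Non-negative ROM values in degrees.
#' @return `rom_a + rom_b`.
#' @export
compute_trom <- function(rom_a, rom_b) {
  if (any(c(rom_a, rom_b) < 0)) stop("ROM values must be non-negative")
  rom_a + rom_b
}

#' Peak angular velocities of a trial
#'
#' Minimum and maximum of the angular-velocity channel over the outward and
#' reverse phases. By convention this outcome is reported for single-plane
#' movements only; set `force = TRUE` to compute it anyway.
#'
#' @param s An [angle_series()] with velocity channels.
#' @param phases A [segment_phases()] result.
#' @param channel Channel to read; defaults to the segmentation channel.
#' @param force Compute even for movements where the outcome is
#'   conventionally not reported (rotations, complex patterns).
#' @return Named numeric `c(pav_min = , pav_max = )` in degrees/s.
#' @export
compute_pav <- function(s, phases, channel = phases$channel, force = FALSE) {
  if (!force && s$movement %in% c("ER", "IR", "PNF"))
    stop("peak angular velocity is not reported for ", s$movement,
         "; use force = TRUE to override")
  s <- angular_velocity(s)
  v <- series_channel(s, channel, "velocity")
  idx <- c(phases$outward[1]:phases$outward[2],
           phases$reverse[1]:phases$reverse[2])
  if (!length(idx)) stop("empty movement phases")
  c(pav_min = min(v[idx]), pav_max = max(v[idx]))
}

#' Mean angular velocities in early/late phase windows
#'
#' Mean absolute angular velocity over four narrow windows: the first and
#' last `window_frac` of the outward phase and of the reverse phase
#' (instantaneously after movement initiation and shortly before reaching
#' the terminal / starting position). Absolute velocity makes outward and
#' reverse contributions positive.
#'
#' @param s An [angle_series()] with velocity channels.
#' @param phases A [segment_phases()] result.
#' @param channel Channel to read; defaults to the segmentation channel.
#' @param window_frac Window length as a fraction of the phase (default
#'   0.25).
#' @return Named numeric: `mav_out_early`, `mav_out_late`,
#'   `mav_rev_early`, `mav_rev_late`, and `mav_pooled` (mean of the four),
#'   degrees/s.
#' @export
compute_mav <- function(s, phases, channel = phases$channel,
                        window_frac = 0.25) {
  stopifnot(window_frac > 0, window_frac <= 0.5)
  s <- angular_velocity(s)
  v <- abs(series_channel(s, channel, "velocity"))
  win_mean <- function(phase, side) {
    len <- phase[2] - phase[1] + 1L
    w <- max(1L, as.integer(floor(window_frac * len)))
    if (w < 3L) stop("MAV window shorter than 3 samples")
    idx <- if (side == "early") phase[1]:(phase[1] + w - 1L)
           else (phase[2] - w + 1L):phase[2]
    mean(v[idx])
  }
  out <- c(mav_out_early = win_mean(phases$outward, "early"),
           mav_out_late = win_mean(phases$outward, "late"),
           mav_rev_early = win_mean(phases$reverse, "early"),
           mav_rev_late = win_mean(phases$reverse, "late"))
  c(out, mav_pooled = mean(out))
}

#' Extract all kinematic outcomes from one preprocessed trial
#'
#' Segments the trial on its dominant channel and computes the per-trial
#' scalar outcomes. Single-plane movements yield one row (ROM, PAV min/max
#' where reported, MAV windows). The complex PNF pattern yields two rows
#' per channel -- the excursion of the start pose and of the end pose from
#' neutral -- with MAV split into the windows adjacent to the start pose
#' (outward-early + reverse-late) and to the end pose (outward-late +
#' reverse-early); for PNF the series must retain absolute (calibrated)
#' angles, so baseline offset removal is skipped upstream.
#'
#' @param s A preprocessed [angle_series()] (200 Hz, offsets removed for
#'   single-plane movements).
#' @param subject Subject identifier stamped on the rows.
#' @param threshold_frac,sustain_s Passed to [segment_phases()].
#' @param window_frac Passed to [compute_mav()].
#' @param phases Optional precomputed [segment_phases()] result. Two
#'   synchronized streams of one trial share their movement events, so the
#'   pipeline fragments the reference stream once and reuses the phases for
#'   the paired stream, keeping outcome windows sample-identical across
#'   systems.
#' @return data.frame with columns `subject`, `movement`, `system`,
#'   `channel`, `rom_deg`, `pav_min_deg_s`, `pav_max_deg_s`,
#'   `mav_deg_s`, plus segmentation metadata (`onset_s`, `dwell_s`).
#' @export
extract_outcomes <- function(s, subject = NA, threshold_frac = 0.05,
                             sustain_s = 0.1, window_frac = 0.25,
                             phases = NULL) {
  stopifnot(inherits(s, "angle_series"))
  s <- angular_velocity(s)
  m <- s$movement
  ph <- if (is.null(phases))
    segment_phases(s, threshold_frac = threshold_frac,
                   sustain_s = sustain_s)
  else phases
  meta <- data.frame(onset_s = (ph$outward[1] - 1L) / s$rate_hz + s$t0_s,
                     dwell_s = (ph$dwell[2] - ph$dwell[1] + 1L) / s$rate_hz)
  if (m == "PNF") {
    rows <- lapply(channel_names, function(ch) {
      a <- series_channel(s, ch)
      mav <- compute_mav(s, ph, channel = ch, window_frac = window_frac)
      # neutral = 0 by calibration; start pose read off the baseline,
      # end pose off the terminal dwell
      rom_start <- abs(mean(a[ph$baseline[1]:ph$baseline[2]]))
      rom_end <- abs(terminal_angle(s, ph, ch))
      data.frame(
        subject = subject, movement = paste0("PNF-", toupper(ch), " ",
                                             c("start", "end")),
        system = s$system, channel = ch,
        rom_deg = c(rom_start, rom_end),
        pav_min_deg_s = NA_real_, pav_max_deg_s = NA_real_,
        mav_deg_s = c(mean(mav[c("mav_out_early", "mav_rev_late")]),
                      mean(mav[c("mav_out_late", "mav_rev_early")])),
        meta)
    })
    return(do.call(rbind, rows))
  }
  rom <- compute_rom(s, ph)
  mav <- compute_mav(s, ph, window_frac = window_frac)
  pav <- if (m %in% c("ER", "IR")) c(pav_min = NA_real_, pav_max = NA_real_)
         else compute_pav(s, ph)
  data.frame(subject = subject, movement = m, system = s$system,
             channel = ph$channel, rom_deg = rom,
             pav_min_deg_s = unname(pav["pav_min"]),
             pav_max_deg_s = unname(pav["pav_max"]),
             mav_deg_s = unname(mav["mav_pooled"]), meta)
}
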