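#' Construct an Euler angle time series
#'
#' Container for uniformly sampled XZ'Y'' Euler angle channels (degrees)
#' with optional angular-velocity channels (degrees/s, e.g. from a
#' gyroscope), a sampling rate, and system / movement labels.
#'
#' @param rate_hz Sampling rate in samples per second (> 0).
#' @param x_deg,z_deg,y_deg Angle channels in degrees, equal length >= 2.
#' @param vx,vz,vy Optional angular-velocity channels in degrees/s.
#' @param t0_s Start time of the first sample, seconds.
#' @param system Label of the measuring system, e.g. `"reference"` or
#'   `"wearable"`.
#' @param movement Movement label (one of [movement_battery()]'s
#'   abbreviations, or "").
#' @return An object of class `angle_series`: a list with fields
#'   `rate_hz`, `t0_s`, `x_deg`, `z_deg`, `y_deg`, optional `vx`, `vz`,
#'   `vy`, `system`, `movement`.
#' @export
angle_series <- function(rate_hz, x_deg, z_deg, y_deg,
                         vx = NULL, vz = NULL, vy = NULL,
                         t0_s = 0, system = "reference", movement = "") {
  stopifnot(is.numeric(rate_hz), length(rate_hz) == 1L, rate_hz > 0)
  n <- length(x_deg)
  if (n < 2L) stop("angle_series needs at least 2 samples")
  stopifnot(length(z_deg) == n, length(y_deg) == n)
  if (anyNA(x_deg) || anyNA(z_deg) || anyNA(y_deg))
    stop("angle channels contain NA")
  for (v in list(vx, vz, vy))
    if (!is.null(v) && length(v) != n)
      stop("velocity channels must match the angle channel length")
  has_v <- !is.null(vx) && !is.null(vz) && !is.null(vy)
  structure(
    list(rate_hz = rate_hz, t0_s = t0_s,
         x_deg = as.numeric(x_deg), z_deg = as.numeric(z_deg),
         y_deg = as.numeric(y_deg),
         vx = if (has_v) as.numeric(vx), vz = if (has_v) as.numeric(vz),
         vy = if (has_v) as.numeric(vy),
         system = system, movement = movement),
    class = "angle_series")
}

#' @export
print.angle_series <- function(x, ...) {
  n <- length(x$x_deg)
  cat(sprintf("<angle_series> %s%s: %d samples @ %g Hz (%.2f s)%s\n",
              x$system,
              if (nzchar(x$movement)) paste0(" [", x$movement, "]") else "",
              n, x$rate_hz, n / x$rate_hz,
              if (has_velocity(x)) ", velocity channels" else ""))
  invisible(x)
}

#' @export
length.angle_series <- function(x) length(x$x_deg)

#' Sample times of an angle series
#' @param s An [angle_series()].
#' @return Numeric vector of sample times in seconds.
#' @export
series_time <- function(s) s$t0_s + (seq_along(s$x_deg) - 1L) / s$rate_hz

#' Does a series carry angular-velocity channels?
#' @param s An [angle_series()].
#' @return Logical.
#' @export
has_velocity <- function(s) !is.null(s$vx)

channel_names <- c("x", "z", "y")

#' Extract one angle or velocity channel
#' @param s An [angle_series()].
#' @param channel `"x"`, `"z"` or `"y"`.
#' @param what `"angle"` (degrees) or `"velocity"` (degrees/s).
#' @return Numeric vector.
#' @export
series_channel <- function(s, channel, what = c("angle", "velocity")) {
  what <- match.arg(what)
  channel <- match.arg(channel, channel_names)
  if (what == "angle") s[[paste0(channel, "_deg")]]
  else {
    if (!has_velocity(s)) stop("series has no velocity channels")
    s[[paste0("v", channel)]]
  }
}

fd_velocity <- function(a, rate_hz) {
  # central differences inside, one-sided at the endpoints
  n <- length(a)
  v <- numeric(n)
  v[1] <- (a[2] - a[1]) * rate_hz
  v[n] <- (a[n] - a[n - 1]) * rate_hz
  if (n > 2L) v[2:(n - 1)] <- (a[3:n] - a[1:(n - 2)]) * rate_hz / 2
  v
}

#' Fill angular-velocity channels by finite differences
#'
#' Computes degrees-per-second velocity channels from the angle channels
#' using central differences on interior samples and one-sided differences
#' at the endpoints. A series that already carries velocity channels
#' (gyroscope data, for a wearable stream) is returned unchanged: measured
#' angular velocity takes precedence over numerical differentiation.
#'
#' @param s An [angle_series()] with at least 3 samples.
#' @return The series with `vx`, `vz`, `vy` filled.
#' @export
angular_velocity <- function(s) {
  stopifnot(inherits(s, "angle_series"))
  if (has_velocity(s)) return(s)
  if (length(s) < 3L) stop("need at least 3 samples to differentiate")
  s$vx <- fd_velocity(s$x_deg, s$rate_hz)
  s$vz <- fd_velocity(s$z_deg, s$rate_hz)
  s$vy <- fd_velocity(s$y_deg, s$rate_hz)
  s
}

#' Convert an angle series to a data.frame
#' @param x An [angle_series()].
#' @param row.names,optional,... Passed over from the generic (unused).
#' @return data.frame with `time_s`, angle and any velocity columns.
#' @export
as.data.frame.angle_series <- function(x, row.names = NULL,
                                       optional = FALSE, ...) {
  d <- data.frame(time_s = series_time(x), x_deg = x$x_deg,
                  z_deg = x$z_deg, y_deg = x$y_deg)
  if (has_velocity(x)) {
    d$vx_deg_s <- x$vx; d$vz_deg_s <- x$vz; d$vy_deg_s <- x$vy
  }
  d
}
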