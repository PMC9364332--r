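# Shared fixtures and independent oracles used across test files.

# Single-axis rotation matrices, used to build the brute-force composition
# oracle independently of the closed-form implementation.
rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}
rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}
rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}
# intrinsic X -> Z' -> Y'' composition by explicit matrix products
oracle_compose <- function(x, z, y) rot_x(x) %*% rot_z(z) %*% rot_y(y)

# Two-way ANOVA mean-squares ICC oracle via stats::aov (independent of the
# closed-form implementation).
oracle_icc <- function(reference, test, form = "consistency") {
  n <- length(reference)
  d <- data.frame(y = c(reference, test),
                  subj = factor(rep(seq_len(n), 2)),
                  meth = factor(rep(1:2, each = n)))
  av <- stats::anova(stats::aov(y ~ subj + meth, data = d))
  ms_r <- av["subj", "Mean Sq"]
  ms_c <- av["meth", "Mean Sq"]
  ms_e <- av["Residuals", "Mean Sq"]
  k <- 2
  if (form == "consistency")
    (ms_r - ms_e) / (ms_r + (k - 1) * ms_e)
  else
    (ms_r - ms_e) / (ms_r + (k - 1) * ms_e + k * (ms_c - ms_e) / n)
}

# Minimal error models for tests: an exact pass-through system.
null_model <- function(rate_hz, gyro = FALSE, label = "reference") {
  system_error_model(rate_hz = rate_hz, gyro = gyro, label = label)
}

# A short zero-error run configuration over fast movements, for pipeline
# tests that exercise plumbing rather than statistics.
small_config <- function(...) {
  run_config(
    cohort = cohort_spec(n_subjects = 4, movements = c("HEXT", "VEXT")),
    ref_model = reference_model(noise_sd_deg = 0),
    wear_model = wearable_model(noise_sd_deg = 0,
                                static_offset_deg = c(0, 0, 0),
                                misalignment_deg = c(0, 0, 0),
                                amplitude_scale = c(1, 1, 1),
                                drift_rate_deg_s = 0),
    ...)
}

# Build an angle_series with one active channel and zeros elsewhere.
one_channel_series <- function(a, rate_hz, channel = "x", ...) {
  zero <- numeric(length(a))
  args <- list(rate_hz = rate_hz, x_deg = zero, z_deg = zero, y_deg = zero,
               ...)
  args[[paste0(channel, "_deg")]] <- a
  do.call(angle_series, args)
}

# 24 pairs whose per-system means match the requested values exactly
# (residuals centred at machine precision).
pairs_with_means <- function(ref_mean, test_mean, n = 24, sd = 5,
                             seed = 99) {
  set.seed(seed)
  e1 <- rnorm(n, 0, sd); e1 <- e1 - mean(e1)
  e2 <- rnorm(n, 0, sd); e2 <- e2 - mean(e2)
  list(reference = ref_mean + e1, test = test_mean + e2)
}
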