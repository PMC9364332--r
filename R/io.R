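#' Write an angle series to a plain-text trial file
#'
#' CSV with a commented metadata header (`# key=value` lines declaring the
#' sampling rate, start time, system and movement labels), a `time_s`
#' column, angle columns in degrees and, when present, velocity columns in
#' degrees/s. Numbers are written with full double precision, so a
#' write/read round trip reproduces the series exactly and repeated writes
#' of the same series are byte-identical.
#'
#' @param s An [angle_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_file <- function(s, path) {
  stopifnot(inherits(s, "angle_series"))
  d <- as.data.frame(s)
  num <- function(v) sprintf("%.17g", v)
  header <- c("# kinagree trial v1",
              sprintf("# rate_hz=%s", num(s$rate_hz)),
              sprintf("# t0_s=%s", num(s$t0_s)),
              sprintf("# system=%s", s$system),
              sprintf("# movement=%s", s$movement),
              paste(names(d), collapse = ","))
  body <- do.call(paste, c(lapply(d, num), sep = ","))
  con <- file(path, open = "wb")  # fixed newline across platforms
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}

parse_header_kv <- function(lines) {
  kv <- sub("^#\\s*", "", lines)
  kv <- kv[grepl("=", kv, fixed = TRUE)]
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  stats::setNames(as.list(vals), keys)
}

#' Read a plain-text trial file
#'
#' Parses and validates a file written by [write_trial_file()]: the header
#' must declare `rate_hz`, `system` and `movement`; the time column must be
#' uniform and monotone at the declared rate; any non-finite angle or
#' velocity value is an error naming the offending line.
#'
#' @param path Path to the trial file.
#' @return An [angle_series()].
#' @export
read_trial_file <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr_idx <- grep("^#", lines)
  hdr <- parse_header_kv(lines[hdr_idx])
  for (key in c("rate_hz", "system", "movement"))
    if (is.null(hdr[[key]]))
      stop(path, ": missing header field '", key, "'")
  rate <- as.numeric(hdr$rate_hz)
  t0 <- if (is.null(hdr$t0_s)) 0 else as.numeric(hdr$t0_s)
  body_start <- max(hdr_idx) + 1L
  cols <- strsplit(lines[body_start], ",", fixed = TRUE)[[1]]
  need <- c("time_s", "x_deg", "z_deg", "y_deg")
  if (!all(need %in% cols))
    stop(path, ": column header must include ", paste(need, collapse = ", "))
  d <- utils::read.csv(text = lines[body_start:length(lines)])
  if (nrow(d) < 2L) stop(path, ": fewer than 2 data rows")
  val_cols <- setdiff(cols, "time_s")
  for (cn in val_cols) {
    bad <- which(!is.finite(d[[cn]]))
    if (length(bad))
      stop(path, ": non-finite value in column '", cn, "' at line ",
           body_start + bad[1], call. = FALSE)
  }
  dt <- diff(d$time_s)
  if (any(dt <= 0))
    stop(path, ": time column not strictly increasing at line ",
         body_start + which(dt <= 0)[1] + 1L)
  if (max(abs(dt - 1 / rate)) > 1e-6 / rate)
    stop(path, ": time column is not uniform at the declared rate")
  has_v <- all(c("vx_deg_s", "vz_deg_s", "vy_deg_s") %in% cols)
  angle_series(rate, d$x_deg, d$z_deg, d$y_deg,
               vx = if (has_v) d$vx_deg_s, vz = if (has_v) d$vz_deg_s,
               vy = if (has_v) d$vy_deg_s,
               t0_s = t0, system = hdr$system, movement = hdr$movement)
}

#' Assemble a pipeline run configuration
#'
#' All knobs of the simulate -> preprocess -> extract -> agree chain in one
#' serializable object. Serializes losslessly to YAML via
#' [write_run_config()] / [read_run_config()].
#'
#' @param cohort A [cohort_spec()].
#' @param ref_model,wear_model [system_error_model()]s.
#' @param target_rate_hz Common analysis rate (default 200 Hz).
#' @param antialias Low-pass before downsampling (default TRUE).
#' @param sync Cross-correlation synchronization of the two streams.
#' @param baseline_window_s Baseline window for offset removal and
#'   segmentation, seconds.
#' @param threshold_frac,sustain_s Segmentation knobs
#'   (see [segment_phases()]).
#' @param window_frac MAV window fraction (see [compute_mav()]).
#' @param icc_form `"consistency"` or `"agreement"`.
#' @param master_rate_hz Ground-truth sampling rate.
#' @return A `run_config` object.
#' @export
run_config <- function(cohort = cohort_spec(),
                       ref_model = reference_model(),
                       wear_model = wearable_model(),
                       target_rate_hz = 200, antialias = TRUE,
                       sync = TRUE, baseline_window_s = 0.5,
                       threshold_frac = 0.05, sustain_s = 0.1,
                       window_frac = 0.25, icc_form = "consistency",
                       master_rate_hz = 500) {
  stopifnot(inherits(cohort, "cohort_spec"),
            inherits(ref_model, "system_error_model"),
            inherits(wear_model, "system_error_model"),
            target_rate_hz > 0, master_rate_hz > 0)
  structure(list(cohort = cohort, ref_model = ref_model,
                 wear_model = wear_model, target_rate_hz = target_rate_hz,
                 antialias = antialias, sync = sync,
                 baseline_window_s = baseline_window_s,
                 threshold_frac = threshold_frac, sustain_s = sustain_s,
                 window_frac = window_frac, icc_form = icc_form,
                 master_rate_hz = master_rate_hz),
            class = "run_config")
}

#' Write a run configuration to a YAML file
#' @param cfg A [run_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  x <- unclass(cfg)
  x$cohort <- unclass(x$cohort)
  x$ref_model <- unclass(x$ref_model)
  x$wear_model <- unclass(x$wear_model)
  yaml::write_yaml(x, path, precision = 17)
  invisible(path)
}

#' Read a run configuration from a YAML file
#' @param path Path written by [write_run_config()].
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  run_config(
    cohort = do.call(cohort_spec, x$cohort),
    ref_model = do.call(system_error_model, x$ref_model),
    wear_model = do.call(system_error_model, x$wear_model),
    target_rate_hz = x$target_rate_hz, antialias = x$antialias,
    sync = x$sync, baseline_window_s = x$baseline_window_s,
    threshold_frac = x$threshold_frac, sustain_s = x$sustain_s,
    window_frac = x$window_frac, icc_form = x$icc_form,
    master_rate_hz = x$master_rate_hz)
}
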