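check_pairs <- function(reference, test, n_min = 2L) {
  stopifnot(is.numeric(reference), is.numeric(test),
            length(reference) == length(test))
  ok <- is.finite(reference) & is.finite(test)
  reference <- reference[ok]
  test <- test[ok]
  if (length(reference) < n_min)
    stop("need at least ", n_min, " complete pairs")
  list(reference = reference, test = test)
}

#' Bland-Altman bias and 95% limits of agreement
#'
#' Differences are taken as reference minus test, so a positive bias means
#' the test system under-reads. Limits of agreement are
#' `bias +/- 1.96 * SD` of the differences, with the sample SD (n - 1
#' denominator).
#'
#' @param reference,test Paired per-subject outcome values (reference =
#'   criterion system).
#' @return List with `bias`, `loa_upper`, `loa_lower`, `sd_diff`, `n`, and
#'   `plot_data` (a data.frame of pair means and differences, the
#'   Bland-Altman plot coordinates).
#' @export
bland_altman <- function(reference, test) {
  p <- check_pairs(reference, test, 2L)
  d <- p$reference - p$test
  bias <- mean(d)
  sd_d <- stats::sd(d)
  list(bias = bias,
       loa_upper = bias + 1.96 * sd_d,
       loa_lower = bias - 1.96 * sd_d,
       sd_diff = sd_d, n = length(d),
       plot_data = data.frame(mean = (p$reference + p$test) / 2, diff = d))
}

#' Two-way mixed single-measures intraclass correlation
#'
#' ICC from the mean squares of the subjects-by-methods two-way ANOVA
#' decomposition. The default consistency form is
#' `ICC(3,1) = (MS_R - MS_E) / (MS_R + (k - 1) MS_E)`, which ignores a
#' fixed between-method offset; the absolute-agreement form adds the
#' method variance term
#' `(MS_R - MS_E) / (MS_R + (k-1) MS_E + k (MS_C - MS_E) / n)`.
#'
#' @param reference,test Paired per-subject values (k = 2 methods).
#' @param form `"consistency"` (default) or `"agreement"`.
#' @return ICC estimate (<= 1).
#' @export
icc_two_way_mixed <- function(reference, test,
                              form = c("consistency", "agreement")) {
  form <- match.arg(form)
  p <- check_pairs(reference, test, 3L)
  m <- cbind(p$reference, p$test)
  n <- nrow(m); k <- ncol(m)
  g <- mean(m)
  if (sum((m - g)^2) < .Machine$double.eps * max(1, g^2))
    stop("zero total variance; ICC undefined")
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ss_r <- k * sum((row_m - g)^2)
  ss_c <- n * sum((col_m - g)^2)
  ss_e <- sum((m - g)^2) - ss_r - ss_c
  ms_r <- ss_r / (n - 1)
  ms_c <- ss_c / (k - 1)
  ms_e <- ss_e / ((n - 1) * (k - 1))
  if (form == "consistency")
    (ms_r - ms_e) / (ms_r + (k - 1) * ms_e)
  else
    (ms_r - ms_e) / (ms_r + (k - 1) * ms_e + k * (ms_c - ms_e) / n)
}

#' Root mean square error of paired outcomes
#'
#' `sqrt(mean((reference - test)^2))` over subjects. Satisfies
#' `rmse >= |bias|`, via the identity
#' `rmse^2 = bias^2 + ((n-1)/n) * var(d)`.
#'
#' @param reference,test Paired per-subject values.
#' @return Non-negative RMSE in the outcome's units.
#' @export
rmse <- function(reference, test) {
  p <- check_pairs(reference, test, 1L)
  sqrt(mean((p$reference - p$test)^2))
}

#' Classify an ICC into an interpretation band
#'
#' Bands: poor below 0.5, moderate in \[0.5, 0.7), good in \[0.7, 0.9),
#' excellent at 0.9 and above (half-open intervals, so 0.5 is moderate and
#' 0.9 is excellent).
#'
#' @param icc Finite ICC value(s).
#' @return Character vector of band labels.
#' @export
classify_icc <- function(icc) {
  stopifnot(is.finite(icc))
  cut(icc, breaks = c(-Inf, 0.5, 0.7, 0.9, Inf), right = FALSE,
      labels = c("poor", "moderate", "good", "excellent")) |>
    as.character()
}

#' Rank-based heteroscedasticity check for Bland-Altman data
#'
#' Kendall rank correlation between the absolute paired differences and the
#' pair means: a positive, significant tau indicates that disagreement
#' grows with the measured magnitude (heteroscedasticity). Automates what
#' is conventionally judged by visual inspection of the Bland-Altman plot.
#'
#' @param reference,test Paired per-subject values (n >= 5).
#' @return List with `tau`, `p_value`, and `plot_data` as in
#'   [bland_altman()].
#' @export
heteroscedasticity_check <- function(reference, test) {
  p <- check_pairs(reference, test, 5L)
  d <- p$reference - p$test
  mu <- (p$reference + p$test) / 2
  ct <- suppressWarnings(
    stats::cor.test(abs(d), mu, method = "kendall", exact = FALSE))
  list(tau = unname(ct$estimate), p_value = ct$p.value,
       plot_data = data.frame(mean = mu, diff = d))
}

#' All agreement statistics for one movement-by-outcome cell
#'
#' @param reference,test Paired per-subject values.
#' @param icc_form Passed to [icc_two_way_mixed()].
#' @return One-row data.frame: per-system mean and SD, `rmse`, `icc`,
#'   `icc_band`, `bias`, `loa_upper`, `loa_lower`, heteroscedasticity
#'   `het_tau` and `het_p`, `n`, and `rmse_ge_bias` (the internal
#'   consistency flag `rmse >= |bias|`, which always holds for RMSE and
#'   bias computed from the same scalar differences).
#' @export
agreement_stats <- function(reference, test, icc_form = "consistency") {
  p <- check_pairs(reference, test, 3L)
  ba <- bland_altman(p$reference, p$test)
  icc <- icc_two_way_mixed(p$reference, p$test, form = icc_form)
  rm <- rmse(p$reference, p$test)
  het <- if (length(p$reference) >= 5)
    heteroscedasticity_check(p$reference, p$test)
  else list(tau = NA_real_, p_value = NA_real_)
  data.frame(ref_mean = mean(p$reference), ref_sd = stats::sd(p$reference),
             test_mean = mean(p$test), test_sd = stats::sd(p$test),
             rmse = rm, icc = icc, icc_band = classify_icc(icc),
             bias = ba$bias, loa_upper = ba$loa_upper,
             loa_lower = ba$loa_lower,
             het_tau = het$tau, het_p = het$p_value,
             n = ba$n, rmse_ge_bias = rm >= abs(ba$bias) - 1e-12)
}
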