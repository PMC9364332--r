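# Pivot one outcome column of the long per-trial summary table into paired
# reference/test vectors per subject for a given movement label.
pair_outcome <- function(summaries, movement, value_col,
                         ref_label, test_label) {
  d <- summaries[summaries$movement == movement, ]
  r <- d[d$system == ref_label, c("subject", value_col)]
  t_ <- d[d$system == test_label, c("subject", value_col)]
  m <- merge(r, t_, by = "subject", suffixes = c("_ref", "_test"))
  m <- m[order(m$subject), ]
  list(reference = m[[paste0(value_col, "_ref")]],
       test = m[[paste0(value_col, "_test")]],
       n_total = length(unique(d$subject)), n_paired = nrow(m))
}

# TROM values per subject and system for an opposing-movement pair.
trom_table <- function(summaries, movements) {
  d <- summaries[summaries$movement %in% movements, ]
  wide <- merge(
    d[d$movement == movements[1], c("subject", "system", "rom_deg")],
    d[d$movement == movements[2], c("subject", "system", "rom_deg")],
    by = c("subject", "system"), suffixes = c("_a", "_b"))
  wide$trom_deg <- compute_trom(wide$rom_deg_a, wide$rom_deg_b)
  wide[, c("subject", "system", "trom_deg")]
}

#' Build the movement-by-outcome agreement report
#'
#' Aggregates per-trial kinematic summaries into one row per movement and
#' outcome (ROM, TROM for opposing-movement arcs, PAV for single-plane
#' movements, MAV), each carrying per-system means and SDs, RMSE, ICC with
#' its interpretation band, Bland-Altman bias and limits of agreement, and
#' the heteroscedasticity check. Subjects missing either system's value for
#' a cell are dropped listwise; the total number of dropped subject-rows is
#' attached as attribute `"n_dropped"`.
#'
#' The PAV outcome reported here is the peak velocity magnitude,
#' `max(|pav_min|, |pav_max|)`; the signed extremes remain available in the
#' per-trial summaries.
#'
#' @param summaries data.frame from [extract_outcomes()] rows (columns
#'   `subject`, `movement`, `system`, `rom_deg`, `pav_min_deg_s`,
#'   `pav_max_deg_s`, `mav_deg_s`).
#' @param ref_label,test_label System labels of the reference and test
#'   streams.
#' @param icc_form Passed to [icc_two_way_mixed()].
#' @return data.frame: `movement`, `outcome`, `unit`, then the
#'   [agreement_stats()] columns.
#' @export
build_report <- function(summaries, ref_label = "reference",
                         test_label = "wearable",
                         icc_form = "consistency") {
  stopifnot(all(c("subject", "movement", "system", "rom_deg") %in%
                  names(summaries)))
  summaries$pav_deg_s <- pmax(abs(summaries$pav_min_deg_s),
                              abs(summaries$pav_max_deg_s))
  rows <- list()
  dropped <- 0L
  add_row <- function(movement, outcome, unit, pr) {
    if (pr$n_paired < 3L) return(invisible())
    dropped <<- dropped + (pr$n_total - pr$n_paired)
    st <- agreement_stats(pr$reference, pr$test, icc_form = icc_form)
    rows[[length(rows) + 1L]] <<-
      cbind(data.frame(movement = movement, outcome = outcome,
                       unit = unit), st)
  }
  movements <- unique(summaries$movement)
  for (m in movements) {
    add_row(m, "ROM", "deg",
            pair_outcome(summaries, m, "rom_deg", ref_label, test_label))
    sub <- summaries[summaries$movement == m, ]
    if (any(is.finite(sub$pav_deg_s)))
      add_row(m, "PAV", "deg/s",
              pair_outcome(sub, m, "pav_deg_s", ref_label, test_label))
    if (any(is.finite(sub$mav_deg_s)))
      add_row(m, "MAV", "deg/s",
              pair_outcome(sub, m, "mav_deg_s", ref_label, test_label))
  }
  # total arcs: opposing single-plane pairs, and PNF start+end per channel
  arcs <- .trom_pairs[vapply(.trom_pairs, function(p)
    all(p %in% movements), logical(1))]
  for (ch in c("X", "Z", "Y")) {
    p <- paste0("PNF-", ch, c(" start", " end"))
    if (all(p %in% movements)) arcs[[paste0("PNF-", ch)]] <- p
  }
  for (label in names(arcs)) {
    tt <- trom_table(summaries, arcs[[label]])
    tt$movement <- label
    add_row(label, "TROM", "deg",
            pair_outcome(tt, label, "trom_deg", ref_label, test_label))
  }
  rep_ <- do.call(rbind, rows)
  rownames(rep_) <- NULL
  attr(rep_, "n_dropped") <- dropped
  rep_
}

#' Format an agreement report as an aligned text table
#'
#' One block per outcome, columns in the conventional method-comparison
#' order: per-system mean +/- SD, RMSE, ICC (with band), bias, upper; lower
#' limits of agreement.
#'
#' @param report data.frame from [build_report()].
#' @return Character vector of text lines.
#' @export
format_report_text <- function(report) {
  lines <- character(0)
  for (oc in unique(report$outcome)) {
    d <- report[report$outcome == oc, ]
    lines <- c(lines,
               sprintf("== %s [%s] ==", oc, d$unit[1]),
               sprintf("%-12s %16s %16s %7s %6s %-9s %7s %15s",
                       "Movement", "Reference", "Test", "RMSE", "ICC",
                       "band", "Bias", "Upper; lower LoA"))
    for (i in seq_len(nrow(d))) {
      r <- d[i, ]
      lines <- c(lines, sprintf(
        "%-12s %9.1f ± %4.1f %9.1f ± %4.1f %7.1f %6.3f %-9s %7.1f %7.1f; %6.1f",
        r$movement, r$ref_mean, r$ref_sd, r$test_mean, r$test_sd,
        r$rmse, r$icc, r$icc_band, r$bias, r$loa_upper, r$loa_lower))
    }
    lines <- c(lines, "")
  }
  lines
}
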