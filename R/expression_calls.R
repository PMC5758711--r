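#' Call EMT direction per probe
#'
#' A probe is `induced` if its stimulated-mock log2 value exceeds the
#' baseline-mock value by more than `threshold_log2`, `repressed` if it falls
#' short by more than the threshold, and `unchanged` otherwise. Inequalities
#' are strict: a difference of exactly the threshold is `unchanged`.
#'
#' @param table Expression data.frame with columns `probe_id`,
#'   `baseline_mock`, `stim_mock` (log2 scale).
#' @param threshold_log2 Differential-expression threshold in log2 units
#'   (default 0.5).
#' @return Character vector (`induced`/`repressed`/`unchanged`) named by
#'   probe id.
#' @export
#' @examples
#' tab <- data.frame(probe_id = "p1", baseline_mock = 5.0, stim_mock = 5.6)
#' call_emt_direction(tab) # induced
call_emt_direction <- function(table, threshold_log2 = 0.5) {
  check_columns(table, c("probe_id", "baseline_mock", "stim_mock"),
                "expression table")
  check_arm_values(table, c("baseline_mock", "stim_mock"))
  d <- table$stim_mock - table$baseline_mock
  out <- ifelse(d > threshold_log2, "induced",
         ifelse(d < -threshold_log2, "repressed", "unchanged"))
  stats::setNames(out, table$probe_id)
}

#' Call knockdown sensitivity (reversibility) per probe
#'
#' An induced probe is sensitive when the knockdown arm drops below the
#' stimulated mock arm by more than `threshold_log2`; a repressed probe is
#' sensitive when the knockdown arm rises by more than the threshold
#' (the change opposing the EMT direction). Unchanged probes are never
#' sensitive.
#'
#' @param table Expression data.frame with columns `probe_id`, `stim_mock`,
#'   `stim_sirna`.
#' @param directions Direction calls from [call_emt_direction()], aligned to
#'   `table`.
#' @param threshold_log2 Reversal threshold in log2 units (default 0.5, the
#'   same magnitude as the differential-expression threshold).
#' @return Logical vector named by probe id.
#' @export
call_lsd1_sensitivity <- function(table, directions, threshold_log2 = 0.5) {
  check_columns(table, c("probe_id", "stim_mock", "stim_sirna"),
                "expression table")
  check_arm_values(table, c("stim_mock", "stim_sirna"))
  if (length(directions) != nrow(table)) {
    stop_input("call_lsd1_sensitivity: directions must align with the table")
  }
  d <- table$stim_sirna - table$stim_mock
  out <- (directions == "induced" & d < -threshold_log2) |
    (directions == "repressed" & d > threshold_log2)
  stats::setNames(out, table$probe_id)
}

#' Call CSC/NCSC expression bias per probe
#'
#' A probe is labelled `csc` if its CSC-compartment log2 value exceeds the
#' NCSC value by more than `threshold_log2`, `ncsc` for the opposite, and
#' `none` otherwise.
#'
#' @param table Expression data.frame with columns `probe_id`, `csc_log2`,
#'   `ncsc_log2`.
#' @param threshold_log2 Bias threshold in log2 units (default 0.5).
#' @return Character vector (`csc`/`ncsc`/`none`) named by probe id.
#' @export
call_csc_bias <- function(table, threshold_log2 = 0.5) {
  check_columns(table, c("probe_id", "csc_log2", "ncsc_log2"),
                "expression table")
  check_arm_values(table, c("csc_log2", "ncsc_log2"))
  d <- table$csc_log2 - table$ncsc_log2
  out <- ifelse(d > threshold_log2, "csc",
         ifelse(d < -threshold_log2, "ncsc", "none"))
  stats::setNames(out, table$probe_id)
}

# Input error naming the first probe with a missing value in a required arm.
check_arm_values <- function(table, cols) {
  for (col in cols) {
    bad <- which(is.na(table[[col]]))
    if (length(bad) > 0L) {
      stop_input("expression table: missing ", col, " value for probe ",
                 table$probe_id[bad[1L]])
    }
  }
  invisible(table)
}

#' Combined probe-level sensitivity calls
#'
#' Convenience wrapper running direction, knockdown-sensitivity and (when the
#' compartment columns are present) CSC-bias calling, returning one tidy
#' table. Enforces the invariant that unchanged probes are never sensitive.
#'
#' @param table Expression data.frame (see the individual callers for
#'   required columns).
#' @param threshold_log2 Shared log2 threshold (default 0.5).
#' @return Data.frame with columns `probe_id`, `gene_id` (when present),
#'   `direction`, `sensitive` and `csc_bias`.
#' @export
sensitivity_calls <- function(table, threshold_log2 = 0.5) {
  direction <- call_emt_direction(table, threshold_log2)
  sensitive <- call_lsd1_sensitivity(table, direction, threshold_log2)
  csc <- if (all(c("csc_log2", "ncsc_log2") %in% names(table))) {
    call_csc_bias(table, threshold_log2)
  } else rep("none", nrow(table))
  out <- data.frame(probe_id = table$probe_id,
                    direction = unname(direction),
                    sensitive = unname(sensitive & direction != "unchanged"),
                    csc_bias = unname(csc),
                    stringsAsFactors = FALSE)
  if ("gene_id" %in% names(table)) {
    out <- cbind(out[1L], gene_id = table$gene_id, out[-1L])
  }
  out
}

#' Summarize reversibility per EMT direction
#'
#' For each direction (induced, repressed) counts the probes and the subset
#' reversible on knockdown and reports the percentage rounded half-up to one
#' decimal. A direction with no probes reports `NA` rather than 0.
#'
#' @param directions Direction calls (`induced`/`repressed`/`unchanged`).
#' @param sensitive Logical knockdown-sensitivity calls, aligned.
#' @return Data.frame with columns `direction`, `n_total`, `n_reversible`,
#'   `percent`.
#' @export
#' @examples
#' d <- rep(c("induced", "repressed"), c(3502, 3351))
#' s <- c(rep(c(TRUE, FALSE), c(1459, 3502 - 1459)),
#'        rep(c(TRUE, FALSE), c(790, 3351 - 790)))
#' summarize_reversibility(d, s) # 41.7% and 23.6%
summarize_reversibility <- function(directions, sensitive) {
  if (length(directions) != length(sensitive)) {
    stop_input("summarize_reversibility: call vectors must be aligned")
  }
  rows <- lapply(c("induced", "repressed"), function(dir) {
    n_total <- sum(directions == dir)
    n_rev <- sum(directions == dir & sensitive)
    pct <- if (n_total == 0L) NA_real_ else
      round_half_up(100 * n_rev / n_total, 1)
    data.frame(direction = dir, n_total = n_total, n_reversible = n_rev,
               percent = pct, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
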