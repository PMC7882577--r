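#' Recording quality-control gate
#'
#' A recording fails if any of the standard whole-cell rejection rules is
#' violated: more than 200 pA holding current to maintain the command
#' potential, series resistance above 30 MOhm (before or after the
#' recording), or a series-resistance change of more than 20% relative to
#' the pre-recording value. Every violated rule is reported.
#'
#' @param rec a [synq_recording()] with QC metadata, or `NULL` when the
#'   three values are given directly.
#' @param holding_current_pA,rs_before_mohm,rs_after_mohm override / direct
#'   QC values, pA and MOhm.
#' @param max_holding_pA,max_rs_mohm,max_rs_change thresholds (defaults
#'   200 pA, 30 MOhm, 0.20).
#' @return One-row tibble: `pass` (logical) and `reasons` (list-column of
#'   character).
#' @export
qc_pass <- function(rec = NULL, holding_current_pA = NULL,
                    rs_before_mohm = NULL, rs_after_mohm = NULL,
                    max_holding_pA = 200, max_rs_mohm = 30,
                    max_rs_change = 0.20) {
  if (!is.null(rec)) {
    stopifnot(inherits(rec, "synq_recording"))
    holding_current_pA <- holding_current_pA %||% rec$qc$holding_current_pA
    rs_before_mohm <- rs_before_mohm %||% rec$qc$rs_before_mohm
    rs_after_mohm <- rs_after_mohm %||% rec$qc$rs_after_mohm
  }
  vals <- list(holding_current_pA = holding_current_pA,
               rs_before_mohm = rs_before_mohm,
               rs_after_mohm = rs_after_mohm)
  missing <- names(vals)[vapply(vals, function(v) {
    is.null(v) || !is.finite(v)
  }, logical(1))]
  if (length(missing) > 0) {
    abort(paste("missing qc fields:", paste(missing, collapse = ", ")))
  }
  reasons <- character()
  if (abs(holding_current_pA) > max_holding_pA) {
    reasons <- c(reasons, sprintf("holding current %.0f pA exceeds %g pA",
                                  abs(holding_current_pA), max_holding_pA))
  }
  if (rs_before_mohm > max_rs_mohm || rs_after_mohm > max_rs_mohm) {
    reasons <- c(reasons, sprintf("series resistance above %g MOhm",
                                  max_rs_mohm))
  }
  if (abs(rs_after_mohm - rs_before_mohm) / rs_before_mohm > max_rs_change) {
    reasons <- c(reasons, sprintf("series resistance changed by more than %g%%",
                                  100 * max_rs_change))
  }
  tibble(pass = length(reasons) == 0L, reasons = list(reasons))
}
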