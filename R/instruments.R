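#' @include methods.R
NULL

#' Select instruments at a significance threshold
#'
#' Retains records whose exposure association p-value falls strictly below
#' `p_threshold` (genome-wide significance, 5e-8, by default), preserving
#' table order.  The operation is idempotent and monotone in the threshold.
#'
#' @param x a [SummaryStats-class] of exposure associations
#' @param p_threshold significance level in (0, 1); strict inequality
#' @return the filtered [SummaryStats-class]; an empty result triggers a
#'   warning because downstream MR needs at least one instrument
#' @examples
#' selectInstruments(periodontalInstruments())  # keeps all 47
#' @export
setMethod("selectInstruments", "SummaryStats", function(x, p_threshold = 5e-8) {
  stopifnot(is.numeric(p_threshold), length(p_threshold) == 1L,
            p_threshold > 0, p_threshold < 1)
  keep <- x@records$pvalue < p_threshold
  if (!any(keep) && nrow(x@records))
    warning("no instrument reaches p < ", format(p_threshold),
            "; downstream MR requires at least one instrument", call. = FALSE)
  x[keep]
})

#' Exclude instruments absent from or associated with the outcome
#'
#' Applies the outcome-side exclusion rule of the study design: an
#' instrument is dropped when its identifier is absent from the outcome
#' table, or when its outcome association is itself significant
#' (`pvalue < p_threshold`, strict), since such variants are suspect of
#' affecting the outcome through a pathway of their own.  Every drop is
#' recorded in the audit log with reason `"absent"` or
#' `"outcome_significant"`; absence takes precedence, so the reasons
#' partition the dropped set.
#'
#' @param x a [SummaryStats-class] of selected instruments
#' @param outcome a [SummaryStats-class] of outcome associations
#' @param p_threshold outcome-side significance level (default the same
#'   genome-wide 5e-8)
#' @return the surviving instruments as a [SummaryStats-class]; drops are
#'   reported by [auditLog()] with `action == "dropped"`
#' @export
setMethod("excludeOutcomeAssociated", "SummaryStats",
          function(x, outcome, p_threshold = 5e-8) {
  stopifnot(methods::is(outcome, "SummaryStats"),
            is.numeric(p_threshold), length(p_threshold) == 1L,
            p_threshold > 0, p_threshold < 1)
  ids <- x@records$snp_id
  idx <- match(ids, outcome@records$snp_id)
  absent <- is.na(idx)
  out_p <- rep(NA_real_, length(ids))
  out_p[!absent] <- outcome@records$pvalue[idx[!absent]]
  significant <- !absent & out_p < p_threshold
  reason <- ifelse(absent, "absent",
                   ifelse(significant, "outcome_significant", ""))
  dropped <- reason != ""
  audit <- rbind(x@audit,
                 if (any(dropped)) auditRow(ids[dropped], "dropped",
                                            reason[dropped])
                 else emptyAudit())
  SummaryStats(x@records[!dropped, , drop = FALSE], trait = x@trait,
               provenance = x@provenance, audit = audit)
})

#' Write an instrument drop report
#'
#' Emits the audit log of a filtered table as a tab-separated drop report
#' (`snp_id`, `reason`).
#'
#' @param x a [SummaryStats-class] whose audit log holds drop records
#' @param path destination file
#' @return `path`, invisibly
#' @export
writeDropReport <- function(x, path) {
  log <- auditLog(x)
  utils::write.table(log[, c("snp_id", "reason")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
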