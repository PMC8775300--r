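#' @include AllClasses.R
NULL

#' @describeIn SummaryStats-class the canonical records `data.frame`
#' @param x,object a `SummaryStats` object
#' @export
setMethod("summaryData", "SummaryStats", function(x) x@records)

#' @describeIn SummaryStats-class variant identifiers, in table order
#' @export
setMethod("snpIds", "SummaryStats", function(x) x@records$snp_id)

#' @describeIn SummaryStats-class trait label
#' @export
setMethod("trait", "SummaryStats", function(x) x@trait)

#' @describeIn SummaryStats-class audit log of rejected/dropped rows
#' @export
setMethod("auditLog", "SummaryStats", function(x) x@audit)

#' @describeIn SummaryStats-class number of records
#' @export
setMethod("length", "SummaryStats", function(x) nrow(x@records))

#' @describeIn SummaryStats-class subset records, keeping trait and provenance
#' @param i row index
#' @param j,drop ignored
#' @param ... ignored
#' @export
setMethod("[", "SummaryStats", function(x, i, j, ..., drop = FALSE) {
  SummaryStats(x@records[i, , drop = FALSE], trait = x@trait,
               provenance = x@provenance, audit = x@audit)
})

setMethod("show", "SummaryStats", function(object) {
  cat(sprintf("SummaryStats: %d variant(s)  trait: %s\n",
              nrow(object@records),
              if (is.na(object@trait)) "<unset>" else object@trait))
  if (!is.na(object@provenance))
    cat("  provenance:", object@provenance, "\n")
  if (nrow(object@records)) {
    show_n <- min(5L, nrow(object@records))
    print(utils::head(object@records[, MANDATORY_COLUMNS], show_n))
    if (nrow(object@records) > show_n)
      cat(sprintf("  ... and %d more\n", nrow(object@records) - show_n))
  }
  if (nrow(object@audit))
    cat(sprintf("  audit: %d logged row(s)\n", nrow(object@audit)))
})

#' @describeIn HarmonizedSet-class the pairs `data.frame`
#' @param x,object a `HarmonizedSet`
#' @export
setMethod("harmonizedPairs", "HarmonizedSet", function(x) x@pairs)

#' @describeIn HarmonizedSet-class audit log of harmonization decisions
#' @export
setMethod("auditLog", "HarmonizedSet", function(x) x@audit)

#' @describeIn HarmonizedSet-class variant identifiers of retained pairs
#' @export
setMethod("snpIds", "HarmonizedSet", function(x) x@pairs$snp_id)

#' @describeIn HarmonizedSet-class number of harmonized pairs
#' @export
setMethod("length", "HarmonizedSet", function(x) nrow(x@pairs))

#' @describeIn HarmonizedSet-class subset pairs
#' @param i row index
#' @param j,drop ignored
#' @param ... ignored
#' @export
setMethod("[", "HarmonizedSet", function(x, i, j, ..., drop = FALSE) {
  methods::initialize(x, pairs = x@pairs[i, , drop = FALSE])
})

setMethod("show", "HarmonizedSet", function(object) {
  cat(sprintf("HarmonizedSet: %d pair(s)  %s -> %s\n", nrow(object@pairs),
              object@exposure, object@outcome))
  if (nrow(object@pairs))
    cat(sprintf("  flipped: %d  palindromic: %d\n",
                sum(object@pairs$flipped), sum(object@pairs$palindromic)))
  drops <- object@audit[object@audit$action == "dropped", , drop = FALSE]
  if (nrow(drops))
    cat(sprintf("  dropped: %d (%s)\n", nrow(drops),
                paste(names(table(drops$reason)), table(drops$reason),
                      sep = ":", collapse = ", ")))
})

#' @describeIn MREstimate-class estimator name
#' @param x,object an `MREstimate`
#' @export
setMethod("mrMethod", "MREstimate", function(x) x@method)

#' @describeIn MREstimate-class pooled causal effect
#' @export
setMethod("estimate", "MREstimate", function(x) x@theta)

#' @describeIn MREstimate-class standard error of the pooled effect
#' @export
setMethod("stdError", "MREstimate", function(x) x@se)

#' @describeIn MREstimate-class 95\% confidence bounds, `c(low, high)`
#' @export
setMethod("confInt", "MREstimate",
          function(x) c(low = x@ci_low, high = x@ci_high))

#' @describeIn MREstimate-class two-sided p-value
#' @export
setMethod("pValue", "MREstimate", function(x) x@pvalue)

#' @describeIn MREstimate-class number of instruments used
#' @export
setMethod("nSNPs", "MREstimate", function(x) x@n_snps)

#' @describeIn MREstimate-class Egger intercept estimate with SE and p-value
#' @export
setMethod("eggerIntercept", "MREstimate", function(x)
  c(intercept = x@intercept, se = x@intercept_se, pvalue = x@intercept_p))

#' @describeIn MREstimate-class Cochran heterogeneity `c(Q, df, pvalue)`
#' @export
setMethod("heterogeneity", "MREstimate", function(x)
  c(Q = x@q_stat, df = x@q_df, pvalue = x@q_p))

setMethod("show", "MREstimate", function(object) {
  cat(sprintf("%s estimate (J = %d instruments)\n", object@method,
              object@n_snps))
  cat(sprintf("  theta = %.4g (SE %.4g), 95%% CI [%.4g, %.4g], p = %.3g\n",
              object@theta, object@se, object@ci_low, object@ci_high,
              object@pvalue))
  if (!is.na(object@intercept))
    cat(sprintf("  intercept = %.4g (SE %.4g), p = %.3g\n", object@intercept,
                object@intercept_se, object@intercept_p))
  if (!is.na(object@q_stat))
    cat(sprintf("  Cochran Q = %.4g on %g df, p = %.3g\n", object@q_stat,
                object@q_df, object@q_p))
})

#' Coerce an MREstimate to a one-row data.frame
#'
#' @param x an [MREstimate-class]
#' @param row.names,optional,... ignored
#' @return one-row `data.frame` with all estimate fields
#' @export
as.data.frame.MREstimate <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  data.frame(method = x@method, n_snps = x@n_snps, theta = x@theta,
             se = x@se, ci_low = x@ci_low, ci_high = x@ci_high,
             pvalue = x@pvalue, intercept = x@intercept,
             intercept_se = x@intercept_se, intercept_p = x@intercept_p,
             q_stat = x@q_stat, q_df = x@q_df, q_p = x@q_p,
             stringsAsFactors = FALSE)
}

setMethod("as.data.frame", "MREstimate", as.data.frame.MREstimate)

#' @describeIn MRResult-class named list of available [MREstimate-class]s
#' @param x,object an `MRResult`
#' @export
setMethod("estimates", "MRResult", function(x) x@estimates)

#' @describeIn MRResult-class named logical of Bonferroni verdicts
#' @export
setMethod("significance", "MRResult", function(x) x@significant)

#' @describeIn MRResult-class the familywise-corrected threshold
#' @export
setMethod("bonferroniAlpha", "MRResult", function(x) x@bonferroni_alpha)

#' @describeIn MRResult-class combined exclusion/harmonization drop log
#' @export
setMethod("auditLog", "MRResult", function(x) x@audit)

setMethod("show", "MRResult", function(object) {
  cat(sprintf("MRResult: %s -> %s\n", object@exposure, object@outcome))
  cat(sprintf("  instruments: %d selected, %d used; Bonferroni alpha = %.4g\n",
              object@n_instruments_initial, object@n_instruments_used,
              object@bonferroni_alpha))
  for (m in names(object@estimates)) {
    est <- object@estimates[[m]]
    cat(sprintf("  %-15s theta = %8.4g  p = %.3g%s\n", m, est@theta,
                est@pvalue,
                if (object@significant[[m]]) "  *significant*" else ""))
  }
  for (m in names(object@unavailable))
    cat(sprintf("  %-15s unavailable: %s\n", m, object@unavailable[[m]]))
})
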