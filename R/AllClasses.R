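#' @include AllGenerics.R
NULL

# Canonical column schema shared by readers, writers and the simulator.
CANONICAL_COLUMNS <- c("snp_id", "effect_allele", "other_allele",
                       "eaf", "beta", "se", "pvalue", "n")
MANDATORY_COLUMNS <- c("snp_id", "effect_allele", "beta", "se", "pvalue")

# Per-row contract checks for summary records.  Returns a character vector of
# reasons, one entry per offending row ("" for clean rows is never emitted;
# clean rows are simply absent from the result names).
recordProblems <- function(df) {
  reasons <- character(nrow(df))
  bad <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    reasons[cond & reasons == ""] <<- why
  }
  bad(is.na(df$snp_id) | df$snp_id == "", "missing snp_id")
  bad(is.na(df$effect_allele) | df$effect_allele == "", "missing effect_allele")
  bad(is.na(df$beta), "beta not a finite number")
  bad(!is.finite(df$beta), "beta not a finite number")
  bad(is.na(df$se), "se not a finite number")
  bad(!is.finite(df$se), "se not a finite number")
  bad(df$se <= 0, "se not strictly positive")
  bad(is.na(df$pvalue), "pvalue missing or not numeric")
  bad(df$pvalue <= 0 | df$pvalue > 1, "pvalue outside (0, 1]")
  bad(!is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1), "eaf outside [0, 1]")
  bad(!is.na(df$other_allele) &
        tolower(df$other_allele) == tolower(df$effect_allele),
      "effect_allele equals other_allele")
  reasons
}

coerceRecords <- function(df) {
  for (col in setdiff(CANONICAL_COLUMNS, colnames(df))) {
    df[[col]] <- rep(if (col %in% c("other_allele")) NA_character_
                     else NA_real_, nrow(df))
  }
  for (col in c("snp_id", "effect_allele", "other_allele"))
    df[[col]] <- as.character(df[[col]])
  for (col in c("eaf", "beta", "se", "pvalue", "n"))
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  extras <- setdiff(colnames(df), CANONICAL_COLUMNS)
  df <- df[, c(CANONICAL_COLUMNS, extras), drop = FALSE]
  rownames(df) <- NULL
  df
}

#' SummaryStats: a validated GWAS summary-statistic table
#'
#' One row per variant, holding the association of that variant with a single
#' trait: identifier, effect allele (the allele the `beta` refers to),
#' optional other allele, effect-allele frequency, effect size, its standard
#' error, two-sided p-value and sample size.  Indel alleles coded `"d"`/`"i"`
#' and chr:pos-style identifiers are stored verbatim.
#'
#' @slot records `data.frame` with canonical columns `snp_id`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`
#'   (extra columns are carried through untouched)
#' @slot trait trait label
#' @slot provenance free-text source tag
#' @slot audit per-row audit log (`snp_id`, `action`, `reason`) accumulated by
#'   readers and filters
#' @export
setClass("SummaryStats",
         representation(records = "data.frame", trait = "character",
                        provenance = "character", audit = "data.frame"),
         prototype(records = coerceRecords(
                     data.frame(snp_id = character(0),
                                effect_allele = character(0))),
                   trait = NA_character_, provenance = NA_character_,
                   audit = emptyAudit()))

setValidity("SummaryStats", function(object) {
  df <- object@records
  missing_cols <- setdiff(CANONICAL_COLUMNS, colnames(df))
  if (length(missing_cols))
    return(paste("records lacks columns:", paste(missing_cols, collapse = ", ")))
  problems <- recordProblems(df)
  if (any(problems != ""))
    return(paste0("invalid records: ",
                  paste(unique(problems[problems != ""]), collapse = "; ")))
  if (anyDuplicated(df$snp_id))
    return("snp_id values must be unique within a table")
  if (length(object@trait) != 1L || length(object@provenance) != 1L)
    return("trait and provenance must be single strings")
  TRUE
})

#' Construct a SummaryStats table
#'
#' @param records data.frame with at least `snp_id`, `effect_allele`, `beta`,
#'   `se`, `pvalue`; missing optional columns are filled with `NA`
#' @param trait trait label
#' @param provenance free-text source tag
#' @param audit optional audit log carried on the object
#' @return a validated [SummaryStats-class] object
#' @examples
#' SummaryStats(data.frame(snp_id = "rs1", effect_allele = "a",
#'                         beta = 0.02, se = 0.003, pvalue = 1e-10),
#'              trait = "example")
#' @export
SummaryStats <- function(records, trait = NA_character_,
                         provenance = NA_character_, audit = emptyAudit()) {
  obj <- methods::new("SummaryStats", records = coerceRecords(records),
                      trait = as.character(trait)[1L],
                      provenance = as.character(provenance)[1L],
                      audit = audit)
  methods::validObject(obj)
  obj
}

#' HarmonizedSet: exposure and outcome effects on a common effect allele
#'
#' The result of harmonizing an exposure table against an outcome table: one
#' row per retained variant with both effects expressed relative to the
#' exposure's effect allele, plus an audit log of kept/flipped/dropped
#' decisions.
#'
#' @slot pairs `data.frame` with columns `snp_id`, `effect_allele`,
#'   `beta_exposure`, `se_exposure`, `beta_outcome`, `se_outcome`,
#'   `eaf_exposure`, `eaf_outcome`, `flipped`, `palindromic`
#' @slot audit audit log (`snp_id`, `action`, `reason`)
#' @slot exposure,outcome trait labels
#' @export
setClass("HarmonizedSet",
         representation(pairs = "data.frame", audit = "data.frame",
                        exposure = "character", outcome = "character"))

PAIR_COLUMNS <- c("snp_id", "effect_allele", "beta_exposure", "se_exposure",
                  "beta_outcome", "se_outcome", "eaf_exposure", "eaf_outcome",
                  "flipped", "palindromic")

setValidity("HarmonizedSet", function(object) {
  df <- object@pairs
  missing_cols <- setdiff(PAIR_COLUMNS, colnames(df))
  if (length(missing_cols))
    return(paste("pairs lacks columns:", paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(df$snp_id)) return("duplicate snp_id in harmonized pairs")
  if (nrow(df)) {
    if (!all(is.finite(df$se_exposure)) || any(df$se_exposure <= 0))
      return("se_exposure must be finite and > 0")
    if (!all(is.finite(df$se_outcome)) || any(df$se_outcome <= 0))
      return("se_outcome must be finite and > 0")
    if (!all(is.finite(df$beta_exposure)) || !all(is.finite(df$beta_outcome)))
      return("betas must be finite")
  }
  TRUE
})

#' Construct a HarmonizedSet from aligned effect vectors
#'
#' Convenience constructor used by the harmonizer, the simulator and tests.
#' All vector arguments are recycled to a common length.
#'
#' @param snp_id variant identifiers (unique)
#' @param beta_exposure,se_exposure exposure-side effects and standard errors
#' @param beta_outcome,se_outcome outcome-side effects and standard errors
#' @param effect_allele common effect allele labels
#' @param eaf_exposure,eaf_outcome optional effect-allele frequencies
#' @param flipped logical, outcome sign was inverted during harmonization
#' @param palindromic logical, A/T or C/G allele pair
#' @param exposure,outcome trait labels
#' @param audit audit log carried on the object
#' @return a validated [HarmonizedSet-class]
#' @examples
#' h <- HarmonizedSet(snp_id = c("rs1", "rs2", "rs3"),
#'                    beta_exposure = c(0.1, 0.2, 0.3), se_exposure = 0.01,
#'                    beta_outcome = c(0.02, 0.04, 0.06), se_outcome = 0.01)
#' mrIVW(h)
#' @export
HarmonizedSet <- function(snp_id, beta_exposure, se_exposure,
                          beta_outcome, se_outcome,
                          effect_allele = NA_character_,
                          eaf_exposure = NA_real_, eaf_outcome = NA_real_,
                          flipped = FALSE, palindromic = FALSE,
                          exposure = "exposure", outcome = "outcome",
                          audit = emptyAudit()) {
  n <- length(snp_id)
  df <- data.frame(
    snp_id = as.character(snp_id),
    effect_allele = rep_len(as.character(effect_allele), n),
    beta_exposure = rep_len(as.numeric(beta_exposure), n),
    se_exposure = rep_len(as.numeric(se_exposure), n),
    beta_outcome = rep_len(as.numeric(beta_outcome), n),
    se_outcome = rep_len(as.numeric(se_outcome), n),
    eaf_exposure = rep_len(as.numeric(eaf_exposure), n),
    eaf_outcome = rep_len(as.numeric(eaf_outcome), n),
    flipped = rep_len(as.logical(flipped), n),
    palindromic = rep_len(as.logical(palindromic), n),
    stringsAsFactors = FALSE)
  obj <- methods::new("HarmonizedSet", pairs = df, audit = audit,
                      exposure = exposure, outcome = outcome)
  methods::validObject(obj)
  obj
}

#' MREstimate: one causal estimate from one MR method
#'
#' Pooled causal effect of the exposure on the outcome from one estimator,
#' with its standard error, 95\% confidence interval, p-value and diagnostics.
#' The Egger intercept slots are `NA` for the other methods; the heterogeneity
#' slots are `NA` when fewer than two instruments are available.
#'
#' @slot method `"IVW"`, `"MR-Egger"` or `"weighted-median"`
#' @slot theta pooled causal effect per unit of exposure liability
#' @slot se standard error of `theta`
#' @slot ci_low,ci_high 95\% confidence bounds
#' @slot pvalue two-sided p-value for `theta != 0`
#' @slot n_snps number of instruments used
#' @slot intercept,intercept_se,intercept_p MR-Egger intercept (average
#'   directional pleiotropy), its SE and p-value
#' @slot q_stat,q_df,q_p Cochran heterogeneity statistic, degrees of freedom
#'   and p-value
#' @export
setClass("MREstimate",
         representation(method = "character", theta = "numeric",
                        se = "numeric", ci_low = "numeric",
                        ci_high = "numeric", pvalue = "numeric",
                        n_snps = "integer", intercept = "numeric",
                        intercept_se = "numeric", intercept_p = "numeric",
                        q_stat = "numeric", q_df = "numeric", q_p = "numeric"),
         prototype(intercept = NA_real_, intercept_se = NA_real_,
                   intercept_p = NA_real_, q_stat = NA_real_, q_df = NA_real_,
                   q_p = NA_real_))

setValidity("MREstimate", function(object) {
  if (!object@method %in% c("IVW", "MR-Egger", "weighted-median"))
    return("unknown method")
  if (!is.finite(object@se) || object@se <= 0) return("se must be > 0")
  if (object@ci_low > object@theta || object@theta > object@ci_high)
    return("confidence interval must bracket theta")
  if (!is.finite(object@pvalue) || object@pvalue <= 0 || object@pvalue > 1)
    return("pvalue must lie in (0, 1]")
  min_snps <- if (object@method == "IVW") 1L else 3L
  if (object@n_snps < min_snps)
    return(sprintf("%s needs at least %d instruments", object@method, min_snps))
  TRUE
})

MREstimate <- function(method, theta, se, pvalue, n_snps,
                       ci_low = theta - 1.96 * se, ci_high = theta + 1.96 * se,
                       intercept = NA_real_, intercept_se = NA_real_,
                       intercept_p = NA_real_, q_stat = NA_real_,
                       q_df = NA_real_, q_p = NA_real_) {
  obj <- methods::new("MREstimate", method = method, theta = theta, se = se,
                      ci_low = ci_low, ci_high = ci_high, pvalue = pvalue,
                      n_snps = as.integer(n_snps), intercept = intercept,
                      intercept_se = intercept_se, intercept_p = intercept_p,
                      q_stat = q_stat, q_df = q_df, q_p = q_p)
  methods::validObject(obj)
  obj
}

#' MRResult: all estimators for one exposure-outcome pair
#'
#' @slot exposure,outcome trait labels
#' @slot n_instruments_initial instruments entering after exposure-side
#'   selection
#' @slot n_instruments_used harmonized instruments entering estimation
#' @slot estimates named list of [MREstimate-class] objects (methods that
#'   could be computed)
#' @slot unavailable named character vector of reasons for methods that could
#'   not be computed
#' @slot bonferroni_alpha familywise-corrected significance threshold
#' @slot significant named logical, `pvalue < bonferroni_alpha` per method
#' @slot audit combined drop log from instrument exclusion and harmonization
#' @export
setClass("MRResult",
         representation(exposure = "character", outcome = "character",
                        n_instruments_initial = "integer",
                        n_instruments_used = "integer", estimates = "list",
                        unavailable = "character",
                        bonferroni_alpha = "numeric", significant = "logical",
                        audit = "data.frame"))

setValidity("MRResult", function(object) {
  if (object@n_instruments_used > object@n_instruments_initial)
    return("n_instruments_used cannot exceed n_instruments_initial")
  if (!all(vapply(object@estimates, methods::is, logical(1L), "MREstimate")))
    return("estimates must all be MREstimate objects")
  for (m in names(object@estimates)) {
    est <- object@estimates[[m]]
    want <- est@pvalue < object@bonferroni_alpha
    if (!identical(unname(object@significant[m]), want))
      return("significant flags must equal pvalue < bonferroni_alpha")
  }
  TRUE
})
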