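#' @include instruments.R
NULL

ALLELE_COMPLEMENT <- c(a = "t", t = "a", c = "g", g = "c")

isACGT <- function(a) !is.na(a) & a %in% names(ALLELE_COMPLEMENT)

complementAllele <- function(a) unname(ALLELE_COMPLEMENT[a])

#' Harmonization policy
#'
#' Settings controlling how allele orientation conflicts are resolved.
#'
#' Palindromic variants (A/T or C/G pairs) carry no strand information in
#' their allele labels.  Under `palindromic = "freq"` they are aligned by
#' frequency concordance when both effect-allele frequencies are available
#' and both minor-allele frequencies fall below `freq_threshold` (frequencies
#' close to 0.5 cannot distinguish the strands); otherwise the variant is
#' dropped.  `palindromic = "drop"` drops every palindromic variant
#' unconditionally.
#'
#' @param palindromic `"freq"` (default) or `"drop"`
#' @param freq_threshold minor-allele-frequency bound below which frequency
#'   alignment is considered unambiguous (default 0.42)
#' @return a named list used by [harmonizePair()] and [harmonizeTables()]
#' @export
harmonizationPolicy <- function(palindromic = c("freq", "drop"),
                                freq_threshold = 0.42) {
  stopifnot(is.numeric(freq_threshold), length(freq_threshold) == 1L,
            freq_threshold > 0, freq_threshold <= 0.5)
  list(palindromic = match.arg(palindromic), freq_threshold = freq_threshold)
}

# Frequencies are ambiguous when either is missing or too close to 0.5 to
# tell the two strand interpretations apart.
freqUnambiguous <- function(eaf_e, eaf_o, threshold) {
  !is.na(eaf_e) && !is.na(eaf_o) &&
    min(eaf_e, 1 - eaf_e) < threshold && min(eaf_o, 1 - eaf_o) < threshold
}

freqConcordant <- function(eaf_e, eaf_o) (eaf_e < 0.5) == (eaf_o < 0.5)

#' Harmonize one exposure/outcome record pair
#'
#' Expresses the outcome association on the exposure's effect allele.  A
#' matching outcome effect allele keeps the pair as-is; the opposite allele
#' (directly, via the stated other allele, or via the strand complement for
#' single-base alleles) negates the outcome effect and complements its
#' frequency.  When the exposure side publishes only its effect allele
#' (effect-allele-only mode, the situation of the bundled periodontal
#' instruments) a differing, non-complementary outcome allele is treated as
#' the opposite allele and sign-flipped; a strand-complementary allele is a
#' palindromic suspect and is resolved by frequency or dropped.  Indel codes
#' (`"d"`/`"i"`) and other non-ACGT alleles are compared by literal string
#' equality only and never strand-complemented.
#'
#' @param exposure,outcome one-row slices of [summaryData()] (or equivalent
#'   named lists) sharing the same `snp_id`
#' @param policy a [harmonizationPolicy()]
#' @return a list: either `list(pair = <one-row data.frame>)` with the
#'   harmonized fields, or `list(drop = TRUE, reason = <why>)`
#' @export
harmonizePair <- function(exposure, outcome, policy = harmonizationPolicy()) {
  if (!identical(as.character(exposure$snp_id), as.character(outcome$snp_id)))
    stop("harmonizePair requires records sharing snp_id", call. = FALSE)

  e_ea <- tolower(exposure$effect_allele)
  e_oa <- if (is.null(exposure$other_allele) || is.na(exposure$other_allele))
    NA_character_ else tolower(exposure$other_allele)
  o_ea <- tolower(outcome$effect_allele)
  o_oa <- if (is.null(outcome$other_allele) || is.na(outcome$other_allele))
    NA_character_ else tolower(outcome$other_allele)
  eaf_e <- if (is.null(exposure$eaf)) NA_real_ else exposure$eaf
  eaf_o <- if (is.null(outcome$eaf)) NA_real_ else outcome$eaf

  drop <- function(reason) list(drop = TRUE, reason = reason)

  # Palindromic status, where an allele pair is known on either side.
  pal <- NA
  if (!is.na(e_oa)) {
    pal <- isACGT(e_ea) && isACGT(e_oa) && complementAllele(e_ea) == e_oa
  } else if (!is.na(o_oa)) {
    pal <- isACGT(o_ea) && isACGT(o_oa) && complementAllele(o_ea) == o_oa
  }

  orientation <- NULL
  if (!is.na(e_oa) && !is.na(o_oa)) {
    all_acgt <- all(isACGT(c(e_ea, e_oa, o_ea, o_oa)))
    if (o_ea == e_ea && o_oa == e_oa) orientation <- "same"
    else if (o_ea == e_oa && o_oa == e_ea) orientation <- "flip"
    else if (all_acgt && complementAllele(o_ea) == e_ea &&
             complementAllele(o_oa) == e_oa) orientation <- "same"
    else if (all_acgt && complementAllele(o_ea) == e_oa &&
             complementAllele(o_oa) == e_ea) orientation <- "flip"
    else return(drop("allele_mismatch"))
  } else if (!is.na(e_oa)) {
    if (o_ea == e_ea) orientation <- "same"
    else if (o_ea == e_oa) orientation <- "flip"
    else if (isACGT(o_ea) && complementAllele(o_ea) == e_ea)
      orientation <- "same"
    else if (isACGT(o_ea) && !is.na(e_oa) && isACGT(e_oa) &&
             complementAllele(o_ea) == e_oa) orientation <- "flip"
    else return(drop("allele_mismatch"))
  } else if (!is.na(o_oa)) {
    if (o_ea == e_ea) orientation <- "same"
    else if (o_oa == e_ea) orientation <- "flip"
    else if (isACGT(o_ea) && complementAllele(o_ea) == e_ea)
      orientation <- "same"
    else if (isACGT(o_oa) && complementAllele(o_oa) == e_ea)
      orientation <- "flip"
    else return(drop("allele_mismatch"))
  } else {
    # Effect-allele-only mode on both sides.
    if (o_ea == e_ea) orientation <- "same"
    else if (isACGT(e_ea) && isACGT(o_ea) &&
             complementAllele(o_ea) == e_ea) {
      # Strand complement of the exposure allele: either the same allele on
      # the opposite strand, or the opposite allele of a palindromic
      # variant.  Frequency is the only arbiter.
      pal <- NA  # undecidable from labels
      if (freqUnambiguous(eaf_e, eaf_o, policy$freq_threshold))
        orientation <- if (freqConcordant(eaf_e, eaf_o)) "same" else "flip"
      else return(drop("ambiguous"))
    } else orientation <- "flip"
  }

  if (isTRUE(pal)) {
    if (policy$palindromic == "drop") return(drop("palindromic"))
    if (!freqUnambiguous(eaf_e, eaf_o, policy$freq_threshold))
      return(drop("palindromic"))
    # Frequency overrides allele labels: labels cannot see the strand.
    orientation <- if (freqConcordant(eaf_e, eaf_o)) "same" else "flip"
  }

  flipped <- orientation == "flip"
  list(pair = data.frame(
    snp_id = as.character(exposure$snp_id),
    effect_allele = as.character(exposure$effect_allele),
    beta_exposure = exposure$beta,
    se_exposure = exposure$se,
    beta_outcome = if (flipped) -outcome$beta else outcome$beta,
    se_outcome = outcome$se,
    eaf_exposure = eaf_e,
    eaf_outcome = if (flipped) 1 - eaf_o else eaf_o,
    flipped = flipped,
    palindromic = isTRUE(pal),
    stringsAsFactors = FALSE))
}

#' Harmonize an exposure table against an outcome table
#'
#' Applies [harmonizePair()] to every variant present in both tables
#' (exposure order preserved) and collects the retained pairs into a
#' [HarmonizedSet-class].  The audit log records one row per shared variant:
#' `kept`, `flipped` (kept with the outcome sign inverted) or `dropped` with
#' a reason.  Standard errors and exposure-side effects are never altered.
#'
#' @param exposure,outcome [SummaryStats-class] tables
#' @param policy a [harmonizationPolicy()]
#' @return a [HarmonizedSet-class]
#' @examples
#' sim <- simulateTwoSample(simConfig(n_snps = 10, seed = 7))
#' h <- harmonizeTables(sim$exposure, sim$outcome)
#' length(h)
#' @export
setMethod("harmonizeTables", signature(exposure = "SummaryStats",
                                       outcome = "SummaryStats"),
          function(exposure, outcome, policy = harmonizationPolicy()) {
  shared <- intersect(exposure@records$snp_id, outcome@records$snp_id)
  e_rows <- exposure@records[match(shared, exposure@records$snp_id), ,
                             drop = FALSE]
  o_rows <- outcome@records[match(shared, outcome@records$snp_id), ,
                            drop = FALSE]
  pairs <- vector("list", length(shared))
  audit <- vector("list", length(shared))
  for (k in seq_along(shared)) {
    res <- harmonizePair(e_rows[k, ], o_rows[k, ], policy)
    if (isTRUE(res$drop)) {
      audit[[k]] <- auditRow(shared[k], "dropped", res$reason)
    } else {
      pairs[[k]] <- res$pair
      audit[[k]] <- auditRow(shared[k],
                             if (res$pair$flipped) "flipped" else "kept")
    }
  }
  kept <- !vapply(pairs, is.null, logical(1L))
  df <- if (any(kept)) do.call(rbind, pairs[kept]) else
    HarmonizedSet(character(0), numeric(0), numeric(0), numeric(0),
                  numeric(0))@pairs
  obj <- methods::new("HarmonizedSet", pairs = df,
                      audit = do.call(rbind, c(audit, list(emptyAudit()))),
                      exposure = if (is.na(exposure@trait)) "exposure"
                                 else exposure@trait,
                      outcome = if (is.na(outcome@trait)) "outcome"
                                else outcome@trait)
  methods::validObject(obj)
  obj
})

#' Write a harmonized set as a tab-separated file
#'
#' @param x a [HarmonizedSet-class]
#' @param path destination file
#' @return `path`, invisibly
#' @export
writeHarmonized <- function(x, path) {
  stopifnot(methods::is(x, "HarmonizedSet"))
  df <- x@pairs
  out <- df
  for (col in colnames(df))
    out[[col]] <- if (is.numeric(df[[col]])) formatRoundTrip(df[[col]])
                  else as.character(df[[col]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
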