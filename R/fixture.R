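#' @include summary-io.R
NULL

#' The 47 periodontal-disease instrument variants
#'
#' Loads the bundled exposure-side instrument set: 47 independent variants
#' associated with dental caries and periodontitis at genome-wide
#' significance in the largest liability GWAS to date (GLIDE consortium plus
#' UK Biobank, n = 487,823).  Each record carries the effect allele, its
#' frequency, the per-allele effect on the liability scale, its standard
#' error and the association p-value; the nearest gene is carried as an
#' extra column.  Indel alleles are coded `"d"`/`"i"` and one variant is
#' identified by a chr:pos token rather than an rsID; both are stored
#' verbatim.
#'
#' Only the effect allele is published for these variants, so downstream
#' harmonization runs in effect-allele-only mode (see [harmonizeTables()]).
#'
#' @return a [SummaryStats-class] with 47 records, trait
#'   `"dental caries and periodontitis"`
#' @examples
#' instruments <- periodontalInstruments()
#' length(instruments)
#' summaryData(instruments)[1, ]
#' @export
periodontalInstruments <- function() {
  path <- system.file("extdata", "periodontal_instruments.tsv",
                      package = "perioMR", mustWork = TRUE)
  readSummaryStats(path, trait = "dental caries and periodontitis",
                   provenance = "GLIDE consortium + UK Biobank (n = 487,823)")
}
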