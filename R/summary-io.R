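#' @include AllClasses.R
NULL

#' Read a GWAS summary-statistic table
#'
#' Reads a tab-separated summary-statistic file into a [SummaryStats-class]
#' object.  The canonical dialect is one header row, UTF-8, tab separator and
#' `NA` as the missing token; `column_map` translates arbitrary source
#' headers onto the canonical fields.  Rows violating the record contract
#' (non-positive standard error, p-value outside `(0, 1]`, unparseable
#' numbers, duplicated identifiers, ...) are rejected row by row and logged
#' with a reason in the audit log, never aborting the whole read.
#'
#' @param path file to read
#' @param column_map named character vector mapping canonical field names to
#'   the file's headers, e.g. `c(snp_id = "SNP", beta = "b")`; canonical
#'   names already present in the file need not be listed
#' @param trait trait label for the table (default: unset)
#' @param provenance free-text source tag (default: the path)
#' @return a [SummaryStats-class]; rejected rows are reported in
#'   [auditLog()] with `action == "rejected"`
#' @seealso [writeSummaryStats()], [periodontalInstruments()]
#' @export
readSummaryStats <- function(path, column_map = NULL, trait = NA_character_,
                             provenance = path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", na.strings = "NA",
                           check.names = FALSE, quote = "",
                           comment.char = "", fileEncoding = "UTF-8")
  if (!is.null(column_map)) {
    if (is.null(names(column_map)) || any(names(column_map) == ""))
      stop("column_map must be a fully named character vector", call. = FALSE)
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% colnames(raw))
        stop("column_map refers to absent header: ", src, call. = FALSE)
      colnames(raw)[colnames(raw) == src] <- canon
    }
  }
  missing_cols <- setdiff(MANDATORY_COLUMNS, colnames(raw))
  if (length(missing_cols))
    stop("mandatory column(s) not resolvable: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  df <- coerceRecords(raw)
  reasons <- recordProblems(df)
  dup <- duplicated(df$snp_id) & reasons == ""
  reasons[dup] <- "duplicate snp_id"
  keep <- reasons == ""
  audit <- emptyAudit()
  if (any(!keep)) {
    audit <- auditRow(ifelse(is.na(df$snp_id[!keep]), "<missing>",
                             df$snp_id[!keep]),
                      "rejected", reasons[!keep])
  }
  SummaryStats(df[keep, , drop = FALSE], trait = trait,
               provenance = provenance, audit = audit)
}

#' Write a GWAS summary-statistic table
#'
#' Writes the canonical tab-separated dialect (header row, `NA` missing
#' token).  Numeric fields are rendered with the shortest decimal form that
#' reparses to the identical double, so a write/read cycle is the identity on
#' valid tables.
#'
#' @param x a [SummaryStats-class]
#' @param path destination file
#' @return `path`, invisibly
#' @export
writeSummaryStats <- function(x, path) {
  stopifnot(methods::is(x, "SummaryStats"))
  df <- x@records
  out <- df
  for (col in colnames(df)) {
    out[[col]] <- if (is.numeric(df[[col]])) formatRoundTrip(df[[col]])
                  else ifelse(is.na(df[[col]]), "NA", as.character(df[[col]]))
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(colnames(out), collapse = "\t"), con)
  if (nrow(out))
    writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
  invisible(path)
}

#' Flip the reported allele orientation of selected records
#'
#' Re-expresses records on the opposite allele: effect and other allele are
#' swapped, the effect size is negated and the effect-allele frequency
#' becomes its complement.  The association itself is unchanged; this is the
#' transformation harmonization must undo, and it is useful for constructing
#' orientation-robustness checks.
#'
#' @param x a [SummaryStats-class]
#' @param snps identifiers to flip (default: all records)
#' @return a [SummaryStats-class] with the selected records re-oriented
#' @export
flipOrientation <- function(x, snps = snpIds(x)) {
  stopifnot(methods::is(x, "SummaryStats"))
  df <- x@records
  i <- df$snp_id %in% snps
  old_ea <- df$effect_allele[i]
  if (any(is.na(df$other_allele[i])))
    stop("cannot flip records lacking other_allele", call. = FALSE)
  df$effect_allele[i] <- df$other_allele[i]
  df$other_allele[i] <- old_ea
  df$beta[i] <- -df$beta[i]
  df$eaf[i] <- 1 - df$eaf[i]
  SummaryStats(df, trait = x@trait, provenance = x@provenance,
               audit = x@audit)
}
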