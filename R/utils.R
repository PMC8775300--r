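# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed, restoring the caller's state
#'
#' @param seed single integer-like seed
#' @param code expression to evaluate
#' @return value of `code`
#' @keywords internal
#' @noRd
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed %% (.Machine$integer.max - 1L)))
  force(code)
}

# Shortest decimal representation that survives a write/read round trip.
formatRoundTrip <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    for (d in 15:17) {
      s <- formatC(v, digits = d, format = "g")
      if (as.numeric(s) == v) return(s)
    }
    s
  }, character(1L))
}

# Two-sided normal p-value, floored away from exactly zero so the (0, 1]
# contract on p-values survives extreme z scores.
pNormTwoSided <- function(z) {
  pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
}

pTTwoSided <- function(t, df) {
  pmax(2 * stats::pt(-abs(t), df = df), .Machine$double.xmin)
}

emptyAudit <- function() {
  data.frame(snp_id = character(0), action = character(0),
             reason = character(0), stringsAsFactors = FALSE)
}

auditRow <- function(snp_id, action, reason = "") {
  data.frame(snp_id = snp_id, action = action, reason = reason,
             stringsAsFactors = FALSE)
}

isSingleString <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
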