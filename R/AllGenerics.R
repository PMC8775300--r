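#' @include utils.R
NULL

#' Accessor generics
#'
#' Small accessor generics used across the package's S4 classes.
#'
#' @param x an object of a perioMR class
#' @param ... passed to methods
#' @return The slot content documented on each method page.
#' @name perioMR-accessors
#' @keywords internal
NULL

#' @rdname perioMR-accessors
#' @export
setGeneric("summaryData", function(x) standardGeneric("summaryData"))

#' @rdname perioMR-accessors
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))

#' @rdname perioMR-accessors
#' @export
setGeneric("trait", function(x) standardGeneric("trait"))

#' @rdname perioMR-accessors
#' @export
setGeneric("auditLog", function(x) standardGeneric("auditLog"))

#' @rdname perioMR-accessors
#' @export
setGeneric("harmonizedPairs", function(x) standardGeneric("harmonizedPairs"))

#' @rdname perioMR-accessors
#' @export
setGeneric("mrMethod", function(x) standardGeneric("mrMethod"))

#' @rdname perioMR-accessors
#' @export
setGeneric("estimate", function(x) standardGeneric("estimate"))

#' @rdname perioMR-accessors
#' @export
setGeneric("stdError", function(x) standardGeneric("stdError"))

#' @rdname perioMR-accessors
#' @export
setGeneric("confInt", function(x) standardGeneric("confInt"))

#' @rdname perioMR-accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname perioMR-accessors
#' @export
setGeneric("nSNPs", function(x) standardGeneric("nSNPs"))

#' @rdname perioMR-accessors
#' @export
setGeneric("eggerIntercept", function(x) standardGeneric("eggerIntercept"))

#' @rdname perioMR-accessors
#' @export
setGeneric("heterogeneity", function(x) standardGeneric("heterogeneity"))

#' @rdname perioMR-accessors
#' @export
setGeneric("estimates", function(x) standardGeneric("estimates"))

#' @rdname perioMR-accessors
#' @export
setGeneric("significance", function(x) standardGeneric("significance"))

#' @rdname perioMR-accessors
#' @export
setGeneric("bonferroniAlpha", function(x) standardGeneric("bonferroniAlpha"))

#' @rdname selectInstruments
#' @export
setGeneric("selectInstruments",
           function(x, p_threshold = 5e-8) standardGeneric("selectInstruments"))

#' @rdname excludeOutcomeAssociated
#' @export
setGeneric("excludeOutcomeAssociated",
           function(x, outcome, p_threshold = 5e-8)
             standardGeneric("excludeOutcomeAssociated"))

#' @rdname harmonizeTables
#' @export
setGeneric("harmonizeTables",
           function(exposure, outcome, policy = harmonizationPolicy())
             standardGeneric("harmonizeTables"))

#' @rdname waldRatio
#' @export
setGeneric("waldRatio", function(x) standardGeneric("waldRatio"))

#' @rdname mrIVW
#' @export
setGeneric("mrIVW",
           function(x, mode = c("random", "fixed")) standardGeneric("mrIVW"))

#' @rdname mrEgger
#' @export
setGeneric("mrEgger", function(x) standardGeneric("mrEgger"))

#' @rdname mrWeightedMedian
#' @export
setGeneric("mrWeightedMedian",
           function(x, n_boot = 1000L, seed) standardGeneric("mrWeightedMedian"))

#' @rdname cochranQ
#' @export
setGeneric("cochranQ", function(x, theta) standardGeneric("cochranQ"))
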