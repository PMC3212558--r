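#' Accessors for mirSeedShift result objects
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @return \code{typeFractions}: named numeric over the six strand-collapsed
#'   substitution types; \code{classFractions}: named numeric over
#'   S2W/W2S/S2S/W2W; \code{spectrumCounts}: the raw named counts;
#'   \code{pctGC}/\code{pctAT}: percentages of Strong/Weak alleles;
#'   \code{alleleCounts}: c(gc, at); \code{geneAggregate}: named integer
#'   per-gene aggregate of a \code{BindingTable}; \code{siteCounts}: the
#'   genes x miRNAs count matrix; \code{population}: the population label.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("typeFractions", function(x) standardGeneric("typeFractions"))

#' @rdname accessors
#' @export
setGeneric("classFractions", function(x) standardGeneric("classFractions"))

#' @rdname accessors
#' @export
setGeneric("spectrumCounts", function(x) standardGeneric("spectrumCounts"))

#' @rdname accessors
#' @export
setGeneric("pctGC", function(x) standardGeneric("pctGC"))

#' @rdname accessors
#' @export
setGeneric("pctAT", function(x) standardGeneric("pctAT"))

#' @rdname accessors
#' @export
setGeneric("alleleCounts", function(x) standardGeneric("alleleCounts"))

#' @rdname accessors
#' @export
setGeneric("geneAggregate", function(x) standardGeneric("geneAggregate"))

#' @rdname accessors
#' @export
setGeneric("siteCounts", function(x) standardGeneric("siteCounts"))

#' @rdname accessors
#' @export
setGeneric("population", function(x) standardGeneric("population"))

#' @rdname accessors
#' @export
setMethod("typeFractions", "MutationSpectrum", function(x)
    x@counts / sum(x@counts))

#' @rdname accessors
#' @export
setMethod("classFractions", "MutationSpectrum", function(x) {
    fr <- typeFractions(x)
    c(S2W = unname(fr[["C>T|G>A"]] + fr[["C>A|G>T"]]),
      W2S = unname(fr[["T>C|A>G"]] + fr[["T>G|A>C"]]),
      S2S = unname(fr[["C>G|G>C"]]),
      W2W = unname(fr[["T>A|A>T"]]))
})

#' @rdname accessors
#' @export
setMethod("spectrumCounts", "MutationSpectrum", function(x) x@counts)

#' @rdname accessors
#' @export
setMethod("pctGC", "GcComposition", function(x)
    100 * x@gcAlleles / (x@gcAlleles + x@atAlleles))

#' @rdname accessors
#' @export
setMethod("pctAT", "GcComposition", function(x)
    100 * x@atAlleles / (x@gcAlleles + x@atAlleles))

#' @rdname accessors
#' @export
setMethod("alleleCounts", "GcComposition", function(x)
    c(gc = x@gcAlleles, at = x@atAlleles))

#' @rdname accessors
#' @export
setMethod("population", "GcComposition", function(x) x@population)

#' @rdname accessors
#' @export
setMethod("population", "SnpCallSet", function(x) x@population)

#' @rdname accessors
#' @export
setMethod("geneAggregate", "BindingTable", function(x) {
    if (x@counting == "distinct_mirnas") {
        setNames(as.integer(rowSums(x@counts > 0)), rownames(x@counts))
    } else {
        setNames(as.integer(rowSums(x@counts)), rownames(x@counts))
    }
})

#' @rdname accessors
#' @export
setMethod("siteCounts", "BindingTable", function(x) x@counts)

#' @describeIn SnpCallSet-class The underlying calls data.frame.
#' @param x a \code{SnpCallSet}.
#' @export
snpCalls <- function(x) {
    stopifnot(is(x, "SnpCallSet"))
    x@calls
}
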