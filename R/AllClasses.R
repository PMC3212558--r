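#' @import methods
#' @importFrom stats rbinom rpois runif setNames t.test binom.test chisq.test
#'   fisher.test wilcox.test
NULL

.DNA_BASES <- c("A", "C", "G", "T")
.RNA_BASES <- c("A", "C", "G", "U")
.STRONG <- c("C", "G")

#' Hydrogen-bond weights for seed:target base pairs
#'
#' Holds the per-pair hydrogen-bond counts used by the seed scanner. Defaults
#' reflect base-pair chemistry: a Watson-Crick G:C pair has three hydrogen
#' bonds, an A:U(T) pair two, and a G:U wobble pair two. Mismatches always
#' contribute zero. The equal-weight ablation (\code{\link{equalWeights}})
#' sets the G:C weight to two so Strong and Weak pairs are thermodynamically
#' indistinguishable.
#'
#' @slot wcGC integer, hydrogen bonds for a Watson-Crick G:C pair.
#' @slot wcAU integer, hydrogen bonds for a Watson-Crick A:U (A:T) pair.
#' @slot wobble integer, hydrogen bonds for a G:U wobble pair.
#' @export
setClass("SeedWeights", representation(
    wcGC = "integer", wcAU = "integer", wobble = "integer"))

setValidity("SeedWeights", function(object) {
    w <- c(object@wcGC, object@wcAU, object@wobble)
    if (length(w) != 3L || anyNA(w)) return("all three weights must be single integers")
    if (any(w < 0L)) return("weights must be >= 0")
    TRUE
})

#' @describeIn SeedWeights-class Constructor.
#' @param wcGC,wcAU,wobble hydrogen-bond counts (non-negative integers).
#' @return A \code{SeedWeights} object.
#' @examples
#' SeedWeights()          # chemistry defaults: G:C = 3, A:U = 2, wobble = 2
#' equalWeights()         # ablation: G:C counted like A:U
#' @export
SeedWeights <- function(wcGC = 3L, wcAU = 2L, wobble = 2L) {
    new("SeedWeights", wcGC = as.integer(wcGC), wcAU = as.integer(wcAU),
        wobble = as.integer(wobble))
}

#' @describeIn SeedWeights-class Ablation weights with G:C pairs counted like
#'   A:U pairs (removes the Strong/Weak thermodynamic asymmetry).
#' @export
equalWeights <- function() SeedWeights(wcGC = 2L, wcAU = 2L, wobble = 2L)

setMethod("show", "SeedWeights", function(object) {
    cat(sprintf("SeedWeights: G:C=%d  A:U=%d  G:U wobble=%d  mismatch=0\n",
                object@wcGC, object@wcAU, object@wobble))
})

.COLLAPSED_TYPES <- c("C>T|G>A", "C>A|G>T", "C>G|G>C",
                      "T>C|A>G", "T>A|A>T", "T>G|A>C")
.SW_CLASSES <- c("S2W", "W2S", "S2S", "W2W")

#' Strand-collapsed somatic substitution spectrum
#'
#' Counts over the six strand-collapsed single-nucleotide substitution types
#' (a substitution and its reverse complement form one class, e.g. C>T with
#' G>A) together with the derived Strong/Weak transition-class fractions.
#' Strong bases are G and C (three hydrogen bonds per Watson-Crick pair),
#' Weak bases A and T (two).
#'
#' @slot counts named integer vector over the six collapsed types.
#' @seealso \code{\link{mutationSpectrum}}, \code{\link{classifySubstitution}}
#' @export
setClass("MutationSpectrum", representation(counts = "integer"))

setValidity("MutationSpectrum", function(object) {
    if (!identical(names(object@counts), .COLLAPSED_TYPES))
        return("counts must be named by the six strand-collapsed types")
    if (anyNA(object@counts) || any(object@counts < 0L))
        return("counts must be non-negative")
    if (sum(object@counts) == 0L) return("spectrum must contain at least one mutation")
    TRUE
})

setMethod("show", "MutationSpectrum", function(object) {
    fr <- typeFractions(object)
    cat("MutationSpectrum of", sum(object@counts), "mutations\n")
    for (k in .COLLAPSED_TYPES)
        cat(sprintf("  %-8s %6d  (%.1f%%)\n", k, object@counts[[k]], 100 * fr[[k]]))
    cf <- classFractions(object)
    cat(sprintf("  S2W %.1f%%  W2S %.1f%%  S2S %.1f%%  W2W %.1f%%\n",
                100 * cf[["S2W"]], 100 * cf[["W2S"]], 100 * cf[["S2S"]],
                100 * cf[["W2W"]]))
})

#' Per-individual SNP genotype calls for one population
#'
#' One row per (site, individual) genotype call: chromosome, 1-based
#' position, sample id, the two called alleles and the read depth (DP)
#' supporting the call. This mirrors per-sample genotype tables such as the
#' 1000 Genomes pilot genotype files.
#'
#' @slot population character label for the population.
#' @slot calls data.frame with columns chrom, pos, sample, a1, a2, dp.
#' @export
setClass("SnpCallSet", representation(population = "character", calls = "data.frame"))

setValidity("SnpCallSet", function(object) {
    req <- c("chrom", "pos", "sample", "a1", "a2", "dp")
    if (!all(req %in% names(object@calls)))
        return(paste("calls must have columns:", paste(req, collapse = ", ")))
    cl <- object@calls
    if (nrow(cl) == 0L) return("call set is empty")
    if (any(cl$dp < 0L)) return("DP must be >= 0")
    if (any(cl$pos < 1L)) return("positions are 1-based (>= 1)")
    if (!all(cl$a1 %in% .DNA_BASES) || !all(cl$a2 %in% .DNA_BASES))
        return("alleles must be A/C/G/T")
    TRUE
})

#' @describeIn SnpCallSet-class Constructor from a calls data.frame.
#' @param population population label.
#' @param calls data.frame with columns chrom, pos, sample, a1, a2, dp.
#' @return A \code{SnpCallSet}.
#' @export
SnpCallSet <- function(population, calls) {
    calls$pos <- as.integer(calls$pos)
    calls$dp <- as.integer(calls$dp)
    for (col in c("chrom", "sample", "a1", "a2"))
        calls[[col]] <- as.character(calls[[col]])
    new("SnpCallSet", population = population,
        calls = calls[c("chrom", "pos", "sample", "a1", "a2", "dp")])
}

setMethod("show", "SnpCallSet", function(object) {
    cl <- object@calls
    cat(sprintf("SnpCallSet '%s': %d calls at %d sites, %d individuals\n",
                object@population, nrow(cl),
                length(unique(paste(cl$chrom, cl$pos))),
                length(unique(cl$sample))))
})

#' GC/AT composition of alleles called at SNP sites
#'
#' Result of tallying Strong (G/C) versus Weak (A/T) alleles over the calls
#' of one population that pass a minimum-depth filter and an optional region
#' restriction. \code{nSnps} counts sites with at least one passing call,
#' \code{nCalls} the passing (site x individual) calls.
#'
#' @slot population character label.
#' @slot dpMin integer, the minimum DP applied.
#' @slot nSnps,nCalls integer tallies.
#' @slot gcAlleles,atAlleles integer allele tallies.
#' @seealso \code{\link{gcComposition}}, \code{\link{comparePopulations}}
#' @export
setClass("GcComposition", representation(
    population = "character", dpMin = "integer",
    nSnps = "integer", nCalls = "integer",
    gcAlleles = "numeric", atAlleles = "numeric"))

setValidity("GcComposition", function(object) {
    if (object@gcAlleles + object@atAlleles <= 0)
        return("no alleles tallied")
    if (object@nCalls < object@nSnps) return("nCalls cannot be below nSnps")
    TRUE
})

setMethod("show", "GcComposition", function(object) {
    cat(sprintf(
        "GcComposition '%s' (DP >= %d): %d SNPs, %d calls, %%GC %.2f  %%AT %.2f\n",
        object@population, object@dpMin, object@nSnps, object@nCalls,
        pctGC(object), pctAT(object)))
})

#' Per-gene, per-miRNA binding-site counts at one threshold
#'
#' Matrix of admissible seed-match site counts (genes x miRNAs) at a given
#' hydrogen-bond threshold, with the scan settings recorded. The per-gene
#' aggregate is either the number of distinct miRNAs with at least one site
#' (\code{"distinct_mirnas"}) or the summed site count (\code{"total_sites"}).
#'
#' @slot counts integer matrix, rows = genes, columns = miRNAs.
#' @slot threshold integer hydrogen-bond threshold.
#' @slot mode "strict" (all 7 seed positions paired) or "lenient".
#' @slot counting aggregate rule.
#' @slot weights the \code{SeedWeights} used.
#' @seealso \code{\link{countBinding}}, \code{\link{geneAggregate}}
#' @export
setClass("BindingTable", representation(
    counts = "matrix", threshold = "integer", mode = "character",
    counting = "character", weights = "SeedWeights"))

setValidity("BindingTable", function(object) {
    if (any(object@counts < 0)) return("site counts must be >= 0")
    if (is.null(rownames(object@counts)) || is.null(colnames(object@counts)))
        return("counts must carry gene and miRNA names")
    if (!object@mode %in% c("strict", "lenient")) return("bad mode")
    if (!object@counting %in% c("distinct_mirnas", "total_sites"))
        return("bad counting rule")
    TRUE
})

setMethod("show", "BindingTable", function(object) {
    cat(sprintf(
        "BindingTable: %d genes x %d miRNAs at threshold %d (%s, %s)\n",
        nrow(object@counts), ncol(object@counts), object@threshold,
        object@mode, object@counting))
    agg <- geneAggregate(object)
    cat(sprintf("  genes with >= 1 bound miRNA: %d; total sites: %d\n",
                sum(rowSums(object@counts) > 0), sum(object@counts)))
})
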