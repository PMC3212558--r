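## Somatic point mutations in UTR space, their Strong/Weak classification,
## spectrum summaries, application to sequences, and randomization nulls.
##
## A mutation set is a data.frame with columns geneId, offset (0-based into
## the gene's 3'UTR), ref and alt (A/C/G/T, alt != ref). The canonical
## representation is UTR-space on the mRNA sense strand.

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Validate a mutation table against a UTR set
#'
#' Checks column presence, base alphabet, alt != ref, offsets in range,
#' known gene ids and reference-base agreement with the UTR sequences.
#'
#' @param muts data.frame with columns geneId, offset (0-based), ref, alt.
#' @param utrs named \code{DNAStringSet}; when supplied, every mutation's
#'   ref must match the UTR base at its offset.
#' @return The validated data.frame (offsets as integer), invisibly usable
#'   downstream. Errors name the offending gene and offset.
#' @export
validateMutations <- function(muts, utrs = NULL) {
    req <- c("geneId", "offset", "ref", "alt")
    if (!all(req %in% names(muts)))
        stop("mutation table needs columns: ", paste(req, collapse = ", "))
    muts$geneId <- as.character(muts$geneId)
    muts$offset <- as.integer(muts$offset)
    muts$ref <- toupper(as.character(muts$ref))
    muts$alt <- toupper(as.character(muts$alt))
    if (nrow(muts) == 0L) return(muts[req])
    bad <- !(muts$ref %in% .DNA_BASES) | !(muts$alt %in% .DNA_BASES)
    if (any(bad)) stop("invalid base in mutation row(s) ",
                       paste(which(bad), collapse = ", "))
    if (any(muts$ref == muts$alt))
        stop("alt must differ from ref (row ",
             which(muts$ref == muts$alt)[1], ")")
    if (any(muts$offset < 0L)) stop("offsets are 0-based and must be >= 0")
    if (!is.null(utrs)) {
        unknown <- setdiff(muts$geneId, names(utrs))
        if (length(unknown))
            stop("mutation(s) for unknown gene(s): ",
                 paste(unknown, collapse = ", "))
        w <- setNames(Biostrings::width(utrs), names(utrs))
        oob <- muts$offset >= w[muts$geneId]
        if (any(oob))
            stop(sprintf("offset %d out of range for gene %s",
                         muts$offset[which(oob)[1]],
                         muts$geneId[which(oob)[1]]))
        seqs <- as.character(utrs)
        obs <- substr(seqs[muts$geneId], muts$offset + 1L, muts$offset + 1L)
        mism <- obs != muts$ref
        if (any(mism)) {
            k <- which(mism)[1]
            stop(sprintf(
                "ref mismatch for gene %s at offset %d: table says %s, UTR has %s",
                muts$geneId[k], muts$offset[k], muts$ref[k], obs[k]))
        }
    }
    muts[req]
}

#' Classify substitutions in the Strong/Weak scheme
#'
#' Strong bases (G, C) form three hydrogen bonds in a Watson-Crick pair,
#' Weak bases (A, T) two; the class of a substitution is determined solely
#' by the Strong/Weak membership of its ref and alt. The canonical
#' UV-signature substitution C>T is Strong-to-Weak (S2W).
#'
#' @param ref,alt character vectors of single bases (A/C/G/T), elementwise
#'   \code{alt != ref}.
#' @return Factor with levels S2W, W2S, S2S, W2W.
#' @examples
#' classifySubstitution(c("C", "A", "G"), c("T", "G", "C"))
#' @export
classifySubstitution <- function(ref, alt) {
    ref <- toupper(ref); alt <- toupper(alt)
    if (!all(ref %in% .DNA_BASES) || !all(alt %in% .DNA_BASES))
        stop("bases must be A/C/G/T")
    if (any(ref == alt)) stop("alt must differ from ref")
    rs <- ref %in% .STRONG
    as <- alt %in% .STRONG
    cls <- ifelse(rs & !as, "S2W",
           ifelse(!rs & as, "W2S",
           ifelse(rs & as, "S2S", "W2W")))
    factor(cls, levels = .SW_CLASSES)
}

#' Strand-collapsed substitution type of each mutation
#'
#' A substitution and its reverse complement are one class (C>T counted
#' with G>A, etc.), giving the six standard types.
#'
#' @inheritParams classifySubstitution
#' @return Factor with the six collapsed-type levels.
#' @export
collapsedType <- function(ref, alt) {
    ref <- toupper(ref); alt <- toupper(alt)
    flip <- ref %in% c("G", "A")
    r <- ifelse(flip, .COMPLEMENT[ref], ref)
    a <- ifelse(flip, .COMPLEMENT[alt], alt)
    factor(paste0(r, ">", a, "|", .COMPLEMENT[r], ">", .COMPLEMENT[a]),
           levels = .COLLAPSED_TYPES)
}

#' Summarize a mutation set as a strand-collapsed spectrum
#'
#' @param muts mutation data.frame (see \code{\link{validateMutations}}).
#' @return A \code{\link{MutationSpectrum-class}} object; fractions via
#'   \code{\link{typeFractions}} and \code{\link{classFractions}}.
#' @examples
#' m <- data.frame(geneId = "g", offset = 0:3,
#'                 ref = c("C", "C", "G", "T"),
#'                 alt = c("T", "T", "A", "C"))
#' classFractions(mutationSpectrum(m))
#' @export
mutationSpectrum <- function(muts) {
    muts <- validateMutations(muts)
    if (nrow(muts) == 0L) stop("cannot summarize an empty mutation set")
    tt <- table(collapsedType(muts$ref, muts$alt))
    new("MutationSpectrum",
        counts = setNames(as.integer(tt[.COLLAPSED_TYPES]), .COLLAPSED_TYPES))
}

#' Apply point mutations to UTR sequences
#'
#' Returns a copy of the UTR set with each mutated offset replaced by its
#' alt base. Offsets must be unique within a gene (multi-hit genes carry
#' several rows, applied jointly); a ref that disagrees with the sequence
#' is a hard error naming the gene and offset.
#'
#' @param utrs named \code{DNAStringSet}.
#' @param muts mutation data.frame.
#' @return A \code{DNAStringSet} of the same genes in the same order.
#' @examples
#' u <- Biostrings::DNAStringSet(c(g = "ACGT"))
#' applyMutations(u, data.frame(geneId = "g", offset = 1, ref = "C", alt = "T"))
#' @export
applyMutations <- function(utrs, muts) {
    utrs <- .asGeneSet(utrs)
    muts <- validateMutations(muts, utrs)
    if (nrow(muts) == 0L) return(utrs)
    if (anyDuplicated(muts[c("geneId", "offset")]))
        stop("duplicate (gene, offset) in mutation set")
    seqs <- as.character(utrs)
    for (g in unique(muts$geneId)) {
        mg <- muts[muts$geneId == g, ]
        s <- seqs[[g]]
        for (k in seq_len(nrow(mg)))
            substr(s, mg$offset[k] + 1L, mg$offset[k] + 1L) <- mg$alt[k]
        seqs[[g]] <- s
    }
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- names(utrs)
    out
}

#' Generate randomized in-silico mutation sets
#'
#' Builds null mutation sets matched to an observed set, within the same
#' genes' UTRs:
#' \describe{
#'   \item{random_any}{for each observed mutation, a uniform random
#'     position in the same gene's UTR and a uniform alt among the three
#'     non-ref bases there — both position and type randomized.}
#'   \item{same_type}{keeps each (ref, alt) pair and relocates it to a
#'     uniform position of that UTR carrying the ref base, so the
#'     substitution spectrum is preserved exactly.}
#'   \item{same_position}{keeps each position and redraws the alt
#'     uniformly from the three non-ref bases.}
#' }
#' Positions are drawn without replacement within a gene so the result can
#' be applied jointly; if a draw pool is exhausted the original position is
#' kept and a warning is counted.
#'
#' @param utrs named \code{DNAStringSet}.
#' @param muts observed mutation data.frame.
#' @param mode one of \code{"random_any"}, \code{"same_type"},
#'   \code{"same_position"}.
#' @param seed integer RNG seed (mandatory; same seed, same output).
#' @return A mutation data.frame of the same size as \code{muts}.
#' @export
randomizeMutations <- function(utrs, muts,
                               mode = c("random_any", "same_type",
                                        "same_position"),
                               seed) {
    mode <- match.arg(mode)
    if (missing(seed)) stop("an RNG seed is mandatory")
    utrs <- .asGeneSet(utrs)
    muts <- validateMutations(muts, utrs)
    seqs <- as.character(utrs)
    withr::with_seed(seed, {
        out <- muts
        if (mode == "same_position") {
            for (k in seq_len(nrow(out))) {
                alts <- setdiff(.DNA_BASES, out$ref[k])
                out$alt[k] <- sample(alts, 1L)
            }
            return(out)
        }
        nKept <- 0L
        used <- split(muts$offset, muts$geneId)  # reserve originals? no: fresh pools
        used <- lapply(used, function(x) integer(0))
        for (k in seq_len(nrow(out))) {
            g <- out$geneId[k]
            chars <- strsplit(seqs[[g]], "")[[1]]
            if (mode == "same_type") {
                pool <- which(chars == out$ref[k]) - 1L
            } else {
                pool <- seq_along(chars) - 1L
            }
            pool <- setdiff(pool, used[[g]])
            if (length(pool) == 0L) {
                nKept <- nKept + 1L
                pos <- out$offset[k]
            } else {
                pos <- pool[sample.int(length(pool), 1L)]
            }
            used[[g]] <- c(used[[g]], pos)
            out$offset[k] <- pos
            out$ref[k] <- chars[pos + 1L]
            if (mode == "same_type") {
                out$ref[k] <- muts$ref[k]   # pool guarantees agreement
                out$alt[k] <- muts$alt[k]
            } else {
                out$alt[k] <- sample(setdiff(.DNA_BASES, out$ref[k]), 1L)
            }
        }
        if (nKept > 0L)
            warning(nKept, " mutation(s) kept their original position ",
                    "(no free eligible site in the UTR)")
        out
    })
}
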