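## Seedable generators for every input the analysis consumes: 3'UTR sets
## with controlled GC content, miRNA sets with GC-enriched (G-skewed)
## seeds, mutation sets drawn from parameterized substitution spectra, and
## two-population diploid genotype tables with per-call read depths.

.PRESETS <- list(
    ## UV signature: C>T/G>A dominated; 64.5% C>T|G>A, S2W 75%, W2S 13.9%
    melanoma_uv = c("C>T|G>A" = 0.645, "C>A|G>T" = 0.105, "C>G|G>C" = 0.055,
                    "T>C|A>G" = 0.100, "T>A|A>T" = 0.056, "T>G|A>C" = 0.039),
    ## non-UV cancers (lung/AML-like): S2W 47.5%, W2S 32%
    balanced = c("C>T|G>A" = 0.240, "C>A|G>T" = 0.235, "C>G|G>C" = 0.105,
                 "T>C|A>G" = 0.160, "T>A|A>T" = 0.100, "T>G|A>C" = 0.160))

#' Substitution-spectrum presets
#'
#' Probability vectors over the six strand-collapsed substitution types.
#' \code{"melanoma_uv"} emulates a UV-damage spectrum (64.5\% C>T/G>A;
#' Strong-to-Weak 75\%, Weak-to-Strong 13.9\%); \code{"balanced"} emulates
#' a non-UV cancer spectrum (Strong-to-Weak 47.5\%, Weak-to-Strong 32\%).
#'
#' @param name preset name, or a named numeric vector over the six
#'   collapsed types (normalized to sum to one).
#' @return Named probability vector over the six collapsed types.
#' @examples
#' spectrumPreset("melanoma_uv")
#' @export
spectrumPreset <- function(name = c("melanoma_uv", "balanced")) {
    if (is.numeric(name)) {
        if (!identical(sort(names(name)), sort(.COLLAPSED_TYPES)))
            stop("custom preset must name all six collapsed types")
        p <- name[.COLLAPSED_TYPES]
        if (any(p < 0) || sum(p) <= 0) stop("invalid probabilities")
        return(p / sum(p))
    }
    .PRESETS[[match.arg(name)]]
}

.sampleBases <- function(n, gc, gRatio = 1) {
    ## gRatio = P(G)/P(C) among Strong draws; A and T(U) equally likely
    pG <- gc * gRatio / (1 + gRatio)
    pC <- gc / (1 + gRatio)
    sample(.DNA_BASES, n, replace = TRUE,
           prob = c((1 - gc) / 2, pC, pG, (1 - gc) / 2))
}

#' Generate a synthetic 3'UTR set
#'
#' Bases are drawn i.i.d. with P(G) = P(C) = utrGC/2 and
#' P(A) = P(T) = (1 - utrGC)/2. The default GC fraction 0.424 matches the
#' composition typical of human 3'UTRs.
#'
#' @param nGenes number of genes.
#' @param utrLength UTR length in nt (scalar or per-gene vector).
#' @param utrGC target GC fraction in [0, 1].
#' @param seed integer RNG seed (mandatory).
#' @return Named \code{DNAStringSet} (\code{gene001}, ...).
#' @export
genUtrs <- function(nGenes = 200L, utrLength = 1000L, utrGC = 0.424, seed) {
    stopifnot(nGenes >= 1L, utrGC >= 0, utrGC <= 1)
    if (missing(seed)) stop("an RNG seed is mandatory")
    len <- rep_len(as.integer(utrLength), nGenes)
    withr::with_seed(seed, {
        seqs <- vapply(len, function(l)
            paste(.sampleBases(l, utrGC), collapse = ""), character(1))
    })
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- sprintf("gene%03d", seq_len(nGenes))
    out
}

#' Generate a synthetic mature miRNA set
#'
#' Seed positions (nt 2-8) are drawn with GC fraction \code{seedGC} and a
#' G:C ratio of \code{gRatio} (seeds of real miRNAs are GC-enriched with
#' an excess of G over C of about 20\%); the remaining positions use
#' \code{bodyGC} with the same skew. Defaults put the seed GC at 0.509 and
#' the whole-molecule GC near 0.493.
#'
#' @param nMirnas number of miRNAs.
#' @param length mature length in nt (default 22).
#' @param seedGC GC fraction of seed positions.
#' @param bodyGC GC fraction of non-seed positions.
#' @param gRatio G:C ratio among Strong draws (default 1.2).
#' @param seed integer RNG seed (mandatory).
#' @return Named \code{RNAStringSet} (\code{mir001}, ...).
#' @export
genMirnas <- function(nMirnas = 100L, length = 22L, seedGC = 0.509,
                      bodyGC = 0.486, gRatio = 1.2, seed) {
    stopifnot(nMirnas >= 1L, length >= 8L)
    if (missing(seed)) stop("an RNG seed is mandatory")
    withr::with_seed(seed, {
        seqs <- vapply(seq_len(nMirnas), function(i) {
            b <- .sampleBases(length, bodyGC, gRatio)
            b[2:8] <- .sampleBases(7L, seedGC, gRatio)
            paste(b, collapse = "")
        }, character(1))
    })
    out <- Biostrings::RNAStringSet(chartr("T", "U", seqs))
    names(out) <- sprintf("mir%03d", seq_len(nMirnas))
    out
}

#' Draw somatic point mutations from a substitution spectrum
#'
#' For each mutation a strand-collapsed type is drawn from the preset and
#' then a uniform position among all UTR positions carrying either strand
#' representative of that type (e.g. a C>T|G>A draw lands on a C, becoming
#' T, or on a G, becoming A). Positions are unique within a gene.
#'
#' @param utrs named \code{DNAStringSet}.
#' @param n number of mutations.
#' @param preset a preset name or probability vector, see
#'   \code{\link{spectrumPreset}}.
#' @param seed integer RNG seed (mandatory).
#' @return Mutation data.frame (geneId, offset, ref, alt).
#' @export
genMutations <- function(utrs, n = 300L, preset = "melanoma_uv", seed) {
    utrs <- .asGeneSet(utrs)
    if (missing(seed)) stop("an RNG seed is mandatory")
    p <- spectrumPreset(preset)
    chars <- strsplit(as.character(utrs), "")
    ## flat index of every position, by base
    geneOf <- rep(names(utrs), Biostrings::width(utrs))
    offOf <- unlist(lapply(Biostrings::width(utrs), seq_len)) - 1L
    baseOf <- unlist(chars, use.names = FALSE)
    byBase <- split(seq_along(baseOf), baseOf)
    ## ref base alternatives per collapsed type: pyrimidine rep and its
    ## purine complement, with the matching alt
    typeRefAlt <- list(
        "C>T|G>A" = rbind(c("C", "T"), c("G", "A")),
        "C>A|G>T" = rbind(c("C", "A"), c("G", "T")),
        "C>G|G>C" = rbind(c("C", "G"), c("G", "C")),
        "T>C|A>G" = rbind(c("T", "C"), c("A", "G")),
        "T>A|A>T" = rbind(c("T", "A"), c("A", "T")),
        "T>G|A>C" = rbind(c("T", "G"), c("A", "C")))
    withr::with_seed(seed, {
        types <- sample(.COLLAPSED_TYPES, n, replace = TRUE, prob = p)
        usedFlat <- logical(length(baseOf))
        rows <- vector("list", n)
        for (k in seq_len(n)) {
            ra <- typeRefAlt[[types[k]]]
            pool <- c(byBase[[ra[1, 1]]], byBase[[ra[2, 1]]])
            pool <- pool[!usedFlat[pool]]
            if (length(pool) == 0L)
                stop("eligible positions exhausted for type ", types[k],
                     "; use longer or more UTRs")
            i <- pool[sample.int(length(pool), 1L)]
            usedFlat[i] <- TRUE
            alt <- if (baseOf[i] == ra[1, 1]) ra[1, 2] else ra[2, 2]
            rows[[k]] <- data.frame(geneId = geneOf[i], offset = offOf[i],
                                    ref = baseOf[i], alt = alt)
        }
    })
    do.call(rbind, rows)
}

#' Generate a diploid genotype call set for one population
#'
#' Each site gets one fixed Strong allele (G or C, equally likely) and one
#' fixed Weak allele (A or T); each individual's two alleles are i.i.d.
#' Strong with probability \code{sAlleleFreq}. Per-call read depth is
#' Poisson(\code{dpLambda}) (default 6, so depth cutoffs around 5-11 bite).
#'
#' @param population population label.
#' @param nIndividuals,nSites cohort dimensions.
#' @param sAlleleFreq probability that a called allele is the Strong one.
#' @param dpLambda mean of the Poisson read-depth distribution.
#' @param chrom chromosome label for all sites.
#' @param positions optional integer vector of site positions (1-based);
#'   default 1..nSites scaled by 100.
#' @param seed integer RNG seed (mandatory).
#' @return A \code{\link{SnpCallSet-class}}.
#' @export
genGenotypes <- function(population, nIndividuals = 100L, nSites = 2000L,
                         sAlleleFreq = 0.55, dpLambda = 6, chrom = "chr1",
                         positions = NULL, seed) {
    stopifnot(nIndividuals >= 1L, nSites >= 1L,
              sAlleleFreq >= 0, sAlleleFreq <= 1)
    if (missing(seed)) stop("an RNG seed is mandatory")
    if (is.null(positions)) positions <- seq_len(nSites) * 100L
    stopifnot(length(positions) == nSites)
    withr::with_seed(seed, {
        strong <- sample(.STRONG, nSites, replace = TRUE)
        weak <- sample(c("A", "T"), nSites, replace = TRUE)
        nCalls <- nSites * nIndividuals
        site <- rep(seq_len(nSites), each = nIndividuals)
        a1 <- ifelse(rbinom(nCalls, 1L, sAlleleFreq) == 1L,
                     strong[site], weak[site])
        a2 <- ifelse(rbinom(nCalls, 1L, sAlleleFreq) == 1L,
                     strong[site], weak[site])
        dp <- rpois(nCalls, dpLambda)
    })
    SnpCallSet(population, data.frame(
        chrom = chrom, pos = positions[site],
        sample = sprintf("%s_ind%03d", population,
                         rep(seq_len(nIndividuals), times = nSites)),
        a1 = a1, a2 = a2, dp = dp))
}

#' Generate miRNA target intervals with a focal-subset id list
#'
#' Random non-degenerate intervals on one chromosome, each annotated with
#' a miRNA id, plus a focal (e.g. melanoma-expressed) subset of the ids.
#' Used to exercise the target-partition analysis of SNP calls.
#'
#' @param nIntervals number of intervals.
#' @param mirnaIds pool of miRNA ids to annotate intervals with.
#' @param focalFraction fraction of \code{mirnaIds} put on the focal list.
#' @param chrom chromosome label.
#' @param span genomic span to place intervals in.
#' @param width interval width.
#' @param seed integer RNG seed (mandatory).
#' @return list: \code{targets} (a \code{GRanges} with \code{mirnaId}) and
#'   \code{focalIds} (character).
#' @export
genTargetIntervals <- function(nIntervals = 200L, mirnaIds,
                               focalFraction = 0.3, chrom = "chr1",
                               span = 200000L, width = 25L, seed) {
    stopifnot(length(mirnaIds) >= 1L, nIntervals >= 1L)
    if (missing(seed)) stop("an RNG seed is mandatory")
    withr::with_seed(seed, {
        starts <- sample.int(span - width, nIntervals, replace = TRUE)
        ids <- sample(mirnaIds, nIntervals, replace = TRUE)
        nFocal <- max(1L, round(focalFraction * length(mirnaIds)))
        focal <- sample(mirnaIds, nFocal)
    })
    gr <- GenomicRanges::GRanges(chrom,
                                 IRanges::IRanges(starts, width = width))
    gr$mirnaId <- ids
    list(targets = gr, focalIds = focal)
}

#' Write a complete synthetic study to disk
#'
#' Emits every input the end-to-end analysis consumes: UTR and miRNA
#' FASTA, a mutation TSV, two population genotype TSVs, a target-interval
#' BED and the focal miRNA id list. All files are plain text and the run
#' is reproducible from the seed.
#'
#' @param dir output directory (created if needed).
#' @param seed integer RNG seed (mandatory; derived sub-seeds are used per
#'   generator).
#' @param nGenes,utrLength,utrGC,nMirnas,seedGC,nMutations,preset
#'   generator settings, see the individual generators.
#' @param popFreqs named numeric of length two: Strong-allele frequency
#'   per population.
#' @param nIndividuals,nSites genotype cohort dimensions.
#' @return Named character vector of the file paths written, invisibly.
#' @export
simulateStudy <- function(dir, seed, nGenes = 200L, utrLength = 1000L,
                          utrGC = 0.424, nMirnas = 100L, seedGC = 0.509,
                          nMutations = 300L, preset = "melanoma_uv",
                          popFreqs = c(YRIlike = 0.57, CEUlike = 0.55),
                          nIndividuals = 30L, nSites = 500L) {
    if (missing(seed)) stop("an RNG seed is mandatory")
    stopifnot(length(popFreqs) == 2L, !is.null(names(popFreqs)))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utrs <- genUtrs(nGenes, utrLength, utrGC, seed = seed)
    mirnas <- genMirnas(nMirnas, seedGC = seedGC, seed = seed + 1L)
    muts <- genMutations(utrs, nMutations, preset, seed = seed + 2L)
    pops <- lapply(seq_along(popFreqs), function(i)
        genGenotypes(names(popFreqs)[i], nIndividuals, nSites,
                     sAlleleFreq = popFreqs[[i]], seed = seed + 2L + i))
    tg <- genTargetIntervals(mirnaIds = names(mirnas),
                             span = as.integer(nSites) * 100L + 1000L,
                             seed = seed + 5L)
    paths <- c(utrs = file.path(dir, "utrs.fa"),
               mirnas = file.path(dir, "mirnas.fa"),
               muts = file.path(dir, "muts.tsv"),
               pop1 = file.path(dir, "pop1.tsv"),
               pop2 = file.path(dir, "pop2.tsv"),
               targets = file.path(dir, "targets.bed"),
               focalIds = file.path(dir, "focal_mirna_ids.txt"))
    Biostrings::writeXStringSet(utrs, paths[["utrs"]])
    Biostrings::writeXStringSet(mirnas, paths[["mirnas"]])
    writeMutations(muts, paths[["muts"]])
    writeGenotypesTsv(pops[[1]], paths[["pop1"]])
    writeGenotypesTsv(pops[[2]], paths[["pop2"]])
    writeTargetBed(tg$targets, paths[["targets"]])
    writeLines(tg$focalIds, paths[["focalIds"]])
    invisible(paths)
}
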