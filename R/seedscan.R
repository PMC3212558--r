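## Hydrogen-bond seed-match scanner.
##
## A mature miRNA recognises a target through its seed (nucleotides 2-8).
## The scanner slides the 7-nt seed along every 7-nt window of a 3'UTR in
## antiparallel orientation and sums the hydrogen bonds of the base pairs
## formed: Watson-Crick G:C = 3, A:U(T) = 2, G:U wobble = 2, mismatch = 0
## (all configurable through SeedWeights). A window is an admissible site
## when its hydrogen-bond sum reaches the threshold (lenient mode), or
## additionally has all seven positions paired (strict mode).

.DNA_LUT <- local({
    l <- rep(NA_integer_, 127L)
    l[utf8ToInt("A")] <- 1L; l[utf8ToInt("C")] <- 2L
    l[utf8ToInt("G")] <- 3L; l[utf8ToInt("T")] <- 4L
    l
})
.RNA_LUT <- local({
    l <- rep(NA_integer_, 127L)
    l[utf8ToInt("A")] <- 1L; l[utf8ToInt("C")] <- 2L
    l[utf8ToInt("G")] <- 3L; l[utf8ToInt("U")] <- 4L
    l
})

.encodeDNA <- function(s) {
    v <- .DNA_LUT[utf8ToInt(as.character(s))]
    if (anyNA(v)) stop("sequence contains characters outside {A,C,G,T}")
    v
}

.encodeRNA <- function(s) {
    v <- .RNA_LUT[utf8ToInt(as.character(s))]
    if (anyNA(v)) stop("sequence contains characters outside {A,C,G,U}")
    v
}

## rows: miRNA base (A,C,G,U); columns: UTR DNA base (A,C,G,T)
.scoreMatrix <- function(weights) {
    SM <- matrix(0, 4L, 4L, dimnames = list(.RNA_BASES, .DNA_BASES))
    SM["G", "C"] <- weights@wcGC
    SM["C", "G"] <- weights@wcGC
    SM["A", "T"] <- weights@wcAU
    SM["U", "A"] <- weights@wcAU
    SM["G", "T"] <- weights@wobble  # rG . dT wobble
    SM["U", "G"] <- weights@wobble
    SM
}

## legal-pair indicator is fixed chemistry, independent of the weights
.PAIR_MATRIX <- local({
    PM <- matrix(0L, 4L, 4L, dimnames = list(.RNA_BASES, .DNA_BASES))
    PM["G", "C"] <- 1L; PM["C", "G"] <- 1L
    PM["A", "T"] <- 1L; PM["U", "A"] <- 1L
    PM["G", "T"] <- 1L; PM["U", "G"] <- 1L
    PM
})

## Scores every 7-nt window of utrCodes against one seed. Antiparallel
## pairing: seed position i (5'->3') pairs window position 8-i, i.e. UTR
## index o+7-i for the window starting at o (1-based).
.windowScores <- function(seedCodes, utrCodes, SM) {
    n <- length(utrCodes)
    nw <- n - 6L
    sc <- numeric(nw)
    np <- numeric(nw)
    for (i in 1:7) {
        idx <- utrCodes[(8L - i):(n + 1L - i)]
        sc <- sc + unname(SM[seedCodes[i], ])[idx]
        np <- np + unname(.PAIR_MATRIX[seedCodes[i], ])[idx]
    }
    list(score = sc, npaired = np)
}

#' Extract the seed region (nucleotides 2-8) of mature miRNAs
#'
#' @param mirnas an \code{RNAStringSet} of mature miRNA sequences
#'   (each of length >= 8).
#' @return An \code{RNAStringSet} of 7-nt seeds, names preserved.
#' @examples
#' m <- Biostrings::RNAStringSet(c(mir1 = "UGAGGUAGUAGGUUGUAUAGUU"))
#' seedRegion(m)
#' @export
seedRegion <- function(mirnas) {
    stopifnot(is(mirnas, "RNAStringSet"))
    if (any(Biostrings::width(mirnas) < 8L))
        stop("all miRNA sequences must be at least 8 nt to carry a seed")
    Biostrings::subseq(mirnas, 2L, 8L)
}

#' Hydrogen-bond score of one seed:window duplex
#'
#' Pairs a 7-nt miRNA seed against a 7-nt UTR window in antiparallel
#' orientation (seed position i against window position 8 - i, both given
#' 5' to 3') and sums the hydrogen-bond weights of the pairs formed.
#'
#' @param seed 7-nt RNA string (character or \code{RNAString}).
#' @param window 7-nt DNA string, the UTR window 5' to 3'.
#' @param weights a \code{\link{SeedWeights}} object.
#' @return Named numeric: \code{score} (summed hydrogen bonds) and
#'   \code{nPaired} (positions forming a legal Watson-Crick or wobble pair).
#' @examples
#' hbondScore("GGGGGGG", "CCCCCCC")   # 21 bonds, 7 pairs
#' hbondScore("GAAAAAA", "TTTTTTT")   # one G.T wobble plus six A:T
#' @export
hbondScore <- function(seed, window, weights = SeedWeights()) {
    sc <- .encodeRNA(seed)
    wc <- .encodeDNA(window)
    if (length(sc) != 7L || length(wc) != 7L)
        stop("seed and window must both be exactly 7 nt")
    ws <- .windowScores(sc, wc, .scoreMatrix(weights))
    c(score = ws$score, nPaired = ws$npaired)
}

.asGeneSet <- function(utrs) {
    stopifnot(is(utrs, "DNAStringSet"))
    if (is.null(names(utrs)) || anyNA(names(utrs)) || any(names(utrs) == ""))
        stop("UTR set must be named by gene id")
    utrs
}

.asMirnaSet <- function(mirnas) {
    stopifnot(is(mirnas, "RNAStringSet"))
    if (is.null(names(mirnas)) || any(names(mirnas) == ""))
        stop("miRNA set must be named")
    if (anyDuplicated(names(mirnas))) stop("duplicate miRNA ids")
    mirnas
}

.sitesGRanges <- function(geneId, mirnaId, offsets, scores, npaired, seqlens) {
    GenomicRanges::GRanges(
        seqnames = geneId,
        ranges = IRanges::IRanges(start = offsets + 1L, width = 7L),
        strand = "+",
        mirnaId = mirnaId, score = as.integer(scores),
        nPaired = as.integer(npaired),
        seqlengths = seqlens)
}

#' Enumerate admissible seed-match sites on UTR sequences
#'
#' Evaluates every 7-nt window of each UTR against each miRNA seed and
#' reports windows whose hydrogen-bond sum reaches \code{threshold}. In
#' \code{"strict"} mode a site must additionally have all seven seed
#' positions paired (Watson-Crick or wobble); \code{"lenient"} mode
#' thresholds the sum alone, so mismatched positions merely contribute
#' zero bonds.
#'
#' @param mirnas named \code{RNAStringSet} of mature miRNAs (seeds are
#'   taken as nucleotides 2-8).
#' @param utrs named \code{DNAStringSet} of 3'UTR sequences (sense strand).
#' @param threshold integer, minimum summed hydrogen bonds.
#' @param weights a \code{\link{SeedWeights}}.
#' @param mode \code{"lenient"} (default) or \code{"strict"}.
#' @return A \code{GRanges} in UTR coordinates (seqnames = gene id, 1-based
#'   start, width 7, strand \code{"+"}) with metadata columns
#'   \code{mirnaId}, \code{score} and \code{nPaired}, sorted by gene and
#'   offset. UTRs shorter than 7 nt contribute no sites (with a message).
#' @examples
#' utrs <- Biostrings::DNAStringSet(c(g1 = "AACCCCCCCAA"))
#' mirs <- Biostrings::RNAStringSet(c(m1 = "AGGGGGGGCCCCCCCCCCCCCC"))
#' scanSites(mirs, utrs, threshold = 21, mode = "strict")
#' @export
scanSites <- function(mirnas, utrs, threshold, weights = SeedWeights(),
                      mode = c("lenient", "strict")) {
    mode <- match.arg(mode)
    utrs <- .asGeneSet(utrs)
    mirnas <- .asMirnaSet(mirnas)
    stopifnot(threshold >= 0)
    SM <- .scoreMatrix(weights)
    seeds <- as.character(seedRegion(mirnas))
    seedCodes <- lapply(seeds, .encodeRNA)
    seqlens <- setNames(Biostrings::width(utrs), names(utrs))
    short <- Biostrings::width(utrs) < 7L
    if (any(short))
        message(sum(short), " UTR(s) shorter than 7 nt skipped")
    gene <- mir <- list()
    off <- sco <- npd <- list()
    k <- 0L
    seqsChr <- as.character(utrs)
    for (g in names(utrs)[!short]) {
        uc <- .encodeDNA(seqsChr[[g]])
        for (m in names(mirnas)) {
            ws <- .windowScores(seedCodes[[m]], uc, SM)
            keep <- ws$score >= threshold
            if (mode == "strict") keep <- keep & ws$npaired == 7L
            if (any(keep)) {
                k <- k + 1L
                w <- which(keep)
                gene[[k]] <- rep(g, length(w))
                mir[[k]] <- rep(m, length(w))
                off[[k]] <- w - 1L
                sco[[k]] <- ws$score[keep]
                npd[[k]] <- ws$npaired[keep]
            }
        }
    }
    if (k == 0L) {
        gr <- GenomicRanges::GRanges(seqlengths = seqlens)
        gr$mirnaId <- character(0)
        gr$score <- integer(0)
        gr$nPaired <- integer(0)
        return(gr)
    }
    gr <- .sitesGRanges(
        factor(unlist(gene), levels = names(utrs)), unlist(mir),
        unlist(off), unlist(sco), unlist(npd), seqlens)
    GenomicRanges::sort(gr)
}

#' Rescan a local region of a UTR
#'
#' Identical to \code{\link{scanSites}} restricted to windows overlapping
#' the 0-based half-open interval \code{[lo, hi)} of each UTR. Used to
#' re-evaluate only the windows a point mutation can touch.
#'
#' @inheritParams scanSites
#' @param lo,hi 0-based half-open bounds, \code{0 <= lo <= hi <= width}.
#' @return A \code{GRanges} as in \code{\link{scanSites}}.
#' @export
scanRegion <- function(mirnas, utrs, threshold, weights = SeedWeights(),
                       mode = c("lenient", "strict"), lo, hi) {
    mode <- match.arg(mode)
    utrs <- .asGeneSet(utrs)
    if (lo < 0 || hi < lo || any(hi > Biostrings::width(utrs)))
        stop("need 0 <= lo <= hi <= UTR length")
    gr <- scanSites(mirnas, utrs, threshold, weights, mode)
    ## window at 0-based offset o covers [o, o+7); it overlaps [lo, hi)
    ## iff o < hi and o + 7 > lo
    off <- GenomicRanges::start(gr) - 1L
    gr[off < hi & off + 7L > lo]
}

## Per-gene site-count matrix (miRNAs x thresholds) from encoded codes.
.geneMirnaCounts <- function(utrCodes, seedCodes, SM, thresholds, strict) {
    nm <- length(seedCodes)
    cnt <- matrix(0L, nm, length(thresholds))
    if (length(utrCodes) < 7L) return(cnt)
    for (j in seq_len(nm)) {
        ws <- .windowScores(seedCodes[[j]], utrCodes, SM)
        sc <- ws$score
        if (strict) sc <- sc[ws$npaired == 7L]
        cnt[j, ] <- vapply(thresholds, function(t) sum(sc >= t), integer(1))
    }
    cnt
}

#' Precompute per-gene, per-miRNA site counts over a threshold sweep
#'
#' Scores every (gene, miRNA) pair once and tabulates admissible-site
#' counts at each requested threshold. The returned profile can be fed to
#' \code{\link{deltaBSweep}} so that randomization replicates reuse the
#' wild-type scan instead of recomputing it.
#'
#' @inheritParams scanSites
#' @param thresholds integer vector of hydrogen-bond thresholds.
#' @return A list with the count array (genes x miRNAs x thresholds) and
#'   the scan settings, of class \code{"bindingProfile"}.
#' @export
bindingProfiles <- function(utrs, mirnas, thresholds = 14:21,
                            weights = SeedWeights(),
                            mode = c("lenient", "strict")) {
    mode <- match.arg(mode)
    utrs <- .asGeneSet(utrs)
    mirnas <- .asMirnaSet(mirnas)
    if (anyDuplicated(names(utrs))) stop("duplicate gene ids")
    stopifnot(length(thresholds) > 0)
    SM <- .scoreMatrix(weights)
    seedCodes <- lapply(as.character(seedRegion(mirnas)), .encodeRNA)
    arr <- array(0L, dim = c(length(utrs), length(mirnas), length(thresholds)),
                 dimnames = list(names(utrs), names(mirnas), thresholds))
    seqs <- as.character(utrs)
    strict <- mode == "strict"
    for (i in seq_along(seqs))
        arr[i, , ] <- .geneMirnaCounts(.encodeDNA(seqs[i]), seedCodes, SM,
                                       thresholds, strict)
    structure(list(counts = arr, thresholds = as.integer(thresholds),
                   mode = mode, weights = weights),
              class = "bindingProfile")
}

#' Count admissible binding sites for every (gene, miRNA) pair
#'
#' @inheritParams scanSites
#' @param counting per-gene aggregate rule: \code{"distinct_mirnas"} (number
#'   of distinct miRNAs with at least one site) or \code{"total_sites"}
#'   (summed site count); see \code{\link{geneAggregate}}.
#' @return A \code{\link{BindingTable-class}} object.
#' @export
countBinding <- function(utrs, mirnas, threshold, weights = SeedWeights(),
                         mode = c("lenient", "strict"),
                         counting = c("distinct_mirnas", "total_sites")) {
    mode <- match.arg(mode)
    counting <- match.arg(counting)
    utrs <- .asGeneSet(utrs)
    if (anyDuplicated(names(utrs))) stop("duplicate gene ids in UTR set")
    if (length(utrs) == 0L || length(mirnas) == 0L)
        stop("need at least one UTR and one miRNA")
    prof <- bindingProfiles(utrs, mirnas, thresholds = threshold,
                            weights = weights, mode = mode)
    cnts <- prof$counts[, , 1L, drop = FALSE]
    cnts <- matrix(cnts, nrow = dim(cnts)[1L], ncol = dim(cnts)[2L],
                   dimnames = dimnames(cnts)[1:2])
    new("BindingTable", counts = cnts,
        threshold = as.integer(threshold), mode = mode,
        counting = counting, weights = weights)
}
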