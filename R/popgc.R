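## GC/AT composition of alleles called at SNP sites, compared between two
## populations under read-depth filters and region restrictions, plus base
## composition of sequence sets (miRNAs vs UTRs).

.siteKey <- function(chrom, pos) paste(chrom, pos, sep = ":")

.regionFilter <- function(calls, regions) {
    if (is.null(regions)) return(rep(TRUE, nrow(calls)))
    stopifnot(is(regions, "GRanges"))
    snps <- GenomicRanges::GRanges(
        calls$chrom, IRanges::IRanges(calls$pos, width = 1L))
    IRanges::overlapsAny(snps, regions, ignore.strand = TRUE)
}

#' GC/AT composition of alleles called at SNP sites
#'
#' A call passes when its read depth is at least \code{dpMin} and (when
#' \code{regions} is given) its site lies inside an interval. In the
#' default \code{"genotype"} mode each passing diploid call contributes its
#' two genotype alleles to the Strong (G/C) versus Weak (A/T) tally, which
#' distinguishes the number of SNPs from the number of SNP calls; in
#' \code{"site"} mode each distinct allele observed at a passing site is
#' counted once per site (a sensitivity analysis that ignores genotype
#' frequencies).
#'
#' @param x a \code{\link{SnpCallSet-class}}.
#' @param dpMin integer, minimum read depth per call (default 0, no filter).
#' @param regions optional \code{GRanges} restriction (e.g. 3'UTRs or
#'   miRNA target intervals).
#' @param alleleMode \code{"genotype"} (default) or \code{"site"}.
#' @return A \code{\link{GcComposition-class}}; zero passing calls is an
#'   error naming the filter.
#' @examples
#' calls <- data.frame(chrom = "chr1", pos = 100, sample = "s1",
#'                     a1 = "C", a2 = "T", dp = 9)
#' gcComposition(SnpCallSet("demo", calls), dpMin = 5)
#' @export
gcComposition <- function(x, dpMin = 0L, regions = NULL,
                          alleleMode = c("genotype", "site")) {
    stopifnot(is(x, "SnpCallSet"))
    alleleMode <- match.arg(alleleMode)
    cl <- x@calls
    pass <- cl$dp >= dpMin & .regionFilter(cl, regions)
    if (!any(pass))
        stop(sprintf("no calls pass DP >= %d%s for population '%s'",
                     dpMin, if (is.null(regions)) "" else " within regions",
                     x@population))
    cl <- cl[pass, , drop = FALSE]
    nSnps <- length(unique(.siteKey(cl$chrom, cl$pos)))
    if (alleleMode == "genotype") {
        alleles <- c(cl$a1, cl$a2)
    } else {
        keys <- .siteKey(cl$chrom, cl$pos)
        alleles <- unlist(lapply(split(c(cl$a1, cl$a2), c(keys, keys)),
                                 unique), use.names = FALSE)
    }
    gc <- sum(alleles %in% .STRONG)
    new("GcComposition", population = x@population,
        dpMin = as.integer(dpMin), nSnps = as.integer(nSnps),
        nCalls = as.integer(nrow(cl)),
        gcAlleles = gc, atAlleles = length(alleles) - gc)
}

#' Split SNP calls by overlap with miRNA target intervals
#'
#' SNPs falling in at least one target interval of a miRNA on the focal
#' (e.g. melanoma-expressed) list form the first set; SNPs only in other
#' miRNAs' intervals form the second; SNPs outside every interval are
#' excluded. A SNP in intervals of both kinds goes to the focal set
#' (focal-first precedence; the number of such overlaps is reported via a
#' message).
#'
#' @param x a \code{\link{SnpCallSet-class}}.
#' @param targets \code{GRanges} of predicted target sites with a
#'   \code{mirnaId} metadata column.
#' @param focalIds character vector of focal miRNA ids (non-empty).
#' @return list of two \code{SnpCallSet}s: \code{focal} and \code{other}
#'   (either may be absent-calls and is then NULL).
#' @export
partitionByTargets <- function(x, targets, focalIds) {
    stopifnot(is(x, "SnpCallSet"), is(targets, "GRanges"))
    if (is.null(targets$mirnaId)) stop("targets need a mirnaId column")
    if (length(focalIds) == 0L) stop("focal id list is empty")
    cl <- x@calls
    snps <- GenomicRanges::GRanges(cl$chrom,
                                   IRanges::IRanges(cl$pos, width = 1L))
    isFocal <- targets$mirnaId %in% focalIds
    inFocal <- IRanges::overlapsAny(snps, targets[isFocal],
                                    ignore.strand = TRUE)
    inOther <- IRanges::overlapsAny(snps, targets[!isFocal],
                                    ignore.strand = TRUE)
    nBoth <- length(unique(.siteKey(cl$chrom, cl$pos)[inFocal & inOther]))
    if (nBoth > 0L)
        message(nBoth, " site(s) overlap both focal and other targets; ",
                "assigned to the focal set")
    mk <- function(keep, tag) {
        if (!any(keep)) return(NULL)
        SnpCallSet(paste0(x@population, ".", tag), cl[keep, , drop = FALSE])
    }
    list(focal = mk(inFocal, "focalTargets"),
         other = mk(inOther & !inFocal, "otherTargets"))
}

#' Restrict two call sets to SNP sites present in both
#'
#' @param a,b \code{\link{SnpCallSet-class}} objects on the same genome
#'   build.
#' @return list of the two restricted call sets; an empty intersection is
#'   an error.
#' @export
commonSnps <- function(a, b) {
    stopifnot(is(a, "SnpCallSet"), is(b, "SnpCallSet"))
    ka <- .siteKey(a@calls$chrom, a@calls$pos)
    kb <- .siteKey(b@calls$chrom, b@calls$pos)
    shared <- intersect(ka, kb)
    if (length(shared) == 0L)
        stop("the two call sets share no SNP positions")
    list(SnpCallSet(a@population, a@calls[ka %in% shared, , drop = FALSE]),
         SnpCallSet(b@population, b@calls[kb %in% shared, , drop = FALSE]))
}

#' Chi-square comparison of two GC compositions
#'
#' Pearson chi-square (1 df, no continuity correction) on the 2x2 table of
#' Strong/Weak allele counts by population. When a cell is zero the exact
#' Fisher test is used instead and flagged.
#'
#' @param r1,r2 \code{\link{GcComposition-class}} objects.
#' @return list: \code{statistic} (chi-square, NA under the exact
#'   fallback), \code{p.value}, \code{method}, \code{table}.
#' @examples
#' \dontrun{comparePopulations(gcComposition(a, 5), gcComposition(b, 5))}
#' @export
comparePopulations <- function(r1, r2) {
    stopifnot(is(r1, "GcComposition"), is(r2, "GcComposition"))
    tab <- rbind(alleleCounts(r1), alleleCounts(r2))
    rownames(tab) <- c(r1@population, r2@population)
    if (any(tab == 0)) {
        ft <- fisher.test(tab)
        return(list(statistic = NA_real_, p.value = ft$p.value,
                    method = "fisher.exact (zero cell)", table = tab))
    }
    ct <- chisq.test(tab, correct = FALSE)
    list(statistic = unname(ct$statistic), p.value = ct$p.value,
         method = "pearson.chisq", table = tab)
}

#' Pooled base composition of a sequence set
#'
#' Pools base counts over a set of sequences, either over full length or
#' restricted to the seed region (nucleotides 2-8, requiring length >= 8).
#' Used to contrast the GC (and G versus C) enrichment of miRNAs and their
#' seeds with the composition of 3'UTRs.
#'
#' @param seqs a \code{DNAStringSet} or \code{RNAStringSet}.
#' @param region \code{"full"} (default) or \code{"seed"}.
#' @return Named numeric: per-base fractions (U reported for RNA input,
#'   T for DNA) plus \code{gc}, the Strong-base fraction.
#' @export
sequenceComposition <- function(seqs, region = c("full", "seed")) {
    region <- match.arg(region)
    stopifnot(is(seqs, "DNAStringSet") || is(seqs, "RNAStringSet"))
    if (length(seqs) == 0L) stop("empty sequence set")
    if (region == "seed") {
        if (any(Biostrings::width(seqs) < 8L))
            stop("seed mode needs all sequences >= 8 nt")
        seqs <- Biostrings::subseq(seqs, 2L, 8L)
    }
    letters <- if (is(seqs, "RNAStringSet")) .RNA_BASES else .DNA_BASES
    counts <- colSums(Biostrings::letterFrequency(seqs, letters))
    if (sum(counts) < sum(Biostrings::width(seqs)))
        stop("sequences contain bases outside the A/C/G/T(U) alphabet")
    fr <- counts / sum(counts)
    c(fr, gc = unname(fr[["G"]] + fr[["C"]]))
}
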