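## The delta-b statistic: per-gene comparison of predicted miRNA binding
## between wild-type and mutated 3'UTRs, swept over hydrogen-bond
## thresholds; significance tests; per-miRNA differential-binding ranking
## and cross-program consensus.

## 1-based window offsets whose 7-nt window covers any mutated base.
.affectedOffsets <- function(offsets0, nWindows) {
    q <- offsets0 + 1L
    A <- unlist(lapply(q, function(p) seq.int(max(1L, p - 6L),
                                              min(nWindows, p))))
    sort(unique(A[A >= 1L & A <= nWindows]))
}

.offsetRuns <- function(A) {
    if (length(A) == 0L) return(list())
    brk <- which(diff(A) > 1L)
    starts <- c(1L, brk + 1L)
    ends <- c(brk, length(A))
    Map(function(s, e) c(A[s], A[e]), starts, ends)
}

## Mutant site counts for one gene by rescoring only affected windows.
.mutantGeneCounts <- function(wtCodes, mutCodes, offsets0, seedCodes, SM,
                              thresholds, strict, wtCnt) {
    nw <- length(wtCodes) - 6L
    if (nw < 1L) return(wtCnt)
    delta <- matrix(0L, nrow(wtCnt), ncol(wtCnt))
    for (run in .offsetRuns(.affectedOffsets(offsets0, nw))) {
        idx <- run[1]:(run[2] + 6L)
        delta <- delta +
            .geneMirnaCounts(mutCodes[idx], seedCodes, SM, thresholds, strict) -
            .geneMirnaCounts(wtCodes[idx], seedCodes, SM, thresholds, strict)
    }
    wtCnt + delta
}

.checkProfile <- function(prof, genes, mirnas, thresholds, mode, weights) {
    ok <- inherits(prof, "bindingProfile") &&
        identical(prof$thresholds, as.integer(thresholds)) &&
        identical(prof$mode, mode) &&
        identical(prof$weights, weights) &&
        all(genes %in% dimnames(prof$counts)[[1]]) &&
        identical(dimnames(prof$counts)[[2]], names(mirnas))
    if (!ok) stop("wtProfile does not match this scan's settings")
    prof
}

#' Delta-b over a hydrogen-bond threshold sweep
#'
#' For each threshold, counts admissible binding per gene on the wild-type
#' and on the mutated 3'UTR and classifies every mutated gene as having
#' more binding on the wild type, more on the mutant, or tied. Delta-b is
#' the number of wild-type-preferring genes minus the number of
#' mutant-preferring genes; the normalized form divides by the number of
#' mutated genes (so ties, including genes whose mutations touch no
#' admissible window, stay in the denominator).
#'
#' @inheritParams countBinding
#' @param muts mutation data.frame (see \code{\link{validateMutations}});
#'   a mutation for a gene absent from \code{utrs} is a hard error.
#'   Multiple mutations in one gene are applied jointly.
#' @param thresholds integer vector, default 14:21 (min to max hydrogen-bond
#'   sum of a fully paired 7-mer under the default weights).
#' @param rescan \code{"local"} re-scores only windows overlapping a
#'   mutation (exactly equivalent, much faster); \code{"full"} rescans the
#'   whole mutant sequence.
#' @param wtProfile optional precomputed \code{\link{bindingProfiles}} for
#'   these UTRs/miRNAs/settings, reused across randomization replicates.
#' @return data.frame with one row per threshold: \code{threshold},
#'   \code{nWtMore}, \code{nMutMore}, \code{nTied}, \code{deltaB},
#'   \code{normalized}; the number of mutated genes is in
#'   \code{attr(, "nGenes")}.
#' @seealso \code{\link{deltaBSignificance}}, \code{\link{perMirnaDeltaB}}
#' @export
deltaBSweep <- function(utrs, muts, mirnas, thresholds = 14:21,
                        weights = SeedWeights(),
                        mode = c("lenient", "strict"),
                        counting = c("distinct_mirnas", "total_sites"),
                        rescan = c("local", "full"), wtProfile = NULL) {
    mode <- match.arg(mode)
    counting <- match.arg(counting)
    rescan <- match.arg(rescan)
    utrs <- .asGeneSet(utrs)
    mirnas <- .asMirnaSet(mirnas)
    muts <- validateMutations(muts, utrs)
    stopifnot(length(thresholds) > 0)
    thresholds <- as.integer(thresholds)

    if (nrow(muts) == 0L) {
        ## nothing mutated: every gene trivially tied
        res <- data.frame(threshold = thresholds, nWtMore = 0L, nMutMore = 0L,
                          nTied = length(utrs), deltaB = 0L, normalized = 0)
        attr(res, "nGenes") <- length(utrs)
        return(res)
    }

    genes <- unique(muts$geneId)
    if (is.null(wtProfile)) {
        wtProfile <- bindingProfiles(utrs[genes], mirnas, thresholds,
                                     weights, mode)
    } else {
        .checkProfile(wtProfile, genes, mirnas, thresholds, mode, weights)
    }
    strict <- mode == "strict"
    SM <- .scoreMatrix(weights)
    seedCodes <- lapply(as.character(seedRegion(mirnas)), .encodeRNA)
    mutUtrs <- applyMutations(utrs[genes], muts)

    nT <- length(thresholds)
    wtAgg <- matrix(0L, length(genes), nT)
    mutAgg <- matrix(0L, length(genes), nT)
    for (i in seq_along(genes)) {
        g <- genes[i]
        wtCnt <- matrix(wtProfile$counts[g, , ], ncol = nT)
        if (rescan == "local") {
            mutCnt <- .mutantGeneCounts(
                .encodeDNA(utrs[[g]]), .encodeDNA(mutUtrs[[g]]),
                muts$offset[muts$geneId == g], seedCodes, SM,
                thresholds, strict, wtCnt)
        } else {
            mutCnt <- .geneMirnaCounts(.encodeDNA(mutUtrs[[g]]), seedCodes,
                                       SM, thresholds, strict)
        }
        if (counting == "distinct_mirnas") {
            wtAgg[i, ] <- colSums(wtCnt > 0L)
            mutAgg[i, ] <- colSums(mutCnt > 0L)
        } else {
            wtAgg[i, ] <- colSums(wtCnt)
            mutAgg[i, ] <- colSums(mutCnt)
        }
    }
    nWtMore <- colSums(wtAgg > mutAgg)
    nMutMore <- colSums(mutAgg > wtAgg)
    res <- data.frame(
        threshold = thresholds,
        nWtMore = as.integer(nWtMore),
        nMutMore = as.integer(nMutMore),
        nTied = as.integer(length(genes) - nWtMore - nMutMore),
        deltaB = as.integer(nWtMore - nMutMore),
        normalized = (nWtMore - nMutMore) / length(genes))
    attr(res, "nGenes") <- length(genes)
    res
}

#' Significance of a delta-b sweep
#'
#' Two complementary tests of whether wild-type sequences systematically
#' bind more miRNAs than their mutated versions: a two-sided paired t-test
#' pairing (nWtMore, nMutMore) across the threshold rows, and an exact
#' two-sided binomial sign test per threshold on the wt-preferring versus
#' mutant-preferring gene counts (ties excluded). Threshold rows are not
#' independent observations, so the per-threshold sign tests are reported
#' alongside as the robustness check.
#'
#' @param rows the data.frame returned by \code{\link{deltaBSweep}}
#'   (at least two rows for the t-test).
#' @return A list: \code{tStat}, \code{pPairedT}, \code{signP} (named
#'   numeric, one exact binomial p per threshold), and \code{allTied}
#'   (TRUE when every gene was tied at every threshold, in which case
#'   p = 1 is returned by convention).
#' @export
deltaBSignificance <- function(rows) {
    stopifnot(all(c("threshold", "nWtMore", "nMutMore") %in% names(rows)))
    if (nrow(rows) < 2L) stop("need >= 2 thresholds for the paired t-test")
    d <- rows$nWtMore - rows$nMutMore
    allTied <- all(rows$nWtMore == 0L & rows$nMutMore == 0L)
    if (allTied || all(d == d[1])) {
        ## zero-variance differences: t undefined (or all-tied); report by
        ## convention p = 1 when the common difference is 0
        tStat <- if (all(d == 0)) 0 else NA_real_
        pT <- if (all(d == 0)) 1 else NA_real_
    } else {
        tt <- t.test(rows$nWtMore, rows$nMutMore, paired = TRUE)
        tStat <- unname(tt$statistic)
        pT <- tt$p.value
    }
    signP <- vapply(seq_len(nrow(rows)), function(i) {
        n <- rows$nWtMore[i] + rows$nMutMore[i]
        if (n == 0L) return(1)
        binom.test(rows$nWtMore[i], n, p = 0.5)$p.value
    }, numeric(1))
    list(tStat = tStat, pPairedT = pT,
         signP = setNames(signP, rows$threshold), allTied = allTied)
}

#' Rank miRNAs by differential binding to wild-type versus mutant UTRs
#'
#' Totals each miRNA's admissible binding sites across all mutated genes on
#' the wild-type and the mutated sequences at one threshold. Delta-b per
#' miRNA is sitesWt - sitesMut; miRNAs are sorted by decreasing delta-b
#' (rank 1 = most wild-type-preferring, i.e. most binding lost to the
#' mutations), ties sharing their average rank.
#'
#' @inheritParams deltaBSweep
#' @param threshold single integer hydrogen-bond threshold.
#' @return data.frame: \code{mirnaId}, \code{sitesWt}, \code{sitesMut},
#'   \code{deltaB}, \code{rank}, sorted by decreasing \code{deltaB}.
#' @export
perMirnaDeltaB <- function(utrs, muts, mirnas, threshold,
                           weights = SeedWeights(),
                           mode = c("lenient", "strict")) {
    mode <- match.arg(mode)
    utrs <- .asGeneSet(utrs)
    mirnas <- .asMirnaSet(mirnas)
    muts <- validateMutations(muts, utrs)
    if (nrow(muts) == 0L) stop("no mutations supplied")
    genes <- unique(muts$geneId)
    wt <- countBinding(utrs[genes], mirnas, threshold, weights, mode,
                       counting = "total_sites")
    mut <- countBinding(applyMutations(utrs[genes], muts), mirnas, threshold,
                        weights, mode, counting = "total_sites")
    sitesWt <- colSums(siteCounts(wt))
    sitesMut <- colSums(siteCounts(mut))
    db <- sitesWt - sitesMut
    out <- data.frame(mirnaId = names(mirnas),
                      sitesWt = as.integer(sitesWt),
                      sitesMut = as.integer(sitesMut),
                      deltaB = as.integer(db),
                      rank = rank(-db, ties.method = "average"))
    out[order(-out$deltaB, out$mirnaId), , drop = FALSE]
}

#' Consensus miRNA ranking across prediction programs
#'
#' Aggregates per-program miRNA rankings by summing ranks: the consensus
#' score of a miRNA is the sum of its ranks over the tables, lower = more
#' wild-type-preferring overall. The miRNA universe is the outer union;
#' a miRNA missing from a table receives that table's worst rank + 1
#' (reported via a message).
#'
#' @param tables named list of data.frames each with columns \code{mirnaId}
#'   and \code{rank} (a \code{deltaB} column is accepted instead, ranked by
#'   decreasing value, average ties), e.g. outputs of
#'   \code{\link{perMirnaDeltaB}} or imported external-program tables.
#' @return data.frame: \code{mirnaId}, one rank column per table,
#'   \code{consensus}, sorted by increasing consensus score.
#' @export
consensusRank <- function(tables) {
    if (length(tables) == 0L) stop("need at least one ranking table")
    if (is.null(names(tables)))
        names(tables) <- paste0("program", seq_along(tables))
    ranks <- lapply(tables, function(tb) {
        if (!"mirnaId" %in% names(tb)) stop("table lacks a mirnaId column")
        if (nrow(tb) == 0L) stop("empty ranking table")
        if (!"rank" %in% names(tb)) {
            if (!"deltaB" %in% names(tb))
                stop("table needs a rank or deltaB column")
            tb$rank <- rank(-tb$deltaB, ties.method = "average")
        }
        setNames(tb$rank, tb$mirnaId)
    })
    universe <- Reduce(union, lapply(ranks, names))
    nFilled <- 0L
    mat <- vapply(ranks, function(r) {
        miss <- setdiff(universe, names(r))
        nFilled <<- nFilled + length(miss)
        r[universe]  # NA for missing
    }, numeric(length(universe)))
    mat <- matrix(mat, nrow = length(universe),
                  dimnames = list(universe, names(tables)))
    for (j in seq_len(ncol(mat))) {
        worst <- max(mat[, j], na.rm = TRUE)
        mat[is.na(mat[, j]), j] <- worst + 1
    }
    if (nFilled > 0L)
        message(nFilled, " missing table entr(ies) filled with worst rank + 1")
    out <- data.frame(mirnaId = universe, mat, consensus = rowSums(mat),
                      row.names = NULL, check.names = FALSE)
    out[order(out$consensus, out$mirnaId), , drop = FALSE]
}

#' Restrict a miRNA set to a list of ids
#'
#' @param mirnas named \code{RNAStringSet}.
#' @param ids character vector of miRNA ids to keep (e.g. a
#'   tissue-expressed subset); unknown ids are reported via a message, an
#'   empty intersection is an error.
#' @return The filtered \code{RNAStringSet}, original order preserved.
#' @export
subsetMirnas <- function(mirnas, ids) {
    mirnas <- .asMirnaSet(mirnas)
    if (length(ids) == 0L) stop("id list is empty")
    unknown <- setdiff(ids, names(mirnas))
    if (length(unknown))
        message(length(unknown), " id(s) not in the miRNA set: ",
                paste(utils::head(unknown, 5), collapse = ", "),
                if (length(unknown) > 5) ", ..." else "")
    keep <- names(mirnas) %in% ids
    if (!any(keep)) stop("no miRNA ids matched the id list")
    mirnas[keep]
}
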