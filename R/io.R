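## Shared readers and writers: FASTA (UTR/miRNA), mutation TSV, genotype
## TSV and VCF, target BED, binding-site BED/TSV, and the run manifest.

#' Read 3'UTR sequences from FASTA
#'
#' The first whitespace-delimited header token becomes the gene id;
#' sequences are upper-cased. Records containing characters outside
#' A/C/G/T (ambiguity codes such as N) are dropped with a message giving
#' the count. Duplicate ids and empty files are errors.
#'
#' @param path FASTA file.
#' @return Named \code{DNAStringSet}.
#' @export
readUtrFasta <- function(path) {
    raw <- Biostrings::readBStringSet(path)
    if (length(raw) == 0L) stop("empty FASTA: ", path)
    names(raw) <- vapply(strsplit(names(raw), "\\s+"), `[`, character(1), 1L)
    if (anyDuplicated(names(raw)))
        stop("duplicate gene id(s) in ", path)
    seqs <- toupper(as.character(raw))
    if (any(grepl("U", seqs, fixed = TRUE)))
        stop("RNA alphabet (U) in DNA FASTA: ", path)
    clean <- !grepl("[^ACGT]", seqs)
    if (any(!clean))
        message(sum(!clean), " record(s) with ambiguous/non-ACGT bases dropped")
    if (!any(clean)) stop("no clean A/C/G/T records in ", path)
    out <- Biostrings::DNAStringSet(seqs[clean])
    names(out) <- names(raw)[clean]
    out
}

#' Read mature miRNA sequences from FASTA
#'
#' As \code{\link{readUtrFasta}} but for the RNA alphabet: T is silently
#' converted to U (miRNA FASTA files are frequently DNA-alphabet), and any
#' other non-A/C/G/U character is an error.
#'
#' @param path FASTA file.
#' @return Named \code{RNAStringSet}.
#' @export
readMirnaFasta <- function(path) {
    raw <- Biostrings::readBStringSet(path)
    if (length(raw) == 0L) stop("empty FASTA: ", path)
    names(raw) <- vapply(strsplit(names(raw), "\\s+"), `[`, character(1), 1L)
    if (anyDuplicated(names(raw)))
        stop("duplicate miRNA id(s) in ", path)
    seqs <- chartr("T", "U", toupper(as.character(raw)))
    bad <- grepl("[^ACGU]", seqs)
    if (any(bad))
        stop("non-A/C/G/U(T) characters in record(s): ",
             paste(names(raw)[bad], collapse = ", "))
    out <- Biostrings::RNAStringSet(seqs)
    names(out) <- names(raw)
    out
}

#' Read a mutation TSV
#'
#' Tab-separated with header columns \code{geneId}, \code{offset}
#' (0-based), \code{ref}, \code{alt}. Validation against the UTR set is
#' eager; errors cite the file line.
#'
#' @param path TSV file.
#' @param utrs optional named \code{DNAStringSet} to validate against.
#' @return Mutation data.frame; a header-only file returns an empty frame
#'   with a warning.
#' @export
readMutations <- function(path, utrs = NULL) {
    tb <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (nrow(tb) == 0L) {
        warning("no mutation rows in ", path)
        return(validateMutations(tb[c("geneId", "offset", "ref", "alt")]))
    }
    out <- tryCatch(validateMutations(tb, utrs), error = function(e) {
        ## re-derive the offending line for the message
        for (k in seq_len(nrow(tb))) {
            ok <- tryCatch({
                validateMutations(tb[k, , drop = FALSE], utrs); TRUE
            }, error = function(e2) FALSE)
            if (!ok) stop(sprintf("%s (line %d of %s)",
                                  conditionMessage(e), k + 1L, path),
                          call. = FALSE)
        }
        stop(conditionMessage(e), call. = FALSE)
    })
    out
}

#' @describeIn readMutations Write a mutation table as TSV.
#' @param muts mutation data.frame.
#' @export
writeMutations <- function(muts, path) {
    utils::write.table(validateMutations(muts), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read genotype calls from a simple TSV
#'
#' Tab-separated with header columns \code{chrom}, \code{pos} (1-based),
#' \code{sample}, \code{a1}, \code{a2}, \code{dp}.
#'
#' @param path TSV file.
#' @param population population label for the set.
#' @return A \code{\link{SnpCallSet-class}}.
#' @export
readGenotypesTsv <- function(path, population) {
    tb <- utils::read.delim(path, stringsAsFactors = FALSE)
    SnpCallSet(population, tb)
}

#' @describeIn readGenotypesTsv Write a call set as TSV.
#' @param x a \code{SnpCallSet}.
#' @export
writeGenotypesTsv <- function(x, path) {
    stopifnot(is(x, "SnpCallSet"))
    utils::write.table(x@calls, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read genotype calls from a VCF
#'
#' Uses the per-sample GT and DP FORMAT fields; genotype allele indices
#' are resolved against REF/ALT (multi-allelic sites supported). A call
#' with missing DP is kept with DP = 0, so any depth filter of 1 or more
#' removes it; the number of such calls is reported via a warning.
#' Missing or half-missing genotypes are skipped.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param population population label.
#' @return A \code{\link{SnpCallSet-class}} (positions 1-based, as in VCF).
#' @export
readGenotypesVcf <- function(path, population) {
    vcf <- VariantAnnotation::readVcf(path)
    gt <- VariantAnnotation::geno(vcf)$GT
    if (is.null(gt)) stop("VCF has no GT field: ", path)
    dp <- VariantAnnotation::geno(vcf)$DP
    rr <- SummarizedExperiment::rowRanges(vcf)
    ref <- as.character(rr$REF)
    altL <- lapply(rr$ALT, as.character)
    chrom <- as.character(GenomicRanges::seqnames(rr))
    pos <- GenomicRanges::start(rr)
    samples <- colnames(gt)
    rows <- list()
    nMissDP <- 0L
    for (j in seq_along(samples)) {
        g <- gt[, j]
        keep <- !(g %in% c(".", "./.", ".|.")) & !grepl("\\.", g)
        if (!any(keep)) next
        parts <- strsplit(g[keep], "[/|]")
        i1 <- as.integer(vapply(parts, `[`, character(1), 1L))
        i2 <- as.integer(vapply(parts, `[`, character(1), 2L))
        idx <- which(keep)
        alleleOf <- function(i, ai) {
            out <- character(length(i))
            zero <- ai == 0L
            out[zero] <- ref[i[zero]]
            if (any(!zero))
                out[!zero] <- mapply(function(k, a) altL[[k]][a],
                                     i[!zero], ai[!zero])
            out
        }
        d <- if (is.null(dp)) rep(NA_integer_, length(idx)) else dp[idx, j]
        nMissDP <- nMissDP + sum(is.na(d))
        d[is.na(d)] <- 0L
        rows[[j]] <- data.frame(
            chrom = chrom[idx], pos = pos[idx], sample = samples[j],
            a1 = alleleOf(idx, i1), a2 = alleleOf(idx, i2), dp = d)
    }
    if (length(rows) == 0L) stop("no usable genotype calls in ", path)
    if (nMissDP > 0L)
        warning(nMissDP, " call(s) with missing DP treated as DP = 0")
    SnpCallSet(population, do.call(rbind, rows))
}

#' Read miRNA target intervals from BED
#'
#' BED3/BED6; the name column (4th) is taken as the miRNA id when present.
#' BED coordinates are 0-based half-open and become 1-based closed
#' \code{GRanges}.
#'
#' @param path BED file.
#' @return \code{GRanges} with a \code{mirnaId} metadata column.
#' @export
readTargetBed <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    gr$mirnaId <- if (!is.null(gr$name)) gr$name else NA_character_
    gr$name <- NULL
    gr
}

#' @describeIn readTargetBed Write intervals (with \code{mirnaId} as the
#'   BED name) back to BED6.
#' @param gr \code{GRanges} with a \code{mirnaId} column.
#' @export
writeTargetBed <- function(gr, path) {
    stopifnot(is(gr, "GRanges"))
    df <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(gr)),
        start = GenomicRanges::start(gr) - 1L,
        end = GenomicRanges::end(gr),
        name = if (!is.null(gr$mirnaId)) gr$mirnaId else ".",
        score = 0L,
        strand = ifelse(as.character(GenomicRanges::strand(gr)) == "*",
                        "+", as.character(GenomicRanges::strand(gr))))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Write binding sites as BED6 plus a TSV with pairing detail
#'
#' BED6 in UTR space: chrom = gene id, 0-based start, end, name = miRNA
#' id, score = hydrogen-bond sum, strand "+". The companion TSV adds the
#' \code{nPaired} column.
#'
#' @param sites \code{GRanges} from \code{\link{scanSites}}.
#' @param bedPath,tsvPath output paths (either may be NULL to skip).
#' @return Invisibly, the paths written.
#' @export
writeSites <- function(sites, bedPath = NULL, tsvPath = NULL) {
    stopifnot(is(sites, "GRanges"))
    df <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(sites)),
        start = GenomicRanges::start(sites) - 1L,
        end = GenomicRanges::end(sites),
        name = sites$mirnaId,
        score = sites$score,
        strand = "+")
    if (!is.null(bedPath))
        utils::write.table(df, bedPath, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
    if (!is.null(tsvPath)) {
        df$nPaired <- sites$nPaired
        utils::write.table(df, tsvPath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    invisible(c(bed = bedPath, tsv = tsvPath))
}

#' Read an external-program prediction table
#'
#' TSV with header columns \code{program}, \code{geneId}, \code{mirnaId},
#' \code{threshold} and either \code{bound} (0/1) or \code{sites}
#' (integer). External target-prediction programs are consumed through
#' this interface only, never re-run.
#'
#' @param path TSV file.
#' @return data.frame with a \code{sites} column (bound coerced to 0/1
#'   site counts when necessary).
#' @export
readPredictionTable <- function(path) {
    tb <- utils::read.delim(path, stringsAsFactors = FALSE)
    req <- c("program", "geneId", "mirnaId", "threshold")
    if (!all(req %in% names(tb)))
        stop("prediction table needs columns: ", paste(req, collapse = ", "))
    if (!"sites" %in% names(tb)) {
        if (!"bound" %in% names(tb))
            stop("prediction table needs a bound or sites column")
        tb$sites <- as.integer(tb$bound != 0)
    }
    tb
}

#' Write a run manifest
#'
#' Records the command name, full parameter set, RNG seed, input-file MD5
#' digests, package version and timestamp as JSON, so a run can be
#' reproduced exactly.
#'
#' @param path output JSON path.
#' @param command short name of the analysis step.
#' @param params named list of parameters.
#' @param seed the RNG seed used (or NA for deterministic steps).
#' @param inputs character vector of input file paths to digest.
#' @return The manifest list, invisibly.
#' @export
writeRunManifest <- function(path, command, params = list(), seed = NA,
                             inputs = character(0)) {
    manifest <- list(
        command = command,
        params = params,
        seed = seed,
        inputs = as.list(tools::md5sum(inputs)),
        version = as.character(utils::packageVersion("mirSeedShift")),
        timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
    invisible(manifest)
}
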