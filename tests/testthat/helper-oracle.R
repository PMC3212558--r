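# Independent exhaustive scorer used as the oracle for the vectorized
# scanner: per window, per position, if-chain pairing rules. Deliberately
# naive; shares no code with the package internals.

oraclePairBonds <- function(mirBase, utrBase, gc = 3, au = 2, wob = 2) {
    if ((mirBase == "G" && utrBase == "C") ||
        (mirBase == "C" && utrBase == "G")) return(gc)
    if ((mirBase == "A" && utrBase == "T") ||
        (mirBase == "U" && utrBase == "A")) return(au)
    if ((mirBase == "G" && utrBase == "T") ||
        (mirBase == "U" && utrBase == "G")) return(wob)
    0
}

# all windows of a UTR scored against the seed (nt 2-8) of mirSeq;
# returns data.frame(offset0, score, npaired)
oracleScoreAll <- function(mirSeq, utrSeq, gc = 3, au = 2, wob = 2) {
    seed <- strsplit(substr(mirSeq, 2, 8), "")[[1]]
    utr <- strsplit(utrSeq, "")[[1]]
    n <- length(utr)
    if (n < 7) return(data.frame(offset0 = integer(0), score = integer(0),
                                 npaired = integer(0)))
    res <- lapply(0:(n - 7), function(o) {
        win <- utr[(o + 1):(o + 7)]
        score <- 0; np <- 0
        for (i in 1:7) {
            b <- oraclePairBonds(seed[i], win[8 - i], gc, au, wob)
            score <- score + b
            if (b > 0) np <- np + 1
        }
        c(o, score, np)
    })
    m <- do.call(rbind, res)
    data.frame(offset0 = m[, 1], score = m[, 2], npaired = m[, 3])
}

oracleSites <- function(mirSeq, utrSeq, threshold, strict,
                        gc = 3, au = 2, wob = 2) {
    sc <- oracleScoreAll(mirSeq, utrSeq, gc, au, wob)
    keep <- sc$score >= threshold
    if (strict) keep <- keep & sc$npaired == 7
    sc[keep, , drop = FALSE]
}

# random sequence helpers (plain base R on purpose)
randDna <- function(n, gc = 0.5) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
}
randRna <- function(n, gc = 0.5) chartr("T", "U", randDna(n, gc))
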