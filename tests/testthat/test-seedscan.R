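dss <- Biostrings::DNAStringSet
rss <- Biostrings::RNAStringSet

test_that("hbondScore counts hydrogen bonds of an antiparallel seed:window duplex", {
    expect_equal(unname(hbondScore("AAAAAAA", "TTTTTTT")), c(14, 7))
    expect_equal(unname(hbondScore("GGGGGGG", "CCCCCCC")), c(21, 7))
    # mixed seed: scores frozen from the per-position oracle
    expect_equal(unname(hbondScore("GGGAAAA", "TTTTCCC")),
                 unname(unlist(oracleScoreAll("NGGGAAAAN", "TTTTCCC")[1, 2:3])))
    expect_equal(unname(hbondScore("GGGAAAA", "TTTTCCC")), c(17, 7))
    # one rG.dT wobble (weight 2) plus six A:T
    expect_equal(unname(hbondScore("GAAAAAA", "TTTTTTT")), c(14, 7))
    # antiparallel orientation matters: seed pos 1 pairs window pos 7
    expect_equal(unname(hbondScore("GAAAAAA", "TTTTTTC")), c(15, 7))
    expect_equal(unname(hbondScore("GAAAAAA", "CTTTTTT")), c(12, 6))
})

test_that("hbondScore rejects bad input", {
    expect_error(hbondScore("GGG", "CCCCCCC"), "7 nt")
    expect_error(hbondScore("GGGGGGT", "CCCCCCC"), "A,C,G,U")
    expect_error(hbondScore("GGGGGGG", "CCCCCCU"), "A,C,G,T")
})

test_that("scanSites enumerates admissible windows", {
    utr <- dss(c(g1 = "AACCCCCCCAA"))
    mir <- rss(c(m1 = "AGGGGGGGAAAAAAAAAAAAAA"))
    # threshold 0 lenient: one site per window
    s0 <- scanSites(mir, utr, 0, mode = "lenient")
    expect_equal(length(s0), 11 - 6)
    expect_equal(GenomicRanges::start(s0), 1:5)
    # perfect complement at offset 2 only
    s21 <- scanSites(mir, utr, 21, mode = "strict")
    expect_equal(length(s21), 1L)
    expect_equal(GenomicRanges::start(s21), 3L)  # 0-based offset 2
    expect_equal(s21$score, 21L)
    # above the maximum score: always empty
    expect_equal(length(scanSites(mir, utr, 22)), 0L)
    # UTR shorter than 7 contributes nothing, with a message, not an error
    expect_message(sShort <- scanSites(mir, dss(c(tiny = "ACGT")), 0),
                   "shorter than 7")
    expect_equal(length(sShort), 0L)
})

test_that("scanSites agrees with the exhaustive per-window oracle", {
    set.seed(42)
    for (rep in 1:40) {
        utrSeq <- randDna(sample(7:60, 1), gc = runif(1, 0.2, 0.8))
        mirSeq <- randRna(22, gc = runif(1, 0.2, 0.8))
        utr <- dss(setNames(utrSeq, "g"))
        mir <- rss(setNames(mirSeq, "m"))
        for (t in c(0, 7, 12:21)) {
            for (strict in c(FALSE, TRUE)) {
                got <- scanSites(mir, utr, t,
                                 mode = if (strict) "strict" else "lenient")
                exp <- oracleSites(mirSeq, utrSeq, t, strict)
                expect_equal(GenomicRanges::start(got) - 1L, exp$offset0)
                expect_equal(got$score, as.integer(exp$score))
                expect_equal(got$nPaired, as.integer(exp$npaired))
            }
        }
    }
})

test_that("site sets shrink with threshold and strictness", {
    set.seed(7)
    for (rep in 1:15) {
        utr <- dss(setNames(randDna(50), "g"))
        mir <- rss(setNames(randRna(22), "m"))
        prev <- NULL
        for (t in 0:21) {
            len <- scanSites(mir, utr, t)
            str <- scanSites(mir, utr, t, mode = "strict")
            # strict sites are a subset of lenient sites at equal threshold
            expect_true(all(GenomicRanges::start(str) %in%
                            GenomicRanges::start(len)))
            if (!is.null(prev)) expect_lte(length(len), prev)
            prev <- length(len)
        }
    }
})

test_that("a C-to-T substitution at a position pairing seed G turns G:C into wobble", {
    set.seed(11)
    for (rep in 1:20) {
        # build a window whose position j carries a C paired with seed G
        j <- sample(1:7, 1)
        seed <- strsplit(randRna(7), "")[[1]]
        seed[8 - j] <- "G"
        win <- strsplit(randDna(7), "")[[1]]
        win[j] <- "C"
        before <- hbondScore(paste(seed, collapse = ""),
                             paste(win, collapse = ""))
        win[j] <- "T"
        after <- hbondScore(paste(seed, collapse = ""),
                            paste(win, collapse = ""))
        # G:C (3 bonds) becomes a G.T wobble (2): down exactly one, and
        # the position stays paired
        expect_equal(after[["score"]], before[["score"]] - 1)
        expect_equal(after[["nPaired"]], before[["nPaired"]])
    }
})

test_that("equal weights collapse the score to 2 x nPaired", {
    set.seed(3)
    for (rep in 1:10) {
        utr <- dss(setNames(randDna(40), "g"))
        mir <- rss(setNames(randRna(22), "m"))
        s <- scanSites(mir, utr, 0, weights = equalWeights())
        expect_equal(s$score, 2L * s$nPaired)
    }
})

test_that("the reverse complement of a seed is its maximal Watson-Crick target", {
    set.seed(5)
    for (rep in 1:10) {
        mirSeq <- randRna(22)
        seed <- substr(mirSeq, 2, 8)
        target <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(chartr("U", "T", seed))))
        sc <- hbondScore(seed, target)
        nGC <- sum(strsplit(seed, "")[[1]] %in% c("G", "C"))
        expect_equal(unname(sc["score"]), 7 * 2 + nGC * (3 - 2))
        expect_equal(unname(sc["nPaired"]), 7)
    }
})

test_that("scanRegion restricts the scan to windows overlapping [lo, hi)", {
    set.seed(9)
    utrSeq <- randDna(60)
    utr <- dss(setNames(utrSeq, "g"))
    mir <- rss(setNames(randRna(22), "m"))
    full <- scanSites(mir, utr, 10)
    expect_equal(scanRegion(mir, utr, 10, lo = 0, hi = 60), full)
    off <- GenomicRanges::start(full) - 1L
    expect_error(scanRegion(mir, utr, 10, lo = 0, hi = 61), "<=")
    # local rescan around a mutation reproduces a full rescan
    for (rep in 1:10) {
        p <- sample(0:59, 1)
        mutSeq <- utrSeq
        old <- substr(mutSeq, p + 1, p + 1)
        new <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
        substr(mutSeq, p + 1, p + 1) <- new
        mutUtr <- dss(setNames(mutSeq, "g"))
        fullMut <- scanSites(mir, mutUtr, 10)
        local <- scanRegion(mir, mutUtr, 10, lo = max(0, p - 6), hi = p + 7)
        # sites of the mutant = local rescan union untouched wild-type sites
        untouched <- full[!(off < p + 7 & off + 7L > p - 6)]
        merged <- GenomicRanges::sort(c(local, untouched))
        expect_equal(GenomicRanges::start(merged),
                     GenomicRanges::start(fullMut))
        expect_equal(merged$score, fullMut$score)
    }
})

test_that("countBinding aggregates per-gene site counts", {
    utrs <- dss(c(g1 = "AACCCCCCCAA", g2 = "TTTTTTTTTTT"))
    mirs <- rss(c(m1 = "AGGGGGGGAAAAAAAAAAAAAA",
                  m2 = "AAAAAAAAGGGGGGGGGGGGGG"))
    bt <- countBinding(utrs, mirs, 21, mode = "strict")
    expect_s4_class(bt, "BindingTable")
    expect_equal(siteCounts(bt)["g1", "m1"], 1L)
    expect_equal(sum(siteCounts(bt)["g2", ]), 0L)
    expect_equal(unname(geneAggregate(bt)), c(1L, 0L))
    # total_sites vs distinct_mirnas on a double-bound gene
    utr2 <- dss(c(g = "CCCCCCCTTTTTTTCCCCCCC"))
    btd <- countBinding(utr2, mirs, 14, mode = "strict",
                        counting = "distinct_mirnas")
    bts <- countBinding(utr2, mirs, 14, mode = "strict",
                        counting = "total_sites")
    expect_equal(unname(geneAggregate(btd)), 2L)
    expect_gt(unname(geneAggregate(bts)), unname(geneAggregate(btd)))
    expect_error(countBinding(dss(c(g = "ACGTACG", g = "ACGTACG")), mirs, 14),
                 "duplicate")
})

test_that("countBinding matches a brute-force double loop on random instances", {
    set.seed(21)
    utrs <- dss(setNames(vapply(1:4, function(i) randDna(35), ""),
                         paste0("g", 1:4)))
    mirs <- rss(setNames(vapply(1:3, function(i) randRna(22), ""),
                         paste0("m", 1:3)))
    for (t in c(10, 14, 17)) {
        bt <- countBinding(utrs, mirs, t)
        for (g in names(utrs)) for (m in names(mirs)) {
            expect_equal(siteCounts(bt)[g, m],
                         nrow(oracleSites(as.character(mirs[[m]]),
                                          as.character(utrs[[g]]), t, FALSE)),
                         info = paste(g, m, t))
        }
    }
})
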