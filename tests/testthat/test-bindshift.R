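dss <- Biostrings::DNAStringSet
rss <- Biostrings::RNAStringSet

toyUtrs <- dss(c(G1 = "AACCCCCCCAA", G2 = "ACGTACGTACGT"))
toyMirs <- rss(c(mGGG = "AGGGGGGGAAAAAAAAAAAAAA",
                 mAAA = "AAAAAAAAGGGGGGGGGGGGGG"))

test_that("deltaBSweep with no mutations is all ties", {
    sw <- deltaBSweep(toyUtrs, data.frame(geneId = character(0),
                                          offset = integer(0),
                                          ref = character(0),
                                          alt = character(0)),
                      toyMirs, thresholds = 14:21)
    expect_equal(sw$deltaB, rep(0L, 8))
    expect_equal(sw$nTied, rep(2L, 8))
    expect_equal(sw$normalized, rep(0, 8))
})

test_that("a site-destroying mutation gives delta-b +1, a site-creating one -1", {
    # G1 wild type carries one perfect site for mGGG; C>T at offset 5 breaks it
    m <- data.frame(geneId = "G1", offset = 5, ref = "C", alt = "T")
    sw <- deltaBSweep(toyUtrs, m, toyMirs, thresholds = 21, mode = "strict")
    expect_equal(sw$nWtMore, 1L)
    expect_equal(sw$nMutMore, 0L)
    expect_equal(sw$deltaB, 1L)
    expect_equal(sw$normalized, 1)   # one mutated gene
    # reciprocal: T>C completes the site in the mutant only
    utrs2 <- dss(c(G1 = "AACCCCTCCAA"))
    m2 <- data.frame(geneId = "G1", offset = 6, ref = "T", alt = "C")
    sw2 <- deltaBSweep(utrs2, m2, toyMirs, thresholds = 21, mode = "strict")
    expect_equal(sw2$deltaB, -1L)
    # a mutation for a gene with no UTR is a hard error
    expect_error(deltaBSweep(toyUtrs, data.frame(
        geneId = "GX", offset = 0, ref = "A", alt = "C"), toyMirs), "unknown")
})

test_that("tally conservation holds at every threshold", {
    u <- genUtrs(nGenes = 12, utrLength = 200, seed = 31)
    mu <- genMutations(u, n = 20, seed = 32)
    m <- genMirnas(nMirnas = 8, seed = 33)
    sw <- deltaBSweep(u, mu, m, thresholds = 12:20)
    nG <- attr(sw, "nGenes")
    expect_equal(sw$nWtMore + sw$nMutMore + sw$nTied, rep(nG, nrow(sw)))
    expect_true(all(abs(sw$normalized) <= 1))
    expect_equal(sw$deltaB, sw$nWtMore - sw$nMutMore)
})

test_that("local rescan equals a full mutant rescan", {
    set.seed(44)
    for (rep in 1:8) {
        u <- genUtrs(nGenes = 6, utrLength = 150, seed = 100 + rep)
        m <- genMirnas(nMirnas = 6, seed = 200 + rep)
        mu <- genMutations(u, n = 12, seed = 300 + rep)
        for (cnt in c("distinct_mirnas", "total_sites")) {
            a <- deltaBSweep(u, mu, m, thresholds = c(10, 14, 16, 18),
                             counting = cnt, rescan = "local")
            b <- deltaBSweep(u, mu, m, thresholds = c(10, 14, 16, 18),
                             counting = cnt, rescan = "full")
            expect_identical(a, b)
        }
    }
})

test_that("a precomputed wild-type profile reproduces the direct sweep", {
    u <- genUtrs(nGenes = 8, utrLength = 150, seed = 51)
    m <- genMirnas(nMirnas = 5, seed = 52)
    mu <- genMutations(u, n = 10, seed = 53)
    prof <- bindingProfiles(u, m, thresholds = 14:18)
    direct <- deltaBSweep(u, mu, m, thresholds = 14:18)
    cached <- deltaBSweep(u, mu, m, thresholds = 14:18, wtProfile = prof)
    expect_identical(direct, cached)
    # profile with mismatched settings is rejected
    expect_error(deltaBSweep(u, mu, m, thresholds = 14:17, wtProfile = prof),
                 "settings")
})

test_that("deltaBSignificance reports paired-t and exact sign tests", {
    rows <- data.frame(threshold = 14:17, nWtMore = c(5L, 5L, 5L, 5L),
                       nMutMore = c(5L, 5L, 5L, 5L), nTied = 0L,
                       deltaB = 0L, normalized = 0)
    s <- deltaBSignificance(rows)
    expect_equal(s$pPairedT, 1)
    expect_equal(s$tStat, 0)
    # exact binomial: 10 vs 0 gives 2 * 0.5^10
    rows2 <- data.frame(threshold = 14:15, nWtMore = c(10L, 6L),
                        nMutMore = c(0L, 4L))
    s2 <- deltaBSignificance(rows2)
    expect_equal(unname(s2$signP[["14"]]), 2 * 0.5^10, tolerance = 1e-12)
    expect_equal(unname(s2$signP[["15"]]),
                 binom.test(6, 10, 0.5)$p.value)
    # all-tied flag
    rows3 <- data.frame(threshold = 14:16, nWtMore = 0L, nMutMore = 0L)
    s3 <- deltaBSignificance(rows3)
    expect_true(s3$allTied)
    expect_equal(s3$pPairedT, 1)
    expect_equal(unname(s3$signP), rep(1, 3))
    expect_error(deltaBSignificance(rows3[1, ]), ">= 2 thresholds")
})

test_that("perMirnaDeltaB ranks site-destroying miRNAs first and conserves totals", {
    m <- data.frame(geneId = "G1", offset = 5, ref = "C", alt = "T")
    pm <- perMirnaDeltaB(toyUtrs, m, toyMirs, threshold = 21, mode = "strict")
    expect_equal(pm$mirnaId[1], "mGGG")
    expect_equal(pm$deltaB[pm$mirnaId == "mGGG"], 1L)
    expect_equal(pm$deltaB[pm$mirnaId == "mAAA"], 0L)
    expect_equal(pm$rank[1], 1)
    # conservation: sum of per-miRNA delta-b = total WT sites - mutant sites
    u <- genUtrs(nGenes = 10, utrLength = 150, seed = 61)
    mir <- genMirnas(nMirnas = 6, seed = 62)
    mu <- genMutations(u, n = 15, seed = 63)
    pm2 <- perMirnaDeltaB(u, mu, mir, threshold = 15)
    genes <- unique(mu$geneId)
    wt <- countBinding(u[genes], mir, 15, counting = "total_sites")
    mt <- countBinding(applyMutations(u[genes], mu), mir, 15,
                       counting = "total_sites")
    expect_equal(sum(pm2$deltaB), sum(siteCounts(wt)) - sum(siteCounts(mt)))
    # ties share average rank
    expect_equal(sort(pm2$rank), sort(rank(-pm2$deltaB)))
})

test_that("consensusRank sums per-program ranks over the outer union", {
    t1 <- data.frame(mirnaId = c("a", "b", "c"), rank = 1:3)
    # single table: order preserved
    c1 <- consensusRank(list(p1 = t1))
    expect_equal(c1$mirnaId, c("a", "b", "c"))
    # two reversed rankings of n items: full tie at n + 1
    t2 <- data.frame(mirnaId = c("a", "b", "c"), rank = 3:1)
    c2 <- consensusRank(list(p1 = t1, p2 = t2))
    expect_equal(c2$consensus, rep(4, 3))
    # three tables on 5 items match independently computed rank sums
    ids <- letters[1:5]
    set.seed(8)
    tabs <- lapply(1:3, function(i)
        data.frame(mirnaId = ids, rank = sample(5)))
    names(tabs) <- paste0("p", 1:3)
    cc <- consensusRank(tabs)
    expected <- sapply(ids, function(id)
        sum(sapply(tabs, function(tb) tb$rank[tb$mirnaId == id])))
    expect_equal(setNames(cc$consensus, cc$mirnaId)[ids], expected)
    expect_false(is.unsorted(cc$consensus))
    # missing entries get worst rank + 1
    t3 <- data.frame(mirnaId = c("a", "b"), rank = 1:2)
    expect_message(c3 <- consensusRank(list(p1 = t1, p3 = t3)), "worst rank")
    expect_equal(c3$p3[c3$mirnaId == "c"], 3)
    # deltaB column accepted in place of rank
    t4 <- data.frame(mirnaId = c("a", "b", "c"), deltaB = c(5L, 2L, 2L))
    c4 <- consensusRank(list(p = t4))
    expect_equal(setNames(c4$p, c4$mirnaId)[c("a", "b", "c")],
                 c(a = 1, b = 2.5, c = 2.5))
    expect_error(consensusRank(list()), "at least one")
})

test_that("subsetMirnas filters by id with order preserved", {
    m <- genMirnas(nMirnas = 6, seed = 71)
    expect_identical(subsetMirnas(m, names(m)), m)
    half <- names(m)[c(2, 4, 6)]
    expect_equal(names(subsetMirnas(m, rev(half))), half)
    expect_error(subsetMirnas(m, c("nope1", "nope2")), "matched")
    expect_message(subsetMirnas(m, c(half, "nope")), "not in the miRNA set")
})
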