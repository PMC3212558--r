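Package: mirSeedShift
Title: Mutation-Signature Effects on Global miRNA Seed Binding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies how somatic point-mutation spectra shift predicted
    microRNA binding to 3'UTRs. Implements a hydrogen-bond seed-match scanner
    (Watson-Crick and G:U wobble pairing over miRNA seed positions 2-8), the
    delta-b wild-type-versus-mutant binding statistic over a threshold sweep
    with paired t and exact sign tests, Strong/Weak classification of
    substitution spectra, randomization null models (fully random, same-type,
    same-position), a GC-weight ablation, per-miRNA differential-binding
    ranking with cross-program consensus, and a two-population comparison of
    GC/AT allele composition at SNP sites under read-depth filters. A seedable
    synthetic-data module generates UTR sets, GC-enriched miRNA seeds,
    parameterized mutation spectra (UV-like versus balanced) and diploid
    genotype tables so the whole analysis runs end to end without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    withr,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
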