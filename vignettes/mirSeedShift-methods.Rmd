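---
title: "Methods: mutation-signature effects on global miRNA seed binding"
author: "mirSeedShift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutation-signature effects on global miRNA seed binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirSeedShift)
```

## The question

Ultraviolet radiation leaves a characteristic somatic mutation spectrum:
the large majority of single-base substitutions are C→T (with G→A on the
opposite strand). In Watson–Crick pairing terms these are Strong-to-Weak
(S2W) changes — a G:C pair carries three hydrogen bonds, an A:T(U) pair
two — so a UV-skewed mutation load systematically lowers the
thermodynamic stability of any hybridization involving the mutated
strand. microRNAs recognise their targets mainly through the *seed*
(nucleotides 2–8 of the mature miRNA) pairing with the mRNA 3′UTR, and
seeds are GC-enriched relative to 3′UTRs, with an excess of G over C.
Putting these together, a UV-type mutation spectrum should *globally
reduce* predicted miRNA binding to mutated 3′UTRs, while more balanced
spectra (as in non-UV cancers) should not. This package implements the
whole chain of that argument so it can be run, tested and perturbed on
synthetic data.

## The hydrogen-bond seed scanner

`scanSites()` slides the 7-nt seed along every 7-nt window of a 3′UTR in
antiparallel orientation (seed position $i$ pairs window position
$8-i$). Each position contributes the hydrogen-bond count of the pair it
forms:

| pair (miRNA : UTR) | bonds (default) |
|---|---|
| G:C, C:G | 3 (`wcGC`) |
| A:T, U:A | 2 (`wcAU`) |
| G·T, U·G wobble | 2 (`wobble`) |
| anything else | 0 |

A window is an admissible site when the summed bonds reach a threshold.
Two site definitions are supported and both are first-class:

* **lenient** (default): the threshold applies to the sum alone, so a
  mismatched position merely contributes nothing. This keeps the sweep
  meaningful under the equal-weight ablation, where the score collapses
  to twice the number of paired positions.
* **strict**: additionally all seven positions must form a legal pair
  (Watson–Crick or wobble), which is how individual predicted duplexes
  are usually drawn.

The seed is fixed to nucleotides 2–8 (a 7-mer); no 6-mer or offset-7-mer
variants are scanned, and only the given (sense) strand of the UTR is
scanned, because miRNA:mRNA hybridization is strand-specific. UTR
offsets are 0-based with half-open 7-nt windows; records containing
ambiguity codes are dropped at load with a reported count. The wobble
weight defaults to 2 — the G·U pair has two hydrogen bonds chemically —
and is configurable, as is the whole weight set.

Because the published description of this scanner class leaves the
mismatch policy, the wobble weight and the threshold grid open, all
three are parameters with the defaults above, and the test suite checks
the scanner against an independent exhaustive per-window scorer across
the full threshold range in both modes.

## The Δb statistic

For a set of mutated genes, `deltaBSweep()` counts per-gene binding on
the wild-type and on the mutated 3′UTR at each threshold and classifies
every mutated gene as wild-type-preferring, mutant-preferring, or tied:

$$\Delta b = \#\{\text{genes with more binding on WT}\} -
             \#\{\text{genes with more binding on mutant}\},$$

normalized by the number of mutated 3′UTR genes. Genes whose mutations
touch no admissible window still count (as ties) — they are mutated
genes, and the normalizer is the total number of them. Multiple
mutations in one gene are applied jointly.

"More binding" is deliberately ambiguous in the source analyses: per
gene one can count *distinct miRNAs with at least one site* or *total
sites*. The default for Δb is distinct miRNAs; the per-miRNA ranking
(`perMirnaDeltaB()`) totals sites. Both are exposed via `counting=`.

Significance (`deltaBSignificance()`) reports a two-sided paired t-test
pairing the wild-type- and mutant-preferring counts across the
threshold rows, as the original analysis did. Threshold rows are *not*
independent observations — the same genes are classified at every
threshold — so an exact two-sided binomial sign test per threshold
(ties excluded) is always reported alongside, and conclusions in the
package's own tests rest on the sign tests.

Internally the mutant side is evaluated by *local rescan*: only windows
overlapping a mutated base are re-scored (`scanRegion()` is the exported
form). This is exactly equivalent to a full rescan (tested on random
instances) and makes randomization replicates cheap, as the wild-type
scan can be precomputed once with `bindingProfiles()` and shared.

## Randomization nulls

`randomizeMutations()` builds three in-silico null sets matched to an
observed mutation set, always within the same genes' UTRs (the
contrast of interest is *where/what* the mutations are, not *which
genes* carry them):

* `random_any` — random position, random substitution;
* `same_type` — each (ref, alt) pair is kept and relocated to a uniform
  position of the same UTR carrying that ref base, preserving the
  substitution spectrum exactly;
* `same_position` — positions kept, alt redrawn uniformly from the
  three non-ref bases (the source text says only that the type was
  "randomly changed"; uniform is the documented choice).

Positions are drawn without replacement within a gene so the resulting
set remains jointly applicable; a draw pool that runs dry falls back to
the original position with a counted warning. All generators and nulls
take a mandatory seed and are byte-reproducible.

If substitution *type* (not position) drives the binding shift, the
`same_type` null must reproduce the original effect while `random_any`
from a balanced spectrum must not — this is asserted in the acceptance
tests.

## The GC-weight ablation

Setting `wcGC = 2` (`equalWeights()`) makes Strong and Weak pairs
thermodynamically indistinguishable, removing the asymmetry that the
UV-spectrum argument relies on, while leaving motif disruption intact.
Note the most common UV change, C→T under a paired seed G, turns a G:C
pair into a G·T wobble: it *remains paired* and loses exactly one bond,
so under equal weights it is score-neutral. One numerical subtlety: with
equal weights the maximum window score is $7 \times 2 = 14$, so the
default 14:21 grid would be degenerate. The ablation is therefore swept
over 8:14 — the same rule that produced 14:21 (the score range of a
fully paired 7-mer) applied to the ablated weights.

## The population SNP analysis

The evolutionary corollary: populations under chronic UV exposure
should show relatively more Strong (G/C) alleles at polymorphic sites in
3′UTRs. `gcComposition()` tallies Strong vs Weak alleles over
per-individual diploid genotype calls under a minimum read-depth (DP)
filter and an optional region restriction; it distinguishes the number
of SNP *sites* from the number of SNP *calls*, and by default each
passing diploid call contributes its two genotype alleles (a
`site`-allele mode that counts each observed allele once per site is
provided for sensitivity analysis, since the original tabulation did not
state which was used). `commonSnps()` restricts two cohorts to shared
sites; `partitionByTargets()` splits SNPs by overlap with predicted
miRNA target intervals, with focal-list (e.g. melanoma-expressed
miRNAs) precedence when a SNP sits in both kinds of interval, and the
overlap count is reported. `comparePopulations()` applies the Pearson
chi-square (1 df, no continuity correction) to the 2×2 allele-count
table, with an exact-test fallback flagged when a cell is empty.
VCF input takes per-sample GT and DP; a call with missing DP is kept at
DP 0, so any depth filter of ≥1 removes it — conservative under a
minimum-coverage rule.

## The synthetic-data generators

Every input has a seeded generator, so the full analysis runs with no
external data. The defaults encode the study conditions the analysis
assumes:

* `genUtrs()` — 200 genes × 1 kb, i.i.d. bases at GC 0.424 (typical
  human 3′UTR composition). UTR bases are i.i.d. by design: the
  analysis's own conclusion is that substitution *type*, not local
  sequence context, drives the effect, so dinucleotide structure is
  deliberately not modelled.
* `genMirnas()` — 100 mature miRNAs of 22 nt; seed GC 0.509 with a
  G:C ratio of 1.2 (the ~20% G excess), body GC 0.486 so whole-molecule
  GC sits near 0.493.
* `genMutations()` — 300 draws from a named spectrum over the six
  strand-collapsed substitution types. The `"melanoma_uv"` preset is
  {C>T|G>A 0.645, C>A|G>T 0.105, C>G|G>C 0.055, T>C|A>G 0.100,
  T>A|A>T 0.056, T>G|A>C 0.039}: the 64.5% leading-type share, the 75%
  S2W and the 13.9% W2S aggregates are the anchored values, and the
  remaining split is an implementer choice consistent with them. The
  `"balanced"` preset {0.240, 0.235, 0.105, 0.160, 0.100, 0.160}
  realises the non-UV aggregates S2W 47.5% / W2S 32%.
* `genGenotypes()` — per site one fixed Strong and one fixed Weak
  allele; each individual's two alleles i.i.d. Strong with probability
  `sAlleleFreq`; read depth Poisson(6) so DP cutoffs of 5/8/11 all
  bite. Cohorts of 100 individuals × 5000 sites give ≈ 3.6 × 10⁵
  passing calls at DP ≥ 5, the scale at which a 57% vs 55%
  Strong-allele difference is detected at astronomically small p.

What the generators do *not* emulate: real UTR length distributions and
composition heterogeneity, miRNA family structure (shared seeds),
linkage between SNP sites, genotype error, or genomic coordinates beyond
what the interval analyses need. Passing tests on this synthetic data
therefore demonstrate that the machinery implements the model
correctly and that the qualitative effect follows from the stated
composition asymmetries — not that any particular real genome shows
effects of a particular size.

## Numerical and design notes

* Thresholds, scores and counts are integers throughout; there are no
  floating-point site decisions.
* Ties in per-miRNA rankings share average ranks; consensus ranking
  over several programs sums ranks over the outer union of miRNAs,
  filling a table's missing entries with its worst rank + 1 (reported).
* Degenerate inputs are defined behaviors, not crashes: UTRs shorter
  than 7 nt contribute no windows (reported); an empty mutation set
  yields Δb = 0 with all genes tied; an all-tied sweep returns p = 1
  with a flag; a zero cell in the 2×2 test falls back to the exact
  test with a flag.
* At the default scale the extremes of the 14:21 grid are
  uninformative: thresholds 20–21 admit essentially no sites (a
  score-21 site needs an all-GC seed *and* its perfect complement), so
  all genes tie there, and at 14–15 the distinct-miRNA aggregate
  saturates near the full miRNA count. The wild-type-preferring shift
  under the UV spectrum is carried by the mid-range thresholds
  (roughly 16–19); the per-threshold sign tests reflect exactly this.
* Problem sizes used in the shipped tests and in
  `scripts/acceptance.R` are the defaults above; the scanner-oracle
  comparison uses 200 random (miRNA, UTR ≤ 60 nt) pairs over the full
  0–21 threshold grid in both modes.

## Worked example

```{r example, eval = FALSE}
utrs   <- genUtrs(seed = 1)                       # 200 x 1 kb, GC 0.424
mirnas <- genMirnas(seed = 2)                     # 100 seeds, GC 0.509
muts   <- genMutations(utrs, seed = 3)            # 300 UV-spectrum SNVs

classFractions(mutationSpectrum(muts))            # ~75% S2W

sweep <- deltaBSweep(utrs, muts, mirnas)          # thresholds 14:21
deltaBSignificance(sweep)$signP                   # exact sign tests

# nulls and ablation
same  <- randomizeMutations(utrs, muts, "same_type", seed = 4)
abl   <- deltaBSweep(utrs, muts, mirnas, thresholds = 8:14,
                     weights = equalWeights())

# population GC composition
hi <- genGenotypes("popHi", sAlleleFreq = 0.57, nSites = 5000, seed = 5)
lo <- genGenotypes("popLo", sAlleleFreq = 0.55, nSites = 5000, seed = 6)
comparePopulations(gcComposition(hi, 5), gcComposition(lo, 5))
```

## Known limitations

* Seed pairing is the entire binding model: no free-energy (ΔΔG)
  computation, no site accessibility, no 3′-compensatory pairing.
  External predictors that model those are consumed as ranking tables
  (`readPredictionTable()`, `consensusRank()`), never re-implemented.
* The paired t-test across threshold rows inherits the original
  analysis's non-independence caveat; treat the per-threshold sign
  tests as primary.
* Dinucleotide mutations (e.g. CC→TT) are not modelled; all analyses
  are single-nucleotide.
* Genome-build handling (liftover) is out of scope; coordinate
  conventions are BED 0-based half-open on disk, 1-based internally
  for SNP positions, 0-based offsets for UTR mutations.
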