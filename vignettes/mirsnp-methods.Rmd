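---
title: "Methods: pattern-based allele-specific miRNA target prediction and pedigree genotype cleaning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pattern-based allele-specific miRNA target prediction and pedigree genotype cleaning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirsnp)
```

## Scope and model

`mirsnp` predicts, for a SNP inside a 3'UTR, which allele is expected to
bind miRNAs more strongly. The procedure is pattern-based rather than
homology-based: no cross-species conservation is used. Three stages feed a
per-SNP classification; a fourth, independent module implements the
pedigree genotype-cleaning stage used before family-based association
analysis. This vignette records the model assumptions, the tunable
parameters and their defaults, the numerical choices, and what the
synthetic fixtures do and do not demonstrate.

## Stage 1: (L,W) pattern discovery

A pattern is a motif over `{A,C,G,U,.}` that begins and ends with a
literal; the wildcard `.` matches any single base. The (L,W) density rule
requires every window of W consecutive motif positions to contain at least
L literals; windows exist only for motifs of length ≥ W, so short motifs
are constrained only by their literal endpoints. Support counts corpus
sequences containing at least one match — counting sequences rather than
occurrences prevents long miRNAs from dominating. `discover_patterns()`
returns exactly the *maximal* patterns at a support floor: no prefix/suffix
extension and no wildcard→literal specialization retains the same support.

The enumerator extends motifs rightward (a literal, preceded by 0..W−1
wildcards) with occurrence lists carried along, prunes on the support floor
(support is monotone non-increasing under extension and specialization),
and additionally prunes any subtree whose motif has a wildcard that is
base-uniform across all current occurrences — every pattern in such a
subtree is subsumed, with identical occurrences, by the literal
specialization, which is enumerated separately. A final pairwise filter
removes non-maximal survivors: pattern Q subsumes P when they have equal
support and P matches inside Q (treating P as a regular expression). Output
order is total — support desc, literal count desc, motif byte-order — so
runs are byte-reproducible.

Defaults: `L = 4`, `W = 6`, `min_support = max(2, 1% of corpus)`. The
(L,W) values are in the range used by pattern-discovery tools of this
lineage; they are exposed in `mirsnp_config()` and the test suite verifies
the enumerator against a brute-force oracle for several (L,W) combinations,
not just the default.

## Stage 2: significance against a Markov background

"Over-represented" is made precise by a log-odds score:
`log(observed support / expected support)` with patterns kept at
`log_odds ≥ log 2` (support at least twice expectation). The background is
a Markov chain over `{A,C,G,U}` of order 0-2 (default 2) with add-one
smoothing; the initial distribution is the smoothed empirical
order-gram frequency.

Expected support is computed, by default, with a **position-wise inclusion
bound**: the exact probability that the motif matches at a fixed position
(a forward pass over Markov contexts, wildcards summing over all four
bases), multiplied by the number of windows per sequence and capped at 1,
summed over sequences. This slightly over-estimates the per-sequence match
probability (it ignores overlap between window events), making the
significance filter mildly conservative — acceptable because the filter's
role is to remove patterns *at* background expectation, for which the bound
is tight. A Monte Carlo estimator (`significance_method = "mc"`,
`n_null = 1000` simulated corpora with the observed sequence lengths, fixed
seed) is available when an unbiased expectation is wanted; the default is
the inclusion bound because it is deterministic and fast enough to sit
inside the full pipeline, and the two agree on all planted fixtures in the
test suite.

## Stage 3: islands and duplex alignment

Significant patterns are mapped to target space — reverse complement,
transliterated to DNA (`U→T`, `.` fixed) — and scanned against each
*allelic* UTR: both alleles of the SNP are substituted in turn
(`apply_allele()`), and every overlapping match of every pattern is
recorded. `N` in a UTR matches nothing, conservatively.

**Island rule.** Whenever at least `min_island_hits = 5` hit starts fall
within a `window = 25` nt span, those hits seed an island running from the
first hit start to the last member hit's end; overlapping islands merge.
The defaults size the island to a typical miRNA site footprint (a ~22-nt
site tiled by ≥5 pattern hits); both are configurable, and the windowed
rule is validated against an all-spans brute-force oracle. Only islands
overlapping the SNP proceed to alignment — the object of interest is the
SNP's effect on binding, not UTR-wide site discovery (other islands are
still reported by the `scan` subcommand as BED).

**Duplex scoring.** miRNA (5'→3') versus island (3'→5') is aligned by
local affine-gap dynamic programming over complementarity: Watson-Crick
+5, G:U wobble +1, mismatch −3, gap open −8, extend −2 (a length-k gap
costs `open + (k−1)·extend`). Complementarity alignment, not thermodynamic
folding, is the "favorable alignment" criterion: an alignment DP is fully
checkable against an exhaustive pairing-enumeration oracle, whereas a
folding engine would import another model wholesale. An alignment
qualifies when its score is ≥ `min_report_score = 40` (eight Watson-Crick
pairs) *and* at least `seed_min_pairs = 6` of miRNA positions 2-8 (1-based,
5' end) are paired; wobble counts toward the seed by default
(`wobble_in_seed`). Traceback is deterministic: diagonal moves are
preferred over gaps, positive predecessors over fresh starts, and the best
cell is the first maximum in row-major order, so equal-scoring alignments
resolve to the one with fewer gaps and the earliest coordinates.

**Classification.** Per allele, the best qualifying score across
SNP-overlapping islands represents the allele (the simplest defensible
aggregation when several islands overlap); an allele with islands but no
qualifying alignment contributes 0. With ε = `epsilon = 0.5` score units:
`equal` when the difference is ≤ ε (an "equal binding" outcome requires a
nonzero tolerance by construction), `stronger:<allele>` otherwise,
`island_no_alignment` when an island overlaps the SNP in some allelic
context but no miRNA qualifies in either, and `no_island` when none does.
ε sits far below the minimum score quantum of the default scheme
(wobble-vs-WC differ by 4), so "equal" effectively means identical best
scores; it is exposed for non-integer scoring schemes.

## Pedigree genotype cleaning

Per-SNP filters run in a fixed order — completion rate (< 0.98 drops),
monomorphism, Mendelian error rate (> 0.01 drops), exact Hardy-Weinberg
(p ≤ 0.001 drops) — followed by genotype-level removal on the survivors.
Choices the filters leave open, decided here:

* **Mendel error rate denominator** is the number of genotyped trios (a
  child with a non-missing genotype and at least one resolvable parent);
  trios with an ungenotyped child cannot exhibit an error and are excluded.
* **Removal policy**: each error trio has all three member genotypes at
  that SNP set missing (PLINK-style), because the trio rule cannot say
  which member is wrong; a `child`-only policy is provided. Either policy
  leaves zero detectable errors, and removal is idempotent.
* **HWE on founders only**, to avoid counting transmitted alleles twice;
  the test is the standard two-sided exact test conditional on allele
  counts (tables as or less probable than the observed one), computed in
  log space by full enumeration of heterozygote counts.
* **Extended pedigrees** are treated as sets of parent-offspring trios;
  second-degree inconsistencies are out of scope.
* A trio with a missing parent is checked under single-parent rules: the
  missing parent may transmit any allele observed at that SNP. An
  all-missing SNP is flagged monomorphic (degenerate but defined).

## Synthetic fixtures: what they emulate, and what they do not

No real miRNA corpus, UTR set, or family genotypes ship with the package;
seeded generators build inputs with the statistical structure each stage
consumes. All generators are pure functions of their parameters and a
mandatory seed, with labelled RNG substreams so adding a generator never
perturbs existing fixtures.

* `gen_mirna_corpus()`: i.i.d. uniform-base sequences of 20-22 nt with an
  optional planted motif in a carrier fraction — the "shared subsequence"
  structure pattern discovery assumes.
* `gen_snp_utrs()`: uniform-base UTRs with planted sites that are exact
  reverse complements of chosen miRNAs; the SNP's in-sequence allele is
  intact, the alternate allele breaks one Watson-Crick pair (a mismatch,
  not a wobble, unless specified). MAF values are drawn from [0.03, 0.5],
  so every planted SNP passes the inclusive ≥ 0.03 frequency filter.
* `gen_mirsnp_fixture()`: the recovery fixture. A 20-nt planted miRNA, a
  "family" of 30 carriers each bearing one of five 7-nt tiles of it
  (offsets 0, 3, 6, 9, 13), five unrelated sequences, and one UTR holding
  the perfect site with a seed-position SNP. The tile family makes the
  discovered patterns *tile* the planted site, so island calling fires at
  the default window/threshold; the disrupting allele removes the covering
  tile hits, and the island (if any remains) no longer reaches the SNP.
  The fixture's config sets `min_support = 6` (the per-tile carrier
  count), the study condition under which the tiles are recoverable.
* `gen_five_mirsnp_fixture()`: a deterministic five-SNP set whose verdicts
  follow structurally from the construction — two alleles that both
  mismatch the miRNA at a non-seed position (`equal`), an intact
  Watson-Crick pair turned wobble or mismatch (`stronger:` the intact
  allele, with alt alleles chosen so the stronger alleles read A, C, C),
  and a 7-nt decoy region matched by five nested planted fragments but
  alignable by no miRNA: a 7-nt island (padded to the aligner's 8-nt
  minimum) cannot yield 40 points and 6 seed pairs simultaneously unless a
  corpus sequence nearly complements the whole window, which the
  construction avoids by keeping decoy fragments out of carrier seed
  registers. A poly-A moat isolates the decoy island so hit clusters
  elsewhere cannot merge into it.
* `gen_pedigree()`: nuclear families; founders drawn from Hardy-Weinberg
  proportions at per-SNP allele frequencies in [0.2, 0.8], children by
  Mendelian transmission, then child genotypes flipped to inconsistent
  values at the requested rate (trios whose parental pair admits all
  genotypes are skipped — AB×AB errors are undetectable by trio rules, an
  inherent blind spot, not a generator artifact) and genotypes masked at
  the missingness rate. Ground truth is returned for sensitivity checks.

What passing tests on these fixtures shows: the machinery recovers planted
structure at documented thresholds, agrees with independent oracles, and
introduces no systematic allele asymmetry (SNPs in unstructured sequence
classify overwhelmingly as `no_island`/`equal`). What it does not show:
that the default thresholds are biologically calibrated for real mirbase
corpora and real UTRs — real miRNA families share seeds rather than
arbitrary tiles, real UTRs have composition bias and repeats, and real
binding involves thermodynamics and accessibility that a complementarity
score ignores. Parameter choices for real data remain the user's.

## Numerical and implementation notes

* Coordinates are 0-based half-open everywhere inside the package;
  conversion to and from 1-based happens only at VCF ingestion and FASTA
  substring extraction. UTRs are sense-strand DNA; miRNAs RNA; patterns
  are matched against UTRs in DNA space.
* Islands shorter than 8 nt are padded symmetrically (within UTR bounds)
  to the aligner's minimum window before ranking.
* Alignment scores are exact floating-point sums of integer-valued
  defaults; the HWE test works in log space and its p-values match a
  full-enumeration oracle to 1e-9 for n ≤ 200.
* Determinism: with the default significance method the whole pipeline is
  RNG-free; with Monte Carlo it is a pure function of the seed. Two runs
  with identical config and seed produce byte-identical reports; ordering
  ties are always broken totally (byte order, never locale collation).
* Study sizes in the test suite — 500 oracle corpora, 1,000 scanned UTRs,
  200 duplex instances, 100 recovery fixtures — are the sizes at which the
  brute-force oracles remain exact and fast; the corresponding properties
  are size-independent.

## Known limitations

* Complementarity alignment is not a free-energy model; wobble-rich or
  bulged sites that fold well may be under-scored.
* The island rule is a windowed hit count, a declared stand-in for an
  enrichment statistic; it has no p-value.
* Trio-based Mendelian checking cannot see AB×AB transmission errors or
  second-degree (grand-parental) inconsistencies.
* VCF ingestion maps positions through a plus-strand transcript offset
  table only; genome-coordinate liftover is out of scope.
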