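---
title: "SynBridge: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SynBridge: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

SynBridge reimplements the bespoke computational stages that sit between a
short-read draft assembly of a diploid plant genome and its comparative
and population-genetic analysis.  This vignette documents the models each
stage assumes, the tunable parameters and their defaults, what the
synthetic-data generators do and do not emulate, and the numerical choices
made where the methods leave room.

## k-mer sizing

Sequencing depth is estimated from the k-mer multiplicity histogram as
$N = M \cdot L / (L - K + 1)$, converting the peak *k-mer* depth $M$
(reads of length $L$ contain $L-K+1$ k-mers) into *read* depth, and genome
size as total bases over $N$.  The error k-mers produced by sequencing
mistakes dominate the lowest multiplicities, so `findKmerPeak()` scans
from $m = 1$ to the first local minimum and takes the maximum count
beyond it; ties resolve to the smaller multiplicity for determinism.  A
histogram that only decreases has no coverage peak and is an error.
Because $M$ is an integer, the estimate carries a quantisation error of
up to $0.5 / (\text{k-mer depth})$ — about 2–3 % at 20× coverage with
$K = 22$, $L = 100$ — which bounds how well genome size can be recovered
at low coverage; the recovery tests therefore run at 25× and 40×.

## Synteny-bridge super-scaffolding

The stage assumes gene order is conserved between the target and two
related reference genomes over block-sized spans.  Collinearity is an
*input* (MCScanX-style text; computing it is out of scope); the package
contributes what happens next:

1. **Recent-peak selection.** Each block's median Ks is a proxy for the
   age of the duplication/speciation event that created it.  Orthologous
   blocks form the lowest mode of the block-Ks distribution; ancient
   whole-genome-duplication blocks form higher modes and must not seed
   links.  A kernel density estimate (Silverman's bandwidth, 0.005 grid)
   is cut at the first local minimum after the lowest mode.  A unimodal
   density means no ancient peak is present; all blocks are kept with a
   warning rather than inventing a cutoff.
2. **Link derivation.** Two blocks adjacent on a reference chromosome
   that land on different target scaffolds imply that the facing ends of
   those scaffolds are joined: a block whose anchors run in the same
   direction as the scaffold coordinate points out of the scaffold tail,
   an inverted block out of the head.  Identical links from several
   references merge with accumulated support.
3. **Consensus chaining.** `minSupport = 2` by default: with two external
   reference genomes, a junction must be implied by both.  At a scaffold
   end touched by several surviving links the strictly highest-support
   link wins; a tie drops them all.  This precision-first conflict policy
   is a design choice — the alternative (keep an arbitrary tied link)
   inflates contiguity at the cost of misjoins, and a genetic map can
   rescue unjoined scaffolds later, while a misjoin propagates.  The
   surviving graph has end-degree ≤ 1, so components are paths or simple
   cycles; cycles (impossible for a linear chromosome) are broken at
   their lowest-support link.
4. **Output.** AGP v2.1, components alternating with 100 bp `N` gaps
   (gap type `scaffold`, evidence `align_genus`).  The gap length is a
   placeholder, configurable; synteny evidence says nothing about
   physical gap size.  Internally coordinates are handled 0-based
   half-open and emitted 1-based inclusive in AGP/GFF3.

Blocks need ≥ 2 anchors, otherwise their orientation is undefined and
they are dropped at parse time with a warning.

## Genetic-map anchoring

GBS genotype calls are processed in three steps before anchoring.  Depth
gating masks calls under 10 reads (the published rule's "over 10" is read
as ≥ 10 and is configurable) and drops sites monomorphic after masking.
Co-segregating sites — maximal chains of same-scaffold sites, each within
1 kb of the previous, with pairwise consistent genotype arrays — collapse
to the member with fewest missing calls.  Consistency under missing data
is defined as agreement wherever both calls are non-N; a strict
identical-array mode is also provided since the published description
does not fix this.  The greedy chain rule is idempotent on
segregation-realistic data (distance-broken chains stay more than a
window apart; consistency-broken chains have segregation-incompatible
representatives); a contrived fixture in which a chain-breaking site is
consistent with the next chain's representative could merge further on a
second pass, which we note as a formal limitation.

Segregation distortion is tested per site by a χ² goodness-of-fit of the
A/H/B counts against the F4 single-seed-descent expectation
(7/16, 1/8, 7/16), α = 0.01, no multiplicity correction — the simplest
test consistent with a "distorted markers removed" description; both the
expectation and α are parameters.  Sites with fewer than 20 calls are
untestable and retained with a flag.

Anchoring assigns each component (scaffold or super-scaffold) to the
linkage group of its markers, orders components by median cM, and orients
by the sign of the Kendall concordance between component-internal
physical position and cM.  A component anchored by a single distinct
position cannot be oriented and is emitted as `?`.  Components whose
markers span several linkage groups are flagged as conflicts and left
unplaced by default (a majority-rule placement mode exists); how such
scaffolds were handled in practice is not documented anywhere we could
follow, so the conservative default refuses to guess.  Linkage-group
construction itself (grouping/ordering, e.g. regression mapping with the
Kosambi function in JoinMap) is out of scope: the map is an input, real
or simulated.  Super-scaffold/map consistency asks whether a chain's
members' median cM values are monotone in chain order after the better
global flip, all on one linkage group.

## Variant-site filters

Four site-level rules, all strict inequalities as documented:
RMS mapping quality < 30; depth > 2 × the genome-wide mean depth (a
duplicated-region signature — two collapsed copies attract twice the
reads); more than 4 zero-MQ reads; zero-MQ fraction above 10 %.  Reasons
accumulate, a site may fail several rules, and sites with missing
statistics are excluded as `no_stats` rather than passed silently.  The
"sequence coverage" baseline is the mean depth over callable sites; the
published text does not fix the averaging base, so it is a parameter.
Coding effects are annotated by in-frame translation on the coding
strand through the gene's exon structure; the summary reports SNPs/kb
over the mapped-region length supplied by the caller.

## Selection scan

Wild-relative ortholog CDS are reconstructed by substituting sample SNPs
into the reference CDS through exon structure and strand; INDELs are not
applied (they would break the frame and the equal-length guarantee), and
reconstructions that create an internal stop are flagged and excluded
from Ka/Ks by default.

Ka/Ks uses Nei–Gojobori (1986) counting: per-position synonymous site
fractions (changes to stop codons count as nonsynonymous, so
S + N = 3 × codons — a convenient conservation property), substitution
counts averaged over all single-step pathways between differing codons
(stop-traversing pathways excluded, with an all-pathways fallback when
every pathway is blocked), sites averaged over the two sequences, and the
Jukes–Cantor correction $d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$, which
is undefined at $p \ge 3/4$ (the pair is flagged saturated).  NG86 was
chosen because the published analysis names no counting method and NG86
is the minimal fully-specifiable standard; the implementation is verified
against an exhaustive, independently written codon-pathway oracle over
all sense-codon pairs with ≤ 2 differences at 10⁻⁹.  The ratio is
reported `NA` when Ks = 0 rather than ∞, and such genes fall outside all
peak bins.

Peak bins default to [0.1, 0.3), [0.4, 0.6), [0.6, 0.9]: the outer two
follow the stated widths of the second and third selection-pressure
peaks; the first peak is only ever described by its mode (0.2), so its
bin takes the same ±0.1 width, a documented decision.  The shared
boundary at 0.6 goes to the third peak via half-open bins.  Conserved
ortholog groups are selected by relative standard deviation of protein
length (population SD over mean) below 10⁻⁵.  Divergence time is
$T = K_s/(2r)$ with $r = 6.1 \times 10^{-9}$ substitutions per site per
year — the factor 2 (divergence accumulates along both lineages) is the
standard reading and reproduces the published pairing of Ks ≈ 0.65 with
~53.3 MYA.

## QTL translation

A marker is located in the unique synteny block whose source-genome span
contains it and interpolated linearly between the flanking anchor pair's
target positions; inverted blocks reverse the axis automatically because
their anchor target coordinates decrease.  Interpolation between nearest
anchors (rather than whole-block linear scaling) is robust to non-uniform
intergenic expansion within a block.  Positions outside the terminal
anchors clamp to them rather than extrapolating out of the block.
Overlapping blocks make a marker ambiguous, and all candidates are
reported rather than silently picking one.  Intervals translate endpoint
by endpoint (reordered so start ≤ end), splitting at block boundaries.
Both point and interval translation are provided since the published
marker projection does not say which was used.

## Synthetic-data generators

The generators exist so that every stage can be tested against known
truth; their defaults are the study conditions the pipeline emulates.

* `simulateGenomes()` builds gene-order genomes: rearrangements operate
  on whole gene-index intervals (synteny anchors are genes, so
  breakpoints inside genes would be unobservable anyway) and scaffold
  breakpoints fall between genes, minimum two genes per scaffold so
  orientation is always inferable.  Gene spacing is uniform (300 bp CDS,
  700 bp intergenic); scaffold identifiers are assigned in shuffled
  order so they carry no positional information.  Anchor Ks values are
  drawn around a recent mode (0.15 ± 0.03) for orthologous runs and an
  ancient mode (0.65 ± 0.05) for optional decoy blocks.
* `simulateF4Population()` propagates each line F1 → F4 by three selfing
  generations, with per-interval recombination from the inverse Kosambi
  (or Haldane) mapping function and no interference beyond it.
  Distortion is planted as biased transmission: heterozygous parents
  transmit the A allele with probability 0.7 at distorted markers — a
  stand-in mechanism chosen because the observed distortion in
  wide-cross populations is attributed to the cross itself without a
  stated mechanism; the bias acts per marker, which weakens local
  linkage around a distorted marker slightly.  Missing calls are masked
  independently at the requested rate; 133 lines and ~1 % missing are
  the emulated design.
* `simulateVariants()` plants violations of each filter rule in disjoint
  site subsets and tags every site with the fate the rules imply and its
  codon-table coding effect.  Site statistics are drawn directly — there
  is no read-level simulation, so alignment artefacts correlated across
  neighbouring sites are not emulated.
* `simulateCdsPairs()` evolves a derived CDS by proposing point
  mutations at `branchLength` (default 0.2) proposals per site and
  accepting synonymous changes always, nonsynonymous with probability ω,
  stops never.  The default transition:transversion ratio is 1: NG86
  counts sites assuming unbiased mutation, so an unbiased generator is
  the setting in which the estimator's truth is well-defined; raising
  the ratio introduces the classic NG86 bias and can be used to study
  it.

All generator randomness sits behind a single integer seed; the same
seed reproduces outputs bit for bit.  What passing tests on these
fixtures shows is that the *rules and estimators* are implemented
correctly; real data add mapping artefacts, nonuniform gene spacing,
segmental duplications and genotyping error modes that the generators do
not attempt.

## Problem sizes and checks

The test suite and the acceptance script exercise: super-scaffolding at
200 scaffolds over 800 genes and two references (recovery with zero
rearrangements is complete, with no false joins); F4 processing at 133
lines, 11 linkage groups, ~260 marker sites with 10 % planted distortion
(≥ 90 % of planted markers removed, ≈ α of clean ones); variant filters
at 440 sites with 8 % planted violations per rule (fates match truth
exactly); dN/dS recovery at 200 genes × 500 codons per ω ∈ {0.2, 0.5,
0.8} (mean estimates within ±0.1, ≥ 80 % of genes in their generating
peak bin); and the full demonstration pipeline twice per seed to confirm
byte-identical artifacts.  These sizes keep a full run to a few minutes
on one core while leaving the statistical checks well-powered.

## Known limitations

* Link derivation works at block level; a single block spanning two
  scaffolds (anchor-level evidence) is not currently used as a link
  source.
* The co-segregation merge's formal non-idempotence corner described
  above.
* Effect annotation assumes the supplied CDS matches the reference
  genome at SNP positions; disagreements warn and trust the CDS.
* The peak-membership counts of real comparisons depend on the (unnamed)
  original counting tool; only the binning rules, not those counts, are
  reproducible.
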