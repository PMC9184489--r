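---
title: "Methods: species assignment from target-enriched sedaDNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: species assignment from target-enriched sedaDNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Lake-sediment cores archive traces of the DNA of organisms that lived around
the lake. After hybridization capture of a chloroplast genome, a sediment
sample yields millions of short, damaged read pairs of which only a small
fraction (on the order of 1%) derives from the target genus. For two closely
related congeners — here modelled on the Siberian larches *Larix gmelinii*
(including *L. cajanderi*) and *L. sibirica*, whose chloroplast genomes are
collinear and nearly identical — species-level information lives entirely in
a small panel of *diagnostic sites*: positions at which every reference
genome of one species group carries one base and every genome of the other
group a different base. A 30 bp molecule covering one such site is
informative about species; everything else is not.

`sedadiag` implements that chain end to end: diagnostic-site discovery from
labelled reference genomes, k-mer confidence filtering to the target genus,
paired-end merging, mapping, per-site species assignment with per-read
majority votes, satellite-repeat nucleotide-frequency profiling, and
deamination-based authentication — together with a fully seeded simulator
whose truth tables make every step testable.

## Diagnostic-site discovery

Reference genomes are aligned to a single anchor genome (for the published
larch panel, GenBank `MK468637.1`), which defines the coordinate system of
every downstream table. The aligner assumes collinear congeneric organelle
genomes — it chains **unique shared 21-mers** by a longest-increasing-
subsequence pass and closes the gaps between anchors with banded global
alignment at unit edit costs (band `2 x |length difference| + 32`). Circular
genomes are first rotated to the anchor's origin, GenBank organelle records
having arbitrary origins. It is deliberately not rearrangement-aware:
genomes that cannot chain at least 10 anchors fail loudly rather than
silently misalign. 21-mers are effectively unique in a ~120 kb chloroplast
genome; the band bounds memory while always admitting a feasible path.

A column of the resulting alignment is called a diagnostic site iff

1. it maps to an anchor position (insertion columns are never sites),
2. no genome has a gap or `N` in it, and
3. each group is fixed for a base and the two bases differ.

Indel columns are excluded by construction: the assignment target is a
single base observed on reads down to 30 bp, and point differences are the
only variants such reads can vote on reliably. The site table records
whether each allele pair is a transition (`C/T` or `A/G`), because those
sites are confoundable with deamination damage (below).

Internally all coordinates are 1-based closed intervals (the R and
Bioconductor convention); every emitted table is 1-based, as GenBank-style
reports expect.

## The k-mer confidence classifier

Reads are pre-filtered to the target genus with a small LCA classifier: each
canonical k-mer (k = 21 by default, lexicographic minimum of k-mer and
reverse complement) of the reference set is assigned to the lowest common
ancestor of the genomes containing it in a user-supplied rooted taxonomy.
For a read, the candidate label maximises the summed k-mer support along its
root-to-node path; ties resolve to the LCA of the tied nodes — conservatism
by construction, a genus call rather than an arbitrary leaf. **Confidence**
is that path support divided by *all* k-mers queried from the read, and a
read is kept only at confidence ≥ 0.8 by default — a deliberately
conservative threshold that sacrifices recall for precision, which is the
right trade when 99% of the library is non-target. This is an explicitly
simplified classifier (no minimizers, no spaced seeds); what downstream
analysis depends on is the confidence-threshold semantics, not any
particular classifier's internals. Paired reads are classified on the
merged fragment when merging succeeds, otherwise on the two mates joined by
an `N` run that contributes no k-mers.

## Mapping, assignment and the per-read vote

Merged molecules at least 30 bp long (the minimum usable molecule length for
this data type) are aligned to the anchor genome semi-globally — the read
end to end, reference end gaps free — with unit edit costs, both strands,
seeded by exact 16-mer diagonals. Alignments with more than 10% edits per
aligned base are discarded (`max_div = 0.1`, sized to admit terminal damage
plus interspecific divergence on short reads); equal-score hits at distinct
loci flag the read ambiguous, and ambiguous reads are excluded from site
calling rather than placed arbitrarily, since organelle repeats would
otherwise inject false calls.

One numerical choice deserves a note: among co-optimal alignments the
traceback minimises the **gap count** as a secondary criterion
(lexicographic DP). Under unit costs, a terminal mismatch is co-optimal with
a terminal indel; a tie-break that tolerates indels systematically converts
terminal deamination mismatches into insertions or deletions and visibly
flattens the damage profile. Minimising gaps second keeps the edit distance
exact while leaving terminal substitutions aligned.

PCR duplicates are removed as alignments sharing start, end, strand and an
identical sequence (one representative kept; idempotent). Each surviving
alignment then emits one observation per covered diagnostic site (sites
under read deletions emit nothing): the strand-resolved base, its species
call (`A` allele, `B` allele, or `other`), and its distance to the nearest
molecule terminus. A read's species is the **majority of its site calls**,
`other` ignored; ties and zero informative calls leave it unassigned.
Published sedaDNA species-assignment figures show per-site percentages and
per-sample species totals without committing to a per-read rule, so the
majority vote is this package's explicit assumption — robust to a single
damage or error hit on multi-site reads, and reported alongside the raw
per-site counts so either view can be used.

### Damage masking

Deamination converts `C→T` (and, read on the other strand, `G→A`) — exactly
the allele pairs of transition-diagnostic sites. Observations at transition
sites within `mask_m = 5` bp of a molecule terminus can therefore be masked
(`mask_on`). Masking is **off by default**, since the reference workflow
does not describe masking; it is implemented and surfaced because the
simulation shows the mechanism directly: with heavy damage and an all-`A`
read set over a transition-heavy panel, masking strictly reduces the
fraction of calls attributed to the absent species (the acceptance suite
asserts this strictly). The masking width matches the region where
`exp(-lambda * i)` keeps the damage probability appreciable for typical
decay rates (at `lambda = 0.3`, damage at i = 5 is ~22% of its terminal
value).

## Damage profiling and authentication

For every alignment, aligned bases are put in molecule orientation; `f_CT[i]`
is the fraction of reference-`C` positions at distance `i` (0-based) from
the 5' end read as `T`, and `f_GA[i]` the mirror quantity from the 3' end,
each over a `w = 25` bp window. The package's damage model is a
single-exponential per strand,

`f(i) = e + d0 * exp(-lambda * i)`

with terminal amplitude `d0`, per-base decay `lambda` and background rate
`e` — a parameterisation of the qualitative "terminal substitution excess"
signature, not the full Briggs overhang model: single-stranded library
chemistry measures C→T at both molecule ends, and the simulator and profiler
share one convention (C→T from 5', G→A from 3') so the estimator is
internally testable. The fit is bounded weighted nonlinear least squares
(`minpack.lm::nlsLM`; weights = position denominators; `d0, e` in [0, 1],
`lambda` in [0, 5]; initialised at `e = min f`, `d0 = f[0] - e`,
`lambda = 0.3`). A flat profile returns `d0 = 0` with a flag instead of an
error, and an optimiser failure falls back the same way — a zero-damage
sample is a result, not an exception. One identifiability guard is built in:
as `lambda → 0` the decaying term becomes exchangeable with the background
`e`, so an undamaged profile can formally fit as `d0 = e, lambda = 0`. The
fitted amplitude is therefore kept only when the exponential model beats the
constant model in a nested weighted-RSS comparison (F ratio ≥ 4 for the two
extra parameters); otherwise the estimate collapses to `d0 = 0` with the
amplitude attributed to `e`, which is what a flat profile means.

`authenticate_damage()` reports a bootstrap interval for `d0` (200
resamples of alignments by default), the sign of the Spearman correlation of
`f_CT` with distance, and a verdict: `consistent with ancient` needs
`d0 ≥ 0.05` and a negative decay; fewer than 100 alignments give
`insufficient data`. The 0.05 amplitude is a surfaced package default — a
practical floor under which terminal excess is not distinguishable from
background at typical depths — not a community constant.

## Satellite-repeat profiling

Reads from tandem satellite arrays (the larch case: a 173 bp motif arranged
in large arrays) are mapped in wraparound phase: semi-global alignment
against the motif concatenated `ceiling(len/P) + 1` times, both strands,
best edit distance, phase = start modulo `P`. The per-sample profile tallies
every aligned base at its motif position; positions with zero coverage carry
undefined frequencies and are excluded from comparisons — sparse ancient
coverage makes that the only defensible treatment. Cross-sample constancy is
summarised as the mean (over positions covered in both samples) of the
total-variation distance between base-frequency vectors, plus a
per-position maximum spread that localises any single divergent position.
The constancy statistic is this package's definition; the underlying
observation it quantifies ("nucleotide frequencies look the same in every
sample") is otherwise purely visual. The repeat divergence ceiling is
`max_div = 0.15`, looser than the chloroplast mapper's because array copies
themselves diverge ~5% from the consensus before damage is added.

## What the simulator emulates — and what it does not

The generator produces truth-labelled inputs with the statistical structure
the analysis assumes:

| feature | default | rationale |
|---|---|---|
| read layout | 2 × 250 bp paired-end | capture libraries sequenced long enough to read through short inserts |
| fragment length | lognormal, median 70 bp, sd(log) 0.35, truncated [20, 500] | sedaDNA fragments are tens of bp; no empirical length distribution is published for these libraries, so the lognormal is a configurable stand-in |
| damage | `d0 = 0.3`, `lambda = 0.3`, `e = 0.01` | strong terminal deamination typical of authentic Late-Pleistocene material |
| sequencing error | 0.001/bp | modern Illumina substitution rates |
| on-target fraction | 1% (`background_frac = 0.99`) | the observed order of magnitude for genus-level reads after chloroplast capture from lake sediments |
| PCR duplicates | rate 0.2 | consistent with the reported scale of duplicate removal in such libraries |
| repeat motif | `P = 173`, 200 copies, 5% copy divergence | the dominant larch satellite's period and a realistic array divergence |
| diagnostic panel | 157 sites in a 120 kb genome | the published inter-group difference count over a chloroplast-sized genome |

Adapter read-through uses one fixed, documented adapter so trimming is
deterministic. A single master seed drives labelled child streams per stage,
so any stage regenerates independently and byte-identically.

Deliberately not modelled: capture-efficiency/bait-tiling bias, GC bias,
indel sequencing errors, polymerase-specific error spectra, within-group
phylogeographic structure beyond implanted polymorphisms, and the Briggs
overhang geometry. Green tests therefore certify the estimators against
clean binomial/exponential structure — they bound implementation error, not
the biases real capture data add on top.

## Validation design and problem sizes

Each operation is checked against an independent oracle rather than against
itself: the site caller against a literal per-column scan; pairwise genome
alignment against base R's Levenshtein distance; the seeded semi-global
mapper against full dynamic programming on windows; the wraparound motif
mapper against exhaustive best-of-all-rotations alignment; the damage
estimator against closed-form binomial expectations and exact-curve
inversion (recovery to 1e-6 from a noiseless profile). Statistical
assertions use 3–4 standard-error bands derived from the generating model.

The shipped suites run at sizes chosen to keep the full validation under a
few minutes on one core while leaving comfortable statistical margins:
truth-panel exactness over 20 seeds at 120 kb × 10 genomes; mixture recovery
at ~2,000 informative reads (single seed ±3 pp; 50-seed mean ±1 pp);
damage recovery at 50,000 fragments (`d0` ±0.03, `lambda` ±0.1, null
`d0 ≤ 0.005`); repeat constancy at 5,000 reads per sample (mean TV < 0.02).
`scripts/acceptance.R` recomputes the same headline quantities from scratch
under a caller-supplied seed.

The one quantity that cannot be recomputed offline is the accession-based
panel statistic: the 20 published chloroplast genomes are fetched by
`analysis/00_download_references.R` (network required, ~2.5 MB once), after
which the same `build_panel() → align_to_anchor() → call_diagnostic_sites()`
path applies. Whether the published count of 157 inter-group differences
includes indel positions is not documented; this package counts
substitutions only, and that assumption would be the first place to look if
the recomputed count deviates.

## Known limitations

- The anchored aligner assumes collinearity; a genuine rearrangement between
  reference genomes fails the anchor-chaining check instead of being
  resolved.
- The classifier is a minimal LCA scheme; its confidence denominator
  (all queried k-mers) differs subtly from production classifiers'
  treatment of ambiguous k-mers. Nothing downstream depends on that
  distinction.
- Per-read majority voting has no genotype-likelihood machinery; at very low
  coverage a single damaged site can still flip an individual read's vote
  (masking exists precisely for the transition-site case).
- Negative-control screening subtracts per-site counts; read-level totals
  are carried over unchanged because control reads cannot be matched to
  sample reads at the matrix level.
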