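---
title: "Methods: from mapped read pairs to conformation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from mapped read pairs to conformation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hicontact)
```

hicontact analyzes genome-wide chromosome-conformation (Hi-C) data starting
from *mapped* paired-end reads: each accepted read pair is one observed
spatial contact between two genomic positions. The package covers the whole
desk-side analysis chain — pair filtering, binned contact matrices,
normalization, correlation/significance/enrichment statistics, reciprocal
translocation detection with matrix correction, and spatial interaction
networks over genes and transcription-factor binding sites (TFBS) — plus a
seeded generator that synthesizes inputs with the statistical structure the
methods assume. This vignette explains each model, its assumptions, the
tunable parameters, and the numerical choices we made where the design was
genuinely open.

## Pair classification and filtering

Aligners report one or more candidate locations per read end. Two
strategies turn candidate sets into contacts:

* **`strict_unique`** (default): keep a pair only when both ends map to
  exactly one location. This is the stringent choice and the default
  because it minimizes mapping ambiguity at the cost of discarding some
  usable pairs.
* **`four_case`**: additionally rescue pairs where one or both ends have
  exactly two candidates. When one end is unique and the other has two
  candidates, the pair is plausible only if one candidate lies within the
  expected DNA insert length (2000 bp, the library's average insert) of
  the unique end. The rules state when such a pair is *valid* but not
  which location to record; we take the nearby candidate to be the
  physically linked insert end, so the *other* candidate — the one that
  carries long-range information — becomes the contact partner. When both
  ends have two candidates (A,B / C,D), the pair is kept if |A−C| and
  |B−D| are both below the read length, and the first candidates (A, C)
  are emitted; this is an arbitrary but deterministic choice, documented
  here because the source rules are silent. Ends with three or more
  candidates are always discarded.

Two post-classification filters follow: same-chromosome contacts closer
than `min_separation` (default 2000 bp, boundary inclusive — a pair
exactly 2000 bp apart is kept) are removed as likely self-ligation or
unligated fragments, and duplicates are *kept* by default (`dedup =
FALSE`) since collapsing PCR duplicates is a separate decision we do not
impose. Every input record is counted exactly once in the filter
statistics, either as accepted or under one rejection reason.

## Contact matrices

Contacts are counted into fixed-resolution bins; position `p` (1-based)
falls in bin `floor((p-1)/resolution)`, half-open bins, last bin short.
Intra-chromosomal matrices are stored symmetrically (each contact
increments `M[i,j]` and `M[j,i]`; same-bin contacts increment the diagonal
once). One consequence worth knowing: when aggregating a fine matrix into
coarse bins, a coarse *diagonal* cell equals `(block_sum +
block_diagonal_sum)/2`, because symmetric storage counts distinct-bin
contacts twice inside the block. Off-diagonal blocks aggregate by plain
summation. 1 Mb is the default comparison resolution; 100 Kb and 10 Kb are
used to localize translocation boundaries. A display cap (default 50
counts) exists purely for heat maps, where short-range contacts would
otherwise saturate the color scale; capped matrices must never enter
statistics.

## Normalization

**Low-coverage bin removal.** Balancing gives every region equal weight,
so noise in sparsely covered bins gets amplified; bins whose row Euclidean
norm is strictly below a threshold are zeroed and masked first. Defaults
follow the coverage regimes of the matrices involved: 10 for
inter-chromosomal maps at 1 Mb and intra maps at 10 Mb, 100 for intra maps
at 1 Mb.

**SCN (sequential component normalization).** Each column is divided by
its Euclidean norm, then each row; the two steps repeat until the matrix
is symmetric. The stopping rule is `max|M − Mᵀ| < 1e-6` (max-abs rather
than a matrix norm — the stricter and simpler metric) with a cap of 1000
passes: coarse maps with dominant diagonals need a couple of hundred
passes, so a tighter cap would warn routinely on ordinary inputs. If the
cap is hit a warning is raised and the last iterate is returned flagged.
At convergence every surviving row has unit Euclidean norm. Zero
rows or columns encountered mid-iteration are left untouched and recorded
as removed bins. For rectangular inter-chromosomal matrices symmetry is
undefined, so the iteration stops when the iterate stops changing
(`max|M_t − M_{t−1}| < tol`). SCN is scale invariant (`SCN(cM) = SCN(M)`)
and idempotent up to tolerance; both properties are tested.

**Distance normalization** divides each intra cell by the mean of all
non-removed cells at the same diagonal offset, removing the dominant
distance-decay trend; afterwards every populated offset has mean 1. Bin
removal happens before distance normalization, so removed bins neither
contribute to nor receive offset means. The combined distance-then-SCN
map is what the correlation analysis consumes.

**Simple scalings** (`x/avg`, `(x−min)/max`, `(x−mean)/sd`) use
whole-matrix statistics, matching their usual use for quick side-by-side
map comparisons.

## Correlation, significance, enrichment

The **correlation map** sets cell `(i,j)` to the Pearson correlation of
rows `i` and `j` of the (normalized) contact matrix; regions sharing
contact partners correlate, which amplifies the plaid (checkerboard)
pattern of A/B chromatin compartments. Full rows are used, including
columns `i` and `j` themselves (the alternative — excluding them — changes
values negligibly at map scale and the simpler definition is kept);
removed-bin columns are excluded, and constant rows are flagged undefined
and stored as 0. Difference maps `|C1 − C2|` and a three-way per-cell
classification (`sign_change` when `C1·C2 < 0`, `unchanged` when `|C1 −
C2| < 1e-9`, else `value_change`) support cross-sample comparison.

**Poisson significance** models off-diagonal raw counts as Poisson with a
single rate λ estimated as their mean (diagonal cells hold local contacts
and are excluded from λ; a per-distance rate is deliberately not used —
this matrix-wide rate asks "is this cell extreme for this map?").
Reported values are strict upper-tail probabilities `Pr(X > m)`; no
multiple-testing correction is applied, matching the descriptive use of
these maps.

**Observed/expected inter-chromosomal enrichment.** With `N` total
inter-chromosomal contacts and `f_i` the fraction of them involving
chromosome `i` (so `Σf_i = 2`), the expected count for pair `(i,j)` is
`E_ij = f_i f_j N` and the report is `N_ij / E_ij`. A subtlety: the map
from counts to fractions has `f'_i = f_i(2 − f_i)/c`, whose only
self-consistent solution is equal fractions — so the "proportional counts
give constant ratios" sanity check is exact only on equal-count fixtures,
and that is how it is tested.

## Translocation detection and matrix correction

A reciprocal translocation joins one segment of each chromosome on a
shared derivative chromosome. In the reference-frame inter-chromosomal
map this shows up as a *corner block* of intra-like dense contacts — and,
because the event is reciprocal, the diagonally opposite corner is
enriched too. Detection scans, for each of the four corners and every
split `(a, b)`, the ratio of the corner-block mean to the mean of the
remaining cells *excluding the opposite corner*; the exclusion exists
because a reciprocal partner block in the "rest" would dilute the score.
A call requires the best coarse-resolution (1 Mb) score to reach
`enrichment_min = 5`; the boundary is then re-estimated at 100 Kb and
10 Kb inside a window of ±2 coarse bins around each boundary, without
re-thresholding. The statistic is a deliberately simple step-fit: the
phenomenon is a sudden, drastic increase, and an exhaustive mean-ratio
search is fully specified, fast at desk scale, and easy to reason about.

Correction keeps reference coordinates and works on the four regions
induced by the breakpoints: `A` (non-translocated × non-translocated) and
`B` (translocated × translocated) are halved, since those contacts pool
two copies; each `C` cell (non-translocated row × translocated column)
has its row's region-`A` mean subtracted, each `D` cell its column's
region-`A` mean, both clamped at zero. Halved counts are kept fractional.
One known limitation: with a truly reciprocal event the second dense
corner falls inside region `A` and inflates the subtracted background
slightly; the correction is still conservative (never negative, never
increases C/D cells).

## Interaction networks

Contacts whose ends fall inside annotated features induce weighted
undirected graphs: nodes are genes (only entries of kind `GENE`;
pseudogenes, RNAs, CDS and UTR entries are excluded) and/or TFBS, an edge
joins two features when their contact count strictly exceeds a threshold,
and the weight is the count. An end overlapping several allowed features
increments *all* induced pairs — any single-assignment rule would need an
arbitrary priority. Threshold 0 gives the "at least one read" network.
Because sequencing depth differs between samples, per-sample thresholds
can be chosen to equalize edge counts: the smallest integer `t` whose
strict network is no larger than the target, with `count == t` edges added
back in deterministic order (weight descending, then lexicographic pair
id) until the target is met exactly.

Graph statistics follow their classical definitions: degree distribution;
unweighted shortest-path-length histogram; clustering coefficient
`2e_n/(k_n(k_n−1))` (0 when `k_n < 2`); closeness as the reciprocal of
the mean distance to reachable nodes (0 for isolated nodes); stress as
the number of shortest paths through a node, counting *all* shortest
paths per pair, with a histogram in power-of-ten bins (0, 1–9, 10–99, …);
and the topological coefficient — the mean, over partners sharing a
neighbor or directly linked, of shared-neighbor counts (+1 for a direct
link), divided by the degree (0 for degree ≤ 1). Scale-free structure is
summarized by a least-squares line through `(log10 k, log10 count)`;
slope and R² are reported. Every statistic is tested against independent
oracles (igraph distances, geodesic enumeration, neighbor-set
arithmetic) on random graphs.

## The synthetic-data generator

`sim_params()` defines the study conditions; `simulate_genome()` and
`simulate_pairs()` realize them deterministically from a master seed, with
one derived RNG stream per component so adding a component never perturbs
the others. The defaults describe a two-chromosome, 5 Mb-each genome with
200,000 read pairs — large enough for stable matrix, compartment and
network structure, small enough that the full pipeline runs in well under
five minutes on one CPU.

What it emulates, and how:

* **Distance decay**: the intra contact rate per locus pair is `d^{−α}`
  (α = 1 by default, the canonical Hi-C decay at these scales).
  Separations are drawn by inverse-CDF on a 1 Kb grid with weight
  `(L − d)·d^{−α}`; the `(L − d)` factor is the number of placements at
  separation `d`, so the *per-pair* rate is exactly `d^{−α}`. Without it,
  near-chromosome-length pairs concentrate into the matrix corner — an
  artifact that mimics a translocation block.
* **Compartments**: alternating A/B labels over 100 Kb bins in blocks of
  geometric length (mean 5 bins); same-compartment pairs are accepted
  with probability ∝ `1 + plaid`, cross-compartment ∝ `1 − plaid`
  (plaid = 0.6), which yields the plaid correlation pattern.
* **Inter background**: uniform random pairs at rate `inter_frac = 0.03`.
  This is deliberately *not* the genome-wide inter fraction of a real
  library: with only one chromosome pair in the synthetic genome, a
  realistic per-pair background is the genome-wide background divided by
  the number of chromosome pairs it would spread over, and 3% of pairs on
  the single simulated pair already sits at the generous end.
* **Mapping artifacts**: exact planted counts (`round(frac·n)`, 10% each
  by default) of multi-mapped records (1–2 decoy candidate locations on
  one end) and short-separation records (< 2000 bp), so filter statistics
  can be checked against ground truth without sampling noise.
* **Translocations**: when requested, pairs are drawn on the derivative
  chromosomes (tail exchange at the breakpoints) and mapped back to
  reference coordinates, so both reciprocal corner blocks and the decay
  across the junction arise mechanically rather than being painted on.

What it does **not** emulate: restriction-fragment geometry, ligation
noise, GC/mappability bias, copy-number variation, or sequence-level
errors. Tests passing on this generator therefore show the *computational*
chain is correct under its stated model; they do not certify behavior on
real libraries with those additional artifacts.

## Problem sizes and numerics

The test suite and the acceptance script use: 1,000-record tables for
filter-statistics recovery; ~1,500–20,000 pairs for conservation and
normalization properties; 100,000 pairs per replicate for translocation
recovery (20 planted) and specificity (100 clean genomes); and the full
200,000-pair default fixture for the end-to-end reproducibility and
compartment checks. These sizes were chosen as the smallest at which the
stochastic properties are stable. Numerical details worth restating:
SCN tolerance 1e-6 / 1000 iterations; Poisson tails via `ppois(...,
lower.tail = FALSE)` (tested to 1e-12 against direct pmf tail sums — the
naive `1 − head sum` form loses precision exactly where p-values are
interesting); equalization and case-4 tie-breaks deterministic as
described; all breakpoints reported on 10 Kb boundaries, the finest
default detection resolution.
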