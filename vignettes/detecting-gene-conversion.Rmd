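---
title: "Detecting and dating ectopic gene conversion between paralogs"
author: "paraconv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and dating ectopic gene conversion between paralogs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paraconv)
```

# The problem

Gene clusters evolve by segmental duplication, and the resulting paralogs do
not diverge independently: non-allelic (ectopic) gene conversion
recombination events overwrite a tract of one paralog with the homologous
sequence of another, locally resetting their divergence. Conversion
distorts duplication-age estimates, confuses orthology assignment, and is
itself of biological interest (converted tracts in disease-associated genes,
concerted evolution of globin and cytochrome clusters, and so on).
`paraconv` detects conversion tracts between paralog pairs using cluster
sequences from several species, collapses redundant detections of one
historical event, and places each event on the species tree.

# The triplet and quadruplet tests

## Setup

For one *primary* species A, take a pair of paralogs A1, A2 (an
intra-species pairwise alignment) and the positional ortholog B1 of A1 in an
*outgroup* species B that split from A after the duplication. If the
duplication predates the speciation, A1 is expected to be closer to its
ortholog B1 (speciation-age divergence) than to its paralog A2
(duplication-age divergence) — everywhere except inside a converted tract,
where A1 and A2 have been homogenised and the ortholog comparison suddenly
looks old.

## The cumulative-score walk

Walking across the columns of the A1–A2 alignment, a column is *informative*
when exactly one of {paralog A2, projected ortholog B1} carries the same
nucleotide as A1. The walk takes a **+1 (up)** step when A1 matches the
ortholog but not the paralog — the state expected under the
duplication-before-speciation null — and a **−1 (down)** step when A1
matches the paralog but not the ortholog, the homogenisation signature of
conversion. Columns with gaps, ambiguity codes, or no ortholog coverage
contribute nothing. With `m` up and `n` down steps the walk drifts upward
under the null (P(down) ≤ 0.5), and a converted tract appears as a
concentrated run of down steps: a deep *maximum descent*.

A note on orientation: the two operational anchors of the method — the
maximum-descent interval *is* the candidate converted region, and down steps
are the rarer kind under the null — fix the sign convention uniquely, and
`paraconv` states and implements it in exactly this form. Descriptions of
this family of tests sometimes label the step directions the other way
around while keeping the same two anchors; only the orientation used here
makes the anchors mutually consistent.

## Maximum descent and its exact P-value

The maximum descent is `k = max over i < j of (S_i − S_j)` of the cumulative
score `S`. Under the null the order of the `m + n` steps is exchangeable (a
hypergeometric random walk), so the significance of `k` is
`P(max descent of a uniformly random ordering ≥ k)`. `maxDescentPValue()`
computes this exactly by a dynamic programme over lattice paths whose state
is (up-steps used, current running-max deficit truncated at `k`), with
sequential-sampling transition probabilities so the mass never overflows.
It is O((m+n)·m·k) time and O(m·k) memory and handles walks with thousands
of informative sites; the test suite verifies it against exhaustive
enumeration of all C(m+n, n) orderings for every m + n ≤ 12.

The descent interval is reported from the innermost peak to the first
trough achieving depth `k` (leftmost among equally deep descents). The
innermost-endpoint rule makes the reported tract invariant under
reverse-complementing the input cluster; leftmost-on-ties is an arbitrary
deterministic choice.

## Quadruplet combination and direction

When both paralogs have orthologs (B1 and B2), the two triplet walks
[A1, A2, B1] and [A2, A1, B2] are combined column-wise: a step present in
only one walk is kept as is; concordant steps add to magnitude 2 (opposite
steps cannot occur, because both triplets share the same paralogous
nucleotide pair). The combination averages out rate variation seen by only
one ortholog.

For significance, the combined walk is scored with **one unit step per
informative site** (the sign of the combined step). This choice is what
keeps the test exact: site step types are independent across columns under
the null, so the order of per-site unit steps is exchangeable and the
maximum-descent distribution applies as-is. Expanding a concordant site
into two unit steps would instead insert pairs of perfectly correlated
steps — on null clusters roughly half of all informative sites are
concordant — and measurably overstates descent depths (about an 11% false
positive rate at nominal 5% in our null simulations, versus 2% for the
per-site scoring). The magnitudes remain available on the combined walk
object for inspection.

Direction is inferred inside the shared descent interval: the recipient's
own ortholog still carries the overwritten sequence, so the
recipient-anchored triplet shows the *higher* down-step proportion there.
The two proportions are compared with Fisher's exact test on the 2×2
up/down table (the standard exact two-proportion comparison; the exact
construction is a documented choice of this package) at
`direction_alpha = 0.05` by default; non-significant differences leave the
direction `"unknown"`.

# Criterion 2: whole-paralog conversions

When the maximum descent spans (strictly) more than `coverage_threshold =
0.80` of the alignment columns, the max-descent null degenerates — at full
coverage its P-value is 1 because no unconverted flank remains — and long
descents are also where alignment-end artefacts concentrate. Such walks are
routed to an alternative criterion: if and only if the two paralogs map to
*distinct* ortholog regions in the outgroup (`distinctOrthologs()`), the
duplication must predate the speciation, whole-length similarity is genuine
evidence of conversion, and significance is the upper binomial tail
P(X ≥ n) with X ~ Binomial(m + n, p), p = min(0.5, n/(n + m)). The
parameter p is estimated from the same observed step counts being tested —
a deliberate, literal implementation of the published construction. The
step counts are taken over the whole paralog alignment (the descent is
nearly the whole alignment in this branch anyway). Paralog pairs whose
orthologs are missing or overlapping (post-speciation duplicates, for which
whole-length similarity is expected) are never called by this criterion.

The 0.80 threshold is configurable; the acceptance sweep in this package
varies it over 0.60–0.95 and finds sensitivity and false-discovery rate
nearly flat around 0.80, so results do not hinge on the exact setting.

# Multiple testing

Every (primary species, paralog pair, outgroup) combination with at least
`min_informative = 10` informative sites counts as one attempted test; the
family-wise level `alpha = 0.05` is Bonferroni-divided by the number of
attempted tests in the run. Combinations below `min_informative` are
reported untested rather than contributing noise calls. Both constants are
`detectionConfig()` settings.

# Redundancy: one event, many observations

A single historical conversion is typically observed several times, and the
observations are collapsed in a fixed order:

* **Type (a)** — across outgroups: within one (primary, paralog pair),
  observations whose converted intervals reciprocally overlap by at least
  `boundary_tol = 0.5` share an event id; the minimum-P observation
  represents the event. Dissimilar boundaries stay separate (repeated
  conversions do occur).
* **Type (b)** — across primary species: an observation between the
  orthologous paralogs of another primary, detected with the *same*
  outgroup, joins the event. The converted interval is mapped between
  primaries through the ortholog alignments before boundaries are compared.
  Observations made with different outgroups are never merged by this rule.
* **Type (c)** — across post-conversion duplicates: two observations
  sharing a target paralog (A1→A3 and A2→A3) with similar boundaries are
  arbitrated by the three percent identities inside the tract,
  S1 = Sim(A1,A2), S2 = Sim(A1,A3), S3 = Sim(A2,A3): S1 maximal means the
  conversion predates the A1/A2 duplication (both observations kept, one
  event); S2 (resp. S3) maximal identifies A1–A3 (resp. A2–A3) as the real
  conversion and removes the other observation. Exact ties are broken
  toward before-duplication — the most conservative reading, since it
  posits the fewest distinct events — with a warning. Dissimilar
  boundaries are separate events.

Applying (a) then (b) then (c) is order-dependent only when some redundant
observations are missing; the order is fixed for reproducibility.
Deduplication is idempotent, and event ids are renumbered by (primary
species, tract start) of the representatives.

# Dating events on the species tree

Edges of the rooted species tree are numbered in depth-first post-order
(each edge keyed by its child node; id 0 is a virtual pre-root marker).
Detection with an outgroup places the event *after* the primary/outgroup
split; per primary the closest detecting outgroup (fewest edges on the
leaf-to-leaf path — topology only, branch lengths are deliberately ignored)
gives the tightest such bound, and with several carrying primaries the most
recent of those edges still ancestral to all of them is the upper bound.
Carriage in several primaries places the event *before* their split: the
edge above their last common ancestor is the lower bound (a single carrier
gives its terminal edge). The event's sub-lineage is the connected edge
path between the bounds, written as hyphen-joined edge ids (e.g. `"4-6"`);
inconsistent bounds yield `"?"`. Absence of detection in a species never
tightens any bound.

# The simulator

`simulateCluster()` evolves an ancestral paralog down a species tree with
branch lengths in expected substitutions per site: Jukes–Cantor point
substitutions; duplications that insert a full copy adjacent to its source;
conversions that overwrite a uniformly placed tract (geometric length,
mean `conv_tract_mean = 500` bp) of a uniformly chosen recipient with the
donor's current sequence. Events can be scripted per branch (including a
pre-speciation stem) for controlled scenarios. Because the histories are
recorded, true gapless paralog and ortholog alignments, the positional
orthology map and a ground-truth log come out for free — no aligner is
involved — and `evaluateDetection()` scores detections against the truth
(reciprocal-overlap matching at 0.5; sensitivity over conversions whose
duplication predates an available outgroup split; FDR 0 by convention when
nothing is detected).

What the simulator deliberately omits: indels, inversions, deletions,
rate heterogeneity across sites and lineages, biased conversion, and
alignment error. Passing tests on simulated data therefore demonstrate the
statistical machinery under clean alignments and clock-like evolution, not
robustness to misalignment — the main real-data failure mode that the
coverage-threshold routing exists to absorb.

## Study conditions used by the tests and acceptance script

Chosen once as realistic for a small primate-like cluster and then left
alone: a three-species clock-like tree `((A:0.03,B:0.03):0.03,C:0.06)`
with a 0.05-substitutions/site stem carrying the ancestral duplication;
root paralog length 1000 bp (calibration, sweep) or 2000 bp (recovery);
one 500-bp tract implanted mid-way along A's terminal branch for recovery;
500 null replicates, 100 recovery replicates, 16 sweep replicates with
tract lengths 100–1000 bp over thresholds 0.60–0.95. All randomness flows
from one integer seed.

# Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally, 1-based inclusive in every
  written table. Minus-strand alignment rows are normalised at read time
  (row 1 forward); projected ortholog bases are complemented when the
  ortholog block reads the shared species on the opposite strand from the
  paralog block, so detection is orientation-free.
* Gap and ambiguity columns are excluded from percent-identity denominators
  and never informative; a window with no comparable columns gives `NA`
  with a warning rather than a number.
* Empty walks have k = 0 and P-value 1; `m = n = 0` is an error for the
  binomial criterion (no informative sites).
* A MAF block is one paralog pair; overlapping blocks are tested
  independently. Projections from several ortholog blocks merge
  first-come per column.
* The converted interval is reported between the first and last informative
  sites inside the descent — conservative, unambiguous endpoints.

# Known limitations

Only intra-species paralog pairs are tested (no cross-species conversion
calls); orthology is taken as given rather than inferred; the binomial
criterion's p is estimated from the tested data (as published), which makes
its P-value conservative rather than exact; direction calls need enough
post-conversion divergence inside the tract and are otherwise `"unknown"`;
and simulator-based evidence carries the idealisations listed above.
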