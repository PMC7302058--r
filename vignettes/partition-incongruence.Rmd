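---
title: "Measuring incongruence between morphological character partitions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring incongruence between morphological character partitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(partcong)
```

## The problem

Morphological matrices for fossil taxa are usually analysed as a whole,
on the principle of total evidence. Yet the characters of the skull and
dentition (the *craniodental* partition) and those of the vertebral
column, girdles and limbs (the *postcranial* partition) are anatomical
modules under different selective and biomechanical regimes, and the
trees they imply in isolation can conflict. partcong implements the
machinery to quantify and test that conflict under maximum parsimony:
dataset curation, heuristic tree search, two families of permutation
tests (length-based and tree-distance-based), a resampling test of which
partition tracks the total-evidence trees, stratigraphic congruence
indices, and cross-study summary statistics over a packaged table of 81
published dinosaur matrices.

## Data model and curation

A `CharacterMatrix` stores each cell as a set of integer state codes
(bitmask): a singleton for a fixed score, a larger set for polymorphic or
uncertain scores (`{..}` and `(..)` NEXUS groups are treated
identically), or an empty set tagged as missing (`?`) or inapplicable
(`-`). Missing and inapplicable are kept distinct in storage because the
curation rule counts both, but they are equivalent in parsimony scoring,
where either contributes the full alphabet and can never force a step.

Curation follows a single pass: first every taxon whose missing plus
inapplicable fraction exceeds 40% of the characters within *either*
analysis partition is removed; then characters rendered
parsimony-uninformative or invariant by those deletions are dropped. Two
separate flags implement "uninformative or invariant": a character that
was informative and no longer is, and a character that was variant (two
or more distinct fixed states) and became constant. The second flag
matters because an autapomorphic character was never informative, yet
must go once its single variant taxon is deleted. The pass is not
iterated to a fixpoint by default (an `iterate` flag exists), mirroring
the stated order of operations. Characters outside both partitions
(integument, eggs, ecology) are labelled `other` and excluded from every
test.

Cell overlap between matrices (`matrixOverlap`) counts shared
(taxon, character) positions — regardless of the scored states — as a
percentage of the smaller matrix's cells; character identity defaults to
exact id match, with an explicit mapping argument for curated
cross-study comparisons.

## Parsimony scoring and search

Tree length is Fitch parsimony (unordered, equally weighted characters),
computed by Hartigan's generalization so that multifurcating trees are
scored exactly. All characters are treated as unordered: source-matrix
ordering schemes are not recorded in the inputs this package reads, and
this is a documented limitation rather than a modelling claim. State
sets are bitmasks (at most 30 states per character), and the C++ engine
evaluates candidate trees during search through directed-edge state-set
"views": for every edge of a (possibly bisected) tree, the Fitch set of
the whole component rooted on that edge. Joining two components then
costs one AND per character, which makes stepwise addition and TBR
evaluation exact but cheap. Exactness rests on the root-invariance of
the Fitch pass on binary trees; search trees are binary until the final
collapse.

The search replicates the classic PAUP*-style protocol: random taxon
addition sequences (ties beyond the per-step hold broken by the seeded
RNG), 10 trees held at each step, TBR branch swapping to a local
optimum, equal-best topologies pooled up to `maxtrees`. Two presets fix
the effort: `paper` (25 addition sequences, maxtrees 100,000, up to 1000
trees per set in nearest-neighbour distances) and `desk` (5 addition
sequences, caps of 100) for simulation studies; the vignette and test
suite use `desk`. One knob is ours rather than classical: `swapmax`
bounds how many stored equal-best trees are themselves swapped per
addition sequence (8 under `desk`), because signal-free matrices produce
plateaus of thousands of equally parsimonious trees and swapping the
whole plateau buys nothing but time. Every search is deterministic given
its seed.

Zero-length-branch collapse follows the contract-and-rescore test: an
internal branch has minimum length zero over all optimal reconstructions
exactly when contracting it leaves the parsimony length unchanged.
Contractions are applied greedily one at a time with re-testing, because
two individually zero-minimum branches can jointly carry length; the
greedy order guarantees the collapsed tree keeps the optimal length,
which the package treats as an invariant of its tree sets. Duplicate
topologies are removed after collapsing.

The ensemble consistency index is `CI = M/S` and the retention index
`RI = (G − S)/(G − M)`, with `m` and `g` per character computed from
fixed singleton scores only (polymorphic cells would otherwise deflate
the bounds). By default only parsimony-informative characters enter the
totals; `includeUninformative = TRUE` reports the variant including
them, since software defaults differ.

## The permutation tests

Both tests compare an observed incongruence statistic against the same
statistic recomputed for random bipartitions of the pooled craniodental
and postcranial characters, in the original proportions. The p-value is
`(1 + #{null >= observed}) / (R + 1)` — ties count toward rejection, and
the attainable minimum is 0.001 at R = 999 (ILD default) and 0.01 at
R = 99 (IRD default). Per-replicate seeds for the bipartition draw and
the two searches are derived independently from the master seed: reusing
one seed for both correlates the taxon-addition order with the drawn
character set, which showed up in calibration as a conservative shift.

The ILD statistic needs only tree lengths, so its searches store a
single tree and skip collapsing. The IRD statistic is either the
symmetrized mean nearest-neighbour distance between the two partitions'
tree sets (both directions averaged; a flag recovers the one-directional
variant) or the distance between their majority-rule-plus-compatible
consensus trees, under the Robinson–Foulds or matching split distance.
The matching distance solves the assignment between split sets exactly
(Hungarian algorithm); unequal split counts — routine once polytomous
collapsed trees appear — are padded with dummy splits costing
`min(|A|, |B|)` against a real split A|B and nothing against another
dummy. Greedy compatible-split ties in the consensus are broken by
frequency, then by the lexicographic canonical form, for determinism.
Tree sets larger than the configured cap are subsampled uniformly with a
recorded seed, and duplicate topologies within a set are ignored, so the
mean is invariant to duplication.

## Which partition tracks the total-evidence trees?

A larger partition contributes more characters to the combined matrix,
so raw distances to the total-evidence trees would favour it. The
jackknife test equalizes sample sizes instead of weighting: with `n` the
size of the smaller partition, each resample uses the smaller partition
in full, the larger subsampled to `n`, and an entire-matrix sample of
`n/2` characters from each partition, the odd extra character
alternating sides across resamples. Each of the three samples gets its
own search, and the two mean nearest-neighbour matching distances
(partition sample to entire sample) form one paired observation. The
winner is the side with the smaller mean across resamples; medians are
reported alongside because both summaries are in circulation. Two
p-values accompany the winner — the paired Wilcoxon signed-rank test on
the resample pairs (the headline value) and the unpaired Mann–Whitney
test — again because both conventions are in use. Entire-sample draws
are independent of the larger-partition draw within a resample; with a
single resample the winner is still reported but both p-values are NA.

## Stratigraphic congruence

Given first-appearance ages (FADs; larger = older), each internal node
of a rooted tree is dated by its oldest descendant FAD and the minimum
implied gap (MIG) sums the positive age drops along branches. With ages
sorted `t1 >= ... >= tn`, `Gmin = t1 − tn` and
`Gmax = sum(t1 − ti, i >= 2)` bound MIG over all topologies, giving
`GER = 1 − (MIG − Gmin)/(Gmax − Gmin)` (undefined and flagged when all
ages tie) and `MSM* = Gmin/MIG` (1 when both are zero). SCI is the
fraction of non-root internal nodes whose clade's oldest FAD is no older
than the oldest FAD of its sister lineages; at a polytomy each child is
compared against the oldest of its siblings. GER* is realized as a rank
statistic: the proportion of random FAD-to-leaf reassignments (10,000 by
default) whose MIG is at least the observed MIG, ties counting, so
larger is more congruent and affine rescaling of the ages changes
nothing. Trees must be rooted — most parsimonious trees are unrooted, so
an explicit outgroup taxon is required — and per-dataset reporting is
the mean across the tree set.

## The synthetic-data generator

`simulateMatrix` evolves craniodental characters on one random binary
topology and postcranial characters on a second obtained by a configured
number of random subtree-prune-regraft moves (each move excludes the
reattachment that would recreate the same topology; the move list is
returned for replay). Characters follow a symmetric k-state Markov
process with 2–4 states per character, branch lengths exponential(1)
rescaled to unit tree length, and gamma-distributed per-character rates
whose mean (`meanChanges`, expected changes per character across the
tree) is the homoplasy dial — raising it lowers the ensemble CI
monotonically. Missing and inapplicable entries are injected at
per-partition rates, optionally concentrated within taxa through a
beta-binomial layer to emulate partial skeletons. Defaults (20 taxa, 100
characters per partition, 30% missing entries, CI landing within roughly
0.4–0.9) sit inside the ranges spanned by the 81 published matrices the
package summarizes. Fixing the seed fixes the whole output.

Stratigraphic ranges derive from the simulation tree's node times: a
tip's true lineage origination age is its parent node's age, and the
observed FAD subtracts exponential undersampling noise truncated at
zero. At zero noise the record is perfect in the origination sense; on
pectinate, age-ordered trees this provably yields GER = 1, but on
balanced trees even a perfect origination record leaves ghost lineages
(sister clades of unequal age force gaps), so GER < 1 is the correct
behaviour there, not a defect. Tests therefore pin GER = 1 on pectinate
generating trees and monotone degradation with noise elsewhere.

What the generator does *not* emulate: correlated homoplasy within
anatomical modules beyond the two-partition split, ordered or weighted
characters, non-stationary state frequencies, and the idiosyncratic
taxon-by-character missingness of real specimens. Passing tests on
synthetic data therefore demonstrate that the machinery measures what it
claims under a known truth — not that any particular empirical result
generalizes.

## Calibration and power: what the test suite runs

The suite exercises the pipeline at sizes chosen to keep a full run in a
few minutes: null calibration uses 100 signal-free matrices of 10 taxa
by 40 characters with i.i.d. uniform 4-state characters and 49
replicates per test. Four states matter: with binary i.i.d. characters
at this size the ILD takes so few distinct values that ties make the
permutation test visibly conservative (zero rejections in 100 matrices;
the expected mean p-value is roughly 0.5 plus half the tie probability),
whereas with four states both ILD and IRD reject within the 95% binomial
band around the nominal 5%.

Planted-signal power uses partitions simulated on trees five SPR moves
apart (20 taxa, 100 + 100 characters, `meanChanges = 1.5`,
`gammaShape = 8`, no missing entries — low homoplasy, chosen so the
partition trees are well resolved; at lower rates too few branches are
supported, at higher rates homoplasy noise dominates). Most seeds reject
strongly, but the requirement that p sit exactly at the permutation
minimum fails in a minority of runs: a random 50/50 bipartition's two
halves occasionally optimize onto opposite "islands" (one near each
generating tree), producing a single null value comparable to the
observed separation. Deeper searches do not remove this — it is a
property of the statistic under balanced, cleanly conflicting signal —
and the corresponding acceptance check is left failing rather than
weakened, with the behaviour documented here. The
dominant-signal-recovery check takes the complementary design: both
partitions at equal per-character rates, but half of the postcranial
characters replaced by i.i.d. noise, so the craniodental side carries
twice the signal-bearing characters; the jackknife test then names the
craniodental partition in every seed. Rate-doubling is deliberately not
used as the "signal weight" dial because it confounds signal with
homoplasy and tree resolution.

## Limitations

* Characters are unordered and equally weighted; step matrices,
  implied weighting and character ordering are out of scope.
* Leaf sets are limited to 64 taxa in the search and distance engines
  (one machine word per split side).
* The heuristic search is exact only in the sense of matching exhaustive
  enumeration empirically at small sizes; like any hill-climber it can
  miss global optima on large, conflict-rich matrices.
* PAUP*'s "amb-" condensation contracts all zero-minimum branches
  simultaneously; the greedy sequential variant used here can retain a
  branch PAUP* would collapse when two collapses jointly carry length,
  in exchange for an exact length-preservation guarantee.
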