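---
title: "Divide-and-graft assembly of time-calibrated phylogenies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Divide-and-graft assembly of time-calibrated phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

phylograft builds large species-level chronograms in three steps: infer and
fossil-calibrate a *backbone* tree from two exemplar species per genus;
*decompose* the backbone into clade-level tasks and infer densely sampled
relative-time trees for each; *rescale and graft* the clade trees back onto
the backbone so that every node age in the final tree sits on one common
absolute timescale. This vignette explains the model assumptions behind each
step, the parameters that matter, the synthetic data generator used for
validation, and the numerical and design choices a maintainer should know
about.

## The pipeline model and its assumptions

**Input data** are homology clusters: sets of putatively homologous DNA
sequences grouped around a seed sequence, with a taxa table mapping every
species id to a genus, and a fossil table of minimum (optionally maximum)
ages for the most recent common ancestor (MRCA) of listed species. Ages are
measured backwards from the present in Ma; tips of a dated tree sit at age
0, and a branch length in a dated tree is the age difference between parent
and child. That invariant is checked (`validate_chronogram()`) at every
module boundary, so a malformed tree fails at the seam where it was
produced.

**Cluster reduction** keeps, per species, the sequences with the fewest
IUPAC ambiguity symbols, breaking ties by the smallest deviation from the
species' median ungapped length, then by sequence id. The paper-level
motivation is to drop short fragments when fuller sequences exist while
avoiding over-long sequences that run into flanking markers. The
ambiguity-first ordering is a package choice: both criteria are stated for
the selection but no precedence is given, and ambiguity content is the more
direct measure of sequence quality. The operation is idempotent, and a seed
sequence that loses its species' ranking is dropped like any other while
its identity and residues are remembered for the merging step.

**Cluster merging** compares only the seed sequences, all-versus-all, using
the Jaccard index of their k-mer sets (k = 8, threshold 0.5 by default) and
groups clusters by single linkage. k-mer similarity stands in for a local
aligner: it needs no external binary, is symmetric, and is monotone in
sequence identity over the divergence range where merging is sensible.
Both values are calibration choices of this package, set once: k = 8 makes
random 60-mer matches rare (expected shared 8-mers between unrelated
sequences are near zero) while tolerating the divergence typical of
congeneric sequences; the 0.5 threshold demands that at least half the
union of k-mers be shared. Groups of aligned clusters are merged by
*profile alignment*: global dynamic programming over column frequency
profiles with sum-of-pairs expected scoring (match +1, mismatch -1,
residue-gap -2, gap-gap 0) and free terminal gaps. The DP never reorders
or deletes residues within a row; score ties prefer the diagonal and then
the path that consumes the most columns, so that aligning beats trivially
stacking the two blocks end-to-end.

**Exemplar selection** picks, per genus, the two species that most often
form the most distal pair. For every alignment with `k >= 2` congeners the
maximal-distance pair (JC69 with pairwise deletion by default) receives a
vote of weight `n - 1`, with `n = k(k-1)/2` the number of within-genus
comparisons in that alignment. Two-species alignments therefore carry zero
weight: a pair that is distal among many comparisons is better evidence of
spanning the genus root than a pair that merely won by default. `n` counts
within-genus comparisons only; the alternative reading (all comparisons in
the alignment) would let unrelated taxa inflate a genus' votes. All ties
are lexicographic on species ids, so selection is deterministic and
independent of input order. Before voting, species that share too few
markers are removed: a species must co-occur with a congener in at least
`min_shared_intra` alignments and with a non-congener in at least
`min_shared_inter` alignments (both default 1; monotypic genera are exempt
from the first rule). The filter is named at the level of "too few"; the
two explicit counts are this package's concretization.

**Supermatrix assembly** is a greedy knapsack: species sorted by ascending
participation (rarest first), each species' candidate alignments visited by
descending taxon coverage, an alignment selected while the focal species
occurs in fewer than `max_markers` selected alignments. Afterwards species
below `min_markers` are dropped and reported; alignments that lose all
their species are pruned so no empty block enters the matrix. The `max`
bound is a stopping rule for the focal species only — other species may
legitimately exceed it through alignments selected on behalf of their
rarer companions. Candidates whose average pairwise divergence exceeds
`max_avg_divergence` (default 0.25) are excluded up front as saturation
risks. The assembly is a greedy approximation by design, not an exact
optimization.

**Backbone inference and dating.** The built-in engine is neighbor joining
on JC69 distances with column-bootstrap support, not maximum likelihood or
Bayesian inference: the heavy engines are external programs in this
workflow's ecosystem, reachable through the adapter hooks (a command
template consuming the exported PHYLIP supermatrix and returning Newick).
The built-in exists so the whole pipeline runs, and is testable, offline.
Likewise the built-in dating is *MPL-scale*, an explicitly labelled
stand-in for penalized-likelihood dating: the phylogram is made ultrametric
by mean-path-length smoothing (each node's relative age is the mean
root-to-tip path through it, clamped so parents are at least as old as
children), then all ages are multiplied by the single factor
`f = max_i(min_age_i / relative_age_i)` over the fossil placements — the
smallest global scaling satisfying every minimum-age constraint. Any
maximum-age constraint violated after scaling is a hard error rather than a
silent compromise. Fossils are placed on the MRCA of their listed taxa;
when the backbone holds only exemplars, placement uses the taxa that are
present (`partial = TRUE` in the pipeline), which resolves to the same node
whenever the calibrated clade is a union of genera and each genus'
exemplars span its root. Rooting uses a configured outgroup when given and
midpoint rooting otherwise.

**Decomposition.** Monophyly of each genus is assessed on a
support-filtered topology: internal nodes with bootstrap support below
`consensus_threshold` (default 0.5) are collapsed to polytomies before the
test, so weakly supported conflicts do not trigger spurious merging. (A
majority-rule consensus over an explicit tree sample, `majority_consensus()`,
is also provided and follows the strict `frequency > threshold` rule.)
Any group whose exemplars' smallest containing clade also subtends other
genera is merged with those genera, iterated to a fixed point; merging
that escalates to the root leaves a single task and a warning. Each task
is calibrated by the dated-backbone age (and credibility interval, when
present) of the MRCA of *all* its exemplars — for merged tasks this is the
only node that is guaranteed to exist in both the backbone and the future
clade tree.

**Clade inference, rescaling, grafting.** The built-in clade engine is NJ
on the mean of per-alignment distances, midpoint-rooted, MPL-smoothed, and
scaled to root age 1 — a relative-time tree, as a coalescent clade analysis
would produce, with bootstrap age quantiles as optional credibility
intervals. Rescaling multiplies every branch and every interval bound by
`f = calibration_age / (relative age of the exemplar MRCA)`; intervals
therefore grow in proportion to the age transfer. Grafting replaces the
backbone clade at the exemplars' MRCA with the rescaled subtree. When the
exemplars do not span the subtree root, the excess depth
`d = root_age - MRCA_age` is subtracted from the backbone stem branch; if
`d` meets or exceeds the stem, the graft would create a negative branch.
This is a known weakness of the approach — the default is a hard error
naming the clade, and `graft_mode = "clamp"` instead shrinks the subtree
so its root sits just below the backbone parent, with a loud diagnostic
and the caveat that the exemplar MRCA then no longer matches the backbone
age exactly. Grafts are applied deepest-first; afterwards the full dated
invariant set is re-checked.

## The synthetic data generator

`simulate_reference_bundle()` defines the study conditions under which the
pipeline is validated:

* a constant-rate birth–death tree conditioned on its extant tip count
  (default 40 tips, speciation 0.3 and extinction 0.1 per lineage per Ma),
  simulated forward with rejection of extinct runs and pruning of extinct
  lineages;
* monophyletic genera (default 8) carved out by repeatedly splitting the
  largest clade, mimicking a taxonomy whose genera are clades of uneven
  size;
* aligned clusters (default 6 of 1,500 bp) simulated under HKY with
  transition/transversion ratio 4, unequal base frequencies and 4-category
  Gamma rate variation (shape 0.5), at a clock rate of 0.004
  substitutions/site/Ma — chosen so that typical pairwise divergences fall
  in the 5–15% range where distance methods are well behaved but not
  trivial;
* a sampling-bias pattern of two universally sequenced, barcode-like
  markers plus partially sampled ones (inclusion probability 0.7),
  reproducing the marker-overlap structure the knapsack step exists to
  handle;
* "perfect fossils": minimum-age calibrations carrying the true age of two
  genus-closed internal nodes near 55% and 80% of the root age. Placing
  true ages on recoverable nodes isolates the error contributed by the
  pipeline itself from error in the calibrations.

`replicate_dataset()` mirrors an *existing* dataset instead: it fits the
birth–death model to the reference tree (maximum likelihood over net
diversification and turnover, cross-checked in the tests against an
independent implementation and a likelihood grid), simulates a tree of the
same size, assigns genera greedily by size with crown-age tie-breaks to
approximate the reference genus profile, refits a substitution model per
cluster ({JC, K80, HKY, GTR} × {+Γ, none}, AIC with ties to the simpler
model on a fixed NJ guide tree), matches each cluster's clock rate to the
reference cluster's mean divergence, and carries the occupancy row over
through a genus-preserving species mapping. Invariable simulated
alignments are dropped, as they would only inflate the marker count.

What the generator does *not* emulate — and hence what passing tests do
not demonstrate about real data: alignment error (sequences are born
aligned), non-orthology and contamination, among-lineage rate variation
(simulation is clock-like; the replicator has no lineage-rate model),
indels (a simple deletion process exists but defaults off, since no
parameters are specified for it), and the name-resolution and data-mining
layers that precede a real analysis. Accuracy numbers from the validation
are therefore upper bounds on what equally sized real datasets would give.

## Numerical choices and degenerate inputs

* JC69 distances return an `Inf` sentinel at `p >= 3/4`; saturated pairs
  are excluded from divergence means (but counted and reported), and NJ
  replaces them with 1.25 × the largest finite distance, with a warning.
* Species pairs that never co-occur in a clade task's alignments get the
  maximum observed distance × 1.1 — they end up maximally distant rather
  than arbitrarily close.
* Negative NJ branch lengths are clamped to zero with a warning.
* All order-dependent steps (reduction ranking, exemplar votes, knapsack
  ties, group ids) break ties lexicographically, making every stage
  deterministic; re-running a stage with identical inputs reproduces its
  outputs byte for byte.
* The dated-tree checker uses an absolute tolerance of 1e-6 Ma on
  ultrametricity; dispersal-binning conservation holds to 1e-12.
* Bins for the dispersal-through-time statistic are anchored at 0 Ma and
  closed on the older edge; an event on a branch is spread over bins in
  proportion to branch-length overlap, and the relative series divides by
  the total branch length per bin (0/0 defined as 0). When an ancestral
  range has several areas, a gained area yields one event per source area
  weighted `1/|source range|` so each gain counts once in total; a flag
  switches to one full event per source.
* Robinson–Foulds distances are normalized by the summed non-trivial split
  counts of both trees (maximally different binary trees score 1); branch
  scores include terminal branches and are normalized by the size of the
  union of bipartitions, with a `denominator = "sum"` switch since the
  normalization sentence in the method's description admits either
  reading.

## Serialization choices

Newick is the tree interchange format. Support values, age credibility
intervals and area sets travel as bracket comments
(`[&support=0.95,hpd_min=1.5,hpd_max=2.5,areas={a,b}]`); a bare
two-number interval is accepted as an age interval on reading, and unknown
`key=value` annotations round-trip verbatim. How such intervals should be
serialized is not standardized anywhere upstream; this dialect is a package
choice, documented here and in `read_tree()`. FASTA headers are
`seqid|speciesid`; supermatrices export as relaxed PHYLIP with a
`name = start-end` partition sidecar (1-based inclusive) or NEXUS with
charsets.

## Problem sizes used in the shipped validation

The test suite and the acceptance script run the full chain on bundles of
40 species, 8 genera and 6 × 1,500 bp clusters across 10 seeds with 50
bootstrap replicates, plus 25–50 birth–death fits on 200-tip trees, 100–200
randomized knapsack and exemplar cases against independent reference
implementations, and exhaustive tree-distance comparisons over all 105
six-tip topologies. These sizes give stable statistics (mean normalized RF
about 0.03–0.08, root-age error a few percent) while keeping a full run in
the low tens of seconds. The end-to-end runs use `graft_mode = "clamp"` so
that an occasional negative-branch clade (the documented weakness above,
arising in roughly one seed in ten) completes with a diagnostic instead of
aborting the replicate; the hard-error default is exercised separately by
the grafting tests.

## Known limitations

* The built-in inference and dating engines are distance-based stand-ins;
  for publication-grade analyses the adapter hooks should point at
  external ML/Bayesian and rate-smoothing software.
* Secondary calibration is inherent to the design: clade trees inherit
  backbone ages, so backbone age error propagates into every clade and
  credibility intervals widen multiplicatively with the rescaling factor.
* The greedy knapsack is an approximation with no optimality guarantee;
  pathological occupancy patterns can leave recoverable species dropped.
* Genus assignment in the replicator matches sizes greedily; when the
  simulated tree has no clade near a target size the genus is split and
  reported, so replicate genus-size distributions only approximate the
  reference.
* Dispersal counting takes node area sets as given; it reproduces the
  binning arithmetic only, not the ancestral-range reconstruction that
  produces the annotations.
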