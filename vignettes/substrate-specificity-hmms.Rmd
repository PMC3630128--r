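---
title: "Predicting NRPS/PKS substrate specificity with ensembles of profile HMMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting NRPS/PKS substrate specificity with ensembles of profile HMMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(substrateHMM)
```

## The problem

Non-ribosomal peptide synthetases (NRPSs) and polyketide synthases (PKSs)
are modular assembly lines. Which building block each module incorporates
is decided by one domain per module: the adenylation (A) domain of an NRPS
selects an amino acid, the acyl-transferase (AT) domain of a PKS selects an
acyl-CoA extender unit (malonyl-CoA, methylmalonyl-CoA, ...). Predicting
this *substrate specificity* from the domain's protein sequence is the key
step in deducing, or engineering, the natural product of an uncharacterized
gene cluster.

Classical predictors extract a handful of active-site residues (numbered
against the FabD [PDB 1MLA] structure for AT domains and the GrsA
[PDB 1AMU] structure for A domains) from a multiple alignment and then
cluster or match them. That makes the prediction hostage to the quality of
the new sequence's alignment. This package takes the profile-HMM route
instead: one probabilistic model is trained per substrate from the aligned
sequences with experimentally validated specificity, a query is scored
against every model without any prior alignment, and the best log-odds bit
score names the substrate. Scores below a reliability threshold are
flagged rather than trusted.

The decisive refinement is the *ensemble*: specificity evolves
convergently, so the same substrate can appear in evolutionarily distant
clades ("analogs among homologs"). A single per-substrate model trained on
a mixture of clades is dominated by the majority clade and underrepresents
the minority; splitting well-represented substrates into 2--4 clade-level
models, guided by Neighbor-Joining (NJ) trees, removes that failure mode.

## The model

Each substrate (sub)group is represented by a profile HMM with match,
insert and delete states over `M` match columns:

* **Match columns.** A column of the training alignment is a match column
  iff its gap fraction is at most 1/2 (ties count as match); `M` is the
  number of such columns.
* **Emissions.** Match emissions are per-column residue counts plus
  `pseudocount * background`, normalized. The background defaults to the
  uniform 1/20; insert states emit the background itself, so inserted
  residues are score-neutral. The unknown residue `X` is skipped in
  training and contributes zero log-odds when scored.
* **Transitions.** Each training row traces a deterministic state path
  through the match/insert/delete skeleton; transition counts are
  Laplace-smoothed with the same `pseudocount` and normalized per state.
  `D -> I` and `I -> D` are fixed to probability zero (plain profile
  architecture); rare training events that would need them are not
  counted. The default `pseudocount = 1` matters: substrate groups can be
  as small as two sequences, and an unsmoothed model would assign
  probability zero (hence an infinite penalty) to residues it happens not
  to have seen.
* **Scoring.** A query is aligned *globally* (domain sequences are
  pre-excised, so no local entry/exit states are modelled) by Viterbi
  dynamic programming, maximizing summed log2 emission odds plus log2
  transition probabilities. The result is the bit score: the log2 odds of
  the best path against the background null model. The DP inner loop is
  implemented in C++; its correctness surface is an exhaustive
  path-enumeration oracle in the test suite (agreement within 1e-9 bits).

A **library** is a named set of such models plus one reliability threshold
in bits. For the curated domain collections the thresholds are 325 (AT)
and 625 (A); because a reimplemented scorer is not numerically identical
to any particular legacy scorer, the threshold is configurable per
library, and synthetic fixtures calibrate their own (below). Classification
is `argmax` bit score, ties broken by model name; the reliability flag
(`bits >= threshold`) is independent of the argmax, so raising the
threshold can only change reliability, never the predicted substrate.

## Supporting pipeline

**Trimming.** Model comparability requires homogeneous alignments with no
terminal extensions or terminal gaps. `trim_terminal_extensions()`
iterates: align, find the leading/trailing runs of columns containing at
least one gap, delete the residues of every row falling in those columns,
re-align. The loop stops at a gap-free first and last column, or after
`max_rounds` (default 10) with a warning flag. Realignment is a pluggable
contract (`mafft_realigner()` shells out to MAFFT; deterministic scripted
realigners make the loop testable without external binaries). Trimming
only ever removes a prefix/suffix of each sequence — interior residues are
untouchable by construction.

**Redundancy removal.** Balanced coverage of sequence space requires
dropping (near-)duplicates. `deduplicate()` is greedy in input order: a
sequence is removed when its global pairwise identity (matches / aligned
columns of a Needleman–Wunsch alignment with simple identity scoring) to
an already-kept sequence *of the same substrate* reaches the threshold.
No numeric criterion is canonical for "near duplicate"; the default 0.98
removes trivial resubmissions without collapsing paralogs, and is a
parameter. Cross-substrate removal is disabled deliberately: identical
sequences with different validated substrates are signal, not redundancy.

**Conservation and residue selection.** Columns are numbered against a
reference row (1MLA/1AMU numbering); per-substrate conservation is strict
100% identity with no gaps (a gap is not a residue — the looser reading
would let half-empty columns count as conserved). Selections: columns
conserved in at least `k` groups, optionally excluding *globally*
conserved columns, where "global" means conserved in every group *with the
same residue*. Columns conserved in every group but with different
residues are maximally discriminative and are never excluded.

**NJ trees and clade partitions.** Distances are simple p-distances over
columns where both rows have residues (no correction — the correction
choice of legacy tools is unstated, and p-distance keeps the module
assumption-free). NJ is the classic Saitou–Nei agglomeration with two
determinism guarantees the reference implementations do not give: ties in
the Q criterion break on the lexicographically smallest pair of cluster
representatives, and negative branch lengths are clamped to zero with the
deficit moved to the sister branch (path lengths between the joined
clusters are preserved). The historical subdivision of substrate groups
into clades was done by eye; the reproducible stand-in midpoint-roots the
tree, takes maximal pure clades of the group as initial parts, and
greedily merges the smallest part into its topologically nearest neighbour
until at most `max_parts` (2–4) parts of at least `min_part_size`
(default 3) members remain. A published or hand-curated partition can be
supplied explicitly instead.

**Validation.** Every labeled sequence lands in exactly one of three bins:
*correct* (reliable and matching under the synonym map), *false* (reliable
and mismatched), *below threshold* (unreliable, regardless of the best
model). A right answer below threshold is counted below-threshold, not
correct. Coverage is the reliably-annotated fraction;
correct-of-covered is the correct fraction within those. All percentages
derive from the integer counts at print time — nothing is stored
pre-rounded. Leave-one-out (LOO) cross-validation rebuilds *only* the
model of the held-out sequence's own (sub)group — sibling parts and other
substrates' models are untouched — and classifies the held-out sequence
against the full rebuilt library. If removal empties a one-member part,
that model is dropped for the fold and flagged.

## The synthetic-data generator

Every stochastic claim in the package is exercised on generated families
(`simulate_family()`), fully reproducible from one integer seed through
R's Mersenne–Twister stream:

* a random ancestral scaffold of `scaffold_length` residues (default 150,
  the order of a reduced domain alignment);
* clades arranged on a caterpillar backbone, each edge applying one
  Bernoulli substitution round (`scaffold_mutation_rate` per site, uniform
  over the 19 alternatives); clade stems apply `stem_rounds` extra rounds,
  so between-clade exceeds within-clade divergence;
* per-label *signatures*: `specificity_positions` disjoint columns
  (default 8, the order of an active-site code) overwritten with fixed
  label-specific residues in every member — mutating non-planted positions
  can never change a true label;
* convergent labels planted in two clades (majority/minority split).

What the generator does **not** emulate: indel evolution (sequences stay
ungapped, so match-column assignment is trivial on synthetic data),
rate heterogeneity across sites, realistic amino-acid substitution
matrices, and the absolute score scale of curated domains. Consequently a
passing synthetic benchmark demonstrates the *mechanisms* (kinship signal
versus specificity signal, threshold behaviour, clade recovery), not the
absolute accuracies reachable on curated sequences.

`convergent_benchmark()` is the canned regime for the ensemble mechanism:
three labels, with `S1` split 13/5 over two clades. The minority clade
branches off through a long stem (400 rounds at rate 0.005, taking its
scaffold near saturation relative to everything else) while staying
internally coherent — a distant lineage that converged on the same
substrate. Because absolute bit thresholds mean nothing on synthetic
scaffolds, the fixture calibrates its own: the midpoint between the mean
in-group training score and the mean best out-group score under the
single-model library (`calibrate_threshold()`), recorded in the manifest.
In this regime the single `S1` model, dominated 13:5 by the majority
clade, scores the minority members below the calibrated threshold, while
the two-part ensemble recovers them with a wide margin — the minority
clade is exactly where the single library's errors concentrate. The
regime was chosen once, by this reasoning about emission mixtures, and is
shipped as the fixture's documented setting.

`loo_divergence_benchmark()` contrasts two equal-sized groups whose
within-clade rates differ 12-fold: held-out members of the diverse group
are poorly covered by the model rebuilt without them, so LOO accuracy
orders the groups — the synthetic analogue of tight versus diverse curated
substrate groups.

## Numerical and design choices

* Emission/transition probabilities sum to 1 within 1e-9 (enforced);
  serialization prints with `%.17g`, so a written library re-reads
  bit-for-bit identically.
* Degenerate inputs: an all-gap match column at `pseudocount = 0` falls
  back to uniform emissions; unvisited states fall back to uniform over
  their legal moves; a query with no positive-probability path (possible
  only at `pseudocount = 0`) scores `-Inf` with an undefined path length.
* Tie-breaks are lexicographic everywhere (NJ pair choice, model ranking,
  partition merging), making every pipeline stage invariant to input
  order.
* Pairs of rows with no comparable columns get p-distance 1 with a
  warning.
* E-values are not computed: the bit-score threshold alone decides
  reliability, and no calibration data for a null score distribution
  ships with the package.
* Problem sizes in the shipped benchmarks (45-sequence families, scaffold
  150, 100-matrix NJ sweeps) were chosen as the smallest sizes at which
  the contrasted effects are far from the decision boundary across seeds.

## Known limitations

* Whether curated AT models are best trained on reduced (selected-column)
  or full-length alignments is left to the caller — both are supported by
  passing the wanted alignment — since the historical choice is ambiguous
  and the package takes no side.
* The clade-partition procedure is a reproducible stand-in for manual
  clade reading; on curated data the published subdivision should be
  supplied explicitly for exact reproduction.
* Bit scores of this scorer are close to, but not numerically identical
  with, legacy HMM packages; the 325/625 thresholds transfer only
  approximately and are configurable.
* Domain boundary detection is out of scope: queries must be pre-excised
  A or AT domain sequences.
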