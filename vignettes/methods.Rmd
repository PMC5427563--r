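---
title: "Methods: dimer model evaluation and structure-based PPI network assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dimer model evaluation and structure-based PPI network assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and data model

`ppidock` covers the stages of a structure-based protein–protein
interaction (PPI) pipeline that sit *between* the external heavy engines:
it consumes monomer/dimer structures (PDB ATOM subset) and per-model
binding-energy tables (TSV), and produces model-quality metrics,
interaction calls, filtered edge lists and network topology reports.
Monomer modeling, FFT docking, flexible refinement and interface re-ranking
are upstream tools whose outputs are file-level inputs here; a naive rigid
sampler and a perturbation decoy generator are provided so every downstream
stage can be exercised without them.

Structures are held as `chain_structure` objects — heavy atoms only, in
PDB numbering, keyed by `(chain_id, res_seq)`. Hydrogens and HETATM records
are discarded at parse time: docked and refined models rarely carry
consistent hydrogens, so every distance rule in the package is a heavy-atom
rule. Insertion codes are rejected rather than silently renumbered. In a
dimer the *receptor* is the chain with more residues and the *ligand* the
smaller one; equal lengths fall back to the lexicographically smaller chain
id, a deterministic tie-break chosen because role assignment must be
symmetric in its arguments.

## Model-quality metrics

A residue is **interfacial** when at least one of its heavy atoms lies
within the interface cutoff (default **10 Å**) of any heavy atom of the
partner chain. **iRMSD** superposes the model receptor onto the reference
receptor over Cα atoms matched by residue number (Kabsch, see below), then
takes the Cα RMSD over the ligand interface residues *of the reference*
complex. Defining the interface on the reference, over ligand residues
only and on Cα atoms is the package's resolution of an underdetermined
convention; it makes iRMSD exactly zero for the reference itself and
exactly equal to the displacement under a pure ligand translation, both of
which are tested.

**PCS** compares residue–residue contact maps. A receptor–ligand residue
pair is in contact when any heavy-atom pair is within the contact cutoff,
default **5 Å** — a CAPRI-style residue-contact convention. The cutoff is
exposed as a parameter because the score's definition fixes only the
comparison statistic (the MCC over the receptor × ligand pair universe),
not the underlying contact distance.

The **MCC** is implemented in its standard form
`(TP·TN − FP·FN)/√((TP+FP)(TP+FN)(TN+FP)(TN+FN))` with the value defined
as 0 whenever a denominator factor vanishes. Counts are promoted to double
precision before the product, which otherwise overflows 32-bit integers at
proteome scale. The same routine backs PCS, interface-overlap redundancy
screening, threshold selection and the end-to-end recovery report.

Acceptance presets follow the benchmark convention: crystal-structure
targets (iRMSD ≤ 2.5 Å, PCS ≥ 0.65) and computer-generated monomer models
(iRMSD ≤ 8.5 Å, PCS ≥ 0.30). The success rate counts targets with an
accepted model in the top `top_k = 10`; the failure spectrum additionally
distinguishes scoring failures (a passing pose exists within the sampled
pool, default depth 2000, but outside the top 10) from sampling failures
(no passing pose at all). At every threshold the three fractions partition
the target set — an invariant the tests assert directly.

## Geometry

Superposition uses the SVD form of the Kabsch algorithm with the
determinant sign correction, so reflections are never returned even for
near-planar point sets; inputs with fewer than 3 points or collinear
geometry are rejected. The test suite checks the result against a
numerical minimization over rotation space from many starting orientations,
and checks the invariance of the superposition RMSD under arbitrary rigid
pre-transforms of either point set.

## Decoy generation

`perturb_native()` rotates the ligand about a uniformly random axis through
its centroid (normalized Gaussian 3-vector) and translates it along a
random direction, both seeded; with zero rotation the iRMSD against the
native equals the translation magnitude exactly, which anchors the metric
tests. `naive_rigid_sample()` is a deliberately simple exhaustive sampler:
a seeded set of ligand orientations crossed with a translation grid,
scored by contact count in the 4–6 Å shell minus a clash penalty
(pairs < 2.5 Å, weight 10), deduplicated at 1 Å ligand-Cα RMSD. Its only
purpose is to stand where an FFT engine would, so its shells and weights
are documented constants, all exposed as parameters.

## Interaction classifier

The feature vector is the ten binding-energy terms named in the column
schema (`energy_feature_names()`). Tables can carry raw engine units or
Z-scores; `zscore_normalize()` estimates per-column statistics on the
training split only and re-applies them to held-out data, avoiding
leakage. Whether the classifier consumes raw or normalized energies is a
user choice; the default pipeline trains on whatever scale the table
carries, since forests are invariant to monotone per-feature rescaling.

The classifier is a **500-tree probability forest** (`ranger`,
`probability = TRUE`): trees store terminal-node class frequencies and the
ensemble averages them. Probability trees were chosen over majority-vote
forests because the downstream stages consume the score as a probability
and rank pairs by it — vote fractions from fully grown majority-vote trees
are noticeably noisier, which directly costs ROC area. For the same reason
the minimum terminal-node size defaults to 5% of the training rows
(at least 10): smaller leaves interpolate training noise into the score.
Constant (zero-variance) feature columns are dropped before training —
with them, any tree whose `mtry` draw contains only constants would become
an unsplittable stump. Training, fold assignment and prediction are
seeded and single-threaded, so identical seeds give identical outputs.

Cross-validation is stratified k-fold (default 10): per class, a seeded
permutation is split into folds differing by at most one example, and each
example is scored exactly once out-of-fold. ROC curves and the trapezoidal
AUC come from `pROC`; the suite independently verifies the AUC against the
positive–negative pair-comparison probability. Threshold selection scans
the unique score values and returns the lowest threshold maximizing the
MCC (calls are strict: `score > threshold`). The top-*n* decision rule
calls a pair positive when any of its first `n` per-rank probabilities
exceeds the threshold; since the positive set under top-*n* contains the
one under top-*(n−1)*, TPR and FPR are provably non-decreasing in *n* — a
property the acceptance tests exercise empirically. Defaults are
`threshold = 0.13`, `top_n = 3`, the benchmark configuration.

## Dataset curation

Sequence identity is global Needleman–Wunsch (BLOSUM62, gap open 10,
extension 0.5, end gaps penalized), with identity = identical columns /
alignment length × 100. The word-based heuristic of the original
clustering tool is not replicated; the greedy scheme is: sort by
decreasing length, join the first cluster whose representative matches at
≥ 80% identity, else found a new cluster. Homodimers are chains at ≥ 85%
identity (boundary inclusive). Within clusters, dimers are dropped
greedily in input order when their interface-overlap MCC against any
retained dimer exceeds 0.5. Proteome filters keep 50–600-residue chains
(bounds inclusive — "longer/shorter than" excludes only strict violations)
and dimers with at least 20 interface residues counted over both chains
combined (the per-chain reading was the other candidate; combined was
chosen once and is used consistently). Ligand-swap negatives are a seeded
random derangement of ligand assignments (rejection-sampled, so no dimer
keeps its own ligand and no known positive pair is reproduced); the ligand
multiset is preserved by construction.

## Annotation filters

GO-slim annotations are consumed as a flat `protein_id / aspect / term`
TSV; ontology traversal is out of scope. The co-annotation test has three
outcomes — shared, disjoint, or *unannotated* when either side has no
terms in the aspect — and the cascade applies aspects sequentially with
per-stage retention counts. Unannotated pairs are dropped by default
(exposed as a policy flag): sparse process annotations are the dominant
cause of attrition at the BP stage, and keeping unannotatable pairs would
make the filter vacuous exactly where evidence is missing. MF is
implemented but excluded from the default cascade because molecular
function co-annotation does not separate interacting from non-interacting
pairs. With a uniform policy the cascade is order-independent (it computes
an intersection of per-aspect pass sets), which the tests assert.

## Network assembly

Graphs are simple and undirected; duplicate pairs collapse and self-pairs
are skipped with a warning count. Topology metrics are mean degree
2|E|/|V|, the diameter of the largest connected component (the assembled
networks need not be connected), and the mean local clustering coefficient
with degree < 2 nodes contributing 0 (Watts–Strogatz convention); global
transitivity is reported alongside for transparency. The null model is
G(n, m) — same node and edge counts, edges uniform over distinct pairs —
matching the same-nodes-same-edges comparison the pipeline is built
around; degree-preserving nulls are deliberately out of scope. Hive-plot
support computes the grouping only: axes by degree (low < 50,
50 ≤ medium ≤ 80, high > 80) and within-axis order by ascending local
clustering coefficient with node-id tie-breaks; rendering is left to
dedicated tools.

## Synthetic data: what it does and does not emulate

Toy monomers are ideal α-helical Cα+Cβ traces (rise 1.5 Å/residue,
100°/residue, radius set so consecutive Cα–Cα ≈ 3.8 Å) with seeded random
sequences. Native toy dimers pack two helices side by side, searching the
axis separation and a seeded azimuth until the combined 10 Å interface
holds ≥ 20 residues with no heavy-atom pair under 2.5 Å — i.e. they
satisfy the same inclusion rule the curation stage enforces. This geometry
is deliberately naive: there are no loops, no buried cores, no real
packing. The pipeline under test is geometry-agnostic, so passing tests
demonstrate correct bookkeeping, metric algebra and classifier behavior —
not that the method would succeed on real, flexibly refined complexes.

Class-conditional energy features are drawn per term from a symmetric
two-sided exponential (Laplace) around the class median with scale 0.4 on
the Z-score axis, so sample medians converge to the configured targets and
interquartile boxes stay of order one. Only medians are calibrated —
published distributions report medians, and matching higher moments would
be invention. Defaults: attractive van der Waals −0.230 (interacting) vs
0.214 (non-interacting), repulsive −0.187 vs −0.195, hydrogen bond −0.068
vs 0.418; the remaining terms use mildly discriminative medians chosen
once. Synthetic annotations assign each protein one term per aspect from a
distribution whose pairwise collision probability equals the configured
random-pair rate (CC 0.58, BP 0.32, MF 0.52), then nudge designated
interacting pairs (copy or force-differ with the calibrated probability)
toward the positive rates (CC 0.82, BP 0.93, MF 0.48). Chained nudges on
pairs sharing proteins couple weakly, so empirical rates are verified
within sampling tolerance rather than exactly.

A default scenario plants interactions at ~8% of the possible pairs
(15 edges among 20 proteins), builds native dimers and 20-decoy ranked
sets for each planted pair (the magnitude schedule includes the exact
native, so every planted pair has an accepted model by construction), and
writes structures, features, a disjoint labeled training table,
annotations, reference edges and a ground-truth manifest. Everything is
deterministic given the master seed.

## Problem sizes and numerical choices

The analytic cross-validation benchmark uses two Gaussian classes at
separation δ = 2 on one informative feature, 2000 examples per class: at
that size the sampling error of the pooled out-of-fold AUC is small
relative to the ±0.03 comparison band around Φ(δ/√2) ≈ 0.921, so the check
measures the classifier, not the draw. The calibration checks for feature
medians use 10 000 draws per class (median standard error ≈ 0.004 at
scale 0.4, against a ±0.02 band). The end-to-end scenario uses 20 proteins
(190 candidate pairs), 300 training examples per class, and 200-tree fold
models inside the pipeline helper. Oracle-equivalence tests sweep all
confusion matrices with total ≤ 30, AUC sets up to 200 examples, and
graphs up to 200 nodes.

Other numerical conventions: MCC is 0 on degenerate margins; threshold
candidates are the unique score values with ties resolved to the lowest
threshold; derangement sampling is by seeded rejection (expected ≈ e
draws); pose deduplication uses 1 Å ligand-Cα RMSD; PDB coordinates are
written at 3 decimals, so round trips are exact to 0.001 Å.

## Known limitations

- No real docking or refinement: energies from actual engines are
  file-level inputs, and the surrogate structure-derived features are
  labeled as such and never mixed with engine values in one table.
- Sequence identity ignores the clustering tool's word heuristics, so
  cluster boundaries can differ from the original tool's near the
  threshold.
- The GO layer does no ancestor closure; slims must already be flattened.
- Toy geometry cannot probe side-chain-level scoring behavior.
- iRMSD requires shared residue numbering between model and reference;
  there is no sequence-alignment fallback.
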