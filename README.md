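# ppidock

Structure-based discovery of protein–protein interactions (PPIs) works by
docking candidate partners against each other, scoring the resulting dimer
models, and keeping the pairs whose interfaces look like real complexes.
`ppidock` implements the bespoke stages of such an across-proteome pipeline
in R, for structural bioinformaticians who want to evaluate docking decoys,
classify putative interactions from binding-energy features, and assemble
and analyze the resulting interaction network — all runnable end-to-end on
synthetic toy complexes, with no external docking engine required.

## What the package computes

**Dimer model quality.** A residue is interfacial when any heavy atom lies
within 10 Å of the partner chain. Model quality is measured by

- **iRMSD** — the Cα RMSD over the reference ligand's interface residues
  after least-squares (Kabsch) superposition of the receptor chains, and
- **PCS** (pairwise contact score) — the Matthews correlation coefficient
  (MCC) between the model's and the reference's residue–residue contact
  maps over the receptor × ligand pair universe,

with joint acceptance criteria iRMSD ≤ 2.5 Å ∧ PCS ≥ 0.65 for
crystal-structure targets and iRMSD ≤ 8.5 Å ∧ PCS ≥ 0.30 for
computer-generated monomer models. The **docking success rate** is the
fraction of targets with an accepted model in the top 10 ranked poses, and
the **failure spectrum** splits misses into scoring failures (a good pose
exists in the sampled pool but is not ranked in the top 10) and sampling
failures (no good pose anywhere in the pool).

**Interaction classification.** Each candidate pair carries ten
binding-energy terms per refined model (van der Waals attractive/repulsive,
atomic contact energy, hydrogen bonds, electrostatics, …). A 500-tree
probability forest maps them to P(interacting); 10-fold stratified
cross-validation produces a ROC curve, the probability threshold is chosen
to maximize

MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN)),

and a pair is called positive when any of its top *n* ranked models scores
strictly above the threshold. Negative training pairs are built by a seeded
ligand-swap derangement among homodimers.

**Filters and network.** Predicted pairs pass a Gene Ontology slim
co-annotation cascade (same cellular component, then same biological
process); the surviving edges form an undirected simple graph whose mean
degree, diameter (largest component) and mean local clustering coefficient
are compared against seeded G(n, m) random nulls, with hive-plot axis
grouping by degree class.

**Synthetic data.** `synth_config()` / `build_scenario()` generate toy
helical monomers, packed native dimers with ≥ 20 interface residues,
ranked decoy sets of known quality, class-conditional energy features whose
medians match published benchmark distributions, and calibrated synthetic
GO annotations — a complete miniature experiment for testing every stage.

## Worked example

```r
library(ppidock)

# a toy native dimer and a perturbed decoy of known deviation
native <- make_toy_dimer(40, 30, seed = 3)
decoy  <- perturb_native(native, rot_deg = 0, trans_ang = 3, seed = 7)$dimer
irmsd(decoy, native)   # 3        (pure 3 A ligand translation)
pcs(native, native)    # 1        (identical contact maps)

# a full miniature experiment: 20 proteins, 15 planted interactions
dir <- tempfile()
build_scenario(dir, synth_config(seed = 11, n_proteins = 20))
res <- run_scenario_pipeline(dir, seed = 5)
res$cv$roc$auc         # 0.917    (10-fold CV on the training features)
res$threshold          # 0.49     (MCC-optimal probability threshold)
res$recovery           # TPR 0.867  FPR 0.109  ACC 0.889  MCC 0.546
res$metrics            # 20 nodes, 32 edges | mean degree 3.20,
                       # diameter 3, mean clustering 0.430
```

`res$recovery` says the pipeline recalled 87% of the planted interactions
while calling 11% of the non-interacting pairs positive — the planted edge
set is recovered with a large TPR−FPR margin, which is the package's
headline parameter-recovery check.

A command-line wrapper with one subcommand per stage
(`simulate`, `evaluate`, `classify`, `network`, `run-all`) is installed at
`exec/ppidock`:

```sh
Rscript "$(Rscript -e 'cat(system.file("exec","ppidock",package="ppidock"))')" \
    run-all --out /tmp/scenario --seed 1
```

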