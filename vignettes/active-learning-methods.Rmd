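---
title: "Active learning for binding-affinity optimization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active learning for binding-affinity optimization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alchemal)
```

## The active-learning cycle

`alchemal` automates a batched exploration loop for lead optimization.
A chemical library of candidate ligands is fixed up front. Iteration 0
draws a diversity-weighted random batch, an oracle supplies binding
free energies (ΔG, kcal/mol; more negative is stronger), and an
ensemble regressor is fitted to the labeled set and applied to the
whole library. Every later iteration selects a new batch — disjoint
from everything already evaluated — according to a selection policy,
queries the oracle, refits, and repredicts. The premise is that
oracle calls (alchemical free-energy simulations, assays) dominate the
cost, so the loop's job is to spend them where they matter: either on
the likely strongest binders (exploitation) or on the most informative
ligands (exploration).

Two assumptions matter. First, the oracle is treated as unbiased with
roughly homoscedastic noise; records are append-only and never
revised. Second, the feature representation must make affinity
learnable by a feed-forward network — similar ligands must have
similar representations. Nothing in the loop corrects for a
representation that scrambles chemical neighborhoods.

## Selection strategies

All strategies operate on the prediction table of the previous
iteration (`mean_dg` and an `uncertainty` column) and break every tie
lexicographically by ligand id, so selection is a deterministic
function of the predictions.

* **greedy** — the `batch_size` most negative predicted ΔG.
* **uncertain** — the largest prediction uncertainty.
* **mixed** — the most uncertain among the `pool_factor * batch_size`
  strongest predictions (default 3:1). At 1:1 it selects exactly the
  greedy set; with a pool covering all candidates it reduces exactly
  to `uncertain`. These identities are asserted in the test suite for
  arbitrary prediction tables.
* **narrowing** — for the first `switch_after` (default 3) iterations,
  one ensemble per available ligand representation is trained; the
  `n_models` (default 5) with the best cross-validation RMSE each
  contribute their `per_model_top` (default 20) best predicted
  binders; afterwards the policy switches to greedy on the main
  representation. When several models nominate the same ligand, models
  are visited round-robin in ascending cv-RMSE order and each
  contributes its next-best unclaimed ligand until the batch holds the
  full quota of unique ligands. The round-robin rule is this package's
  own disambiguation of "use the next best ligand from one of the
  representations"; it is documented and tested as such.
* **random2greedy** — uniform random batches for the broad phase, then
  greedy.

Initialization weights each ligand inversely by the occupancy of its
bin in a 2-D embedding histogram (unit-square bins by default), so
over-represented chemotypes do not flood the first training set. The
embedding is a seeded t-SNE of a 2-D feature block (or any
user-supplied coordinates, e.g. the PCA coordinates that synthetic
landscapes carry); because stochastic-neighbor embeddings are
run-to-run variable, the coordinates are computed once and cached in
the run configuration rather than recomputed per iteration.

## The ensemble regressor

Each ensemble member is a multilayer perceptron with ReLU activations
(`hidden_layer_widths`, default 64–32; an empty vector gives a linear
model). Per repeat, the training ligands receive a fresh seeded 5-fold
split; each member trains on four folds and early-stops on the held
fold. Ensembles therefore have `k_folds * n_repeats` members — 5 by
default, 25 when repeats are widened to 5, which the configuration
allows per iteration. The prediction is the arithmetic member mean;
the uncertainty consumed by selection is configurable as the member
standard error (default) or standard deviation, since both conventions
are common and the choice only rescales the exploration signal by
√k.

Training minimizes per-example-weighted L1 loss with plain SGD:

* momentum 0.9, mini-batches of up to 500 ligands;
* learning rate `lr(epoch) = 0.005 · 0.1^(epoch/10000)` — one decade
  of decay per 10000 epochs;
* epoch budgets of order 2000 (20000 for final high-accuracy fits);
* early stopping when the held-fold L1 fails to improve for 10% of the
  epoch budget (evaluated every `eval_every` epochs), restoring the
  best checkpoint. The 10% patience is this package's default; any
  value can be set explicitly.

Targets are transformed affinely before training
(`y' = (y - bias)/scale`); by default the transform standardizes the
training targets, and manually chosen values can be supplied instead.
Predictions are always mapped back to kcal/mol. Features are
standardized to zero mean and unit variance per column, with the
transform fitted **only** on the training records — never on
unevaluated library ligands — and constant columns centered but left
unscaled. The same no-leakage rule applies to the loss weights.

**Inverse-frequency weighting.** Affinity-driven selection makes
training sets progressively top-heavy in strong binders. Each
example's loss weight is `1/KDE(ΔG_i)`, a Gaussian kernel density
estimate of the member's own training targets, renormalized to mean 1.
The bandwidth defaults to Scott's rule on the training targets
(kcal/mol) and is overridable; the kernel estimate is evaluated at the
sample points themselves. A side effect worth knowing: ligands from
sparsely sampled affinity regions dominate the loss, which can
amplify compositional quirks of the library.

**Feature filtering.** Integrated Gradients attribute the prediction
to input features along the straight path from a baseline to the
input; the package uses the all-zeros vector in standardized space
(the training-mean ligand) as baseline and a 256-step midpoint Riemann
sum, exact for linear models and verified against the closed form in
the tests. Importance is the mean absolute attribution over a probe
set and all members, normalized per probe ligand so the default
threshold of 0.02 is scale-free; constant features get importance
exactly zero.

**Determinism contract.** All RNG (fold splits, weight initialization,
batch shuffling) derives from the configured seeds, and the C++
trainer is single-threaded, so a run is bit-reproducible:
retraining with the same configuration reproduces member predictions
exactly, and a run resumed from a checkpoint matches an uninterrupted
one.

## Oracles

The lookup oracle replaces the expensive free-energy step with a table
of known affinities — the retrospective mode used to calibrate
protocols on already-measured series. The synthetic oracle emulates a
replicate-based alchemical protocol: `n_replicates` (default 5)
independent Gaussian perturbations of the true ΔG with standard
deviation σ (default 1.1 kcal/mol, a typical alchemical-vs-experiment
error), returning the replicate mean and its standard error. The noise
is i.i.d. across ligands — the simplest model consistent with an
aggregate error figure; an optional per-ligand bias hook lets tests
probe robustness to systematic cluster-level errors. For real engines,
per-iteration CSV manifests are written and relative ΔΔG results are
read back and combined with the reference ligand's absolute ΔG,
uncertainties propagating in quadrature.

## Featurization

The `2D_3D` block is defined by a versioned manifest (shipped YAML)
naming every descriptor and fingerprint, rather than by toolkit
reflection — so the block's composition survives toolkit upgrades. The
packaged manifest lists the full RDKit 2-D descriptor set plus MACCS
keys and a 1024-bit radius-2 Morgan fingerprint; fingerprints are
folded to the bit lengths the manifest declares. Columns that are
non-finite for any ligand are dropped and recorded on the block, which
matters for R-group-only variants where many descriptors are undefined
on small substructures.

The atom-hot encoding counts ligand atoms per chemical element in
cubic voxels (2 Å edge by default) over a user-declared grid and
flattens the element × voxel tensor to a vector. Binning is half-open
— `[origin + i·edge, origin + (i+1)·edge)` per axis, so an atom
exactly on a face belongs to the higher-index cell — a convention
chosen purely for determinism and cross-checked against a brute-force
floor-index oracle in the tests. Atoms outside the grid are never
dropped silently: they are tallied in per-element overflow columns, so
per-element column sums always reconstruct the atom counts. A
user-supplied boolean mask restricts columns to binding-pocket surface
voxels; computing such a mask from a protein structure is out of the
package's scope, as are protein–ligand interaction features, which are
ingested as precomputed CSV blocks instead.

## Synthetic landscapes

`generate_landscape()` is first-class, tested code, not a fixture: it
produces the study conditions under which the loop's behavior is
asserted. Ligands are Gaussian clusters in a latent feature space
(defaults: 2000 ligands, 8 clusters, latent dimension 8); the true
affinity is a smooth cluster-dependent function of position — cluster
base level plus a radial term weakening away from the center, mild
Gaussian ruggedness unless `noise_free` — rescaled to −17 … −6
kcal/mol. Strong binders (default fraction 0.025, i.e. exactly 50 of
2000) are confined to 3 designated clusters, mirroring affinity data
for a congeneric series where potency concentrates in a few
chemotypes. Five feature views (the latent block, random rotations and
noisy copies) make multi-representation narrowing exercisable. The
latent features stand in for chemical descriptors so the model,
selection and loop logic are tested independently of the chemistry
toolkit; the packaged 20-molecule fixture series covers the
chemistry-dependent paths.

What the landscapes deliberately do **not** emulate: activity cliffs
(the surface is smooth by construction), assay-dependent
heteroscedastic noise, compositional bias in the library, and any
real structure–activity relationship. A strategy ordering observed on
these landscapes is therefore evidence about the loop's mechanics —
exploitation concentrates evaluations in strong clusters, exploration
spreads them — not a performance guarantee on real series.

## Desk-scale experiment sizes

The shipped experiments are sized to run in minutes on one CPU while
preserving the regime of interest (evaluated fraction ≈ 35%, strong
binders rare): strategy comparisons use the default 2000-ligand
landscape, batches of 100, 6 iterations after initialization, 5 paired
seeds (same landscapes and initialization seeds for every strategy),
and per-iteration ensembles of 5 members with 32–16 hidden layers and
a 400-epoch budget. Accuracy-focused checks (learnability of
noise-free landscapes, linear-map recovery) use the default 64–32
architecture with larger epoch budgets. With these conditions greedy
and narrowing recover essentially all designated strong binders while
random tracks the evaluated fraction and uncertainty-driven selection
trades recovery for whole-library accuracy — the orderings the
acceptance checks assert as paired medians, not fixed margins.

## Numerical and degenerate-input choices

* Ties in any ranking: lexicographic by ligand id.
* Constant feature columns: centered, not scaled; they carry zero
  attribution and are dropped by any positive importance threshold.
* Degenerate targets (zero variance): unit loss weights, unit target
  scale; members then fit the constant.
* A member whose weights go non-finite aborts with a warning; the
  ensemble fails only if more than half its members abort.
* Candidate-pool exhaustion yields a shorter batch plus a warning, and
  the loop stops when a batch comes back empty.
* An optional plateau rule halts the loop when the best ΔG found has
  not improved for two consecutive iterations — useful because once
  the strong-binder pool is exhausted, further iterations backfill
  with weaker ligands.

## Limitations

The chemistry layer requires an external `python` with RDKit (the
helper is bundled; no R-native BRICS implementation exists), and
binding-pose generation, pocket-surface computation and the
free-energy simulations themselves are explicitly out of scope —
poses arrive as SDF coordinates, interaction features as CSV, free
energies through the oracle interface. Multi-site linkers enumerate
all site subsets when fewer termini than sites are attached; that is a
package decision, not an assertion about any reference
implementation. Training is CPU-bound single-thread; the determinism
contract does not extend to multi-threaded BLAS reductions.
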