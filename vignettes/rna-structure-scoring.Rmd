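---
title: "Voxel-based quality assessment of RNA 3D structures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-based quality assessment of RNA 3D structures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scoring model

`rnavoxqa` scores an RNA 3D structure model by examining each nucleotide in
turn. The premise is that while global folds vary widely, the local building
blocks of RNA (helices, loops, junctions) recur, so quality can be judged
from a nucleotide's immediate surroundings rather than from the whole
molecule.

For each nucleotide the package:

1. **Anchors a body-fixed local frame** on the nucleotide. With
   $\mathbf{r}_{C1'}, \mathbf{r}_{O5'}, \mathbf{r}_{C5'}, \mathbf{r}_N$ the
   global positions of C1', O5', C5' and the glycosidic nitrogen (N9 in
   purines, N1 in pyrimidines), the frame has origin $\mathbf{r}_{C1'}$,
   $\hat{\mathbf{x}} \propto \mathbf{r}_N - \mathbf{r}_{C1'}$, a provisional
   $\mathbf{y}^* = (\mathbf{r}_{O5'} + \mathbf{r}_{C5'})/2 -
   \mathbf{r}_{C1'}$, $\hat{\mathbf{z}} \propto \hat{\mathbf{x}} \times
   \mathbf{y}^*$ and $\hat{\mathbf{y}} = \hat{\mathbf{z}} \times
   \hat{\mathbf{x}}$. The frame makes everything downstream exactly
   invariant to global rotation and translation of the structure.
2. **Extracts the environment**: every atom of the structure whose local
   coordinates satisfy $\max(|x|,|y|,|z|) < 16$ Å — a 32 Å cube centred on
   the nucleotide, which comfortably covers its base pairing and stacking
   partners. The inequality is strict, and the assessed nucleotide's own
   atoms are included (they are part of the image being judged).
3. **Voxelizes** the environment into a $32^3$ grid of 1 Å cells with three
   channels accumulating, per cell, the atom count (occupation), total mass
   (Da) and total partial charge (e) — an RGB-like 3D image of the local
   structure.
4. **Regresses an unfitness score** from the image with a small VGG-style
   3D convolutional network (below). The per-nucleotide scores are summed
   into the global structure score; lower is better, and 0 means
   native-like.

## The regression target: nucleotide unfitness

The training label for a nucleotide in an assessed (decoy) structure is
RMSD-based: superpose the nucleotide's own atoms onto their native
conformation (Kabsch, proper rotation enforced), take that superposition
RMSD (the *self* term), then apply the same transform to the matched
surrounding atoms and take their RMSD against the native surroundings
(the *surroundings* term), without re-fitting. The raw label is the sum of
the two, in Å. The self term is typically small; the surroundings term
dominates and measures how poorly the nucleotide sits in its environment.

Two choices here were genuinely open and are package decisions:

* the superposition is fitted on the nucleotide's own atoms only, so the
  surroundings RMSD is measured *relative to the nucleotide's pose* — the
  reading under which the label quantifies misfit between nucleotide and
  environment rather than global drift;
* surroundings membership is decided from the **native** structure's cube,
  so the label is a fixed function of the native reference; atoms are
  matched by (chain, residue number, atom name), unmatched atoms dropped
  with the coverage fraction reported.

Both the raw label and the voxel channels are min-max normalized to
$[0, 1]$ with statistics fitted **dataset-wide** over the training stream
and frozen into the model (`NormalizationStats`); at inference,
out-of-range values saturate. Per-sample scaling would destroy
comparability across samples and was rejected.

## The network

The full-scale reference architecture (`modelSpec()`), used for the architecture
checks:

| layer | output edge | channels | notes |
|---|---|---|---|
| input | 32 | 3 | occupation, mass, charge |
| conv 5³ | 28 | 8 | stride 1, no padding, ReLU |
| conv 5³ | 24 | 16 | dropout 0.2 in training |
| maxpool 2/2 | 12 | 16 | |
| conv 3³ | 10 | 32 | |
| conv 3³ | 8 | 64 | dropout 0.2 |
| dense | — | 128 | ReLU, dropout 0.2 |
| output | — | 1 | linear |

This network has exactly 4,282,801 trainable parameters
(`countParameters(modelSpec())`); the pooling window of 2 is forced by that
count, given that only the stride was otherwise specified. Weights are
Glorot-uniform from a seed, biases zero. Training minimizes the MSE by
mini-batch gradient descent (batch 128), learning rate 0.05 halved whenever
the validation MSE has not strictly improved for five consecutive epochs
(patience counter reset after each halving, min-delta 0), stopping at
0.0015625 — the fifth halving. Momentum and a max-epoch cap are exposed as
configuration (defaults 0 and 500) since neither is pinned down by the
protocol above.

The layers are implemented directly in R: convolutions as im2col gathers
feeding BLAS matrix products, with precomputed gather indices per layer.
Because the voxel grids are mostly empty (a nucleotide environment occupies
on the order of 100 of the 98,304 voxels), the first convolution uses an
exact sparse decomposition: the input is a per-channel constant baseline
(the empty-voxel value after normalization) plus sparse deviations; the
baseline contributes one identical row to every valid patch, and the
deviations scatter through a reverse im2col map. The result is bit-for-bit
identical to the dense path (asserted in the tests) and an order of
magnitude faster at desk scale.

## Desk-scale training

Training the full 4.3M-parameter network needs a million-sample corpus of simulation-generated decoys and is out of scope. For complete, runnable training the
package fixes a *desk-scale* configuration:

* `deskModelSpec()`: conv 4@3³ (stride 2) → maxpool 3/3 → conv 8@3³ →
  dense 32 → linear output on the same (3, 32³) input; 8,177 parameters, no
  dropout — desk runs are overfit-style sanity checks and demos, where
  regularization only slows memorization.
* `deskTrainingSchedule()`: the same loss, batch size and plateau schedule
  with momentum 0.9. On the 224-sample fixture set below, plain gradient
  descent plateaus around training MSE 0.026 within 200 epochs while
  momentum reaches below 0.01 — the overfitting bar the test suite holds
  the package to — in comparable time.
* study conditions: a 14-nucleotide synthetic helix, 4 decoys at each
  perturbation level $\sigma \in \{0.05, 0.2, 0.5, 1.0\}$ Å, giving
  $14 \times 16 = 224$ samples; training runs at most 200 epochs with
  validation = training. After training, the model must rank the native
  helix below a fresh $\sigma = 1$ Å decoy in at least 45 of 50 seeded
  replicates. These sizes keep the full pipeline in minutes on one CPU.

## The synthetic generator: what it emulates and what it does not

`makeToyRna()` builds a parametric single-stranded helix (rise 2.8 Å, twist
33°, radius 9 Å) of alternating A/U nucleotides, each carrying C1', O5',
C5', the glycosidic nitrogen, P (except the 5' residue) and six sugar
atoms at fixed offsets chosen so the frame construction is always
well-conditioned. `perturbStructure()` draws independent isotropic Gaussian
displacements per atom (σ per coordinate, seeded), so decoy deformation —
and hence the label distribution — is controlled by a single dial, standing
in for the simulation- and fragment-assembly-generated decoys used at full
scale.

The generator reproduces the *structure of the learning problem* (labels
growing with deformation, rigid-motion invariances, frame-ready
nucleotides), not RNA physics: there is no base pairing, stacking, sterics
or torsional chemistry, and the helix is regular rather than A-form. A
green desk-scale suite therefore demonstrates that the pipeline is
implemented correctly and can learn its target, not that the desk-trained
model scores real RNA usefully — that requires retraining on real decoy
ensembles via the same API.

## Numerical choices

* **Voxel cells** are half-open: on each axis, index
  $i = \lfloor c + 16 \rfloor$ (0-based), covering $[i-16, i-15)$ Å.
  Inclusion is strict at both faces (an atom at exactly ±16.0 Å is outside),
  making the boundary testable and symmetric.
* **Degenerate frames**: the two normalizations in the frame construction
  reject norms below $10^{-6}$ Å (missing or colinear frame atoms raise
  errors naming the atom).
* **Kabsch**: SVD with the reflection branch corrected to determinant +1;
  the suite cross-checks RMSDs against an independently implemented Horn
  quaternion oracle to $10^{-8}$ Å (on the squared deviation near zero,
  where the eigenvalue route loses half its digits).
* **Enrichment Score**: top-decile size $k = \lfloor 0.1 N \rfloor$ with
  $N \ge 10$ enforced; boundary ties broken by decoy identifier so the
  statistic is deterministic. ES is 10 for perfect rank agreement, 1 in
  expectation for independent scores (hypergeometric mean), below 1 for
  anti-correlation. Native identification demands a strict minimum; ties
  are reported but not counted.
* **Saliency** is the exact signed gradient of the scalar output with
  respect to every input voxel (dropout inactive), mapped to atoms by voxel
  membership. One property worth knowing: with hard max-pooling and mostly
  empty grids, conv outputs over the uniform background tie exactly within
  pooling windows, so the score is non-differentiable at almost every
  background voxel. Backpropagation follows the first-tie subgradient;
  finite-difference checks are therefore performed at differentiable
  points (generic dense inputs, or probes passing a one-sided-difference
  smoothness guard).
* **Learning-rate decisions** are a pure replay of the validation history
  (best-so-far tracking with patience reset after each halving), making the
  schedule unit-testable independently of training.
* **Atom properties**: hydrogens are excluded by default (crystal
  structures lack them; decoy sources differ), re-enabled by a flag. The
  shipped per-atom charge table is an amber-force-field-style stand-in
  covering every canonical heavy atom of A/U/G/C, with element-mass
  fallback and charge 0 (logged) for atoms outside the table. Modified
  residues map to parents through a small alias table; unmapped residues
  are skipped with a warning.

## Known limitations

* PDB is the only input dialect (no mmCIF); no structure editing,
  protonation or geometry regularization.
* No symmetry-corrected RMSD and no sequence alignment: native and assessed
  structures must share residue numbering.
* The desk-trained model is a pipeline demonstration, not a production
  scoring function; benchmark-grade performance requires weights trained on
  real decoy ensembles via the same API.
* Scores are sums of normalized per-nucleotide outputs, so global scores
  grow with chain length; comparisons are meaningful within one target's
  decoy set, as in the Enrichment Score and native-identification metrics.
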