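---
title: "Multi-contrast multi-atlas likelihood fusion for DTI parcellation"
author: "dtifusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-contrast multi-atlas likelihood fusion for DTI parcellation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`dtifusion` parcellates a diffusion-tensor brain image into labeled
anatomical structures by fusing evidence from a library of labeled atlases.
Every voxel of the subject carries a five-component intensity vector derived
from the diffusion tensor: fractional anisotropy (FA), mean diffusivity (MD,
mm²/s), and the componentwise absolute values of the primary eigenvector
(|EVx|, |EVy|, |EVz|). No single contrast separates all structure pairs —
CSF-filled spaces stand out in MD, gray/white boundaries in FA, and
differently oriented white-matter tracts only in the eigenvector channels —
but each structure has a unique joint signature across the five channels.

The parcellation `W` is the maximum-a-posteriori estimate given the observed
image, treating two things as latent: *which atlas* best explains each voxel
(the atlas-label selector), and the *per-structure spatial correspondence*
between each atlas and the subject. The resulting EM loop alternates three
steps:

1. **Selector update (E-step).** For each atlas `a` and voxel `x` with
   current label `l = W(x)`, the selector weight is proportional to the
   product of four factors: the intensity likelihood of the subject voxel
   under atlas `a`'s structure-`l` mixture models; the Dice overlap between
   the current structure `l` and atlas `a`'s deformed structure `l`; a prior
   on the magnitude of atlas `a`'s global deformation; and a Gaussian prior
   on its structure-`l` local affine. The three geometric factors are
   constant within a structure; only the intensity factor varies voxelwise.
   Weights are normalized over atlases at each voxel.
2. **Parcellation update.** Each voxel takes the label maximizing the sum
   over atlases of selector weight × intensity likelihood × the trilinearly
   interpolated deformed label probability. Ties break to the smallest label
   index; the label set is completed by an explicit background label (0)
   whose intensity models are fitted from unlabeled voxels, because the
   argmax needs a complete label set.
3. **Correspondence update (mode approximation).** Each (atlas, structure)
   correspondence is the composition of the atlas's global diffeomorphism
   with a local 12-parameter affine, re-optimized against the new
   parcellation by maximizing soft Dice overlap plus the affine log prior.

The loop stops when the changed-voxel fraction drops below `stopTolerance`
(default `1e-4`) or after 30 iterations. The 30-iteration cap is part of the
method's definition; the changed-voxel criterion is the natural
label-stability complement. A divergence guard aborts (with a flag) if the
changed fraction rises five iterations in a row.

### Intensity model

Per (atlas, structure, channel) the intensity histogram is modeled as a
K-component Gaussian mixture fitted by maximum-likelihood EM
(`fitGmm`), with K chosen by structure size: `kSmall = 2` components below
1000 mm³ and `kLarge = 3` at or above it. The size cutoff is fixed at
1000 mm³; the per-class counts are exposed configuration because they are
empirical choices, and the defaults here are the package's own
reconstruction. The mixture serves a second purpose beyond density
estimation: a channel that is uninformative within a structure (e.g.
eigenvector components in low-FA gray matter) is fitted with broad,
overlapping components, which automatically flattens its density and
reduces that channel's influence on the likelihood ratio between competing
structures — an effect the test suite checks explicitly.

Numerical choices: EM initializes from k-means++ style seeding
(deterministic per seed), stops when the log-likelihood gain falls below
1e-7 or 500 iterations, floors variances at 1e-6 (channel units²) against
the ML-EM singularity, and prunes components with weight below 1e-4 so
homogeneous data collapse to a single component with weight 1. Per-channel
densities are floored at 1e-300 and all five-channel products are
accumulated in log space — a plain product of five small densities
underflows double precision.

### Registration

Atlases are brought to the subject grid by a two-channel (FA + MD)
registration. The package implements a greedy multi-resolution
diffeomorphic scheme: demons-type updates computed from the weighted
two-channel residuals, smoothed by a Gaussian kernel (standing in for an
elliptic-operator norm on the velocity field), step-capped, and composed so
invertibility is preserved. Updates that break Jacobian positivity are
rejected and the smoothing increased; the coarse-to-fine schedule plays the
role of a smoothing cascade. This preserves exactly the contract the fusion
stage needs — an invertible field plus a deformation-magnitude prior — and
the registration stage is a pluggable interface, so a full time-dependent
velocity-flow (LDDMM) backend can be substituted without touching the
fusion code. Channel weights default to equal; the accumulated norm of the
smoothed updates is recorded as a geodesic-length proxy, preserving
monotonicity in deformation size, and enters the selector as
`exp(-geodesic)` normalized across the library.

The local affine refinement is parameterized as 9 row-order deviations from
the identity matrix plus 3 translations (voxels), acting about the target
structure's centroid so the zero vector is the identity. Its prior is a
zero-mean diagonal Gaussian with variance 0.01 on the linear block and 100
on translations. Optimization is derivative-free from identity — greedy
unit-step translation search, then Nelder–Mead over all 12 parameters —
restricted to the structure's bounding box dilated by 5 voxels, and the
result is never allowed to score below identity. Soft (probability-weighted)
Dice makes the objective smooth in the parameters; re-optimization is
skipped when a structure's target voxel set is unchanged, which is exact
because the optimum depends only on that voxel set.

### Coordinate conventions and boundaries

All voxel coordinates are 1-based and voxel-centred (the R array
convention). Transforms map subject voxel coordinates to atlas voxel
coordinates (pull-back): the deformed atlas value at subject voxel `x` is
the atlas sampled at `affine(x) + disp(affine(x))`. Outside the atlas grid
the background label has probability 1 and channel intensities fill with 0
— the exterior is unlabeled background by definition. Non-finite voxels in
input volumes are rejected by default (`naAction = "reject"`) so malformed
exports fail loudly; masking them to 0 is available explicitly.

## DTI contrasts and peripheral decomposition

`tensorToContrasts` eigen-decomposes the symmetric tensor per voxel, clamps
negative (noise) eigenvalues to zero before computing MD (mean eigenvalue)
and FA = √(3/2)·‖λ − λ̄‖/‖λ‖, and takes absolute values of the principal
eigenvector, which resolves the eigenvector sign degeneracy at the
acknowledged cost of some orientation information. All-zero tensors yield
FA = MD = 0 with a zero eigenvector, exempt from the unit-norm invariant.

`decomposePeripheral` splits surface-adjacent structures with the standard
DTI tissue thresholds: MD ≥ 0.0015 mm²/s marks CSF, otherwise FA > 0.2
marks peripheral white matter, else cortex. Boundary inclusion is fixed and
documented: MD exactly at threshold → CSF, FA exactly at threshold →
cortex. CSF sublabels are flagged excluded from ROI analysis. Sublabel ids
are `1000·s + 1/2/3` (CSF/cortex/WM). The MD threshold presumes mm²/s
(tissue ≈ 0.0007, CSF ≈ 0.003); both thresholds are configurable for data
in other units.

## The synthetic phantom

The phantom generator is the package's test bed and defines its study
conditions. The default recipe (`defaultPhantomSpec`) is a 48³ grid at
2.5 mm isotropic spacing — the clinical DTI slice scale — with six
structures in a background: a CSF ventricle (MD ≈ 0.0030 mm²/s), two deep
gray nuclei separated by FA (0.18 vs 0.32), two crossing white-matter
tracts distinguishable only by eigenvector orientation, and a peripheral
slab whose FA/MD mixtures straddle the 0.2 / 0.0015 thresholds so the
peripheral decomposition is exercised. A second recipe
(`makeAmbiguityPhantom`) builds five slabs in which each adjacent pair is
separable in exactly one channel group (MD for ventricle/tissue, FA for
gray/tract, EV for tract/tract), the geometry behind the single-contrast
ablation comparisons.

Atlases are fresh intensity realizations of the ground-truth labels (each
with its own seed, emulating distinct subjects rather than warped copies of
one noise field), deformed by random smooth warps: Gaussian-filtered white
noise scaled to 2 voxels RMS with 8 mm smoothness, exponentiated by
scaling-and-squaring so the warp is invertible; the magnitude auto-reduces
if Jacobian positivity would fail. A held-out deformed copy serves as the
subject, and its label map is the evaluation ground truth.

What the phantom does *not* emulate: Rician acquisition noise, cortical
folding geometry, partial-volume tensor mixing, or pathology-scale
morphological outliers. Passing tests therefore demonstrate the estimator's
correctness and its behavior under controlled contrast/geometry ambiguity,
not clinical-grade accuracy; accuracy on real data depends on atlas quality
and registration in ways the phantom cannot probe.

## Evaluation semantics

- Dice is 2|A∩B|/(|A|+|B|); two empty masks are defined as Dice 1 with a
  warning.
- The volume difference between two measurements is
  100·|v₁−v₂|/((v₁+v₂)/2); the mean-of-two denominator is symmetric and
  standard for scan–rescan work. The single-scan denominator is available
  via `denominator = "first"`.
- Scan–rescan reproducibility of mean FA and MD uses the same absolute
  percent difference of means as the volume treatment, since a single
  percent per measure is reported.
- Cross-subject variability is the sample standard deviation (n−1) over the
  mean, per structure and measure.

On mixture-recovery checks: the standard error of a mixture-component mean
MLE at 3σ separation is about 2.1× the single-Gaussian σ/√n (the overlap
discounts the Fisher information), and a 2-SE band covers ~95% per
component per fit. Recovery is therefore asserted in aggregate across the
20 fixed seeds — each fit inside a 4-SE envelope, the across-seed average
within 2 standard errors of the average — rather than per seed, where a
~5% miss rate is expected by construction.

## Problem sizes and determinism

The shipped tests run the full pipeline on the 48³ default phantom with 4
atlases and the 36³ ambiguity phantom with 4 atlases across 3 seeds; unit
tests use 6³–32³ instances where brute-force oracles (exhaustive posterior
evaluation, explicit weighted voting, voxelwise eigen-decomposition) are
feasible. All stochastic steps — phantom draws, warps, subsampling, EM
seeding — take explicit seeds and are bit-reproducible; the fusion loop
itself is deterministic given its inputs.

## Known limitations

- The greedy registration scheme is a desk-scale stand-in: it honors the
  invertibility contract and recovers smooth warps of the phantom's scale,
  but it is not a geodesic (LDDMM) method and its deformation-magnitude
  proxy is only monotone in, not equal to, a metric distance.
- Eigenvector channels are resampled componentwise without tensor
  reorientation; absolute-value channels lose sign information by design.
- Background is modeled as an ordinary label with fitted intensity models;
  in images whose background is not statistically homogeneous this model is
  crude.
- With near-tied evidence the label update can oscillate by a handful of
  boundary voxels; such runs end at the 30-iteration cap (the changed
  fraction stays above tolerance but tiny), which is the method's defined
  behavior, not divergence.
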