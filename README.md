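# dtifusion

Multi-contrast multi-atlas likelihood fusion for diffusion-tensor image
parcellation, in R.

## The problem

Labeling every voxel of a diffusion-tensor (DTI) brain image with an
anatomical structure is the first step of most quantitative DTI analyses.
Single-atlas propagation fails where registration fails; plain multi-atlas
label voting ignores image intensity. DTI is peculiar in that no single
derived contrast separates all structures: CSF-filled spaces stand out in
mean diffusivity (MD), gray/white boundaries in fractional anisotropy
(FA), and differently oriented white-matter tracts only in the fiber
orientation channels. `dtifusion` is for researchers who want a
parcellation engine that uses all of this evidence at once, plus the
downstream ROI statistics, and a synthetic phantom framework to validate
every stage without clinical data.

## The model

Each voxel carries a five-component feature vector
*I(x) = (FA, MD, |e₁ₓ|, |e₁ᵧ|, |e₁ᵤ|)* — FA, MD (mm²/s) and the absolute
components of the primary eigenvector. For each atlas *a* and structure
*l*, every channel's intensity distribution is a Gaussian mixture

  p(I | l, a) = ∏₍c₎ Σₖ πₖ N(I_c; μₖ, σₖ²)

fitted by maximum-likelihood EM from the atlas's labeled voxels, with the
component count set by structure size (2 below 1000 mm³, 3 above). The
parcellation *W* maximizes the posterior given the image, with the
atlas-label selector (which atlas explains which voxel) and the
per-structure atlas-to-subject correspondences as latent variables. An
EM loop alternates:

1. **selector** — per voxel, weight each atlas by intensity likelihood ×
   structure overlap (Dice) × deformation-magnitude prior × local-affine
   Gaussian prior (variances 0.01 on the 9 linear parameters, 100 on the
   3 translations), normalized over atlases;
2. **labels** — per voxel, argmax over labels of the selector-weighted sum
   of intensity likelihood × trilinearly interpolated deformed label
   probability;
3. **correspondences** — per (atlas, structure), re-optimize a local
   12-parameter affine composed with the global diffeomorphic registration
   (two-channel FA + MD, greedy multi-resolution scheme with Gaussian
   velocity smoothing and a positive-Jacobian guard), by soft-Dice plus
   log-prior.

The loop stops on label stability (changed-voxel fraction < 1e-4) or after
30 iterations. ROI quantification reports structure volumes, mean FA and
mean MD; peripheral structures can be split into CSF / cortex / white
matter with the standard MD = 0.0015 mm²/s and FA = 0.2 thresholds (CSF
compartments are flagged excluded); scan-rescan and cross-subject
variability summaries use symmetric percent differences and std/mean.

## Worked example

Build a synthetic multi-atlas library, register, fit signatures, fuse, and
evaluate against the known ground truth:

```r
library(dtifusion)

spec <- defaultPhantomSpec(seed = 1)          # 48^3, 2.5 mm, 6 structures
lib  <- makeLibrary(spec, nAtlases = 4)       # atlases + held-out subject

fields <- lapply(lib$atlases, function(a)
  registerTwoChannel(a@image, lib$subject@image))
sigs <- lapply(lib$atlases, fitAtlasSignature, seed = 1)

res <- runFusion(lib$atlases, lib$subject@image, sigs, fields,
                 fusionConfig(verbose = TRUE))
#> iteration 1: changed 0.01511, objective 1.18e+06
#> iteration 2: changed 0.00011, objective 1.18e+06
#> iteration 3: changed 0.00010, objective 1.18e+06

round(diceByLabel(res$labels, lib$subject@labels, labels = 1:6), 3)
#>     1     2     3     4     5     6
#> 0.952 0.948 0.955 0.969 0.970 0.956
```

The per-iteration log shows the changed-voxel fraction falling below the
1e-4 stopping tolerance by iteration 3 while the surrogate objective (the
summed log fused score of the chosen labels) does not decrease. The Dice
row compares the fused parcellation with the subject's true labels, one
value per structure (ventricle, two gray nuclei, two tracts, peripheral
slab): all structures are recovered at Dice ≈ 0.95–0.97, versus ≈ 0.90–0.92
for the best single-atlas nearest-neighbour propagation on the same fields.

ROI statistics and the peripheral decomposition:

```r
dec <- decomposePeripheral(res$labels, lib$subject@image, peripheralIds = 6L)
head(roiStats(dec, lib$subject@image), 3)
#>   label n_voxels volume_mm3    mean_fa      mean_md
#> 1     1      980   15312.50 0.07838936 0.0027811567
#> 2     2      772   12062.50 0.16431003 0.0006564389
#> 3     3      935   14609.38 0.28245005 0.0006660496
```

Structure 1 is the CSF-filled ventricle (low FA, MD near 0.0028 mm²/s);
structures 2–3 are the gray nuclei (tissue MD ≈ 0.0007, FA 0.16 / 0.28).

Volumes are voxel counts × voxel volume (mm³); the CSF sublabel
(6001 = 1000·6 + 1) is excluded from the table by its flag.

A command-line entry point wraps the same functions
(`inst/cli/dtifusion simulate | features | fit-signatures | register |
parcellate | quantify`); every run writes a provenance manifest with its
parameters and seeds.

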