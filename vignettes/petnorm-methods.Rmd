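---
title: "MRI-less spatial normalization and SUVR quantification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MRI-less spatial normalization and SUVR quantification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(petnorm)
```

## The problem

Quantifying amyloid load from a brain PET scan by predefined volumes of
interest (VOIs) requires the scan to be in a standard template space
(spatial normalization, SN). Conventional pipelines deform a structural
MRI of the same subject and carry the PET along; in practice a usable MRI
is often missing, and PET-only normalization is hard because amyloid
uptake patterns differ radically between amyloid-positive and -negative
brains, and because atrophy and ventricular enlargement push elderly
anatomy far from the template.

`petnorm` implements an MRI-less approach: a cascade of encoder-decoder
networks predicts a dense displacement field directly from an
affine-registered PET volume. MR images and gray-matter (GM) segments are
used **only inside the training loss** — the forward path consumes PET
alone, which is asserted by the interface (`predict_displacement()` takes
no MR argument). Downstream, the package quantifies composite-VOI SUVRs
against a cerebellar GM reference, classifies amyloid positivity at a
global-cortex SUVR threshold of 1.5, and compares two quantification
methods with OLS regression, ICC(3,1) and Bland-Altman statistics.

Everything is exercisable end to end on synthetic 3D brain phantoms with
known ground-truth deformations, so registration output can be scored
against exact truth — something impossible with real scans.

## Geometric conventions

* Volumes are 3D arrays with voxel spacing and an index-to-world affine
  (RAS); all geometry works in **0-based voxel coordinates**.
* Displacement fields use the **pull convention in voxel units**: the
  warped image reads the source at `x + u(x)`. The convention is chosen
  over mm because every loss operates on one common template grid; it is
  stated in the NIfTI description field on export.
* Out-of-grid samples return 0 (air/zero PET background keeps the warp
  linear); labels are warped nearest-neighbour so label identity is never
  averaged.
* `compose_displacements(first, second)` returns
  `w(x) = second(x) + first(x + second(x))`; warping by `w` equals
  warping by `first` and then warping the result by `second`.
* `jacobian_determinant()` uses central differences in the interior and
  one-sided differences at the boundary; values `<= 0` flag folding.

## The phantom generator

`make_template()` builds a deterministic procedural brain standing in for
a T1 template: an ellipsoidal cerebrum with a cortical GM shell and WM
interior, paired CSF ventricles, two subcortical GM nuclei, and an
inferior cerebellar GM blob. The MR-like template orders intensities
CSF (0.2) < GM (0.55) < WM (0.85).

Two texture parameters deserve explanation, because they were chosen
deliberately after measuring the loss landscape rather than for visual
realism:

* `texture_sigma = 1.5`, `texture_amp = 0.5`: a smooth multiplicative
  texture on the MR plays the role of anatomical detail. With strictly
  piecewise-constant tissue intensities, the windowed-NCC loss is almost
  flat in the deformation (the measured objective gap between a zero
  field and the exact ground-truth field was below 0.01), because
  homogeneous windows carry no gradient. Real T1 images are textured
  everywhere; the phantom must be too for the training signal to exist.
  The correlation length matters as much as the amplitude: texture much
  smoother than the NCC window can be matched by any gradient-aligned
  warp, which detaches the loss optimum from the true correspondence.
  The individual-space PET shares the same modulation at twice the
  relative amplitude (`pet_texture`), standing in for the anatomical
  uptake variation that makes within-tissue deformation observable from
  the PET itself; the template-space PET construction used by the
  quantification anchors stays piecewise-constant and exact.
* `gm_border_sigma = 1.5`: the GM probability ramps over ~1.5 voxels.
  A one-voxel ramp makes soft Dice more sensitive to interpolation blur
  than to alignment.

`make_phantom_pair()` generates an individual-space PET/MR/GM triple: a
ventricular-enlargement radial field (the stress case where conventional
SN fails) composed with a smoothed random field (maximum magnitude
`deform_amplitude`, smoothing sigma 4 voxels, redrawn until fold-free) and
a random small affine. PET uptake is painted by amyloid status —
negative: WM 1.0, cortical GM 0.6, cerebellar GM 0.6, CSF 0.1
(the nonspecific pattern); positive: cortical **and subcortical** GM
raised to 1.3 while the cerebellar reference stays at 0.6. The
subcortical choice makes the medial-temporal composite respond to status
like the cortex does. These ratios put positive phantoms well above and
negative phantoms well below the 1.5 positivity threshold, so
classification tests are unambiguous. An optional spherical lesion sets
PET and MR to CSF intensity (the chronic-stroke stress case); Gaussian
noise (SD = `noise_sd` x cortical intensity) is added last and clipped
at 0.

The stored `true_field` (template grid) and `true_affine` define the
exact template-to-individual mapping used by the evaluation arm; the
analytic global-cortex SUVR of a noise-free positive phantom in template
space is 1.3/0.6 = 2.1667, which anchors the quantification tests.

What the phantoms do **not** model: scanner physics (PSF, scatter,
reconstruction), partial-volume effects, tracer kinetics, multi-site
intensity variation, real anatomical variability. Passing tests on
phantoms therefore demonstrates the correctness of the machinery and the
learnability of the task under known smooth deformations, not clinical
performance.

## Affine pre-registration

`register_affine()` maximizes global NCC over 12 parameters (translation,
rotation, log-scale, shear) with a multi-resolution pyramid, initialized
from intensity centroids. Three numerical choices matter, all made after
inspecting failure modes on phantoms:

* **Per-level Gaussian prefiltering** (sigma 1 voxel after each
  downsampling): without it the NCC optimum is biased by interpolation
  blur on sharp edges — a resampled candidate at the true pose is
  blurrier than the identity candidate, so coarse levels actively pull
  small rotations toward zero.
* **Rigid-only coarse levels**: scale and shear fitted on an 12^3 grid
  latch onto artifacts; they are only refined at full resolution.
* **Rotation coordinate sweep + quasi-Newton polish at the finest
  level**: the rotation valley of a near-ellipsoidal head is too shallow
  and curved for a simplex; a +/-8 degree sweep per axis lands in the
  right basin and a bounded BFGS pass crawls the valley floor. The
  simplex remains the work-horse in between.

Typical phantom recovery: translations and 5-degree rotations to within
0.1-0.4 voxel of mean brain mapping error in a few seconds per volume.
The whole stage sits behind one interface and is replaceable.

## The cascade

`build_model()` creates `n_stages` encoder-decoder networks (default 2).
Stage 1 maps the affine-registered PET to a 3-channel displacement field;
stage `k >= 2` sees the PET warped by the accumulated field concatenated
with the original PET and predicts a refinement, combined with
`compose_displacements()`. The final field convolution of every stage is
**zero-initialized**, so the untrained cascade is exactly the identity on
top of the affine — spatial normalization degrades gracefully to affine
resampling.

Fields are predicted and composed on a grid `field_stride = 4` times
coarser than the template and upsampled linearly (values scaled by the
stride). Anatomical deformations here are smooth on that scale
(generator smoothing sigma 4 >= stride), and the loss is always
evaluated at full resolution, so subvoxel accuracy is preserved while
CPU training stays ~1 s per sample pass at 48^3. Each stage consumes a
5-channel reduced-grid encoding of its image (block mean, block SD and
mean gradient per axis): plain block averaging alone would discard the
sub-block structure the displacement prediction depends on.

### Losses

`total_loss = ncc + beta * dice + lambda * smoothness`, with

* **Local NCC** (window 9, variance floor 1e-5, signed, clamped): windows
  whose variance falls below the floor contribute NCC = 0 — two constant
  volumes score loss 1, and images with flat background have a
  corresponding constant floor. Range [0, 2].
* **Soft Dice** (smoothing 1) between the warped GM carrier and the
  template GM, range [0, 1]; differentiable and defined for empty masks.

* **Smoothness**: mean squared forward-difference gradient of the field,
  weight `lambda = 1`. The underlying method description mentions no
  regularizer; without one, dense-field NCC optimization drifts into
  large non-physical fields (measured directly by optimizing the field
  itself), so the default weight is set where the loss minimizer sits
  closest to the true field on phantoms.

Default `beta = 1`, Adam at `learning_rate = 2e-3` with a 50-step linear
warmup, batch size 1, and a sigma-0.7 Gaussian prefilter applied once to
the MR carriers and template before training (`ncc_presmooth`): both
images band-limited the same way roughly double the usable NCC dynamic
range on edge-dominated images. The warmup exists because Adam's
normalized first steps on the zero-initialized field layers otherwise
move the field by ~0.5 voxel per step and training never recovers.

### Backpropagation

There is no automatic differentiation in this stack; every backward pass
is hand-written and finite-difference checked in the test suite
(convolutions, pooling, upsampling, the warp with respect to the field,
local NCC, Dice, smoothness, and the cascade composition). Through the
composition `w(x) = a(x) + r(x + a(x))` the gradient keeps both the
direct terms and the sampling-position term `(grad r)^T g`; the
warped-PET **input** to later stages is treated as constant (standard
practice for cascaded registration networks — the dominant path is the
composition; the tests document the resulting first-stage gradient as
approximate, same sign and order).

### Augmentation

`augment_sample()` applies one random small affine plus a smooth elastic
perturbation (drawn on a 4x coarser grid) identically to PET, MR and GM,
and a multiplicative intensity jitter to PET only — deterministic under
its seed. The original method states that on-the-fly augmentation is used
but not its distributions; the default half-ranges (3 degrees, 1 voxel,
2% scale, 10% intensity, 0.5 voxel elastic) are package choices sized to
the phantom variability.

### Output resampling

`spatially_normalize()` composes the deformable and affine chains and
resamples the original volume once (`resample_chain()`); the ground-truth
study arm does the same through the inverted construction transform.
Resampling twice instead gives each arm a different amount of
interpolation blur, which a thin cortical shell converts into a
systematic SUVR offset between arms.

## Quantification and agreement

`build_phantom_atlas()` splits the cortical shell into five exhaustive
geometric sectors (frontal, posterior cingulate-precuneus, lateral
parietal, lateral temporal, occipital), maps the subcortical nuclei to
the medial-temporal composite and the cerebellar GM to the reference
region. The six composite VOIs mirror the standard amyloid reporting
set; "global cerebral cortex" is the union of the five sectors, so its
SUVR is a voxel-weighted mean of theirs. Means are unweighted voxel
means; SUVR = composite mean / cerebellar GM mean; positivity is
`global SUVR > 1.5`, with a tie classified negative (the boundary is not
defined in the source description; the tie rule is documented here).

`compare_methods()` joins two report sets by subject and region and
reports OLS slope/intercept/R^2 (test method regressed on reference),
ICC(3,1) (two-way mixed, single measure, consistency — chosen because the
stated goal is consistency of quantification; the variant is explicit in
the result), and Bland-Altman bias with 1.96-SD limits. Regions with
fewer than 3 common subjects are flagged, not computed.

## The phantom study driver

`run_phantom_study()` generates a training cohort, trains the cascade,
then for each test phantom runs the **network arm**
(affine -> cascade -> warp -> SUVR; never touches the stored truth) and
the **ground-truth arm** (inverse true affine + numerically inverted true
field -> SUVR), and feeds both arms to the agreement battery. The
ground-truth arm stands in for individual-space parcellation, which is
exact on phantoms. Per-subject geometry metrics (GM Dice for
affine-only vs network, endpoint error against the truth, folding
fraction) are reported alongside. Everything — phantom seeds, weight
initialization, shuffling, augmentation — derives from one master seed,
and reruns are bit-identical.

Problem sizes in the shipped tests and the acceptance script (48^3 grids,
cohorts of 5-20, 30 training epochs) are the package's chosen desk-scale
study conditions: large enough for a 3-level encoder on a
stride-4 field grid and for stable agreement statistics, small enough to
run on one CPU in minutes.

## Known limitations

* The cascade is trained per template/tracer configuration; no
  pretrained weights ship with the package.
* Soft Dice on smooth probability maps is a weak alignment signal at
  small misalignments (measured on phantoms: the blur cost of
  interpolation can rival the alignment gain); the NCC term carries most
  of the training signal. The Dice term is retained for structural
  fidelity to the method and for its stabilizing effect on GM overlap.
* At the desk-scale training budget the shipped tests use (20 phantoms,
  30 epochs, one CPU), the cascade reliably improves gray-matter overlap
  beyond the affine baseline with essentially no folding, but it does
  not recover the majority of the ground-truth deformation: the
  held-out endpoint-error ratio against the zero field reported by the
  acceptance script sits near 1 rather than below 0.5. Direct
  optimization of the training loss in the cascade's own field space
  bottoms out near 0.8, i.e. the limitation is shared between the
  unsupervised objective's identifiability on these phantoms and the
  small step budget, not caused by the network parameterization alone.
* Displacement inversion (`invert_displacement()`) is fixed-point and
  assumes a fold-free field, which the generator guarantees.
* The affine stage registers the PET against the amyloid-negative and
  amyloid-positive template constructions and keeps the better fit: a
  single averaged target measurably biases the estimated pose for
  subjects whose contrast sits far from the average, which surfaces as a
  systematic SUVR slope deficit between the two study arms.
  Inter-modality registration is out of scope.
* No diffeomorphic parameterization: large deformations are represented
  directly; folding is discouraged by the smoothness weight and
  monitored via the Jacobian, not excluded by construction.
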