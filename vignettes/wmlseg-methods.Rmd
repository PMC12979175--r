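---
title: "Tri-planar dense U-Net segmentation of white-matter lesions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tri-planar dense U-Net segmentation of white-matter lesions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmlseg)
```

## The problem

Multiple-sclerosis white-matter lesions appear as hyperintense foci on FLAIR
MRI. Their number, volume and anatomical location (periventricular,
juxtacortical, infratentorial, deep white matter) drive diagnosis and
follow-up, but manual delineation is slow and poorly reproducible. `wmlseg`
implements a complete automated pipeline: intensity standardization,
slice-wise segmentation by three orientation-specific 2D densely connected
U-Nets fused by per-voxel majority voting, CSF-based false-positive removal,
anatomical classification of the segmented lesions, and a voxel- and
object-level evaluation suite. A synthetic brain phantom generator makes
every stage testable end to end without clinical data.

## Segmentation model

Each orientation (axial, coronal, sagittal) has its own 2D network operating
on the slices of that plane; on the canonical 1 mm grid of
160 x 256 x 176 voxels the slice shapes are (160, 256), (160, 176) and
(256, 176). The architecture is a U-Net whose feature extractors are dense
blocks: four sequential 3 x 3 convolution sub-blocks, where sub-block $k$
receives the concatenation of the block input and all previous sub-block
outputs, and the block output concatenates all four sub-block outputs. The
encoder is an initial 3 x 3 convolution followed by two dense-block +
max-pool levels; a single dense block forms the bottleneck; the decoder
mirrors the encoder with 2 x 2 transposed convolutions and long skip
connections from the encoder; a 1 x 1 convolution with a sigmoid produces
the per-pixel lesion probability. Weights are He-normal initialized.

Several architectural details are deliberate package choices where the
design space was open: ReLU activations; "same" zero padding; 2 x 2 max
pooling; transposed-convolution upsampling; batch normalization after every
convolution except the output head; dense-block growth equal to
`base_filters` at full resolution and doubling at each encoder level
(`base_filters = 16` by default, 8 in the scaled-down experiments below).
Batch normalization earns its place empirically: without it, Tversky-loss
training on severely imbalanced slices can drive the sigmoid output into
saturation early (every gradient then vanishes through $p(1-p)$) and the
network dies predicting empty masks. Spatial dimensions are zero-padded
internally to a multiple of 4 — two pooling levels — and cropped back, so
any slice shape is accepted; the canonical shapes need no padding.

## Loss and optimization

Class imbalance is extreme: lesions occupy well under 1% of voxels. Training
minimizes the Tversky loss per slice,

$$L_T = 1 - \frac{\sum_i p_i g_i + \epsilon}
{\sum_i p_i g_i + \alpha \sum_i p_i (1 - g_i) + \beta \sum_i (1 - p_i) g_i
+ \epsilon},$$

with $\alpha = 0.3$, $\beta = 0.7$, $\epsilon = 10^{-6}$: false negatives
(missed lesion voxels) are penalized more than false positives. At
$\alpha = \beta = 0.5$ the loss reduces to one minus soft Dice, which the
test suite exploits as an independent oracle. The analytic gradient is
verified against finite differences, both for the bare loss and through the
whole network.

The optimizer is RMSprop with squared-gradient decay 0.9, heavy-ball
momentum 0.95 and initial learning rate $10^{-3}$. Two numerical safeguards
are package choices: the normalized update is clamped to 10 units per
parameter and step (momentum can otherwise compound normalized gradients
into steps that saturate the output sigmoid), and a non-finite loss aborts
training with the epoch number. Early stopping monitors the validation
Tversky loss (validation Dice is logged alongside): training ends when the
loss has not improved for `patience` consecutive epochs (default 10,
`max_epochs` 100), and the parameters of the best validation epoch are
returned. The repeated-split harness (`make_cv_splits()`) draws 10
independent random splits, each holding out 20% of the subjects.

## Inference and post-processing

A conformed, standardized volume is cut into slices along each of the three
axes, each orientation model predicts per-slice probability maps, and the
maps are reassembled into three 3D probability volumes. Fusion binarizes
each volume at 0.5 and keeps voxels with at least 2 of 3 votes; voting on
binarized maps (rather than averaged probabilities) is the package's reading
of majority voting, and the threshold is configurable. Because
FLAIR-hyperintense structures inside the ventricles (choroid plexus, pineal
gland) are classic false positives, voxels where the CSF partial volume
exceeds 0.5 are then removed from the lesion mask. The mask is cleaned
rather than the input image, which is equivalent for removing CSF-interior
detections and keeps inference independent of the post-processing choice.

## Intensity standardization

MR intensities are scanner- and subject-dependent. `fit_standardizer()`
learns histogram-landmark positions — percentiles p1, p10, ..., p90, p99 of
the within-brain histogram, mapped affinely so p1 and p99 land on a fixed
[0, 100] scale — and averages them across training volumes.
`apply_standardizer()` maps a new volume piecewise-linearly so its own
landmarks land on the learned ones, extrapolating linearly beyond p1/p99 and
zeroing the background. The map is monotone and invariant to positive affine
intensity changes of the input, which the tests verify to $10^{-4}$. The
landmark set and output scale are conventional defaults for this family of
methods and are configurable; histograms are computed only within the brain
mask because background voxels would otherwise dominate the percentiles.
Standardization is applied after grid conformance.

## Anatomical classification and lesion counting

Lesions are 26-connected components. The periventricular band binarizes the
CSF partial-volume map at 0.5, dilates it with a spherical structuring
element (radius 3 voxels, the sphere inscribed in a 7 x 7 x 7 cube) and
subtracts the binarized map; the juxtacortical band repeats the construction
on the cortical-GM map. Each component is labeled by the first rule it
matches, in the priority order infratentorial (single-voxel overlap with the
brainstem/cerebellum mask) > periventricular > juxtacortical > deep white
matter; the priority order mirrors the mutually exclusive McDonald location
classes. Confluent components are split by intensity: the FLAIR signal
restricted to the component is Gaussian-smoothed (sigma 1 mm) and strict
26-neighborhood local maxima at least 3 voxels apart are counted, with a
floor of one; this explicit local-maxima procedure stands in for
random-field-based cluster analysis, whose parameters are not part of this
package's scope. Lesion volumes in ml stratify into the standard bins
small < 5 ml, medium 5-15 ml (boundaries inclusive), large > 15 ml.

## Evaluation metrics

`evaluate()` reports voxel Dice ($2TP/(2TP+FP+FN)$), PPV ($TP/(TP+FP)$),
object-level Dice, object-level detection rates and the average symmetric
surface distance. Object Dice pairs every reference component with the
predicted component of maximal voxel overlap (ties to the smaller label,
unmatched objects score 0) and averages the two directed size-weighted sums.
OTPR is the fraction of reference objects touched by any predicted voxel.
Because object-level true negatives do not exist, the object false-positive
rate is implemented as the fraction of predicted objects with no reference
overlap (one minus object precision) and documented as such. ASSD uses
surface voxels (mask voxels with a face-adjacent background neighbor, grid
border counting as background) and an exact anisotropy-aware Euclidean
distance transform; the denominator counts surface voxels of both masks.
Degenerate cases are fixed conventions: two empty masks score Dice 1 and
PPV 1, PPV is NaN for an empty prediction against a nonempty reference,
object rates are NaN when their object set is empty, and ASSD is an error
(NaN inside `evaluate()`) for empty masks. Size-stratified object Dice
restricts the reference-side sum to reference objects of each bin with
weights renormalized within the bin.

## The synthetic phantom

`generate_phantom()` emulates every input the pipeline needs: concentric
ellipsoids build a brain envelope with a cortical GM shell, a central
ventricular cavity (CSF) and a posterior-inferior infratentorial region;
partial-volume maps come from Gaussian-smoothing the hard tissue labels
(sigma 1 mm); FLAIR levels follow the clinical ordering CSF (10) < WM (42) <
GM (52), lesions add a contrast of 30 over WM, and Gaussian noise
(sigma 2) is added, giving a lesion contrast-to-noise ratio comparable to a
well-behaved clinical FLAIR. Lesion spheres (radius 2-4 mm by default) are
placed by rejection sampling over distance-transform constraints so that
each provably satisfies its class rule with margin — periventricular spheres
abut the ventricle without entering CSF, juxtacortical spheres abut the GM
shell, infratentorial spheres lie inside the infratentorial region, deep-WM
spheres keep at least the band width plus margin away from everything — and
lesions are mutually separated so each is its own 26-connected component. A
bright distractor blob inside the ventricle mimics the choroid plexus. The
default per-phantom lesion load (2 periventricular, 1 juxtacortical, 1
infratentorial, 2 deep-WM) reflects the typical predominance of
periventricular lesions.

What the phantom does *not* model: bias fields, multi-contrast physics,
partial Fourier or motion artifacts, irregular lesion shapes, cortical
folding, and realistic ventricle geometry. Tests passing on phantoms
therefore demonstrate that the implementation is correct and that the
architecture can learn hyperintense-lesion segmentation, not that clinical
accuracy on patient data is attained.

## Scaled-down study conditions

All training in the test suite and acceptance script runs on one CPU at
deliberately small problem sizes: the 2D blob task (64 x 64 images, 200
training / 50 validation, `base_filters = 8`, up to 3 epochs) checks that
the network learns to validation Dice at least 0.85; the end-to-end check
trains three orientation models (`base_filters = 4`, 3 epochs) on a family
of five 64-cubed phantoms and segments a held-out phantom to Dice at least
0.70 after majority voting and CSF post-processing. Training is
deterministic per seed (single-threaded BLAS, seeded R RNG for
initialization and shuffling).

## Known limitations

* Conformance assumes co-registered, axis-aligned inputs; no registration is
  performed (affine rotation is not resampled away, only axis flips are
  normalized at read time).
* The anatomical classifier inherits any segmentation errors and has no
  expert-labeled ground truth; on phantoms it is validated only against the
  generator's construction rules.
* The local-maxima lesion counter is a documented stand-in for
  random-field cluster analysis, not a claimed equivalence.
* The networks here are CPU-scale; clinical-scale training (large volumes,
  many subjects, GPU) is out of scope for the packaged experiments, though
  the implementation itself is size-agnostic.
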