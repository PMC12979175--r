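# wmlseg

Automated segmentation and anatomical classification of multiple-sclerosis
white-matter lesions on 3D FLAIR MRI, implemented as a self-contained R
package. Lesions — hyperintense foci whose count, volume and location
(periventricular, juxtacortical, infratentorial, deep white matter) are core
MS biomarkers — are segmented by three orientation-specific 2D densely
connected U-Nets whose probability maps are fused by per-voxel majority
voting, then cleaned of CSF-interior false positives (choroid-plexus-like
structures) and classified anatomically. The package is aimed at
neuroimaging methodologists who want a fully inspectable, dependency-light
reference implementation of this pipeline, complete with a synthetic brain
phantom so every stage runs and is tested without clinical data.

## Method

A conformed (1 mm isotropic, 160 x 256 x 176) and intensity-standardized
FLAIR volume is cut into axial, coronal and sagittal slices. Each
orientation has its own 2D dense U-Net: an encoder of dense blocks (four
3 x 3 conv sub-blocks, each receiving the concatenation of the block input
and all previous sub-block outputs) with 2 x 2 max pooling, a dense-block
bottleneck, and a symmetric decoder with transposed-convolution upsampling
and encoder skip connections, ending in a 1 x 1 convolution with sigmoid.
Training minimizes the Tversky loss

    L = 1 - (Σ p·g + ε) / (Σ p·g + α Σ p(1-g) + β Σ (1-p)g + ε),

with α = 0.3, β = 0.7 (false negatives cost more than false positives,
countering the extreme lesion/background imbalance), using RMSprop
(learning rate 1e-3, momentum 0.95) with early stopping on the validation
Tversky loss. At inference the three reconstructed probability volumes are
binarized at 0.5 and fused by a 2-of-3 vote; voxels with CSF partial volume
above 0.5 are removed. Segmented lesions (26-connected components) are
classified by overlap with the infratentorial atlas mask, a dilated-CSF
band (7-voxel spherical element) and the analogous cortical-GM band, in
that priority order; confluent lesions are counted via smoothed-intensity
local maxima. The evaluation suite implements Dice, object-level Dice
(maximal-overlap pairing, size-weighted, symmetric), PPV, object-level
detection rates and the average symmetric surface distance, with
brute-force oracles in the tests. The backprop, conv/pool/transposed-conv
and batch-norm kernels are written in C++ (RcppArmadillo); no deep-learning
framework is required.

## Worked example

Generate a phantom, corrupt its truth mask into a fake "prediction", and
evaluate; then classify the true lesions anatomically:

```r
library(wmlseg)

ph  <- generate_phantom(phantom_spec(seed = 42))
ctx <- anatomy_context(ph$csf_pv, ph$gm_pv, ph$infratentorial_mask)
classify_lesions(ph$lesion_truth, ctx, ph$flair)
#>   component_id voxel_count volume_ml        location n_sublesions
#> 1            1         147     0.147  infratentorial            1
#> 2            2         251     0.251         deep-WM            1
#> 3            3         171     0.171         deep-WM            1
#> 4            4         123     0.123   juxtacortical            1
#> 5            5         203     0.203 periventricular            1
#> 6            6         251     0.251 periventricular            1

set.seed(1)
pred <- ph$lesion_truth$data
flip <- sample(which(pred == 1), 60)   # delete 60 lesion voxels
pred[flip] <- 0L
evaluate(ph$lesion_truth, pred)
#> Segmentation metrics (6 reference / 6 predicted objects)
#>   Dice      0.9731   Dice_obj 0.9731   PPV  1.0000
#>   OTPR      1.0000   OFPR     0.0000   ASSD 0.1347 mm
#>   Dice_obj by size: <5 ml 0.9731 | 5-15 ml NaN | >15 ml NaN
```

Each lesion row reports its 26-connected component id, volume in ml, its
anatomical class and the number of sub-lesions found by local-maxima
counting. The metrics report reads: 97.3% voxel overlap, perfect precision
(only true voxels were kept), all six reference lesions detected (OTPR 1),
no spurious components (OFPR 0), and an average surface distance of about
0.13 mm.

Training and end-to-end segmentation follow the same functional style —
`train_orientation_model()` on slice sets from `phantom_slices()` or your
own data, then `segment_volume(flair, models, csf_pv)`; see the methods
vignette (`vignettes/wmlseg-methods.Rmd`) for the full model description.
A thin command-line wrapper (`exec/wmlseg`) exposes the stages as
`wmlseg phantom|standardize|train|predict|evaluate|classify|crossval`.

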