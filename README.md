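# SymSlice

Rotation- and translation-invariant classification of 3D organ images
(CT/MRI-like volumes), for image-analysis researchers and engineers who
need volume classification that does not assume consistent patient
orientation or imaging direction.

## The method

Most 3D medical-image classifiers assume the scan is consistently oriented
(mid-sagittal plane centred, slices in the superior–inferior direction) and
fail when that assumption breaks. SymSlice removes the orientation
dependence geometrically, before any classifier sees the data:

1. **Volume reconstruction.** A DICOM series is stacked by `InstanceNumber`
   and resampled to an isotropic grid by cubic interpolation, with the new
   array size
   `[n_x, round(n_y·ps_y/ps_x), round(n_z·st/ps_x)]`
   for in-plane spacings `(ps_x, ps_y)` and slice thickness `st`.
2. **Segmentation.** Two-threshold global Otsu banding: the histogram is
   split into three classes and voxels inside the middle band
   `[t_low, t_high]` become the organ point cloud, excluding artifacts at
   both intensity extremes.
3. **Symmetry plane.** The cloud is reflected about an initial plane, the
   reflection is registered to the original with point-to-point ICP, and
   the composite map `S(x) = Mx + c` is eigen-decomposed: for a symmetric
   shape `M` has eigenvalues `{-1, 1, 1}`, the eigenvector at `-1` is the
   plane normal `n`, and the offset is `d = (n·c)/2`. Multi-start over the
   cloud's principal axes, lowest ICP residual wins.
4. **Representative slice.** The 2D image lying on the symmetry plane is
   sampled by nearest neighbour on a frame anchored to the cloud, then
   rescaled to 8 bits and resized to 224×224. Because the plane moves with
   the anatomy, this image is essentially orientation-free.
5. **Classification.** A compact 20-layer CNN (4 × conv/batch-norm/ReLU/
   max-pool blocks, then dense + softmax), or optionally HOG features with
   a cross-validated linear SVM. Evaluation uses micro accuracy and
   macro-averaged sensitivity, specificity, precision, F-measure and
   G-mean.

The package also ships the orientation-perturbation machinery used to test
invariance (random ±15° rotations with ±5-voxel translations, random axis
swaps, stratified dataset assembly) and a four-class synthetic phantom
generator (head, thorax, breast, abdomen) with known ground-truth symmetry
planes, so the whole pipeline is testable offline.

## Worked example

```r
library(SymSlice)

ph <- generatePhantom("head", seed = 1)   # known truth: plane x = 47.5
ph$volume
#> VolumeGrid: 96 x 96 x 40 voxels, spacing (0.8, 0.8, 2.4) mm
#>   intensity range [-13.17, 267.3]

rep <- extractRepresentative(ph$volume)
rep$plane
#> SymmetryPlane: n = (1.0000, 0.0000, -0.0000), d = 47.502, residual RMS 0.0489
rep$thresholds
#> IntensityThresholds: [62.87, 185.8]
rep$image
#> RepresentativeImage: 224 x 224, 8-bit, mean intensity 81.4
writeRepresentativeImage(rep$image, "head.png")
```

The estimated plane normal is the x axis and the offset 47.502 voxels —
within 0.002 voxels of the phantom's ground truth (47.5); the thresholds
bracket the soft-tissue band between the background (~5) and bone (~250)
tiers. A confusion matrix from a classification run is summarized as:

```r
cm <- matrix(c(10,0,0,0, 1,9,0,0, 0,0,10,0, 0,0,1,9), 4, 4, byrow = TRUE,
             dimnames = list(PHANTOM_CLASSES, PHANTOM_CLASSES))
computeMetrics(cm)
#> MetricReport (accuracy micro; other metrics macro over classes):
#>    Accuracy Sensitivity Specificity   Precision   F-Measure      G-Mean
#>      0.9500      0.9500      0.9833      0.9545      0.9499      0.9659
```

The full experimental grid (3 test conditions × optional training
augmentation) is run by `runExperiment()`; a thin CLI with `extract`,
`simulate`, `split` and `experiment` subcommands is installed at
`inst/scripts/symslice`.

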