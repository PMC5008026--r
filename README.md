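# sblda — single-block linear detection for CT liver segmentation

`sblda` segments the liver from 2D abdominal CT slices with a
non-iterative, initialization-free edge detector, plus the morphological
postprocessing that turns edge evidence into one liver mask, the standard
evaluation metrics for comparing a predicted mask against a reference, and
a synthetic CT-phantom generator so the entire pipeline can be exercised and
validated without any external dataset. It is aimed at medical-image
analysis work where a fast, dependency-light 2D liver segmenter or its
building blocks (directional ratio detector, surface-distance metrics, CT
phantom) are useful.

## The method

Organ boundaries in windowed CT appear as thin dark interfaces (fat planes)
between brighter tissues. For each pixel and each direction
θ ∈ {0°, 45°, …, 315°}, the detector compares a candidate point `V_c` (one
grid step along θ) against two flanking `N×N` block means `C1`, `C2`
centered `⌊w/2⌋` pixels from the candidate along the same axis:

```
R_c = (C1 + C2 − 2 V_c) / (2 V_c)
```

`R_c` is scale-free and large when the candidate is much darker than both
flanks — a dark-line response. A pixel becomes edge evidence when
`max over θ of |R_c| ≥ T`. The published operating point `T = 0.85`,
`w = 9`, `N = 3` is the default. Postprocessing: opening (outlier removal) →
largest edge network → inversion + erosion (contours become separated
interior regions) → intersection with an Otsu-based body mask that removes
air and ring artifacts → anatomical selection (largest region in the left
part of the image) → Gaussian smoothing + majority-filter reconnection.

Evaluation covers the confusion-matrix metrics (sensitivity, specificity,
accuracy) and the liver-challenge volume/surface metrics: VOE, signed RVD,
and the symmetric surface distances ASD / RMSD / MSD in millimetres.

## Worked example

Generate a phantom with known ground truth, segment it, and evaluate:

```r
library(sblda)
ph <- generate_phantom(phantom_spec(seed = 3))   # 320x320 axial phantom, 10 HU noise
mask <- segment_liver(ph$slice)                  # published defaults T=0.85, w=9, N=3
report <- evaluate_segmentation(mask, ph$truth, spacing = ph$slice$spacing)
print(report)
dice(mask, ph$truth)
```

```
Segmentation report
  TP 20557  FP 0  FN 1816  TN 80027
  sensitivity 0.9188  specificity 1.0000  accuracy 0.9823
  VOE 8.12%  SRVD -8.12%
  ASD 4.620 mm  RMSD 4.639 mm  MSD 5.940 mm
Dice: 0.9577
```

Reading this: the mask covers 92% of the true liver with zero false
positives; overall pixel accuracy is 98.2%. The miss is a thin band just
inside the true boundary — the detector marks the dark interface *outside*
the liver tissue and the inversion step erodes by 2 px, so the mask sits
systematically a few pixels inside the truth (VOE ≈ 8%, ASD ≈ 4.6 mm at
1.4 mm pixels). The negative signed RVD says undersegmentation.

Real data goes through the same API: `read_ct_slice()` reads single-slice
DICOM (uncompressed little-endian), NIfTI volumes (one plane at a time) and
PNG/TIFF rasters; `write_mask()` round-trips binary masks losslessly.

A command-line interface wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/sblda.R", package = "sblda"))')
Rscript $CLI phantom --seed 3 --out demo/
Rscript $CLI segment demo/phantom.nii.gz --out-mask demo/pred.png
Rscript $CLI evaluate demo/pred.png demo/truth.png --spacing 1.4 1.4
Rscript $CLI sweep-threshold --tmin 0.82 --tmax 1.0 --step 0.02 --seed 1 --out sweep.csv
```

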