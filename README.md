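# usnerveseg

Automated segmentation of the median nerve in ultrasound images, and the
reliability of the cross-sectional areas (CSA) it produces, as a fully
tested desk-scale R pipeline. The median nerve swells at the wrist in carpal
tunnel syndrome while the forearm segment stays normal, so wrist CSA
(reference 9.8 ± 2.4 mm²) and the wrist-to-forearm ratio are the clinical
endpoints; measuring them automatically requires a segmentation model whose
pixel overlap *and* downstream CSA agreement are both validated.

The package implements the complete analysis chain:

* **Phantom synthesis** — speckle-textured tissue images with a single
  hypoechoic elliptical nerve of *known* polygon area, site-specific depth
  and size distributions (wrist vs forearm), and a simulated human rater
  that traces boundaries with configurable jitter and bias. All study claims
  are tested against this known ground truth; no clinical data ships with
  the package.
* **Preprocessing** — tracing-to-mask polygon fill (nonzero winding over
  pixel centers), center-crop and symmetric zero-pad canvas geometry with
  recorded offsets (1024 × 690 → 1024 × 1024 at full scale; ÷8 desk scale).
* **Intensity augmentation** — the 11-variant protocol: the original plus
  CLAHE (clip limits 0.01/0.02/0.03, 8 × 8 / 8 × 8 / 16 × 16 tiles), gamma
  (0.70, 0.80, 1.20, 1.30) and multiplicative speckle noise (variance
  0.10, 0.20, 0.30), applied independently, masks passed through bit-exactly
  (35 stills → 385 pairs; 26 → 286).
* **Segmentation network** — a 4-level U-shaped encoder–decoder (two 3 × 3
  convolutions + ReLU per level, 2 × 2 max-pool between levels, learned
  2 × 2 transposed-convolution upsampling with skip concatenations, softmax
  head), trained with Adam on categorical cross-entropy. The convolution
  forward/backward kernels are the package's own vectorized C++ (no
  deep-learning framework), verified against a naive double-precision
  reference network and finite differences.
* **Metrics** — Dice = 2·TP/((TP+FP)+(TP+FN)), IoU = TP/(TP+FP+FN),
  accuracy, precision, specificity, sensitivity; per-image mean ± sample SD.
* **CSA reliability** — paired differences (manual − predicted) with t/CI,
  Pearson r with Fisher-z interval, ICC(2,1) with the F-based interval, and
  Bland–Altman limits of agreement (bias ± 1.96 SD).
* **Experiment designs** — seeded 80-20 baseline splits, cross-dataset
  generalization (train on one intensity domain, test on a gamma-shifted
  one, with and without the augmentation protocol), and repeated
  randomized-split stability trials.

## Worked example

The scaled baseline experiment — 200 wrist phantoms at 128 × 128, an 80-20
split, 30 epochs of the desk profile — runs in about 10 minutes on one CPU:

```r
library(usnerveseg)

spec  <- phantom_spec("wrist")                       # 9.8 ± 2.4 mm², 0.1 mm/px
pairs <- simulate_phantom_dataset(200, spec, rater_model(), seed = 7)
pairs <- preprocess_pairs(pairs, canvas_spec())      # crop 128×87, pad 128×128
prof  <- scaled_profile(seed = 7)                    # 8 filters, 30 epochs, Adam 1e-3
rep   <- run_baseline(pairs, prof$net, prof$train)

print(rep$summary["mean", c("dice", "iou")])
cat("CSA: mean diff", rep$agreement$mean_diff,
    "mm^2, ICC(2,1)", rep$agreement$icc21, "\n")
```

Output from this exact run:

```
          dice       iou
mean 0.9994467 0.9988959
CSA: mean diff 0.0125 mm^2, ICC(2,1) 0.9991425
```

The held-out test Dice of 0.999 says the network segments phantoms almost
perfectly — phantoms are far easier than clinical ultrasound, where Dice
values of 0.91–0.96 are what good systems report. The CSA mean difference of
0.013 mm² (manual simulated-rater tracing minus network prediction) is
negligible against the 9.8 mm² wrist reference, and ICC(2,1) ≈ 0.999 says
the two measurement routes rank and scale subjects almost identically.

The numbered scripts under `analysis/` run the full study narrative:
phantom simulation, the 11-variant augmentation, the baseline experiment,
cross-domain generalization with and without augmentation, five-trial
stability, and CSA agreement, each writing tables under `results/`.

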