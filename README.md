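# thermaltrack

Automated detection and recognition of wild animals in top-view thermal
imagery, for people building wildlife-friendly farming tools: mowing
machinery and UAV surveys kill or miss thousands of leverets, fawns and
ground-nesting birds each year, and a thermal camera over the field sees
warm bodies that RGB cannot. The hard part is not finding hot pixels — sun
heats lamps, molehills and bare soil too — but deciding *which* hot objects
are animals, and doing so robustly across camera altitude.

`thermaltrack` implements a complete pipeline:

1. **Detection.** Each frame is thresholded at `th = t̃ + c`, the median
   frame temperature `t̃` plus a fixed offset (`c = 5` °C by default). The
   median adapts to scene-wide warming but is untouched by the hot objects
   themselves. Above-threshold pixels are grouped into 8-connected blobs.
2. **Thermal signature.** For each blob the *signature* `cm(i)`,
   `i = −1, 0, …, M`, records the mean temperature of successive contours:
   one dilation ring just outside the object (`i = −1`), then the
   4-connected perimeter, which is peeled off repeatedly until the object
   is exhausted. Animals, insulated by fur or feathers, show a steep
   temperature rise just inside their boundary; lamps are uniformly hot,
   molehills gently mounded. The signature is invariant to translation and
   right-angle rotation, and — after subtracting the `i = −1` background
   ring — to absolute scene temperature.
3. **DCT features.** The normalized signature is parameterized by the
   first 7 coefficients of a length-compensated orthonormal cosine
   transform (type II), so objects with different contour counts map into
   one feature space. Seven coefficients capture ≥ 95% of signature energy
   for nearly all animal signatures.
4. **kNN classification.** A k-nearest-neighbour vote (`k = 11`) over a
   labeled training set returns both a label and the likelihood ratio
   `g_A = k_A / k` (animal neighbours over k).
5. **Tracking and belief.** Detections are linked across frames through
   *guess regions* (centre extrapolated from the last movement, gate
   radius 190 px, up to 3 missed frames). Each track carries an animal
   belief updated per detection by Bayes' rule,
   `Bel(n) = Bel(n−1)·g_A / (Bel(n−1)·g_A + (1−Bel(n−1))·(1−g_A))`,
   with `g_A` clamped to [0.05, 0.95]. A finished track is an animal if its
   belief exceeds 0.5, and all its members inherit that label — so frames
   where the camera was too high to classify reliably are relabeled by the
   frames where it was not.

Because no field recordings ship with the package, a first-class synthetic
generator renders ground-truthed scenes — warm animals with steep edge
gradients, hot halogen-lamp disks, shallow molehill mounds, Gaussian scene
clutter, inverse-square footprint scaling and radiative dimming with
altitude — so every stage is testable end to end.

## Worked example

```r
library(thermaltrack)

# a noise-free synthetic scene with one animal at 5 m altitude
sp <- scene_spec(shape = c(96, 96), noise_sd = 0,
                 objects = list(object_spec("animal", c(48, 48))), seed = 2)
sc <- generate_scene(sp)

blob <- detect_objects(sc$frame)[[1]]
blob
#> <blob> frame 0, area 373 px, centroid (48.0, 48.0), peak 31.00 degC

sig <- extract_signature(sc$frame, blob)
sig
#> <thermal_signature> M = 10, cm(-1..10) = 21.61, 26.27, 29.15, 29.44,
#>   29.61, 29.80, 29.98, 30.16, 30.37, 30.58, 30.78, 31.00
```

The signature jumps 7.5 °C across the first two contours (the insulation
edge), then climbs gently to the 31 °C core — the animal fingerprint.

```r
fv <- dct_parameterize(normalize_signature(sig))
fv
#> <feature_vector> [7.452, -1.816, -1.045, -0.992, -0.729, -0.566, -0.364] (N = 12)
energy_fraction(normalize_signature(sig), 7)
#> 0.999

# belief after one detection with 6 of 11 animal neighbours
update_belief(0.5, 6/11)
#> 0.545

# evaluation arithmetic on a close-range confusion matrix
confusion_metrics(confusion_matrix(tp = 2056, fp = 332, fn = 330, tn = 1663))
#> accuracy            0.849
#> balanced accuracy   0.848
#> sensitivity (TPR)   0.862
#> specificity (TNR)   0.834
```

Balanced accuracy — the mean of sensitivity and specificity — is used
throughout because altitude-dependent detection loss unbalances the
classes: animals vanish from the data faster than lamps as the camera
climbs.

## Command line

A thin CLI over the same functions lives at `inst/cli/thermaltrack.R`:

```sh
Rscript inst/cli/thermaltrack.R pipeline --seed 5 --output run1
Rscript inst/cli/thermaltrack.R evaluate --input cm.csv --output report.json
```

Subcommands `simulate`, `detect`, `features`, `train`, `classify`,
`track`, `evaluate`, `pipeline`; flags `--config`, `--seed`, `--output`,
`--input`, `--training`, `--c-offset`, `--k`, `--radius`, `--max-missed`.
Every stage writes inspectable artifacts (TIFF + JSON sidecar, CSV feature
tables, track JSON).

## Package layout

- `R/thermal-frame.R`, `R/io.R` — frame/sequence types, TIFF + sidecar I/O
- `R/detection.R` — dynamic threshold, segmentation, blob extraction
- `R/signature.R`, `R/dct.R` — contour peeling, DCT parameterization
- `R/classification.R` — kNN training sets, likelihood ratio, clamping
- `R/tracking.R` — guess regions, association, belief updates
- `R/metrics.R` — confusion metrics, detection performance, footprints
- `R/synthetic.R` — ground-truthed scene/sequence/training generators
- `R/benchmark.R` — system-level synthetic experiments
- `R/pipeline.R` — stage runners and YAML config behind the CLI
- `vignettes/thermal-wildlife-pipeline.Rmd` — methods and design notes
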