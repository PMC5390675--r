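# lobdetect

Sliding-window detection of **lobulation imaging signs** in 2D lung CT
slices.

Lobulation — an undulating, indented margin of a round or oval lung
lesion — is a CT imaging sign associated with malignancy. Detecting it
directly is hard: lobulations are small, heterogeneous in depth and count,
and classical lesion-segmentation pipelines fail on them. `lobdetect`
implements a detection framework that slides a fixed window (30 px; 31 px
for LIOP-based detectors) over the lung parenchyma and classifies every
window with one of three detector families:

1. **Template matching (A1).** Eight oriented base ROIs are expanded by 6
   length–width ratios (1:0.8 … 1:1.3) and 3 scalings (1.1, 1.2, 1.3) into
   a 72-template bank. Each template is matched by zero-mean normalized
   cross-correlation, `NCC(f, g) = ⟨f−f̄, g−ḡ⟩ / (‖f−f̄‖‖g−ḡ‖) ∈ [−1, 1]`,
   computed densely in the frequency domain and subsampled on the sliding
   step grid; the pooled top-N responses become detections.
2. **Local features + encoding + SVM (A2–A9).** Local descriptors — dense
   SIFT (PHOW), HOG, shape context, global curvature context, LIOP, LBP,
   and their fusions — are pooled into a fixed-length vector by
   bag-of-features, VLAD, or Fisher-vector encoding over a k-means/GMM
   codebook, then classified by a degree-3 polynomial-kernel SVM.
3. **Bending-energy filtering (A10a/A10b).** Candidate windows are
   binarized by Otsu's threshold; the closed margin contour is traced and
   its *average bending energy per unit length*
   `E = (1/P) ∫ k(p)² dp`
   is computed from a truncated Fourier series of the arc-length
   parameterization `(x(p), y(p))`. A circle of radius r has `E = 1/r²`,
   so smooth margins score low while undulating ones score high; windows
   with `E ≥ θ₁ = 0.0124` and foreground-area fraction `≤ θ₂ = 0.8` are
   kept, cutting false positives.

Evaluation uses APPI (average positive detections per image), SNTP
(average true positives per image), recall, precision, and
`F1 = 2PR/(P+R)`.

Because real annotated CT corpora cannot ship with a package, `lobdetect`
includes a **synthetic lung phantom**: a −800 HU lung disc (radius 180 px,
matching the circular parenchyma model) with vessel-like clutter and
nodules whose margin follows `r(φ) = r₀(1 + a·sin(mφ))`. The margin has a
closed-form curvature, so every nodule carries an analytic reference
bending energy — the end-to-end oracle for every stage.

## Worked example

```r
library(lobdetect)

# a seeded 20-image phantom benchmark (16-bit TIFF + HU sidecars + CSVs)
dir <- tempfile()
phantom_benchmark(dir, n_images = 20, mix = 0.5, seed = 42)
bench <- load_benchmark(dir)

# train the LIOP-LBP + BOF detector (A9) on the train split
model <- train_from_benchmark(bench, algorithm = "A9", seed = 42)

# detect on the test split, then apply the bending-energy filter
dets <- detect_benchmark(bench, model, step_px = 12, split = "test")
filt <- detect_benchmark(bench, model, step_px = 12, split = "test",
                         bend = bending_filter_params())

gt <- bench$gt[bench$gt$source_id %in% bench$manifest$test, ]
compute_metrics(dets, gt, image_ids = bench$manifest$test)
#> Detection metrics over 10 image(s) [greedy one-to-one, IoU >= 0.25]
#>   SNTP 1.70 | APPI 6.00 | recall 100.00% | precision 28.33% | F1 0.4416
compute_metrics(filt, gt, image_ids = bench$manifest$test)
#> Detection metrics over 10 image(s) [greedy one-to-one, IoU >= 0.25]
#>   SNTP 1.70 | APPI 3.00 | recall 100.00% | precision 56.67% | F1 0.7234
```

The filter halves APPI (6.0 → 3.0 false+true positives per image) while
keeping every true positive — the phantom analogue of bending-energy
false-positive reduction, where smooth margins (`E = 1/r₀² < θ₁` for
r₀ > 9) are rejected and lobulated margins (E several times θ₁) survive.

A thin command-line wrapper over the same functions ships in
`inst/cli/lobdetect`:

```sh
lobdetect phantom --out bench --n 20 --seed 1
lobdetect train   --images bench --algorithm A9 --out model.rds
lobdetect detect  --images bench --model model.rds --step 12 --out dets.csv
lobdetect bend-filter --images bench --detections dets.csv --out kept.csv
lobdetect evaluate --detections kept.csv --truth bench/ground_truth.csv
lobdetect sweep   --images bench --model model.rds --out sweep.csv
```

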