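---
title: "Detecting lobulation signs in lung CT: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting lobulation signs in lung CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lobdetect)
```

# The problem and the framework

A lobulation sign is an undulating indentation at the margin of a round or
oval lung lesion, visible on CT and associated with malignancy. Detecting
it directly — without first segmenting a nodule — means scanning the lung
parenchyma with a fixed-size window and deciding, for every window,
whether it contains a lobulated margin.

The pipeline has four stages, each an independent module:

1. **Preprocessing.** Raw gray values become Hounsfield units by the linear
   rescale `HU = K·f + C` (slope and intercept from DICOM metadata or a
   sidecar file; never guessed). The lung parenchyma is approximated by a
   circle of radius 180 px about the raster center — deliberately rough,
   because the circle only restricts the search region, it does not
   segment anatomy. Windows whose center leaves the circle are skipped;
   pixels outside it are left untouched.
2. **Window stream.** A `size_px` window (30 px, the mean annotated
   bounding-box size; 31 px for LIOP-based detectors, which need odd
   sizes) slides with stride `step_px` on a grid anchored at the image
   origin, so positions are reproducible across masks and coincide with
   the template-matching subsampling grid. Partial windows at the
   right/bottom edge are dropped.
3. **Classification.** Three detector families score windows (below).
4. **Evaluation.** Greedy one-to-one IoU matching against ground-truth
   boxes; APPI and SNTP are per-image means, precision/recall/F1 are
   pooled over the test set.

# Detector families

## Template matching

Eight base regions of interest, one per ~45° lobulation orientation, are
expanded into 9 variants each — six length–width ratios (1:0.8 … 1:1.3,
the identity counted once) and three scalings (1.1, 1.2, 1.3) — for a
72-template bank. Matching uses zero-mean, unit-variance normalized
cross-correlation: the only reading of "standard NCC" that is invariant to
affine intensity changes, bounded in [−1, 1], and symmetric. Constant
(zero-variance) regions score 0: flat tissue carries no texture evidence.

The dense NCC map is computed in the frequency domain (FFT
cross-correlation for the numerator; summed-area tables for local
variances), subsampled on the step grid, and each template contributes its
single best response; the pooled responses are sorted (ties broken
row-major, then by template label) and the top N returned. Within
floating-point error the FFT path equals the direct spatial definition —
the package tests assert agreement to 1e−9 on random instances.

## Local features, encodings, SVM

The descriptor/encoding matrix of the eight local-feature detectors is
data, not code (`algorithm_table()`):

| id | descriptor | encoding | window |
|----|------------|----------|--------|
| A2 | PHOW (dense SIFT) | BOF | 30 |
| A3 | PHOW | FV | 30 |
| A4 | PHOW | VLAD | 30 |
| A5 | PHOW + HOG | BOF | 30 |
| A6 | PHOW + shape context | BOF | 30 |
| A7 | PHOW + global context | BOF | 30 |
| A8 | LIOP | BOF | 31 |
| A9 | LIOP + LBP | BOF | 31 |

Descriptor defaults (all exposed in `descriptor_defaults()`): dense SIFT
at cell sizes {4, 6, 8, 10} px, grid step 3 (cell sizes whose 4-cell
support exceeds the window are skipped automatically); HOG 3×3 cells of 8
orientations; shape/global context 5 log-radial × 12 angular bins; Canny
hysteresis at (0.1, 0.2) of the patch intensity range; LIOP 4 neighbors at
radius 3 with 6 ordinal bins (dimension 6·4! = 144); uniform LBP with 8
neighbors at radius 1 (59 bins). These are the descriptors' canonical
settings; nothing in the method fixes them.

Two LIOP implementation choices matter:

* **Nearest-pixel neighbor sampling.** Sampling the circular neighbors at
  the nearest pixel (instead of bilinear interpolation) means only
  intensity *comparisons* enter the descriptor, so invariance to strictly
  monotone intensity transformations is *exact* — the tests apply random
  strictly increasing lookup tables to integer rasters and assert
  identity. The price is that rotation invariance is only approximate
  (exact for quarter turns).
* **Stable tie-breaking.** Ranks use first-occurrence tie-breaking, which
  is preserved by monotone maps.

Encodings: BOF is the L1-normalized nearest-centroid histogram (a point on
the probability simplex); VLAD concatenates per-word residual sums,
L2-normalized; the Fisher vector stacks mean- and variance-gradient blocks
of a diagonal GMM, power-normalized (`sign·√|·|`) then L2-normalized. An
empty descriptor set encodes to the zero vector rather than NaN. Codebooks
are k-means (`stats::kmeans`, 5 fixed restarts under the given seed) or,
for FV, a diagonal GMM fitted by mclust's EM started from the seeded
k-means partition. The SVM is e1071/libsvm with a degree-3 polynomial
kernel and class weights proportional to the class imbalance
(the training protocol uses roughly 6 negatives per positive, so
imbalance must be addressed explicitly); the decision threshold is 0 and
the signed decision value is the detection score. Codebook size defaults
to k = 64 — small enough for minutes-scale experiments, standard for
bag-of-features.

Ground-truth boxes are augmented into positives by small integer jitters
(each box yields `per_box` samples, the original included; 25 boxes with
`per_box = 4` give 100 positives), seeded and clamped to the image.

## Bending-energy filtering

The average bending energy per unit length of a closed contour,
`E = (1/P) ∫ k(p)² dp`, separates smooth from undulating margins: a circle
of radius r has `E = 1/r²` exactly, so a smooth nodule of radius 10 px
scores 0.01 while lobulated margins score several times higher. The filter
keeps a candidate window iff `E ≥ θ₁ = 0.0124` and the window's
foreground-area fraction is at most `θ₂ = 0.8` (a guard against windows
swallowed by dense tissue). Both thresholds are parameters
(`bending_filter_params()`), and per-box diagnostics (E, area fraction)
are attached to the filter output so alternative rules can be evaluated
without code changes.

### Numerical choices, in order of how much they matter

* **Sub-pixel contour tracing.** The margin contour is traced with
  marching squares (`grDevices::contourLines`) at the Otsu threshold *on
  the grayscale patch*, not on the binarized mask. CT margins carry
  partial-volume information: the iso-level crossing lands between pixel
  centers with sub-pixel accuracy. Tracing the hard binary mask instead
  produces a staircase whose spurious curvature inflates E by an order of
  magnitude at r = 10. Boolean input is accepted too (pre-smoothed with a
  1 px Gaussian to recover a sub-pixel boundary); its accuracy is
  intrinsically lower (~6% on small discs, perimeters within 2%).
* **Adaptive Fourier truncation.** Curvature comes from differentiating
  the Fourier series of the equal-arc-length parameterization
  `(x(p), y(p))`, truncated by a relative-amplitude rule: besides `|k| ≤ 1`,
  a harmonic is kept iff its amplitude is at least 0.0025× the
  fundamental's (capped at M/4). Empirically, digitization noise on traced
  contours sits below ~0.02 px per harmonic while genuine margin
  undulations sit at ≥ 0.3 px, so the rule adapts the cutoff to the shape:
  a large smooth circle keeps only the fundamental (E exact), an m = 5
  lobulated margin keeps its sideband harmonics (E within 5% of the
  analytic value). Because the threshold is relative, the selection — and
  hence `E(s·contour) = E/s²` — is exactly scale-invariant. A fixed cutoff
  cannot achieve both ends: harmonic 12 already triples the energy of a
  digitized r = 10 circle, while an m = 5 margin needs harmonics beyond 10.
  Explicit cutoffs remain available (`harmonics = <int>`), and a
  three-point finite-difference estimator (`method = "diff"`) is retained
  as an independent cross-check; the two agree within 1% on analytic
  contours at M = 256.
* **Context crops.** A 31-px window rarely contains the whole lesion, and
  a clipped Otsu contour is open (it exits the window). The filter
  therefore analyzes each candidate on a crop grown by half the window
  size per side and selects the closed iso-level loop containing the
  window center. Windows whose object still yields no closed loop are
  rejected — a conservative default, logged per box.
* **Degenerate inputs.** Constant patches have no Otsu threshold and are
  rejected with a message; zero-variance NCC scores 0; empty descriptor
  sets encode to zero vectors. M (contour samples) defaults to 256, even,
  as the FFT wants.

# The phantom: what it emulates, what it does not

The generator renders thorax-like slices: body tissue at +40 HU, a lung
disc at −800 HU with radius 180 px (the parenchyma-circle assumption made
literal), vessel-like bright chords (−100 HU, widths 1–2 px), nodules at
+30 HU, and additive Gaussian noise of σ = 10 HU — typical soft-kernel CT
noise. Nodule margins follow `r(φ) = r₀(1 + a·sin(mφ))`, chosen precisely
because curvature, perimeter and bending energy have closed/quadrature
forms, giving every stage an analytic oracle: smooth margins have
`E = 1/r₀²` exactly; lobulated margins are drawn with r₀ ~ U(10, 14) px,
m ∈ {4, 5, 6}, and a ~ U(0.15, 0.22) — amplitudes chosen to represent
unambiguous lobulation (below a ≈ 0.13 at r₀ = 14 the reference energy
falls to θ₁ itself, i.e. the margin is borderline by the filter's own
operating point). Margins are rendered with 1-px linear partial-volume
antialiasing, as a CT reconstruction would digitize a sharp boundary; this
also makes the traced contour faithful to the analytic reference.

Two deliberate simplifications: vessels taper to zero within a few pixels
of nodule margins (a vessel crossing a margin would invalidate the
analytic contour oracle), and nodules do not overlap. The phantom also
omits CT physics (beam hardening, reconstruction kernels, anisotropic
noise), airways, and the anatomy of real parenchyma. Passing the
end-to-end tests therefore demonstrates that the pipeline recovers
undulating margins among smooth distractors, vessels and noise under
known geometry — not clinical performance on real CT, whose absolute
scores depend on the data corpus.

Benchmarks are written as 16-bit TIFFs with plain-text HU sidecars,
ground-truth and reference-contour CSVs, a vessels CSV, and a JSON
manifest with a deterministic train/test split; regeneration from the same
seed is byte-identical.

# Training-set composition for the phantom experiments

`train_from_benchmark()` builds positives from windows centered on the
lobulated ground-truth boxes of the training split (4 per box via
jittered augmentation) and negatives from three sources: windows on the
smooth nodules, windows along the vessel segments, and 40 uniformly
sampled background windows per training image. The dense negative
vocabulary matters: the LIOP-LBP detector encodes one descriptor per
window, so its BOF vector is one-hot and the SVM effectively labels
codebook words; visual words that appear only at test time would
otherwise be classified arbitrarily. The roughly 6:1
negative-to-positive ratio is handled by class weights, not resampling.

Problem sizes used by the test suite and the acceptance script — 20
images of 448×448 px, 3 nodules each, detection at step 12, codebook
k = 64 — keep a full train-detect-filter-evaluate cycle around a minute
on one CPU while leaving dozens of test windows per class.

# Conventions and known limitations

* Coordinates are 1-based `(row, col)` with inclusive
  `(row, col, height, width)` boxes — the natural R convention, used
  consistently across detections, ground truth, IoU and CSV schemas.
* The IoU threshold for a true positive defaults to 0.25: lobulation
  boxes are small (~30 px), where a 0.5 criterion is needlessly strict;
  it is a parameter everywhere it appears.
* Precision/recall are micro-averaged over the test set; APPI and SNTP
  are per-image means; recall is per-sign (true positives over all
  annotated signs).
* The minimal DICOM reader covers single-frame, uncompressed,
  little-endian files with rescale tags — the common CT export case;
  anything else errors loudly rather than guessing.
* Wall-clock timing is logged but never an acceptance quantity; it is
  hardware-dependent.
* Detector variants A2–A7 are exercised at unit-test scale; the
  end-to-end phantom benchmark runs A9 (LIOP-LBP + BOF), the variant the
  bending filter is designed to follow.
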