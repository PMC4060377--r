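---
title: "Automated CLIFT classification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated CLIFT classification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cliftcad)
```

## The problem

The *Crithidia luciliae* immunofluorescence test (CLIFT) detects anti-dsDNA
autoantibodies, a serological marker of systemic lupus erythematosus. The
antigen is the kinetoplast of the hemoflagellate *C. luciliae* — a
mitochondrial organelle packed with naked circular dsDNA. In a positive
serum the kinetoplast lights up as a small, compact, very bright spot near
one pole of the elongated cell body; the rest of the cell (nucleus, basal
body, cytoplasm) may fluoresce too, but diffusely or in different shapes,
and extracellular debris can produce bright artifacts. A well (one serum)
is imaged as several non-overlapping fields; reading those images by eye is
subjective and poorly reproducible, which is the motivation for an
automated reader.

`cliftcad` implements a three-step architecture:

1. **Screening** — per image, detect *candidate kinetoplasts*: compact
   connected regions distinctly brighter than the rest of the image. An
   image with no candidate is labeled negative outright; this step is
   designed to essentially never lose a true positive, at the price of
   letting many false candidates through.
2. **Cell classification** — localize the cell around each candidate,
   extract a 60-dimensional feature vector (intensity histogram, gray-level
   co-occurrence texture, Fourier spectrum, circular local binary patterns,
   morphology of the presumed kinetoplast) and classify the cell with a
   radial-kernel SVM.
3. **Aggregation** — majority vote from cells to an image label, then from
   images to a well decision; a tied image vote suspends the well (reject
   option) and defers it to the physician.

The package also contains a synthetic image generator with ground truth at
well, image and cell level, so the whole pipeline can be trained, tested
and audited without patient data.

## The synthetic generator

`synth_config()` encodes the study conditions the generator emulates: on
average five images per well and eight cells per image (truncated Poisson),
well prevalence as configured, elongated cell bodies (filled rotated
ellipses, aspect ratio 2.5, length 40 px at the reference 50-fold scale,
normally distributed with 15% CV), a kinetoplast rendered as a Gaussian
spot (sigma 2.5 px at scale 1, peak 0.9) at 0.35 of the body length from
the centroid along the major axis, and two magnification scales (1.0
emulating 50-fold, 0.5 emulating 25-fold). Serum status is a property of
the well: images inherit the well label, and in a positive well each cell
carries a stained kinetoplast with probability 0.9, so majority voting is
actually exercised. Distractors emulate the structures that defeat naive
thresholding: a broad dim nuclear blob (sigma four times the kinetoplast's,
present in 60% of cells), a small bright basal-body spot adjacent to the
kinetoplast pole (present in 30% of cells — the classic kinetoplast mimic),
and extracellular artifact speckles (Poisson rate 1 per image) placed
outside all cell bodies so the artifact-rejection pathway is exercised.
Additive Gaussian sensor noise (sd 0.02) and a constant background (0.05)
are applied last, and images are written as 8-bit grayscale PNG.

Intensity statistics of real stained organelles are not published for this
assay, so the peak values above are the package's own choices: they are set
so that the kinetoplast is the brightest structure when present, the basal
body overlaps the kinetoplast's intensity range (hard negatives), and the
nucleus is too broad to be mistaken for an organelle by shape but bright
enough to confound a global threshold.

What the generator does **not** emulate: optics (no point-spread
convolution, no vignetting), staining heterogeneity within a well,
out-of-focus fields, and color. Tests passing on this material show the
pipeline's logic is sound under the stated conditions; they are not a
clinical validation.

## Screening: threshold calibration

The detector median-subtracts the image (robust exposure correction), then
thresholds at

```
max(mean + k_sigma * sd, max_fraction * max)
```

of the corrected intensities, keeps 8-connected components whose area lies
in a scale-normalized gate (`[0.15, 4]` times the nominal kinetoplast area
`pi * (2.5 * scale)^2`, and at least 2 px), and requires compactness
`4 * pi * area / perimeter^2 >= 0.4`. The perimeter is a weighted
crack-length estimate (Benkrid's configuration weights), which keeps the
compactness of digitized disks near 1 where a raw border-pixel count would
overshoot by 50%; compactness is clamped to (0, 1.2] to absorb residual
discretization for very small regions.

Both threshold terms matter. On images with many stained cells, the
per-image standard deviation is inflated by the cells themselves; `k_sigma
= 8` places the threshold (typically 0.4–0.8) above the cytoplasm ceiling
(~0.30), so whole cell bodies never become candidate components, while
staying below the clipped kinetoplast summit (~0.94 after median
subtraction). On nearly empty images the standard deviation collapses and
the first term can drop below the broad nucleus-over-cytoplasm pedestal
(~0.8 at its center); the second term floors the threshold at 0.78 of the
image's own maximum, which sits between the worst-case nucleus saddle
(~0.71 relative to the summit) and the summit itself. These two constants
were fixed once by this geometric analysis of the generator's intensity
model, validated on probe datasets during development, and are exposed as
`screening_params()` for other imaging conditions.

A consequence worth knowing: in a fully negative image the brightest
structure present (a basal body, an artifact, or noise ripples on the
nucleus summit) always survives a max-referenced threshold, so negative
images frequently carry candidates. That is by design — the screening step
promises *no false negatives*, and discrimination of true from false
candidates is exactly the job of the cell classifier.

Candidate counts are not monotone in `k_sigma` in full generality (a higher
threshold can split a merged blob into two gate-compatible regions, or
shrink an over-large region into the area gate); monotonicity holds for
isolated, gate-compatible unimodal spots, and the property test asserts it
there.

## Cell localization

A window of side three cell lengths around each candidate is segmented by
Otsu's threshold on the median-subtracted window, closed with a disc of
radius 2, and the connected component containing (or within 5 px of) the
candidate is taken as the cell body. Two failure modes required explicit
handling:

* **Trimodal windows.** When a very bright organelle dominates a window
  with dim cytoplasm, Otsu lands *between* cytoplasm and organelle and the
  "body" collapses to the spot itself. If the first pass yields no
  acceptable body, the sub-threshold population is re-thresholded (two-level
  Otsu), which recovers the background/cytoplasm split.
* **Artifact windows.** An extracellular speckle is itself segmented as
  foreground, so the 5-px distance rule alone cannot reject it. Bodies must
  therefore occupy `[0.25, 3]` times the nominal ellipse body area
  `pi * (L/2) * (L/5)` (L = 40 px times the magnification scale): a speckle
  is far below the lower gate, and background noise promoted by the
  second Otsu pass in an empty window is far above the upper gate.

One crop is produced per body, not per candidate: a cell whose kinetoplast
and basal body both produced candidates is judged once, with both
candidates attached. Crops are resampled (bilinear) so the body's major
axis is about 64 px, which makes all window-based texture parameters
magnification-independent.

## Features

The 60 features (fixed order, `feature_names()`):

* **Histogram (5)** — fraction of body pixels above 0.7 ("highly
  fluorescent"; the threshold is this package's choice), maximum, mean, sd,
  and 32-bin entropy. Positive cells concentrate saturated pixels in a
  small spot.
* **GLCM (10)** — contrast, correlation, energy, homogeneity, entropy at
  distances 1 and 2, averaged over the four principal angles, 32 gray
  levels, pairs restricted to the body mask. Standard texture settings for
  a 64-px normalized crop.
* **Fourier (9)** — energy fractions in 8 radial annuli of the 64x64 power
  spectrum (DC excluded) plus the spectral centroid radius. More
  fluorescent objects in a cell push energy to higher spatial frequency.
* **LBP (28)** — rotation-invariant uniform circular local binary patterns,
  (P=8, R=1) and (P=16, R=2), histograms over the 2-px-eroded body
  interior, each normalized to sum 1. Rotation invariance removes the
  cell-orientation nuisance; right-angle rotations reproduce the histograms
  to floating-point precision.
* **Morphology (8)** — computed on the brightest candidate in the cell, in
  original image coordinates so every quantity is a scale-free ratio: area
  fraction, eccentricity, solidity (convex hull of pixel squares),
  compactness, candidate/body mean-intensity ratio, candidate maximum,
  centroid offset relative to the major axis, candidate count.

Degenerate inputs follow documented conventions rather than erroring where
the pipeline can continue: an all-zero crop has zero Fourier features, an
empty LBP interior yields zero histograms, a GLCM with no valid pairs at a
distance contributes zeros.

## Classifier

A radial-kernel SVM (libsvm via `e1071`) on z-scored features with class
weights inverse to class frequency. The grid (C in {0.1, 1, 10, 100},
gamma in {0.25, 0.5, 1, 2, 4}/60) is searched by stratified inner 5-fold
cross-validation maximizing *balanced* accuracy — cell classes are
imbalanced in this assay, and plain accuracy would reward ignoring the
minority class. Ties prefer the smallest C then the smallest gamma (the
least complex model). All randomness flows from an explicit seed; two runs
with the same data and seed select identical hyperparameters.

Evaluation uses one-well-out cross-validation: cells of one well form the
test set, all other wells the training set. The well is the natural
leakage unit — cells of one serum share staining conditions, and splitting
them across train and test would overstate accuracy. Standardization and
hyperparameter selection are redone inside every fold.

## Aggregation and the suspension rule

Image level: strict majority of the classified cells; an image pre-screened
negative is negative without classifying anything; a candidate-positive
image whose candidates were all discarded as extracellular artifacts is
negative (a kinetoplast is intracellular). A tied cell vote goes to
*positive*: at image level a false positive is recoverable by the well
vote, while the screening philosophy is to avoid false negatives early.

Well level: strict majority of image labels; an exact tie suspends the
decision. Suspended wells are always surfaced in the output — the reject
option exists so the physician decides, and silently resolving it would
defeat its purpose.

Scoring a suspended well follows the convention that it counts in the
denominators of accuracy and of its own class's recall (the system failed
to score it) but never as a false call, so precision and the other class's
recall are untouched.

## Problem sizes and numerical choices

The test suite and the acceptance script size their simulations to run on
one CPU in a few minutes: the end-to-end cohort is 30 wells x 5 images x
~8 cells (~1200 cells, ~500 of them candidate-bearing and labeled), images
are 512x384 px, and the magnification-robustness comparison uses two
12-well cohorts at scales 1.0 and 0.5. Percentages are computed from
integer counts and rounded half-up to one decimal at the reporting boundary
only. PNG output is 8-bit, and dataset generation is byte-reproducible
given the seed (a single RNG stream per dataset; the caller's RNG state is
saved and restored).

## Known limitations

* The localization step assumes one dominant cell per candidate window;
  overlapping cells are merged into a single body when closing bridges
  them (the generator avoids body overlap, real slides do not always).
* Screening constants are calibrated to the generator's intensity model;
  on other material they are starting points, exposed via
  `screening_params()`, not universal values.
* The classifier outputs hard labels; no probability calibration or
  confidence-weighted voting is attempted.
* Serum titer (dilution strength) estimation is out of scope; the decision
  is ternary per well.
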