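---
title: "Chromatin homology profiles: model, parameters and design choices"
author: "chp package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromatin homology profiles: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chp)
```

## The model

Increased chromatin and a heterogeneous chromatin pattern are morphological
hallmarks of malignancy, but conventional cytology assesses them by eye.
This package quantifies the *contact degree* of chromatin with homology.
Consider the nucleus image as a grey-level landscape (0 = dark, 255 =
bright) and binarize it at every threshold $t \in \{0,\dots,255\}$:

$$F_t = \{\,p : p \text{ inside the nucleus mask},\ I(p) \le t\,\}.$$

Because stain makes chromatin dark, chromatin enters the foreground first
and $F_t \subseteq F_{t+1}$ — a sublevel-set filtration. At each step we
count the Betti numbers of $F_t$: $b_0$, the number of connected chromatin
components, and $b_1$, the number of *holes* — background regions fully
enclosed by chromatin contact. The function $b_1(t)$ is the chromatin
homology profile (CHP), and three scalar features summarize it:

* **b1MAX** $= \max_t b_1(t)$. Densely packed chromatin (small cell
  carcinoma) merges into a solid mass, so holes vanish and b1MAX is low;
  granular chromatin in non-small cell carcinoma forms many holes.
* **HV**, the homology value: the smallest $t$ with $b_1(t) \ge 5$.
  Cancer nuclei have more chromatin, holes form at earlier (darker)
  thresholds, and HV is low. HV is undefined when the curve never reaches
  5; the package represents that as `NA` (an empty CSV field), never as a
  sentinel number.
* **chromatin density** $=$ b1MAX$/ns^2$, where $ns$ is the diagonal of the
  mask's tight bounding box; $ns^2$ is an area proxy. Fine granular
  chromatin (adenocarcinoma) yields more holes per unit area than coarse
  chromatin (squamous cell carcinoma).

### Digital-topology conventions

A square grid has no unique topology; the package fixes the standard
Jordan-consistent pairing and does not expose it as an option: foreground
is 8-connected, background 4-connected. A hole is a background component
with no 4-connected path to the image border (equivalently, to a one-pixel
background frame padded around the image). With this pairing a 2×2
checkerboard has $b_0 = 1$, $b_1 = 0$ — no "checkerboard paradox" where the
same diagonal pair both connects and encloses. Holes are counted globally,
not attributed to particular components. The Euler characteristic computed
independently by 2×2 bit-quad counting equals $b_0 - b_1$ on every image
and serves as a built-in cross-check; tests also compare against a pure-R
border-seeded flood-fill oracle.

The component counting itself is implemented in C++ (stack-based flood
fill): the profile needs 256 labelings per nucleus, and a 512×512 nucleus
must profile in seconds on one CPU.

### Binarization direction

Foreground at threshold $t$ is *intensity ≤ t*. The alternative (bright
first) would make chromatin the last phase to appear, contradicting how
darkly stained chromatin behaves as black areas in the binarized images.
The convention is fixed and documented rather than configurable.

## Tunable parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `hole_threshold` | 5 | holes | hole count defining HV; the operational definition is $b_1 \ge 5$ (the first threshold *reaching* 5, ties included) |
| `bi_target` | 127 | grey level | target modal intensity for per-nucleus brightness correction; the midpoint of the 0–255 range |
| `b1max_cutoff` | 25 | holes | small cell (<) vs non-small cell (≥) |
| `density_cutoff` | 0.05 | holes·px⁻² | squamous (<) vs adenocarcinoma (≥) |
| `hv_cutoff` | off | grey level | optional cancer/non-cancer stage (cancer below); disabled because no validated cutoff is established |
| `rgb_to_gray` | `luma601` | — | BT.601 luma with round-half-up; `mean` and single channels available for reproduction attempts |
| `um_per_pixel` | off | µm | optional physical calibration, multiplicative only |

Values exactly at a cutoff fall on the "≥" side (non-small-cell, adeno) —
the tie side must be fixed somewhere, and this choice keeps "reaching the
cutoff" meaningful for counts.

**The density cutoff is resolution-bound.** Nearest-neighbour upsampling by
$k$ leaves b1MAX unchanged but divides density by $k^2$ (a tested
invariant), so 0.05 holes·px⁻² is only meaningful at the magnification and
camera resolution at which it was established. Transfer across instruments
requires recalibration; the package surfaces this rather than solving it.

## Brightness normalization

Two mechanisms, both additive:

* `median_offset(reference, target)` returns
  $\mathrm{median}(ref) - \mathrm{median}(tgt)$; adding it to every target
  value aligns group medians. It is generic over the feature being
  corrected (HV or b1MAX): published offsets such as 9 or 15 are
  data-derived outputs of this function, never constants of the package.
  Medians of even-sized groups are the mean of the central pair.
* `bi_correct()` shifts each nucleus so its modal intensity (brightness
  index, computed on raw in-mask intensities; ties broken toward the darker
  level) reaches the target. The shift is additive with clamping to 0–255 —
  the minimal interpretation consistent with the median-offset correction
  being additive. Without clamping the operation is idempotent and exactly
  cancels global additive brightness differences, which is what the tests
  assert; with clamping information is irrecoverably lost at the range
  ends, as with any 8-bit pipeline.

Cytoplasm and slide-background brightness are deliberately excluded from
the BI histogram; only in-mask pixels count.

## The synthetic generator

Real specimens are not required anywhere in the package's validation; two
generators stand in.

**Ring phantoms** place pairwise-disjoint dark Euclidean annuli (width ≥ 2
px, so the loop is closed on the grid) on a bright elliptical nucleus. Their
profile is known in closed form — $b_1(t)$ equals the number of rings with
intensity ≤ $t$ until the background intensity is reached, then 0 — and the
computed profile must equal it *exactly*, which is the strongest oracle in
the test suite.

**Textured nuclei** place dark granules (filled disks, darkest-wins on
overlap) uniformly in an ellipse; holes arise from granule contact, the
same mechanism as in chromatin, not from drawn rings. Identical parameters
and seed give bit-identical images; cohort generation derives per-nucleus
seeds from one master seed.

The three presets caricature the histotype-discriminating patterns: many
tiny granules at moderate coverage (`fine_granular`, adenocarcinoma-like:
high b1MAX, high density), fewer large clumps in a large nucleus (`coarse`,
squamous-like: moderate b1MAX, low density), and near-total dark packing in
a small nucleus (`dense_packed`, small-cell-like: granules merge, b1MAX
collapses). They are illustrative parameter choices, not biological ground
truth.

The presets use `noise_sd = 0`, and that is a modelling statement worth
spelling out: independent per-pixel Gaussian noise on a flat nucleoplasm
creates, at thresholds crossing the background level, a salt-speckle band
whose hole count is proportional to nucleus *area* and essentially
class-independent — it swamps the geometric texture signal and drives every
class's density toward the same constant. Real nucleoplasm texture is
spatially correlated and does not behave like iid salt noise, so the
presets let granule geometry carry the signal; `noise_sd` remains available
for robustness experiments.

Because the synthetic scale (nucleus radii 10–34 px) differs from the
clinical imaging scale, the clinical cutoffs 25 and 0.05 do not apply to
preset cohorts. The shipped `cohort_cutoffs` (b1MAX 13, density 0.0085)
were tuned once, as gap midpoints on a cohort generated from an independent
master seed, then frozen; evaluation cohorts use other seeds. At these
cutoffs the pipeline recovers ≥ 90 % of labels on 30-per-class cohorts, and
the class orderings match the clinical ones (small-cell b1MAX lowest;
adenocarcinoma density above squamous). Passing this says the pipeline
separates what its generator makes separable — it does not certify clinical
performance, which depends on staining, optics and specimen variability the
generator does not emulate (no cytoplasm, no photorealistic Papanicolaou
rendering, no correlated background).

## Degenerate inputs and numerical choices

* Empty foreground: $b_0 = b_1 = 0$; an all-background image is valid.
* Empty mask: rejected at construction — a nucleus must have pixels.
* Constant nucleus: flat zero profile, b1MAX 0, HV absent.
* All 256 thresholds are always evaluated (no early exit) so the stored
  curve is complete for plotting and audit.
* ns of a single-pixel mask is $\sqrt{2}$ (a 1×1 box); bounding boxes are
  inclusive pixel counts. The choice of *bounding-box diagonal* pins down
  an otherwise underdefined "diagonal of the extracted area" measured
  interactively in GUI tools; it is reproducible and monotone in nucleus
  size.
* Grey conversion rounds half up (`floor(x + 0.5)`), not banker's
  rounding, so conversions are monotone in intensity; 16-bit inputs are
  linearly rescaled to 8-bit with a warning.
* Profiles of masked nuclei binarize within the mask only; pixels outside
  the mask are never foreground at any threshold.

## Validation problem sizes

The shipped tests compare against the flood-fill oracle on 1000 random
images up to 64×64, verify exact phantom agreement on 40 randomized
phantoms plus the canonical hand-built cases, exercise the invariance suite
(filtration nesting, HV shift covariance, BI-correction cancellation,
translation invariance, the $k^2$ density law) on small textured nuclei,
and run the classifier on 90-nucleus cohorts. A single 512×512 nucleus
profiles over all 256 thresholds in roughly a second.

## Known limitations

* 2D only: the profile is computed on a single focal plane or projection;
  which plane of a microscope z-stack feeds the analysis is the user's
  choice. Voids enclosed in 3D ($b_2$) are out of scope.
* Nucleus segmentation is not provided; a mask image is required.
* No stain deconvolution, white-balance or cross-institution colour
  calibration; the brightness tools address additive shifts only.
* Cutoffs are univariate and fixed; no ROC optimization or learned
  classifier is included by design.
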