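---
title: "Methods: photograph-based facial anthropometry with corneal calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: photograph-based facial anthropometry with corneal calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facemetrics)
```

## The measurement problem

Frontal facial photographs carry no absolute scale: a pixel distance is
meaningless until something of known physical size appears in the frame.
The corneal white-to-white (WTW) diameter — the horizontal width of the
visible iris between the limbus borders — is remarkably stable across
adults (11.71 ± 0.42 mm in Caucasian populations) and is visible in any
frontal portrait, so it can serve as an in-image metric ruler. This
package implements that idea end to end:

1. segment the pigmented iris from the sclera with a region-based active
   contour seeded at the canthi, and fit a circle to the boundary to get
   the WTW diameter in pixels, per eye;
2. average the two eyes and set `mm_per_px = 11.71 / wtw_px_mean`;
3. compute a battery of ~25 clinical facial measurements from named 2-D
   landmarks, correcting angular quantities for in-plane head rotation;
4. compare cohorts (e.g. female vs male) measurement by measurement.

Every stage is testable without any photograph, because the package ships
a synthetic-face generator whose subjects carry exact ground truth.

## Coordinate conventions

Landmarks live in image coordinates: x grows rightward, y grows
*downward*, origin at the top-left. Side suffixes `_L`/`_R` are
anatomical (the subject's own left/right); on an upright frontal,
non-mirrored photograph the `_R` landmarks appear on the viewer's left.
All angle formulas in the package are stated in this y-down frame.

## Rotation correction

The facial rotation angle is the angle between the glabella-to-menton
median vector and the true vertical, positive for clockwise rotation in
the viewer's frame:

```
rotation = atan2(menton.x − glabella.x, menton.y − glabella.y)
```

folded into (−90°, 90°]. Distances are rotation-invariant and need no
correction. Canthal tilt does: per eye, the raw tilt is the angle of the
endocanthion-to-exocanthion line against the lateral horizontal, positive
when the exocanthion sits superior. A rigid clockwise rotation *adds* the
rotation angle to the left eye's raw tilt and *subtracts* it from the
right eye's, so the correction is applied with opposite signs per side;
the corrected left/right mean is then exactly invariant to rigid rotation
(a property test asserts this to 1e-6°). Brow angles are referenced to
the interpupillary line, which rotates with the head, so they are
self-correcting. Scleral show is a vertical gap and is evaluated after
de-rotating the two involved landmarks.

## Facial thirds as projections

Horizontal thirds (trichion–glabella, glabella–subnasale,
subnasale–menton) are *projected* segment lengths along the median axis,
and the proportions divide by the sum of the three segments. With
non-collinear midline landmarks, raw Euclidean segments would not sum to
the end-to-end distance, so proportions built from them could not sum to
one; projections make the compositional invariant exact, which matches
the published proportion triplets summing to 1.000 in both sexes. The
same construction applies to the vertical thirds along the line through
the two exocanthions. Numerically, the last proportion is computed as the
complement of the partial sum of the other two, so the triplet sums to
exactly 1 in IEEE arithmetic, not merely to within rounding.

## Iris segmentation and circle fitting

The paper-level description of the segmentation is a region criterion
(foreground iris vs background sclera), with canthus points as pilots;
the exact energy and iteration rule are unpublished. We therefore
implement a morphological variant of the two-phase piecewise-constant
(Chan–Vese) model:

- initialise with a disc at the canthal midpoint, radius 0.25 × the
  inter-canthal distance;
- alternate (a) the optimal piecewise-constant region update — each pixel
  joins the phase whose mean intensity is closer, the darker phase being
  the iris — with (b) `smoothing` passes of a 3×3 box filter over the
  region indicator, re-thresholded at 0.5, which plays the role of the
  curvature penalty;
- stop at convergence or after `iterations` sweeps (default 200; the
  update typically converges in under 20);
- keep the connected component containing the canthal midpoint, and fail
  (classed condition, so callers can fall back to manual WTW entry) if
  the image is featureless, the contour collapses below 8 px, or fewer
  than 8 boundary points remain.

Because eyelids occlude the upper and lower limbus in real photographs
while WTW is a *horizontal* diameter, boundary points in the top and
bottom 25% of the contour's vertical extent are dropped before fitting
(config flag, default on); a circle fit on the remaining lateral arcs is
unaffected for the synthetic full disc and robust for occluded crops.

The circle fit is the algebraic Kåsa least-squares solution followed by
one Gauss–Newton step on the geometric (radial) residuals: exact on clean
circle samples (rms residual < 1e-9, tested on full circles and short
arcs) and unbiased enough on partial arcs. Finally, boundary *pixel
centres* sit on average half a pixel inside the true region edge, so one
pixel is added to the fitted diameter; without this correction the
recovered diameter is biased low by ~2% at 50 px irises.

Default rendering contrast is 0.7 (iris 0.15, sclera 0.85); "10% contrast
noise" in the tests means additive Gaussian noise with SD 0.07.

## The synthetic cohort generator

`sample_cohort()` draws each subject's millimetre geometry from
independent Gaussian marginals per measurement — the published group
means and SDs are the package defaults (`dimorphism_norms("female")` /
`"male"`) — then applies a uniform in-plane rotation (default ±10°) and a
uniform pixel scale (default 5–15 px/mm). `truth` records the
pre-rotation, pre-scale geometry. Construction outline:

- midline landmarks are spaced along the vertical axis so the sampled
  horizontal-third proportions of the sampled facial height are realised
  exactly;
- the exocanthion span W is chosen as `2·IPD / (1 + middle proportion)`
  so the canthal midpoints (pupils) realise the sampled interpupillary
  distance while the canthi realise the sampled vertical thirds;
- canthal tilt raises each exocanthion by `span × tan(tilt)`;
- paired widths (zygion, gonion, alare) are placed symmetrically about
  the midline; their vertical placements are fixed layout constants
  (nasion 0.6 cm below glabella, eye line 1.1 cm below glabella, brow
  apex 1.6 cm above the eye line, gonion at 0.86 × facial height) chosen
  once as anatomically plausible — the battery only consumes them through
  distances whose truth is recorded from the constructed geometry;
- the lower-lid margin sits 0.5 mm below the inferior iris border, so
  default cohorts never show sclera, matching the published cohorts;
- the WTW diameter is drawn from N(11.71, 0.42²) mm and both determines
  the iris landmarks and provides the subject's true pixel ruler.

Design choices worth stating:

- **Independent marginals.** Only marginal mean ± SD are published; no
  covariance structure exists to emulate. Per-subject *ratios* therefore
  have the wrong joint distribution under the direct mode, which is why
  `bigonial_mode = "ratio"` exists: it samples the FH/bigonial ratio
  directly and derives bigonial width, for studies of the ratio itself.
- **Compositional sampling.** Third-proportion triplets are positive-
  truncated Gaussians renormalised to sum to 1. Since the published mean
  triplets already sum to 1.000, this preserves the published marginal
  means to first order (bias ≪ 1e-3, far below the 2-SE recovery bands);
  an exponential-scale logistic-normal would have required a mean
  correction.
- **Brow angles.** Angles 1 and 3 are sampled truncated at ≥ 0.5° (the
  measured angle is unsigned, so a negative sampled angle could never be
  recovered) and angle 2 is the implied 180° − θ1 − θ3. The published
  brow-angle means are mutually inconsistent with this three-point
  construction; no validation target uses them.

What a green test establishes — and what it does not: synthetic subjects
have exact landmarks, perfectly Gaussian marginals, bilateral symmetry up
to sampled proportions, and no out-of-plane pose, lens distortion,
landmark-detector noise, or eyelid occlusion beyond what the vertical
trim emulates. Passing the recovery suites validates the *measurement
pipeline's* correctness and its invariances, not the performance of any
landmark detector on photographs.

## Statistics

Group comparisons default to Welch's t test (the published tables do not
name their test; Welch is the safe default under unequal SDs), with
Student's t and Mann–Whitney as options and an optional
Benjamini–Hochberg column (the source analysis applied no correction).
Two groups that are both constant make the t statistic undefined; the
package reports p = 1 for equal means and p = 0 otherwise, which keeps
degenerate zero-SD synthetic cohorts usable. The paired validation
comparison uses the Wilcoxon signed-rank test: zero differences dropped,
exact null distribution for tie-free n ≤ 25, tie-corrected normal
approximation with continuity correction otherwise; an all-zero
difference vector reports p = 1 by convention. A test matches the exact
p-values against full 2^n sign-flip enumeration for n ≤ 10.

## Numerical and degenerate-input choices

- Collinear boundary points, coincident glabella/menton, crossed canthi,
  zero-length brow limbs and non-monotone midline orderings raise classed
  geometry/schema errors rather than returning garbage.
- Landmark file round-trips are bit-exact: CSV and JSON are written with
  17 significant digits.
- All generator and CLI entry points take explicit seeds; the RNG state
  of the caller is saved and restored.
- Eye crops are exchanged as plain ASCII PGM (P2), keeping every artifact
  in the toolchain a text file.

## Known limitations

- In-plane rotation only; out-of-plane (yaw/pitch) pose is explicitly out
  of scope, as in the source method.
- The generator cannot reproduce joint structure between measurements
  (nothing is published to fit), so cohort-level SDs of derived ratios
  are only approximately comparable to published per-subject ratio SDs.
- Segmentation accuracy claims hold for the synthetic bimodal eye model;
  real-world glare, makeup, or light irises will degrade it — which is
  why the manual WTW fallback exists in the cohort table format.
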