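---
title: "Ripe-fruit recognition by dual color-feature wavelet fusion: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ripe-fruit recognition by dual color-feature wavelet fusion: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fruitfusion)
```

## The problem and the model

Detecting ripe tomatoes in canopy images from a cheap RGB camera is
dominated by two failure modes: spatially varying illumination (direct sun
vs. shade, specular highlights that saturate the sensor) and occlusion of
ripe fruit by unripe fruit of nearly the same color as the foliage. No
single color feature is robust to both. This package implements a classical,
training-free pipeline that hedges between two complementary chromatic
features and only then segments:

* the CIELAB **a\*** component computed from *chromaticities*
  `r = R/(R+G+B)` etc., which removes multiplicative brightness changes by
  construction (a gray pixel has `a* = 0` exactly, ripe fruit large positive
  `a*`), but also collapses all intensity information — and fails where
  channels saturate, because a clipped highlight is achromatic;
* the NTSC YIQ **I** component on the *raw* channels,
  `I = 0.5957 R − 0.2745 G − 0.3213 B`, which retains intensity contrast and
  degrades more gracefully under saturation, but responds to bright unripe
  fruit.

Both feature images are min–max normalized to [0, 1] per image. Fusion
operates in the wavelet domain: both images are decomposed by an `L`-level
2-D DWT, and every coefficient is combined as

`C = (1 − d) C1 + d C2`,  with  `d = max(L_max) − min(L_max)`,

where `L_max` is the elementwise maximum of the two normalized images and
`C1`, `C2` are the a\* and I decompositions. The fused reconstruction is
clipped to [0, 1], quantized to 0..255, and thresholded at the minimum of
the iterative intermeans threshold and Otsu's threshold; connected
components below 200 px are discarded as noise.

A structural observation the test suite exploits: since a *single scalar*
`d` multiplies every coefficient of a linear, exactly invertible transform,
the fused image equals the pixelwise convex combination
`(1 − d) A + d B` to machine precision, for any wavelet family. The wavelet
decomposition is retained as the method's structure and because the
per-subband variant (below) genuinely differs; readers who believe a
subband-dependent weight was intended can enable it.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `fusion.levels` | 3 | DWT depth; each image dimension must be ≥ 2^levels |
| `fusion.wavelet` | `db2` | orthogonal family (`haar`, `db2`, `db4`); the fused output is family-independent (scalar-weight argument above) |
| `fusion.boundary` | `periodization` | border extension; see numerical notes |
| `fusion.per_subband_weight` | off | recompute the range weight per subband pair from the coefficient grids, clipped to [0, 1] |
| `threshold.tolerance` | 0.5 | intermeans stopping tolerance, in gray levels; half a quantization step — finer precision is meaningless on an 8-bit scale |
| `threshold.polarity` | `high` | foreground is the bright side (`> T_f`). The fused image renders ripe fruit bright, so the literal dark-side rule is kept available as `low` but is not the default |
| `postprocess.min_area` | 200 px | noise cutoff; regions of exactly 200 px survive (strict "less than" is noise) |
| `postprocess.connectivity` | 8 | component connectivity; 8 avoids splitting anti-aliased fruit boundaries |
| `iou_min` (evaluation) | 0.5 | standard detection overlap criterion |

## Numerical choices

**Wavelet transform.** No assumption is made that image sizes are dyadic.
The per-length analysis operator is materialized as a banded matrix (filters
at stride-2 offsets over the extended signal); synthesis uses its exact left
inverse — the transpose when the operator is orthonormal (periodization,
even length), otherwise the pseudo-inverse. Reconstruction of unmodified
coefficients is exact (< 1e−12 observed, tested at 1e−8) for every size,
family and boundary mode, which is what makes the fusion identity above
exact rather than approximate. Periodization is the default boundary mode
because it yields the expected dyadic subband layout (64×64 → 8×8 at three
levels) and an orthogonal transform for even sizes; symmetric extension is
available for users who prefer reflection at the borders, at the cost of
slightly redundant subbands.

**Degenerate inputs.** A black pixel has undefined chromaticity; it maps to
the achromatic point (1/3, 1/3, 1/3), continuous with dark grays. A constant
image has no threshold: both selectors return the constant, flagged
degenerate, and binarization at `high` polarity yields an empty mask — so a
degenerate scene produces an empty region list, never an error. Pixels
exactly at the threshold go to the lower class, matching the `≤` convention
of the binarization rule. Otsu ties are broken toward the lowest maximizing
level, making results independent of pixel order.

**Intermeans iteration.** The update is a function of the histogram only, so
it converges in far fewer than the 256-iteration cap on 8-bit images (3–10
steps typical); the trace is retained in the `threshold_report` for
inspection and logging.

## The synthetic scene generator

Real canopy imagery for this method is not publicly deposited, so the
package ships a generator whose defaults define the study conditions used
throughout the tests:

* 388 × 260 px scenes — the resolution of the low-cost camera the method
  targets;
* background: dark-green base with ~30 elliptical leaves and a few stems in
  overlapping green hues (`foliage_density` 0.5);
* ripe fruit: shaded red discs (R 170–230, G 35–85, B 30–70), radius 24–40
  px;
* immature fruit: light yellow-green shaded discs — deliberately brighter
  than foliage so they attract the I feature but not a\*, reproducing the
  misidentification hazard;
* illumination group: multiplicative left-to-right gain ramp of strength
  0.7 (gain 0.58 → 1.05 of saturation headroom) plus specular highlights
  (probability 0.9 per fruit) that clip to near-white — exactly the regime
  that hollows out the a\* image;
* overlap group: two immature fruit attached to the ripe fruit, each
  covering up to the geometric maximum of its boundary (requested coverage
  0.6 of the circumference, capped at the rim so the host stays partly
  visible — a fully engulfed fruit is not a recognizable sample); occluder
  radii 55–80 % of the host's;
* additive Gaussian noise, σ = 2 gray levels; disturbance-free group: no
  immature fruit, flat lighting.

Ground-truth masks are *modal* (visible-surface): pixels occluded by an
immature fruit belong to the occluder, the usual convention for evaluating
segmentation output against what is actually visible.

What the generator does **not** emulate: 3-D canopy geometry and
self-shadowing, camera PSF/demosaicing, JPEG artifacts, dried leaves and
greenhouse hardware with fruit-like chroma, and fruit at intermediate
ripeness. Passing the synthetic benchmark therefore demonstrates internal
correctness and the *relative* robustness ordering of the methods — not a
field-ready recognition rate; absolute rates on real greenhouse images will
be lower and can only be assessed on real data.

Batch sizes used in the shipped checks — 100 scenes per disturbance group
and 50 disturbance-free scenes, at the default 388 × 260 resolution — match
the scale of the method's original evaluation protocol while keeping a full
run in the minutes range on one core.

## Evaluation design

"Recognized" is operationalized as: some surviving region overlaps a
ripe-fruit truth mask with IoU ≥ 0.5, **and** no surviving region matches an
immature-fruit mask more closely than any ripe-fruit mask (such a region is
a misidentification and voids the image — treating confusion of unripe
fruit as failure, which is the practically relevant error for a harvesting
robot). Regions that match nothing (e.g. bright clutter) reduce IoU only
indirectly and are otherwise ignored; they are almost always removed by the
area filter.

Two orderings are asserted at full batch size: fusion ≥ a\*-only under
illumination, and fusion ≥ I-only under overlap. These are the method's
motivating claims and they hold with a wide margin (illumination) or a
small-to-zero margin (overlap, where the fused image leans heavily on I
because `d` is typically 0.9–0.97). The stronger statement "fusion ≥ every
single-feature arm in both groups" is *not* asserted: in a disturbance-free
direction the unaffected single feature can reach rate 1.0 and fusion can
drop a single borderline scene below it; with `d` defined as a global range
statistic, near-ties in the fused arm are expected, not a defect.

## Known limitations

* The global weight `d` saturates near 1 on realistic scenes (some pixel is
  dark in both features, some pixel is bright in one), so fusion is usually
  a 90/10-style blend favoring I; the a\* contribution is small but is
  precisely what suppresses bright unripe fruit relative to ripe ones.
* The range-based weight is computed from the spatial-domain images (the
  coefficient-domain alternative is ambiguous and not implemented as the
  default; the per-subband option covers it).
* Only global thresholds are computed; scenes needing locally adaptive
  thresholds are out of scope, as are shape priors, fruit counting across
  occlusion, and any learning.
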