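---
title: "Measuring contaminated areas from orthogonal photographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring contaminated areas from orthogonal photographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluoarea)
```

## The measurement model

A flat surface carries bright fluorescent-dye regions whose total physical
area is wanted. A camera photographs the surface *orthogonally* — optical
axis perpendicular to the plane — at a known distance $d$ (cm). Because
every point of the scene lies on one plane at one depth, the imaged size of
a region is a function of $d$ alone, and no homography or perspective
correction is needed. That orthogonality is the central assumption of the
whole method: a tilted camera makes the scale vary across the frame and
invalidates both calibration routes below.

The pipeline is:

1. **Grayscale.** RGB is collapsed with BT.601 luma weights
   $(0.299, 0.587, 0.114)$ and half-up rounding. The weights are an
   argument of `rgb_to_gray()` (and settable through the CLI config file),
   since the upstream description of the procedure leaves the formula to
   the image library in use.
2. **Otsu threshold.** With $\omega_0,\mu_0$ the pixel fraction and mean
   gray level of the class $\{v \le K\}$ and $\omega_1,\mu_1$ of
   $\{v > K\}$, the interclass variance
   $g(K)=\omega_0\omega_1(\mu_0-\mu_1)^2$ is evaluated for every
   $K \in [0,255]$ and the maximizing $K$ is kept. Maximizing the
   separation between the two classes minimizes the chance that target
   pixels are misclassified as background or vice versa. The method
   assumes a roughly two-tone image (bright dye on a darker, monotone
   background); a strongly textured background or a dye whose gray range
   overlaps it breaks the assumption, which is why the CLI also accepts a
   manual threshold override.
3. **Binarize and count.** Pixels strictly above $K$ become white; the
   white/total fraction $p$ (or the raw white-pixel count $x$) is the
   image-side measurement.
4. **Convert to mm².** Two explicit, separately selected calibrations:
   - **Single-reference $\lambda$:** under the small-angle projection
     relation the imaged fraction is proportional to area over distance,
     so $\text{area} = \lambda\, d\, p$ with $\lambda$ absorbing the
     unknown reciprocal focal length. One photograph of a reference object
     of known area at known distance fixes
     $\lambda = A_{\mathrm{ref}} / (d\, p_{\mathrm{ref}})$.
   - **Distance curves:** per calibrated distance, ordinary least squares
     of physical area (response, mm²) on white-pixel count (predictor):
     $f(x) = a_0 + a_1 x$, with $r^2 = 1 - SS_{res}/SS_{tot}$. At an
     intermediate distance $d_{lo} \le d \le d_{hi}$ the estimate is the
     linear blend
     $f_{lo}(x) + \frac{d - d_{lo}}{d_{hi} - d_{lo}}\,(f_{hi}(x) - f_{lo}(x))$.

The two routes are never auto-selected: $\lambda$ is cheap (one reference
photo) but tied to one distance; curves need a calibration session but
tolerate distance variation within the calibrated range.

## Parameters that matter

| parameter | units | default | rationale |
|---|---|---|---|
| distance $d$ | cm | — | measured per photo (e.g. by a laser ruler app); the calibrated range is typically 50–100 cm |
| grayscale weights | — | 0.299/0.587/0.114 | BT.601 luma; centralized so it can be swapped |
| threshold $K$ | gray level | Otsu's argmax | manual override available; ties broken toward the smallest $K$ |
| regression orientation | — | area on pixels | verified to reproduce the published coefficient sets; the inverse orientation does not |
| extrapolation | — | refuse | the method is only validated inside the calibrated distance range; `--allow-extrapolation` extends the nearest segment explicitly |
| report rounding | mm² / ratio | 2 / 6 decimals | matches the precision the field reports; keeps rerun reports byte-identical |

## The synthetic world

`scene_spec()` + `render_scene()` produce a ground-truthed test scene:
axis-aligned rectangles and disks of known physical size on a uniform
wall, rasterized at the scale implied by `project_pixels()`. A pixel
belongs to a shape iff its center falls inside the projected footprint, so
the expected discrepancy between the ground-truth pixel count and the
ideal projection is at most one perimeter's worth of pixels — that
"rasterization tolerance" is the band tests assert.

Two scale models are provided, both explicit and never inferred:

- `pinhole_inverse_square` (default): pixel count
  $\propto \text{area}/d^2$. This is the physically standard pinhole
  behavior and matches how fixed-area pixel counts in real calibration
  tables fall off with distance.
- `paper_linear`: pixel count $\propto \text{area}/d$, exercising the
  small-angle area relation in its literal linear form. The tension
  between the two (the linear relation underlies the $\lambda$ route,
  while real pixel counts scale inverse-squarely) is absorbed in practice
  by the per-distance curves; we document it rather than resolve it.

`focal_constant` (default 300) is a pure render scale — pixels per mm at
1 cm under the pinhole model, i.e. ~6 px/mm at 50 cm, the order of
magnitude of a phone photo of a 4 × 4 cm target — not a physical focal
length.

Degradations emulate a handheld night-time photo and are applied to the
image only, never the truth mask, in a fixed order: per-channel
multiplicative color cast (failed white balance), additive zero-mean
horizontal illumination ramp, additive Gaussian noise, then rounding and
clamping to [0, 255]. All randomness is governed by the scene seed.
`mild_noise()` (sigma 6, ramp 8, cast R×1.08/B×0.85) is the package's
fixed "degraded imaging" condition; the amplitudes were chosen once so
that Otsu misclassifies well under ~2% of a fixture scene's pixels, and
are not tuned per test.

What the generator does **not** emulate: perspective (non-orthogonal)
views, lens distortion, specular reflections from metal surfaces, defocus,
and fluorescence-intensity variation within a region. A green synthetic
test therefore establishes that the algebra and the pipeline are correct
under the stated projection model — not that a phone photograph of a real
scene meets the same error bounds.

## Numerical choices and degenerate inputs

- **"Exceeds" is strict:** a pixel exactly at $K$ is black. Chosen to
  match the usual wording of the binarization rule; the companion
  convention (class 0 is $\le K$) keeps the two class definitions
  complementary.
- **Otsu ties** go to the smallest $K$, making outputs deterministic; $g$
  is invariant to which class is called foreground, and both classes are
  reported symmetrically.
- **Single-level images** return $g = 0$, $K$ = that level and a
  `degenerate` flag instead of erroring, so batch pipelines continue.
- **Negative curve predictions** (pixel counts below the intercept
  crossing, i.e. regions smaller than the calibration anchored) are
  returned as-is with a `fluoarea_negative_area` warning rather than
  clamped — silently clamping would hide a calibration-range problem.
- **Interpolation at a calibrated distance** returns that curve's
  prediction exactly (the blend is anchored at the lower curve, so the
  estimate is continuous in $d$ across knots).
- **r² of a perfect line** is computed directly from the residual and
  total sums of squares (exactly 1 for collinear input, avoiding spurious
  perfect-fit warnings).
- **Calibration CSVs** tolerate thousands separators ("10,547") because
  published tables print them; parse errors name the offending row.

## Design choices made where the design was open

- The published coefficient set this package's fixture reproduces prints
  an r² of 0.9968 for the 100 cm curve, but refitting the same printed
  points gives 0.9953 — which is also the agreement percentage quoted in
  the accompanying prose. We treat the printed 0.9968 as a typo and test
  against the recomputed 0.9953.
- The published interpolation formula, read literally, is a scaled
  difference of the two curve predictions with no base term; taken at face
  value it would not reduce to either curve at the endpoints. We implement
  the standard two-point linear blend anchored at the lower curve, which
  matches the stated intent ("interpolation") and the endpoint behavior.
- The single-reference worked example in the source rounds its $\lambda$
  to 4376 while the inputs give 4367.5; `fit_lambda()` computes exactly,
  and the worked example is reproduced by constructing
  `lambda_calibration(4376)` with the constant given.
- The interactive threshold-slider workflow of the original mobile app is
  replaced by a single `--threshold` override plus a logged Otsu
  suggestion: reproducible, scriptable, testable.
- TIFF input is not supported (no TIFF reader among the package's
  dependencies); PNG and JPEG are. Alpha channels are rejected because the
  pipeline has no transparency semantics.

## Known limitations

- Orthogonality is assumed, never verified from the image.
- A single threshold is global: uneven illumination strong enough to make
  the background's gray range overlap the dye's defeats Otsu (the manual
  override exists for exactly this case).
- The λ route is strictly per-distance; using it away from its reference
  distance reintroduces the distance dependence it calibrated away.
- Areas are additive only because synthetic shapes are disjoint by
  construction; for photographs the pipeline simply counts white pixels
  and cannot separate touching regions.
- Fluorescence *intensity* is out of scope; only area is measured.
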