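---
title: "Methods: robust 3D registration of serial-section stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: robust 3D registration of serial-section stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cutting a specimen into serial sections destroys its third dimension: each
physical section is independently placed, rotated, stretched and locally
deformed during cutting, fixation, staining and imaging.  Reconstructing
the 3D anatomy from the digitized sections therefore requires registering
every section to its neighbors — and doing so robustly, because any fully
automatic registration of biological images will occasionally fail, and in
a *sequential* chain a single bad pair contaminates everything beyond it.

`stackreg` implements a fully automatic pipeline for this problem with
three layers of defense: a feature-based coarse stage that is robust to
large displacement, an area-based elastic stage that is accurate for small
residual deformation, and a validation model that refuses to propagate
over-deformed results.

## Pairwise registration

### Normalization and feature extraction

Each section's channels are contrast-stretched between saturation bounds:
`x_low` / `x_high` are the intensity levels at which the cumulative
histogram first exceeds a fixed saturated fraction (default
`normalize.p_low = normalize.p_high = 0.01`, i.e. 1% clipped at each end —
a conventional stretch default; the percentage is configurable).  This
suppresses staining variation between sections before any matching.

For H&E-stained color sections, matching operates on the *eosin* channel.
In optical density space (`od = -log10(v / 255)` per channel, zero values
clamped to 1 before the log) stain amounts mix linearly, so with a
row-normalized stain matrix `M` (rows = unit OD vectors of hematoxylin,
eosin, and a residual channel built from their cross product with negative
components zeroed) the forward model is `OD = t(M) %*% C` and per-pixel
stain amounts are recovered as `C = solve(t(M)) %*% OD`.  The multiplication
orientation is a convention this package fixes (rows are stains); the
widely published H&E vectors are the defaults and are overridable via
`stains.hematoxylin` / `stains.eosin`.  Grayscale data (ssTEM, confocal)
skips deconvolution: the normalized image is the feature image.

### Coarse global registration

Difference-of-Gaussian extrema (3 scales per octave, base scale 1.6 px,
contrast threshold 0.015 on unit-scaled intensities, edge ratio 10) with
128-dimensional gradient-orientation descriptors are detected on both
feature images.  Candidate matches pass a Lowe ratio test (0.8) with a
symmetric cross-check, and a global transform — similarity by default,
affine available — is selected by RANSAC (inlier tolerance 3 px, 2000
seeded iterations) and refit by least squares on the consensus set.
None of these constants are inherited from published values for this
pipeline; they are the field's conventional defaults and all are exposed
in the configuration.  A coarse failure (too few features or no
consensus) is deliberately non-fatal: the pair falls back to an identity
initialization and the validation model judges the result.

### Elastic refinement

The residual deformation is modeled by two cubic tensor-product B-spline
fields — source→target and target→source — optimized *jointly* over the
energy

```
E = w_img (E_img_st + E_img_ts) + w_div (E_div_st + E_div_ts)
  + w_rot (E_rot_st + E_rot_ts) + w_cons E_cons
```

where `E_img` is the mean squared intensity difference after warping,
`E_div` and `E_rot` penalize the squared divergence and curl of the
displacement, and `E_cons` is the mean squared distance between
`f_ts(f_st(x))` and `x` (both compositions, averaged) — the bidirectional
consistency that pulls the two fields toward being mutual inverses.
Defaults `w_img = 1, w_div = w_rot = 0.1, w_cons = 1` were fixed a priori
(the consistency term must be material for the bidirectional design to
matter; the curl/divergence terms are kept small so genuine tissue
deformation is not suppressed).

A field stores *absolute* positions `g(x,y) = sum C_kl B3(x/s - k) B3(y/s - l)`;
the identity has every control point at its own grid position, and because
cubic B-splines reproduce affine maps exactly, both fields are initialized
directly from the coarse transform — the optimized forward field *is* the
total deformation, with no second resampling step.

Optimization is L-BFGS-B on all coefficients with analytic gradients
(compiled), coarse-to-fine over control spacings of 64/32/16 px at full
resolution; the images are block-averaged so every level works at an
effective spacing of 16 px.  Stopping: relative energy decrease below
`1e-5`, or 60 iterations per level.  The iteration cap is the one place
where this implementation trades accuracy for time: at 512×512 a cap of
200 costs ~29 s per pair against ~11 s at 60, with identical pair accuracy
on magnitude-8 synthetic deformations (r = 1.0000 both ways), so 60 is the
default and `elastic.max_iters` restores the larger budget.

One coarse-stage robustness guard deserves mention: on self-similar
texture, RANSAC can assemble a geometrically consistent but *wrong*
consensus (under elastic deformation the true matches are non-rigid and
spread their residuals, so a false rigid set can out-vote them).  The
selected transform is therefore accepted only if, on 4× block-averaged
feature images, it does not increase the masked mean squared difference
relative to the untransformed pair; otherwise the pair falls back to the
identity initialization, the same route taken when too few features
match.  The comparison is parameter-free.

## The 3D chain and the validation model

Given a reference section (default: the middle one, `floor(N/2)` —
bidirectional chains halve the worst-case accumulated error), sections are
registered one pair at a time outward: each moving section's target is its
*already registered* neighbor, forward in increasing order and backward in
decreasing order.

Every pair's total deformation field is validated before use: the mean
geometric distance `mean ||g(x,y) − (x,y)||` over the domain must not
exceed the user threshold `alpha` (inclusive; default 50 px, with
published per-data-type working ranges available via `alpha_presets()`).
An accepted pair contributes the warped *original* section; a rejected
pair passes the original through unchanged, so an over-deformed transform
can degrade at most its own two pair scores and never the rest of the
chain.  Validation applies to the total field (coarse + elastic) because
the coarse placement is part of the geometric distance moved; judging only
the elastic increment is available as `validate.scope = "elastic_only"`.

## The accuracy metric

For a consecutive pair, with `M` the common foreground (pixels brighter
than `metric.bg_tol = 0`, plus enclosed dark holes, of both sections) and
`W_i = {x in M : I_i(x) >= t}` the "white" pixels at threshold `t = 200`,
the pair score is the directed overlap `|W_i ∩ W_j| / |W_i|`; the stack
score `R` is the mean over the `N−1` pairs.  The exact published formula
is only partially legible in the source material; the directed form
follows its legible fragments, and a symmetric variant
(`metric.symmetric = TRUE`, normalizing by the union) is provided for
sensitivity checks.  Edge conventions are fixed and tested: a pair with
both white sets empty scores 1, and an empty `W_i` against a nonempty
`W_j` scores 0.  RGB images are reduced to the per-pixel channel maximum
before thresholding.

## The synthetic world

Quantitative evaluation uses a generated sequence that mirrors the
reference construction: one textured section duplicated ten times, each
copy independently warped by a random smooth deformation on a black
background.  Specifics this package had to choose (the source construction
states none of them):

* **Base texture** (512×512): a band-passed Gaussian random field inside an
  ellipse on black, mid-gray ridges with the brightest 20% of the
  foreground lifted above intensity 200 — so the "white pixel" metric has
  structure to measure — and a black frame ≥ 8 px.
* **Deformation family**: the same cubic B-spline fields the registration
  uses, control spacing 48 px, i.i.d. Gaussian control displacements
  rescaled so the mean displacement is exactly the requested magnitude.
* **Magnitude**: 8 px mean displacement.  Large enough that the raw
  sequence visibly degrades (raw R ≈ 0.2–0.3 at t = 200), small enough
  that elastic recovery is feasible — consecutive sections differ by the
  *composition* of two independent 8 px fields.

Ground-truth fields are retained so recovery can also be judged by
endpoint error.  What the generator does **not** emulate: stain variation
across sections, tears, folds, lost sections, or non-black backgrounds.  A
green synthetic test therefore establishes the geometry of the method, not
its robustness to histology artifacts; the real-data behavior is only
inspectable qualitatively through the reslice side views.

## Numerical choices

* Coordinates are 0-based, `x` = column, `y` = row, pixel centers at
  integers, everywhere.
* Warping is backward with bilinear sampling; out-of-domain samples are
  black.  Sample coordinates within 1e−9 of a pixel center are snapped so
  identity and integer-translation warps are bit-exact.
* Field refitting (pyramid upscaling, composition with globals) solves the
  separable least-squares problem per axis with a small second-difference
  penalty (1e−6): edge knots with little support inside the domain are
  otherwise near-unidentifiable, and a plain ridge would drag them toward
  zero and corrupt derivative-based energies; the second-difference
  penalty's null space contains all affine coefficient patterns, so affine
  reproduction stays exact.
* Outside its domain a field is extended by its boundary displacement
  (identity plus edge displacement) when compositions need it.
* A constant channel stretches to all zeros (no registration signal; keeps
  it in background).
* RANSAC and the generators save and restore the caller's RNG state; every
  random step takes an explicit seed.
* `E_img` averages over in-domain pixels with the mask treated as constant
  within a gradient evaluation; a field that pushes *every* sample out of
  domain scores the worst possible similarity (255²) with zero gradient.

## Desk-scale choices in the test suite

The end-to-end acceptance experiment runs at the stated scale (10 sections
of 512×512, seeds 0–2).  The validation-model soundness and
error-containment experiments, whose scale is not fixed by their
statements, run on 256×256 stacks (n = 6 and n = 8) with the same default
configuration to stay inside the suite's runtime budget.  Error
containment uses an explicit fault-injection hook
(`register_stack(field_override = ...)`) to replace one pair's field with
a deliberately over-deformed one: corrupting the *data* instead would not
reliably produce an over-deformed *field*, since the optimizer may simply
fail to chase an unmatchable target.

## Known limitations

* The elastic stage assumes the coarse stage leaves residual displacement
  within roughly half the coarsest control spacing (~32 px); beyond that
  it converges to a wrong local minimum — which is precisely the failure
  mode the validation model exists to contain.
* Baseline uncompressed TIFF only (8/16-bit gray, 8-bit RGB); compressed
  TIFFs must be converted upstream.
* Similarity/affine coarse models: no mirror-image handling.
* Single-threaded by design; registration is deterministic given the
  configuration and seed.
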