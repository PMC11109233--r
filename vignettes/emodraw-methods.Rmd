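---
title: "Measuring and classifying emotion drawings: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and classifying emotion drawings: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`emodraw` measures the color composition of digital emotion drawings and
classifies the depicted emotion from those measurements. This vignette
documents the measurement model, the statistical machinery, the synthetic
data generator and the numerical choices behind each, so results can be
interpreted — and distrusted — for the right reasons.

## The color measurement model

Drawings are 8-bit RGB rasters on a white canvas. Every pixel is converted
to HSV with the OpenCV packing: hue is halved into 0–180 so it fits one
byte, S and V are stretched to 0–255, each channel rounded to the nearest
integer. A hue that rounds to 180 at the red wraparound is kept at 180 —
the upper red range includes it, which preserves the red classification of
near-360° hues.

Classification uses nine inclusive HSV boxes covering eight color names;
red appears twice because its hue interval straddles zero. The six
chromatic hue intervals partition 0–180 exactly (0–10, 11–36, 37–83,
84–124, 125–145, 146–180). The achromatic boxes overlap the chromatic ones
in their dark and pale corners, so classification follows a fixed
precedence: **black, white, gray**, then red (both halves), yellow, green,
blue, purple. The practical consequence is that any pixel with V ≤ 70 is
black regardless of hue — perceptually, such pixels read as black — and
classification is deterministic. Pixels falling in the gaps between boxes
(for instance S between gray's 25 and the chromatic minima) are
*unclassified*: they count as drawn (they are visibly not canvas) but are
excluded from the color shares.

The seven per-drawing metrics:

* **Prominent color** — the color with the largest share; ties break by
  the fixed palette order (red, yellow, green, blue, purple, gray, black).
  Ties have measure zero on real drawings; the rule exists for
  determinism.
* **Color percentages** — each expressive color's share of the *classified
  drawn* pixels. White (canvas) and unclassified pixels are excluded from
  numerator and denominator, so the seven shares always total exactly 100
  (integer pixel counts; the total is exact, not approximate). Shares
  relative to the whole canvas would be incompatible with a sparse drawing
  being "72% red"; relative shares are what cross-emotion composition
  tables describe.
* **Number of colors** — colors with share above a threshold, default 1%
  of drawn pixels. Lossy-compressed drawings carry trace amounts of
  spurious hues along edges; the threshold discards them. It is
  configurable (`n_colors_min_share`).
* **Saturation / brightness percentage** — mean S, mean V over drawn
  pixels, as a percentage of 255. Averaging over the full canvas instead
  would pin brightness near 100 for any sparse drawing.
* **Color fill** — drawn pixels over canvas pixels.
* **Image coverage** — fill plus interior blank holes: the background is
  flood-filled from the border over non-drawn cells with 4-connectivity,
  and everything the flood cannot reach is covered. Coverage ≥ fill for
  every possible mask, since hole-filling only adds cells.
  4-connectivity means a hole sealed only by diagonally-touching pixels
  counts as open; the implementation is a vectorized run-propagation
  fixed point, cross-checked in the tests against a scanline flood fill
  and against `EBImage::fillHull`.

Blank drawings (no drawn pixel, or no classified drawn pixel) raise a
typed `blank_canvas_error`; the batch extractor records them in a rejects
table rather than aborting, mirroring how unreadable submissions are
dropped from studies.

## Depiction styles and agreement

The five depiction-style indicators (facial expression, body language,
symbolic representation, narrative illustration, abstract/ambiguous) are
human judgments. The package only ingests them, validates that they are
binary, computes per-emotion prevalences, and quantifies inter-rater
agreement: Cohen's kappa for two raters, Fleiss' kappa for three or more,
with raw percent agreement reported alongside and never conflated with
kappa (a published "agreement of 85–92%" can mean either; both are
available). When all raters are constant on one category, expected
agreement is 1 and kappa is undefined: the functions return `NA` with a
`degenerate` flag instead of a number.

## The emotion classifier

The design matrix contains dummy indicators for the prominent-color
categorical (reference level dropped — dummy coding is what removes the
exact collinearity of compositional shares summing to 100; the raw share
block is singular by construction and is not included), saturation,
brightness, color count, fill, coverage, and the five style indicators.
Constant columns (colors never prominent in a cohort) are dropped. The
outcome reference emotion defaults to happiness, a conventional
positive-valence baseline; both references are configurable.

The multinomial logit is fitted by full Newton–Raphson on the softmax
log-likelihood: analytic score and block Hessian, step-halving whenever a
step would decrease the log-likelihood (the trace is exposed and tested to
be non-decreasing), convergence when the largest score component drops
below 1e-8 or the relative log-likelihood change below 1e-10, at most 100
iterations. Coefficients drifting beyond ±30 log-odds flag
(quasi-)separation: the fit is marked non-converged, a warning is raised,
and standard errors are withheld, but coefficients, fitted probabilities
and the classification table are still returned — with near-deterministic
predictors (synthetic cohorts make prominence almost a lookup table) the
finite-iteration fit is still the useful object, as any
maximum-likelihood software that caps iterations would report.

Fit statistics: likelihood-ratio chi-square against the intercept-only
model (whose MLE is closed-form at the class proportions), Nagelkerke
pseudo-R² `[1 − exp(2(L0−L1)/n)] / [1 − exp(2 L0/n)]`, and an
observed-by-predicted classification table computed **in-sample** — the
convention of standard multinomial-regression output; it measures apparent,
not generalization, accuracy. The bootstrap is case-resampling with
percentile 2.5/97.5 intervals; non-convergent resamples are counted and
excluded. Everything is seeded and reruns are bit-identical.

## The synthetic-drawing generator

The generator exists so that every pipeline stage can be exercised against
known ground truth. Its default profiles are the study conditions: four
emotions, per-color share means and SDs, prominent-color multinomials
(modal probabilities 0.7311 red for anger, 0.478 yellow for happiness,
0.512 blue for sadness, 0.407 black for fear, with the remaining mass
spread proportionally to the other colors' mean shares),
saturation/brightness/fill/coverage moments, and style prevalences; the
canonical cohort size is 182 participants × 4 emotions.

**Composition sampling.** Shares are drawn per color from normals at
latent (location, scale), clipped at zero and renormalized to 100. The
prominent color is drawn from the multinomial and enforced by *rejection
conditioning*: shares are redrawn (in bulk proposal pools, up to 12
rounds) until the natural maximum matches the assigned prominent color;
the rare unmet cases fall back to swapping the assigned color's share
with the maximum. Clipping, renormalization and prominence conditioning
all bias the raw means, so the latent locations are **calibrated** by
fixed-point iteration with common random numbers (20,000 draws per
iteration, location shifted by the residual, stall detection) until the
*population* means of generated shares match the target means. Latent
scales stay at the target SDs. Residual calibration bias is small
(worst cell ≈ 3 percentage points, against cohort-mean sampling bands
twice that size).

**Scalar metrics.** Saturation, brightness, fill and coverage are clipped
normals (fill floored at 2% — a zero-fill drawing would be a blank canvas,
which the extractor rejects by design; coverage ≥ fill enforced by
resampling the pair). A drawing's color mix constrains what saturation and
brightness are *achievable*: black pixels have V ≤ 70 by definition, gray
pixels S ≤ 25, chromatic pixels V ≥ 71, so a black-dominated drawing
cannot be bright. The renderer projects each drawing's targets onto the
feasible band implied by its mix (flagged in the output), and the
calibration replicates exactly that clamp when matching the population
means. This coupling between composition and brightness is a real property
of the measurement model, not an artifact.

**Rendering.** Canvas cells (default 256×256) are ordered in concentric
Chebyshev rings around the center, with a random per-drawing rotation of
each ring. The coverage region is the first C cells of that order; the
interior hole is the first H = C − F cells; the drawn region is the
annulus between. A 4-connected path from the border into the hole would
have to cross a fully drawn ring, so border flood-fill recovers coverage
*exactly*; the seal requires the enclosing ring to lie strictly inside
the border, and infeasible hole geometries (near-total coverage with tiny
fill) are shrunk to the largest sealable hole and flagged. Drawn cells
are partitioned among colors by largest-remainder rounding of the sampled
shares — shares, fill and coverage are therefore pixel-count exact.
Each color is painted with RGB triples whose min and max channels are set
exactly (mid channel carries the hue), so V is exact and the achieved S
levels are evaluated through the package's own converter; two adjacent
(S, V) levels are mixed per color so the drawn-pixel means hit the
sampled targets to well under 0.1 percentage points. The painter computes
the achieved feature vector analytically, and the tests assert that
`extract_features(render_drawing(gt))` reproduces it exactly.

**Cohort-level Monte Carlo design.** Within a cohort the sampler uses
antithetic normal deviates (pairs z, −z) and balanced largest-remainder
assignment of prominent colors. Marginal distributions are unchanged —
every drawing is still a draw from the profile — but cohort means
concentrate tightly on the calibrated population values, which is what a
generator built for moment-recovery testing should do.

**What the generator does not emulate.** Real drawings have strokes,
shapes, texture, JPEG compression noise, unclassified pixels and
correlated metrics; synthetic drawings are annuli with flat color blocks
and zero unclassified pixels. Passing recovery tests therefore validates
the *measurement and inference machinery*, not the realism of any visual
content. Style labels are sampled metadata with no visual counterpart —
style recognition is a human task. The generated share SDs exceed the
profile SDs somewhat (dispersion induced by renormalization and prominence
conditioning has a structural floor); means are calibrated, dispersions
are approximate. Per-participant correlation across the four emotions is
not modeled, matching the downstream analysis, which also treats rows as
independent.

## Numerical choices and problem sizes

* Palette bounds are inclusive on both ends; out-of-scale components are
  a validation error, not a clamp.
* Flood fill: 4-connectivity, border-seeded; run-based propagation
  converges in a handful of sweeps for blob-like masks.
* Newton tolerances as above; Hessian ridge of 1e-8 only on numerical
  singularity; separation bound ±30 log-odds.
* ANOVA with zero within-group variance and equal means returns F = 0 by
  convention; p-values are reported at machine precision.
* Calibration: 20,000 draws per iteration, tolerance 0.05 percentage
  points on means, seeds fixed internally and the caller's RNG state
  restored; results are cached per session.
* Test and acceptance cohorts use 182 drawings per emotion at 256×256
  (the study layout); unit tests use 64–128 pixel canvases and cohorts of
  1–60 per emotion, sizes chosen to exercise every code path at desk
  scale.

## Known limitations

* The HSV boxes leave unclassified gaps by design; drawings dominated by
  pale chromatic washes would show large unclassified percentages, which
  the feature vector reports as a diagnostic.
* In-sample accuracy overstates generalization; no cross-validation is
  performed (none is part of the reproduced analysis).
* Kappa values assume raters code independently; the percent-agreement
  figure is reported so either convention can be compared.
* The generator matches first moments (and the prominence multinomial)
  exactly and dispersions only approximately; it should not be used to
  benchmark variance estimators.
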