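---
title: "Minimum cross entropy thresholding with heterogeneous mean estimators"
author: "hetMCET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimum cross entropy thresholding with heterogeneous mean estimators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetMCET)
```

## The model

Bilevel thresholding treats an 8-bit image as a mixture of two intensity
populations — a dark and a bright mode of the gray-level histogram
`h(i)` — and reduces segmentation to choosing the split point `t`.
Minimum cross entropy thresholding (MCET) chooses the `t` that minimizes
the cross entropy between the image and its two-region mean-value
reconstruction:

$$n(t) \;=\; -\sum_{i=1}^{t} i\,h(i)\,\log\mu_1(t)
            \;-\; \sum_{i=t+1}^{L} i\,h(i)\,\log\mu_2(t),$$

with `L = 256`. The term `Σ i·h(i)·log i`, which completes the cross
entropy, does not depend on `t` and is dropped. Each candidate split is
scored through the two mode means; everything therefore hinges on how
those means are estimated.

The classical choice is the arithmetic mean of each mode, which is the
maximum-likelihood estimate under a symmetric (Gaussian) intensity
model. Real medical images violate that symmetry: impulse noise forces
pixels to the extremes, and by construction *salt* (255) always falls in
the upper mode and *pepper* (0) always in the lower mode, for any
candidate `t` between them. An arithmetic mean is dragged toward those
impulses, the distorted `μ` shifts `n(t)`, and the threshold moves.

This package replaces each arithmetic mean with a per-mode
order-statistic filter evaluated on the mode viewed as a sorted pixel
multiset: geometric, harmonic, contra-harmonic of order `Q`
(`Σx^{Q+1}/Σx^Q`), or alpha-trimmed (trim `d/2` pixels per tail, then
average). Each filter has a known noise profile — the harmonic and
negative-order contra-harmonic means shrug off salt, the positive-order
contra-harmonic shrugs off pepper, the alpha-trim tolerates both in
moderation. Since the two modes see *different* noise, the estimators
are paired **heterogeneously**: a pepper-robust filter for `μ₁`, a
salt-robust filter for `μ₂`. The admissible pairs are enumerated by
`heterogeneousConfigs()`: each `μ₁` estimator from {classical,
geometric, harmonic, contra-harmonic `Q ∈ {+0.5, +1.5}`, alpha-trim
`d/2 = 55`} against each `μ₂` estimator from the mirrored pool with
`Q ∈ {−0.5, −1.5}`, excluding same-approach pairs except the
sign-opposed contra-harmonic combinations — 32 configurations. The 21
homogeneous baselines (same filter on both modes, with a wider `Q` and
`d/2` grid) are kept in `homogeneousConfigs()` for comparison; row 0,
classical/classical, is exactly the original MCET.

## Index shift and numerical conventions

* **Shifted index scale.** Gray values `g ∈ [0, 255]` are mapped to
  `i = g + 1 ∈ [1, 256]` for every mean and objective computation, and
  thresholds are reported back on the 0–255 scale. This keeps
  `log`, the geometric product and the harmonic reciprocal defined at
  gray level zero without ad-hoc epsilons. Negative contra-harmonic
  orders are likewise always defined since `i ≥ 1`.
* **Histogram weighting.** All filters are computed from bin counts
  (level `i` with weight `counts[i]`), which is mathematically identical
  to filtering the expanded pixel vector but costs `O(L)` per mode. The
  test suite verifies this equivalence against brute-force expanded-list
  filtering on randomized histograms.
* **Log base.** Natural log. Any base rescales `n(t)` by a positive
  constant and cannot change the argmin.
* **Candidate range and sentinels.** All splits leaving both modes
  non-empty are scanned (255 candidates at most). A candidate whose mean
  is undefined (empty mode, vanishing contra-harmonic denominator) or
  non-positive receives an `Inf` sentinel and is skipped rather than
  aborting the scan. Histograms with fewer than two occupied levels are
  rejected as degenerate.
* **Tie-break.** At exactly tied minima the smallest `t` wins. This is
  deterministic and matches the convention of taking the first argmin of
  a scan. Its one visible consequence is analysed below.
* **Alpha-trim fallback.** If a mode holds no more than `2·(d/2)`
  pixels, the untrimmed classical mean is used instead of failing, so a
  full 255-candidate scan never aborts near the histogram tails. The
  trim count is a pixel count, not a bin count.
* **Complexity.** The scan recomputes both means per candidate, `O(L²)`
  per configuration; prefix-sum incremental means would give `O(L)` but
  the quadratic form is kept as the plainly-auditable reference (a
  256-bin scan costs milliseconds either way).

## The flat-plateau behaviour of well-separated modes

When the two modes are separated by a run of empty bins, `μ₁`, `μ₂` and
both partial sums of `n(t)` are *identical* for every `t` in that gap:
the objective has an exactly flat minimum plateau spanning the empty
range. Every `t` in the gap is equally optimal, and the smallest-`t`
rule reports the plateau's low edge — just above the upper tail of the
dark mode. On a clean two-Gaussian phantom with means 60/190 and
`σ = 10` the gap spans roughly [97, 151], so classical MCET reports
`t* ≈ 97`, about 28 levels below the 125 midpoint, while the resulting
mask is still essentially perfect (Jaccard ≈ 1): every pixel between
the modes is classified identically by any threshold on the plateau.
Users comparing `t*` against a mixture-model boundary should therefore
compare *masks*, or inspect `objectiveCurve()` for the plateau extent,
rather than expect the reported scalar to sit mid-gap. We considered
reporting the plateau midpoint instead, and kept the smallest-`t` rule:
it is the standard first-argmin convention, it keeps the reported
threshold an actually-evaluated candidate, and it makes the result of
the scan identical to that of any straightforward re-implementation used
for cross-checking.

## Evaluating a segmentation

Three unsupervised measures score a thresholded image without ground
truth, each in `[0, 1]` with higher better:

* **Image uniformity** `1 − (σ₁² + σ₂²)/Z`, `Z = (I_max − I_min)²/2`,
  with population variances of the two regions. A constant image is
  defined as perfectly uniform. (A printed form of this measure
  subtracts the variances, which would exceed 1 whenever `σ₂² > σ₁²`;
  the sum is the Levine–Nazif uniformity the measure descends from, and
  is what this package computes.)
* **Region contrast** `|μ₁ − μ₂| / (μ₁ + μ₂)`. (The difference, not the
  sum, sometimes appears in print as the denominator, which collapses
  the measure to ±1 for all inputs; the sum is the standard
  normalization.) The means entering this measure are the *actual*
  arithmetic means of the two threshold-induced regions, not the
  estimator pair's outputs: the evaluation describes the segmentation,
  and must rank configurations by where they put the threshold. Wiring
  the estimator outputs in here instead would let a filter that
  *underestimates* `μ₁` inflate its own contrast score — we observed a
  homogeneous contra-harmonic configuration winning a comparison purely
  through that bias before fixing the convention.
* **Inter-region disparity** compares interior contrast (mean over
  region pixels of the largest normalized difference to an 8-neighbor
  inside the region) with exterior contrast (the same over border
  pixels, to neighbors outside): per region `1 − CI/CE` if
  `0 < CI < CE`, `CE` if `CI = 0`, else 0; regions combine by area
  weight. The 3×3 8-connected window and the area weighting are this
  package's choices where the measure's printed form leaves them open.

With a ground-truth mask, Jaccard `TP/(TP+FP+FN)`, F-score
(`2PR/(P+R)`, identically `2J/(1+J)`) and pixel accuracy
`(TP+TN)/total` are added. `selectBestThreshold()` averages all present
scores per configuration — six with ground truth, three without, the
latter matching how unlabeled datasets must be handled — and returns the
configuration maximizing the average, ties broken by smaller
configuration row then smaller threshold. A configuration whose metrics
fail a precondition (e.g. its mask collapses to one label) scores 0 with
a warning instead of aborting the sweep.

## The phantom generator

`generatePhantom()` builds the canonical test scene for this method
family: a geometric foreground (disk, ellipse or rectangle) on a flat
background, intensities `clip(round(N(μ_region, σ)), 0, 255)`, then a
`saltDensity` fraction of pixels forced to 255 and a `pepperDensity`
fraction to 0, chosen uniformly over the canvas so that both modes'
territories are contaminated. Gaussian noise is applied first and
impulses overwrite it, the standard impulse model, which makes the
histogram's tail masses exact — `round(density · N)` pixels at each
extreme. Defaults (100×100 canvas, centered disk of radius 25, means
60/190, `σ = 10`) give a lesion-like foreground occupying ~20% of the
frame with modes separated by 13σ; `bayesThreshold()` returns the
equal-variance midpoint `(μ_bg + μ_fg)/2` as the recovery reference.
Generation is bit-reproducible from the spec's seed and leaves the
caller's RNG state untouched.

What the phantom deliberately does *not* model: spatial noise
correlation, illumination gradients, hair/vessel artifacts, partial
volume effects, or textured regions. Passing results on phantoms
demonstrate correctness of the estimator/objective machinery and the
claimed noise-robustness *mechanism*, not clinical performance on
dermoscopy or MRI data.

## Study sizes used by the test suite

The shipped tests exercise: exhaustive equivalence of the threshold
search against a brute-force expanded-pixel re-scan on 50 random
16-level histograms for all 33 configurations (classical + 32
heterogeneous); filter identities (`Q = 0` ↔ classical, `Q = −1` ↔
harmonic, `d/2 = 0` ↔ classical, AM ≥ GM ≥ HM) on 100 random modes; the
analytic two-delta histogram; parameter recovery and the
classical-vs-homogeneous-vs-heterogeneous comparison on 20 seeded
100×100 phantoms each. These sizes were chosen to keep the full suite
in the low minutes on a single core while leaving each stochastic claim
with enough replicates for a stable median.

## Known limitations

* Single threshold only; no multi-level extension (the scan generalizes
  but its cost grows as `O(L^{x+1})` for `x` thresholds).
* The 8-bit histogram domain is fixed at 256 bins; deeper rasters are
  rescaled on read.
* Region contrast uses shifted-scale means, so its value differs in the
  third decimal from a 0–255-scale evaluation; comparisons within a run
  are unaffected.
* The average-score selector weights all measures equally; no
  application-specific weighting is offered.
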