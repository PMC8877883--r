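# hetMCET

Bilevel segmentation of 8-bit grayscale images — skin-lesion dermoscopy,
brain MRI, or any image whose histogram splits into a dark and a bright
mode — by **minimum cross entropy thresholding (MCET) with heterogeneous
mean estimators**. It is aimed at image-analysis practitioners who need a
deterministic, histogram-based alternative to learned segmenters that
stays robust when impulse (salt-and-pepper) noise contaminates the two
histogram modes asymmetrically.

## The method

MCET picks the threshold *t\** minimizing the cross entropy between the
image and its two-region mean reconstruction:

```
n(t) = − Σ_{i=1..t} i·h(i)·log μ₁(t)  −  Σ_{i=t+1..L} i·h(i)·log μ₂(t)
```

where `h(i)` is the histogram over gray levels `i ∈ [1, L]` (`L = 256`;
internally gray value `g ∈ [0, 255]` maps to `i = g + 1` so logarithms
are always defined) and `μ₁, μ₂` are the means of the two modes induced
by `t`. Classically both means are arithmetic averages. This package
instead estimates each mode's mean with its own order-statistic filter,
treating the mode as a sorted pixel multiset:

| filter | formula | robust against |
|---|---|---|
| classical | `Σ x / n` | — |
| geometric | `(Π x)^{1/n}` | mild high outliers |
| harmonic | `n / Σ 1/x` | salt (255) impulses |
| contra-harmonic, order Q | `Σ x^{Q+1} / Σ x^{Q}` | pepper for `Q > 0`, salt for `Q < 0` |
| alpha-trimmed, d/2 | mean after trimming d/2 pixels per tail | mixed impulses |

Salt impulses always land in the upper mode and pepper in the lower one,
so pairing a pepper-robust estimator for `μ₁` with a salt-robust one for
`μ₂` ("heterogeneous" estimation) matches each filter to the noise it
can actually see. The package enumerates all 32 admissible heterogeneous
pairs plus the 21 homogeneous baselines, scans all 255 candidate splits
per pair, scores every resulting segmentation with three unsupervised
measures (image uniformity, region contrast, inter-region disparity) and
— when a ground-truth mask exists — Jaccard, F-score and pixel accuracy,
and returns the threshold maximizing the average score.

A synthetic phantom generator (bimodal disk/ellipse/rectangle images
with Gaussian and impulse noise and exact ground truth) makes the whole
pipeline testable without any external dataset.

## Worked example

```r
library(hetMCET)

## noisy bimodal phantom: disk (mean 190) on background (mean 60),
## sigma 10, 5% salt + 5% pepper, with its ground-truth mask
ph <- generatePhantom(phantomSpec(saltDensity = 0.05,
                                  pepperDensity = 0.05, seed = 42))
h <- computeHistogram(ph$image)
h
#> GrayHistogram: 10000 pixels, 137 occupied levels in [0, 255]

## original MCET = classical/classical baseline (config row 0)
findThreshold(h, configById(0))
#> ThresholdResult: t* = 103 (config 0), mu1 = 57.047, mu2 = 204.986, objective = -4.2687e+06

## full heterogeneous sweep + evaluation against the ground truth
run <- runSegment(ph$image, gt = ph$mask, configs = "all-heterogeneous",
                  quiet = TRUE)
run$best
#> ThresholdResult: t* = 103 (config 1), mu1 = 57.047, mu2 = 203.155, objective = -4.2645e+06
head(run$table[order(-run$table$average), ], 3)
#>   configId tStar        iu        rc disparity   jaccard    fscore accuracy   average
#> 1        1   103 0.9654139 0.5645829 0.8199032 0.7807531 0.8768797   0.9476 0.8258555
#> 2        2   103 0.9654139 0.5645829 0.8199032 0.7807531 0.8768797   0.9476 0.8258555
#> 3        3   103 0.9654139 0.5645829 0.8199032 0.7807531 0.8768797   0.9476 0.8258555
```

The sweep reports, per configuration, the chosen threshold `tStar`, the
three unsupervised scores (`iu`, `rc`, `disparity`), the three
supervised scores against the mask (`jaccard`, `fscore`, `accuracy`) and
their average; `run$best` is the result with the maximal average (ties
break on the smaller configuration row). Here the Jaccard of 0.78
against the generating mask reflects the 10% of pixels destroyed by
impulse noise — the threshold itself is placed correctly between the
modes.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/hetmcet.R segment lesion.png --gt lesion-mask.png --report report.json
Rscript inst/cli/hetmcet.R configs heterogeneous
```

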