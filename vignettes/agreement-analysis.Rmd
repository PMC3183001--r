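---
title: "Consensus molecular histology for imaging mass spectrometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus molecular histology for imaging mass spectrometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msiagree)
```

## The model

MALDI imaging MS yields one spectrum per pixel on a tissue raster. Regions
whose pixels share a correlated spectral profile constitute a "molecular
histology": tissue annotation driven by chemistry rather than morphology.
Unsupervised multivariate methods expose such regions as component images,
but different methods — and different components of the same method —
amalgamate regions differently, so any single method is an unreliable
witness. The package's core statistic is the *agreement plot*: an integer
image counting, per pixel, how many of five methods (PCA, NNMF, MAF,
fuzzy c-means, PLSA) independently mark that pixel after cross-method
component matching and thresholding. Regions corroborated by four or five
methods are treated as robust findings.

The pipeline is: reduce each dataset to a pixels × features matrix; merge
datasets; TIC-normalize; decompose with all methods; iterate every
method's top-K components as templates, matching each other method's
best-correlating component (unfolded Pearson over tissue pixels);
threshold the matched images at a fixed fraction of their maxima; sum;
remove redundant plots (`cutdown`); and average the matched,
basepeak-normalized loadings into a consensus spectrum.

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| smoothing width / cycles | 2 Da / 4 | FWHM | vendor-style Gaussian smoothing for linear-TOF protein spectra |
| peak picker S/N | 4 | – | detection threshold on representation spectra |
| peak width / integration window | ±500 ppm | ppm | linear-TOF peak width for peptides/proteins |
| collation tolerance | 100 ppm | ppm | cross-dataset mass reproducibility |
| components per method (K) | 8 | – | matching considers each method's top 8 |
| image threshold | 40% of max | – | background in component images sits mostly below 40% of the maximum |
| cutdown correlation | 0.70 | – | plots correlating above this with a kept plot are redundant |
| FCM fuzziness m | 1.25 | – | near-crisp memberships; boundary pixels stay mixed |
| NNMF iterations | 100 (+ extension) | – | multiplicative updates typically stabilize within 100; extended until relative change < 1e-6 |
| PLSA stopping | 1e-5 / 500 iter | – | relative log-likelihood change |

Mean-centering precedes PCA, MAF, k-means and FCM; NNMF and PLSA run on
the raw non-negative matrix, which their models require.

## Numerical and design choices

Several points are underdetermined by the published descriptions of the
constituent algorithms; the package fixes them as follows.

* **Peak picker S/N semantics.** Noise is 1.4826 × the running median
  absolute deviation over a window spanning 2% of the axis. The *signal*
  is the apex height **above the local running median**, with the apex
  estimated as a 3-channel mean (apex centroiding). Convex-hull-corrected
  spectra retain a positive background pedestal; measuring raw intensity
  against the MAD would count that pedestal as signal and flood the peak
  list with false detections. Note that even so, S/N 4–5 detections of
  smooth chemical noise are expected on long axes — real reduced panels
  behave the same way, which is why peak counts in real data run into the
  hundreds.
* **Smoothing semantics.** "Width" is the kernel FWHM; repeated cycles
  compose to a single Gaussian of cycles-fold variance (verified
  numerically in the tests). Boundaries are reflective, conserving total
  intensity away from the edges.
* **Baseline.** The lower convex hull of the (m/z, intensity) point set,
  linearly interpolated between vertices. It is invariant to adding
  constants or linear ramps and never produces negative corrected
  intensities.
* **Collation.** Single-linkage in one dimension: sorted peak centres are
  chained while consecutive gaps stay within tolerance; cluster centres
  are unweighted means. This is order-independent and idempotent.
* **Sign handling.** PCA and MAF components are sign-indefinite. Each is
  stored with the sign giving its score image non-negative skewness;
  matching additionally tries both signs and records a flip flag, and
  negative scores are clipped to zero before thresholding. Tests verify
  end-to-end invariance of the surviving plots under arbitrary component
  negation.
* **MAF boundaries.** The shift covariance pools one-pixel horizontal and
  vertical difference vectors but never pairs pixels from different
  source datasets, so merge gutters cannot inject artificial gradients.
  A ridge of 1e-9 × trace(Σ)/F is added when the data covariance is
  singular (TIC-normalized data are rank-deficient by construction).
* **Cutdown rank.** "Number of correlated images" is operationalized as
  the count of matches with r ≥ 0.7, with mean match correlation as the
  tie-break; redundancy is judged on the *continuous* (non-thresholded,
  min–max scaled) images, whose dynamic range suits Pearson correlation.
  The template's own image is included in the sum, so the agreement scale
  runs 0..5 for five methods.
* **Component counts.** FCM and PLSA use the same K = 8 as the factor
  methods; k-means participates only as an exploratory sixth method and
  is excluded from the default agreement set.
* **Zero-TIC pixels** are retained as zero vectors so image geometry is
  preserved.

## The phantom generator

`phantom_spec()` describes a stated world emulating a nodular sarcoma
dataset: a 60 × 50 grid (3000 pixels) carrying three elliptical nodules;
a shared panel of 85 peaks in m/z 2000–25000 whose mean intensities are
log-normal (meanlog log 10, sdlog 0.6 — most peaks near the detection
limit, a right tail of large uniform contributors, about an order of
magnitude of dynamic range); five differential peaks per nodule at
intensity 80, i.e. among the most intense peaks of their region, as
befits markers of a spectrally distinct nodule; additive Gaussian noise
with sd 2.5, placing the median shared peak at the S/N ≈ 4 detection
threshold a reduced panel is built with and the differential peaks at
S/N 32; a log-normal per-pixel TIC factor with sdlog 0.15 (the
sensitivity drift that motivates TIC normalization); and, for
profile-mode phantoms, Gaussian peaks of 800 ppm FWHM on an exponentially
decaying baseline.

What a green test establishes: that the full reduce → decompose → agree
chain recovers planted, well-separated, spectrally distinct nodules with
Jaccard > 0.8 at agreement level ≥ 4, and that the continuous agreement
plot tracks ROI-derived target images more consistently (lower dispersion)
than any single method. What it does not establish: performance on real
tissue, where peak shapes drift, intensities are ionization-biased,
regions have fuzzy borders, and spectral panels overlap between regions.
The generator's noise is Gaussian-plus-clipping, not Poisson; a hook for
alternative noise models is deliberately left open.

A known structural effect worth understanding: in TIC-normalized data,
any feature that is uniform across the tissue becomes *anti*-correlated
with every nodule (the nodule's extra ions inflate the denominator).
Target images that include large uniform contributors therefore show
shallow dips at all other nodules. This is faithful to how such targets
behave, and it bounds how closely an agreement plot can correlate with an
"unrefined" target.

## Degenerate inputs and tie-breaks

Zero-variance images correlate as 0 (with a warning); all-zero images
threshold to all zeros; matching ties break to the lower component index;
k-means and FCM restarts are seeded deterministically from the
configuration seed, and every stochastic method is bit-reproducible for a
fixed seed. `collate_peaklists` of an empty list is empty; extraction
windows containing no channel yield zero features with a warning naming
the centre.

## Limitations

* The reduced-data target construction selects features by S/N against
  the panel-wide MAD of the ROI profile; with very small panels (< ~8
  features) the MAD is unstable and the selection unreliable.
* Resource accounting implements the published FLOP formula as printed;
  it reproduces the reduced-data entries of the published table, but not
  the raw-data entries, which are inconsistent with the formula.
* imzML support is the minimal continuous/processed subset with 64-bit
  float arrays; vendor raw formats are out of scope.
* Agreement levels carry no significance calibration; they are counts,
  not p-values.
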