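---
title: "Texture analysis and neural-network clustering: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture analysis and neural-network clustering: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(texclust)
```

`texclust` quantifies tissue morphology in histology micrographs with
classical texture statistics, and groups samples — described either by
those statistics or by laboratory indicator panels — with an unsupervised
competitive neural network. This vignette is the package's account of the
underlying models, the conventions adopted where several are in circulation,
and the reasoning behind the defaults.

## 1. From micrograph to gray-level raster

Micrographs are read as 8-bit RGB (PNG via the `png` package; uncompressed
8-/24-bit BMP via a built-in reader, since BMP is the common export format
of older microscope software and no installed package reads it). Luminance
uses the fixed ITU-R 601 weights `0.299 R + 0.587 G + 0.114 B`, rounded
half-up. Fixing the weights — rather than delegating to a library whose
defaults may drift — makes every downstream feature bit-reproducible.

Before the co-occurrence and run-length stages the image is quantized to
`L` gray levels. The default is `L = 64` with `"minmax"` normalization, a
common texture-software default; gradient features are computed on the
unquantized 256-level image, where fine intensity differences carry signal
rather than noise. Three normalization modes are offered:

* `"minmax"` maps the observed range `[lo, hi]` by
  `q = floor((x - lo) * L / (hi - lo + 1))`. On integer input this produces
  *equal-width bins* (a full 0..255 ramp lands in exactly `L` equally
  populated bands), which is the property that matters for co-occurrence
  statistics. The price is a corner case: when the dynamic range of the
  input is smaller than `L - 1`, the top level is not attained. A constant
  image maps to all zeros — an explicit convention avoiding a 0/0 in the
  range mapping.
* `"3sigma"` maps `[mu - 3 sigma, mu + 3 sigma]` with clipping; robust to a
  few extreme pixels.
* `"none"` rescales the nominal `[0, 255]` range and is the identity at
  `L = 256` — useful when images are already comparably exposed.

Min–max normalization also buys shift invariance: adding a constant to all
pixels changes neither the quantized image nor (since central differences
cancel constants) the gradient map, and the test suite verifies this
end-to-end.

## 2. Texture statistics

**Co-occurrence (COM).** For a displacement `(dy, dx)` the matrix counts
co-occurring gray-level pairs; accumulation is *symmetric* (each pair
increments both `[i,j]` and `[j,i]`), the dominant modern convention, which
halves the number of distinct offsets to consider. Eleven second-order
statistics are computed from the normalized matrix with levels indexed
`1..L`: angular second moment, contrast, correlation, sum of squares,
inverse difference moment, sum average, sum variance, sum entropy, entropy,
difference variance and difference entropy. Entropies are log base 2 with
`0 log 0 = 0`. Two conventions deserve note: the sum variance is taken
around the *sum average* (the commonly used corrected form of the classical
definition), and the correlation of a zero-variance marginal is defined as
0, so that constant images still yield finite feature vectors. Features are
computed at distances 1–5 and averaged over the four angles
(0°, 45°, 90°, 135°), giving rotation-robust descriptors named
`com_d<d>_<stat>`.

**Run length (RLM).** Maximal runs of constant gray level are tallied by
(level, length) along each of the four directions; single pixels are runs
of length 1, so runs partition the pixels — the suite checks
`sum(length x count) = H x W` in all directions. The five Galloway
statistics (short- and long-run emphasis, gray-level and run-length
nonuniformity, run percentage) are averaged over the four directions.

**Gradient (GRM).** Central differences at interior pixels,
`sqrt((I[y+1,x]-I[y-1,x])^2 + (I[y,x+1]-I[y,x-1])^2)`, without dividing by
the spacing (absolute-gradient convention). Borders are excluded rather
than padded: padding invents data and the one-pixel frame is negligible for
micrograph-sized inputs. Summary features are the mean, population
variance, skewness, excess kurtosis (both 0 by convention on a
zero-variance map) and the percentage of nonzero magnitudes.

With the default configuration this yields `11 x 5 + 5 + 5 = 65`
descriptors per image. Every feature implementation is tested against an
independent brute-force oracle (direct double loops over the matrices) to
1e-10 on random 8-level images.

## 3. Fisher-coefficient selection

For descriptor selection the Fisher coefficient is the ratio of
between-class to within-class variance with group-size weights
`p_k = n_k / N`:

$$F = \frac{\sum_k p_k\,(\mu_k - \mu)^2}{\sum_k p_k\,\sigma_k^2}$$

Group variances are population (divide-by-n) variances. Size weighting is
the classical Fisher-discriminant form and matters here because image
counts per group vary (36 ± 4 in the motivating design). A perfectly
separating descriptor (zero within-class variance, distinct means) gets
`F = Inf` and sorts above everything — it must never be dropped; `0/0` is
defined as 0. Ties are broken by ascending descriptor name so selection is
deterministic. The default `k = 10` mirrors the common practice of keeping
the ten best texture parameters before clustering; the indicator route
(8 descriptors) skips selection entirely. When a test group is analyzed
together with the two reference groups, `F` is computed on exactly the
groups present in that run — selection adapts to the contrast actually
being clustered.

## 4. Competitive-learning clustering

The clustering network is a set of `n_clusters` weight vectors (default 2)
trained by winner-take-all competitive learning — a one-dimensional Kohonen
network without a neighborhood function, which is the canonical
"neural-network clustering". A separately exported threshold neuron
(`neuron_output`: 1 iff `w·x > threshold`, equality falling to 0) documents
the underlying unit model; binary threshold units are kept as a reference
abstraction because they cannot themselves express nearest-centroid
assignment.

Numerical choices, all of which the suite pins down:

* **Standardization.** Features are scaled to zero mean / unit SD before
  distances are computed; indicator panels span four orders of magnitude
  (catalase ~147 u/mg vs MDA ~1 nmol/mg), so unstandardized Euclidean
  distance would be a catalase ruler. Zero-SD features are excluded with a
  warning.
* **Initialization.** Units start at `n_clusters` distinct randomly chosen
  samples (seeded), so they begin inside the data cloud.
* **Schedule.** Samples are visited in seeded random order each epoch; the
  winning unit moves by `eta(t) = lr * (1 - t/epochs)` toward the sample,
  with defaults `epochs = 100`, `lr = 0.5`. The rate hits 0 in the final
  epoch, which therefore only confirms the assignment.
* **Ties.** Equal distances go to the lowest unit index, making assignment
  deterministic.
* **Reproducibility.** All randomness flows through one seed; training is
  bit-reproducible and restores the caller's RNG state.

On well-separated data the trained partition coincides with the exhaustive
least-squares two-partition (verified against a brute-force oracle at
n = 12), and purity is 100% across seeds on two-blob data separated by 20
within-class SDs.

Cluster indices are arbitrary (label symmetry). All reported outputs are
therefore *canonicalized*: cluster 1 is relabeled to the majority cluster
of the first reference group, cluster 2 to that of the second. If both
references share a majority cluster — no meaningful anchoring — raw indices
are kept and a degeneracy flag is set rather than guessing.

## 5. Characterization

The group-by-cluster table reports each group's percentage split across
clusters (rows sum to 100). The weighted-average profile reports, per
cluster and descriptor, `wa = (mu_d - mu_a) / mu_a`. `mu_a` is taken as the
mean over *all samples*, not the mean of cluster means: under that reading
the size-weighted deviations balance exactly, `sum_c n_c wa_c = 0`, for any
cluster sizes — an invariant the suite checks to 1e-9 — whereas the
mean-of-means reading loses it whenever clusters are unequal. Descriptors
with `mu_a = 0` have no meaningful relative deviation and are flagged
undefined instead of reported. `export_report()` writes the distribution
CSV, the profile CSV, a JSON report (including the degeneracy flag) and one
bar chart per cluster.

## 6. What the synthetic generators emulate — and what they do not

**Images.** `make_texture_image()` builds an annulus-based model of
cross-sectioned tubular tissue: non-overlapping rings (tubule walls, packed
largest-first by seeded rejection sampling) on a bright background, an
interior stippled with cell-like dots at probability `(1 - delta) * p_fill`,
plus Gaussian pixel noise (SD 8 gray levels). The degeneration level
`delta` thins the stippling, shrinks and sparsifies the tubules, and adds
bright luminal vacuoles — a caricature of atrophy and germ-cell depletion.
An annulus model was chosen over, say, Gaussian random fields because it
produces the ring-and-lumen co-occurrence structure real tubule sections
have, giving the texture stage a realistic discriminative signal. Defaults
(density 1.2 per 10^4 px², radii 18–32 px, wall 3 px, `p_fill` 0.35) give
fields that look qualitatively like 40x testis sections at 256 x 256. The
default group schedule of degeneration levels is `N` 0, `CIS` 1, `CIS+L`
0.7, `CIS+M` 0.35, `CIS+H` 0.15 — monotone in dose, severe for the
unprotected toxicant group.

What the generator does *not* model: staining color (images are synthesized
directly in luminance), nucleus-level morphology, interstitial cell
populations, imaging artifacts, or inter-animal correlation between fields.
A pipeline that separates `delta = 0` from `delta = 1` with >= 95% purity
(which the suite demonstrates at 36 images per class, 256 x 256) is
therefore shown to work on textures *of this contrast class*, not certified
for real histology.

**Indicator tables.** `make_animal_table()` draws each of the 8 indicators
independently as `Normal(mean, SE * sqrt(n0))` with `n0 = 10`, the group
size at which the published standard errors were stated; the conversion
deliberately uses `n0` rather than the number of simulated animals, so
calibration runs with many animals keep the per-animal spread. The
published errors are labeled standard errors; a `spread = "sd"` switch
exists for the alternative reading, which would triple the simulated
spread. Negative draws of these positive quantities are truncated at 0
with a warning (relevant only for the high-SE sperm-count entries).
Independence across indicators is an assumption of necessity — no
covariances are published — and is the main caveat on the simulated
clustering results: real MDA/CAT/SOD values are correlated, which could
only make reference groups easier or harder to separate than the simulation
suggests. Three entries of the published tables contain obvious stray
punctuation in the error term; the shipped YAML records the corrected
values with a comment.

## 7. Problem sizes and verification scope

The test suite runs the full image pipeline at its study scale — 36 images
per class at 256 x 256, 65 descriptors, top-10 selection, two-cluster
training — in well under a minute, and the oracle-equivalence battery uses
fifty random 16 x 16 eight-level images, where brute-force double loops are
exact and fast. The indicator-route checks use the published six-group,
n = 10 design directly. `scripts/acceptance.R` re-simulates the reference
separation (t1) and the high-dose aggregation (t2) from the published
summary statistics at the study's own sample sizes.

## 8. Known limitations

* Wavelet, autoregressive and histogram feature families are out of scope;
  the three implemented families are the ones named by the motivating
  analysis.
* The clustering is fixed-k; no model selection for the cluster count.
* Feature extraction is single-threaded, pure R; at 744 x 744 and 20
  offsets it takes a few seconds per image, which is acceptable for
  study-sized batches (~180 images) but not for high-throughput scanning.
* The weighted-average profile is descriptive; no inferential statistics
  (the motivating design's ANOVA/Dunnett analysis is routine and not
  reimplemented here).
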