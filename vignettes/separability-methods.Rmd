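---
title: "Band-by-band spectral separability of forest types: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Band-by-band spectral separability of forest types: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forestsep)
```

## The problem

Forest types defined by tree-species composition (e.g. deciduous broadleaf
vs. Mediterranean coniferous) can have nearly identical spectral signatures
when observed with a broad-band multispectral sensor, while a hyperspectral
imager samples the 400-2500 nm range in hundreds of narrow contiguous bands
and may resolve the differences. Before any classification it is useful to
ask, band by band, *how statistically distinguishable* two class-conditional
reflectance distributions are. `forestsep` implements that pairwise
separability analysis for two sensors at once — a PRISMA-like hyperspectral
preset (239 bands, 30 m) and a Sentinel-2-like multispectral preset (10
land-monitoring bands resampled to 30 m) — and quantifies the hyperspectral
gain as a percentage increment.

## Model and criteria

Each class $x$ is summarized per band by the sample mean $\mu_x$ and sample
standard deviation $\sigma_x$ (with $n-1$ denominators) of the reflectance of
all pixels whose centers fall inside that class's reference polygons. For a
class pair $(a, b)$ and one band, four criteria are computed, all under a
Gaussian class-conditional model:

* **M-statistic** $M = |\mu_a - \mu_b| / (\sigma_a + \sigma_b)$ — peak
  separation in units of spread. Blind to variance-only differences.
* **Bhattacharyya distance**
  $B = \tfrac18 (\mu_a-\mu_b)^\top S^{-1} (\mu_a-\mu_b)
  + \tfrac12 \ln\!\big(|S| / \sqrt{|\Sigma_a||\Sigma_b|}\big)$ with
  $S = (\Sigma_a+\Sigma_b)/2$.
* **Jeffries–Matusita distance** $JM = 2(1 - e^{-B})$, a bounded transform of
  $B$ interpreted as classification potential.
* **Transformed divergence** $TD = 2(1 - e^{-D/8})$, with $D$ the symmetric
  divergence
  $D = \tfrac12 \mathrm{tr}[(C_a - C_b)(C_b^{-1} - C_a^{-1})]
  + \tfrac12 \mathrm{tr}[(C_a^{-1} + C_b^{-1})(\mu_a-\mu_b)(\mu_a-\mu_b)^\top]$.

Some field literature prints $B$ and $D$ with sign typos (a pooled
covariance written as a difference, mismatched inverse sums) under which
identical classes would not score zero; `forestsep` implements the standard
textbook forms above, which are symmetric, nonnegative, and zero exactly at
identical summaries. The same literature describes $JM$ as "asymptotic to
$\sqrt2$" while printing the 2-bounded formula; both conventions exist in
practice, so the 2-bounded form is the default and
`jeffries_matusita(B, sqrt_convention = TRUE)` gives the
$\sqrt{2}$-bounded variant. Every exported table records which convention
was active.

The band-by-band pipeline applies all four with $d = 1$ (per-band variance);
the multivariate forms are exposed for completeness and are tested via their
additivity over independent dimensions, not used by the pipeline.

### Normalization for averaging

"Best wavelength" matrices rank bands by the *average* of the four criteria,
which live on incommensurate scales ($JM, TD \le 2$; $B, M$ unbounded). Raw
averaging would be dominated by $B$ and $M$, so each criterion is first
mapped onto $[0,1]$ by a fixed strictly increasing map with limit 1:
$JM/2$ (or $JM^2/2$ under the square-root convention), $TD/2$,
$1 - e^{-B}$, and $M/(1+M)$. The averaged quantity is the arithmetic mean of
these normalized values.

### Cross-sensor increment

For each pair and criterion, the per-sensor maximum over bands
($\max$ separability) is located, ties broken toward the lowest wavelength,
and the hyperspectral gain is
$I = 100\,(\mathrm{Max}_h - \mathrm{Max}_m)/\mathrm{Max}_m$ percent.
Per-area summaries are the arithmetic mean of per-pair increments; the
headline cross-area figure is the unweighted mean of the per-area means
(`overall_improvement()`). Note that on synthetic scenes whose contrast sits
entirely in multispectral-blind windows, $\mathrm{Max}_m$ is at the noise
floor and increments become arbitrarily large — the ratio is faithful but
its magnitude is then not meaningful beyond "positive".

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `overlap_tolerance_nm` | 0.5 | nm | Two detector bands count as duplicates when their centers differ by at most this; the hyperspectral preset's 9 coincident pairs are exact, and 0.5 nm matches the instrument's stated spectral calibration accuracy. |
| `eps` (variance floor) | 1e-10 | reflectance² | Ridge added when a variance falls below 1e-12, so degenerate (constant) synthetic classes do not crash band loops. Recorded in the QC attribute. |
| `jm_sqrt` | `FALSE` | — | JM convention; see above. |
| `sd_spectrum` | 0.01 | reflectance | Synthetic per-pixel noise; see below. |
| `decimals` | 2 | — | Rounding of exported tables (a raw full-precision copy is always written alongside). |

## The synthetic world

No public archive provides the original paired scenes and reference
polygons, so the package ships a generator that *states* a world with known
parameters instead:

* Every class shares a stylized broadleaf-canopy baseline spectrum
  (`forest_reflectance_baseline()`: green peak, red absorption, red-edge rise
  to a 0.45 NIR plateau, water troughs at 1450/1940 nm) and departs from it
  by constant offsets inside **contrast windows** — blue 405-445 nm,
  red edge 700-745 nm, NIR plateau 1340-1400 nm, SWIR 1790-1860 nm —
  the regions vegetation studies repeatedly report as discriminative.
  Offsets (0.05-0.07) are a few noise standard deviations: separable, not
  trivially so.
* Pixel noise is independent Gaussian per pixel and band, sd 0.01, clipped
  to $[0,1]$. The original instruments publish only SNR bounds, not a band
  noise model, so this sd is a free parameter chosen once: it is comparable
  to the radiometric accuracy of an atmospherically corrected L2 product and
  keeps the clipping probability negligible (< 1e-7 per draw at the darkest
  baseline), so Gaussian oracles remain exact for test purposes. There is no
  spatial or spectral autocorrelation — matching the independence
  assumptions of the criteria and keeping every oracle closed-form. (A
  spectrally correlated generator would be a straightforward extension but
  is deliberately off: the metrics are univariate per band, so correlation
  would change nothing downstream except covariance tests.)
* Two preset areas mirror the study design: Area 1 with four fourth-level
  classes (3111, 3112, 3115, 3121), Area 2 with five (adding 3122), each
  class a 32 × 32-pixel block (1024 px) at 30 m, aggregable to the
  third-level broadleaf/coniferous split.
* The multispectral view is *derived from the same hyperspectral cube* by
  unweighted averaging of the hyperspectral bands inside each multispectral
  band's FWHM window — both sensors literally observe the same field, as in
  a paired-acquisition campaign. Averaging $k$ bands shrinks noise by
  $\sqrt{k}$, so the multispectral sensor can legitimately *win* on pairs
  whose contrast it senses — a realistic and desirable property of the
  simulation.

What a green test on this world establishes: the extraction, statistics,
metric and selection code do what the formulas say, and the pipeline
recovers planted contrast where (and only where) it was planted. What it
does not establish: anything about real atmospheric residuals, topographic
illumination effects, mixed pixels, or spatial autocorrelation — the
published real-data separability values are not reproducible from first
principles and are not targets, with one exception: the published table's
own $B \to JM$ functional relation, which the package does reproduce.

## Numerical choices

* **Tie-breaks**: argmax over bands resolves ties toward the lowest
  wavelength; nearest-neighbor resampling resolves center ties toward the
  smaller row, then smaller column.
* **Pixel-in-polygon**: a pixel belongs to a polygon iff its center is
  inside or on the boundary (even-odd rule, boundary-inclusive). Pixels
  claimed by two *different* classes are excluded and counted; same-class
  multiple claims merge.
* **Grid convention**: 1-based indices, north-up grids only, pixel area
  half-open; no reprojection anywhere (scenes must share a CRS label).
* **Band bookkeeping**: for each VNIR/SWIR pair of centers within the
  overlap tolerance the SWIR member is dropped (VNIR retained); the
  operation is idempotent, and 239 preset bands reduce to 230.
* **Wavelength units**: sidecar or header wavelengths below 100 are treated
  as micrometres and converted to nm, with a warning.
* **Degenerate inputs**: zero-band scenes are unrepresentable; classes with
  fewer than 2 pixels, empty polygon sets, zero-pixel classes, and empty
  spectral averaging windows are hard errors, not silent drops.

## Known limitations

* The hyperspectral preset's individual band centers are a stated, even
  grid honouring the published counts/ranges/overlaps — not the real
  instrument's (unpublished as a flat table) center list. Analyses depending
  on exact real band positions should load their own sensor table.
* ENVI-dialect I/O covers BSQ float32/float64 only; no HDF5 product
  ingestion, cloud masking, or atmospheric correction.
* Separability is descriptive: no hypothesis testing on metric differences
  and no classification accuracy assessment are provided.
* Increment summaries on synthetic worlds with sensor-blind contrast are
  unbounded (see above); compare medians or per-pair signs when the
  multispectral maxima are near zero.
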