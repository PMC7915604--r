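# forestsep

Band-by-band pairwise spectral separability analysis for forest-type
discrimination, built for comparing a hyperspectral imaging spectrometer
(PRISMA-like: 239 bands, 400–2500 nm, 30 m) against a multispectral
benchmark (Sentinel-2-like MSI: 10 land-monitoring bands at 30 m).

It is aimed at remote-sensing and forest-ecology analysts who want to know,
*before* training any classifier, in which wavelengths two forest types
(e.g. CLC third level 311 broadleaf vs 312 coniferous, or fourth-level types
such as 3112 deciduous broadleaf vs 3121 Mediterranean coniferous) are
statistically distinguishable, and how much a hyperspectral sensor buys over
a multispectral one.

## What it computes

For each class pair, band and sensor, four Gaussian separability criteria
from the per-class sample mean μ and standard deviation σ:

* **M-statistic**: `M = |μ_a − μ_b| / (σ_a + σ_b)`
* **Bhattacharyya distance**:
  `B = ⅛ (μ_a−μ_b)ᵀ S⁻¹ (μ_a−μ_b) + ½ ln(|S| / √(|Σ_a||Σ_b|))`,
  `S = (Σ_a+Σ_b)/2`
* **Jeffries–Matusita distance**: `JM = 2(1 − e^(−B))` (a √2-bounded
  convention is available behind a flag)
* **Transformed divergence**: `TD = 2(1 − e^(−D/8))` with the symmetric
  divergence `D`

plus, per pair: the best band per criterion (max over bands, lowest-
wavelength tie-break), the best wavelength by the mean of the four
[0,1]-normalized criteria, and the cross-sensor percentage increment
`I = 100 (Max_hyper − Max_multi) / Max_multi`.

A synthetic-scene module generates labeled two-sensor views of one field
with known per-class Gaussian statistics (contrast injected in stated
wavelength windows), so the entire pipeline is testable offline; ENVI-dialect
raster and GeoJSON polygon I/O let you run the same pipeline on your own
co-registered cubes and reference polygons.

## Worked example

Simulate study area 2 (five forest types, 1024 px each), observe it with
both sensors, and run the fourth-level analysis:

```r
library(forestsep)
bundle <- run_analysis(run_config(area = 2, level = "fourth", seed = 7))

head(bundle$increments[, c("pair", "metric", "max_hyper", "max_multi",
                           "wavelength_hyper", "increment_percent")], 8)
#>        pair metric max_hyper max_multi wavelength_hyper increment_percent
#> 1 3111_3112      B      3.27   6.44469              710            -49.32
#> 2 3111_3112     JM      1.92   1.99682              710             -3.66
#> 3 3111_3112      M      2.56   3.59044              710            -28.81
#> 4 3111_3112     TD      1.92   1.99684              710             -3.66
#> 5 3111_3115      B      4.57   0.00191              419         239381.97
#> 6 3111_3115     JM      1.98   0.00381              419          51789.06
#> 7 3111_3115      M      3.02   0.03513              419           8507.05
#> 8 3111_3115     TD      1.98   0.00383              419          51591.98

bundle$hyper$best_wavelengths
#>         pair class_a class_b wavelength_nm band_index mean_normalized
#> 1  3111_3112    3111    3112           710         34           0.901
#> 2  3111_3115    3111    3115           419          3           0.930
#> 3  3111_3121    3111    3121          1394        109           0.932
#> 4  3111_3122    3111    3122          1833        157           0.945
#> ...
```

Reading the output: pair 3111–3112 differs only in the red edge
(700–745 nm), which the multispectral sensor senses with bands b5/b6 — its
band averaging even reduces noise, so it *wins* there (negative increments).
Pair 3111–3115 differs only in the blue 405–445 nm window, below the
multispectral b2 band's reach, so the multispectral maxima sit at the noise
floor and the hyperspectral increments are enormous. The best-wavelength
matrix localizes every pair's optimum inside its planted contrast window
(red edge 710, blue 419, NIR plateau 1394, SWIR 1833 nm).

The same analysis runs from files
(`run_config(area = NULL, hyper = ..., multi = ..., regions = ...)`), or
from the shell:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "forestsep", package = "forestsep"))')" \
    simulate --area 1 --seed 5 --out sim1
Rscript "$(Rscript -e 'cat(system.file("cli", "forestsep", package = "forestsep"))')" \
    run --hyper sim1/hyper.dat --multi sim1/multi.dat \
    --regions sim1/regions.geojson --level third --out run1
```

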