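# spectrofibro

Quantify and characterize liver fibrosis from FTIR hyperspectral images of
paraffin-embedded cirrhotic tissue.

Cirrhotic liver is organized as regeneration nodules (glycogen-rich,
regrowing hepatocytes) separated by collagen-rich fibrous septa. FTIR
imaging records a mid-infrared absorbance spectrum at every pixel, so both
the *amount* of fibrous tissue and its *molecular quality* (collagen
maturation and crosslinking, visible in the amide III region) can be read
out label-free. This package is for spectroscopists and digital-pathology
researchers who need that analysis as reproducible code rather than
one-off scripts.

## What it implements

* **EMSC digital dewaxing** — per pixel, ordinary least squares of
  `s = a·m + P·b + T·c + H·d + e`, where `m` is a unit-mean tissue
  reference estimated from the image (two passes, orthogonalized against
  the paraffin subspace), `P` holds the mean pure-paraffin spectrum plus
  principal components of its variability, `T` is a polynomial baseline,
  and `H` an optional tissue-heterogeneity subspace that is fitted but
  *retained* by the correction `(s − P·b − T·c)/a`. An outlier rule on the
  relative scale `a/median(a)` and the residual RMSE drops unmodellable
  pixels.
* **k-means segmentation** (seeded Lloyd with k-means++ or random-spectra
  initialization, best-of-10 restarts) of corrected images in the
  900–1800 cm⁻¹ fingerprint region; classes annotated fibrosis/nodule by
  template correlation; the fibrosis class share gives the fibrosis-area
  percentage.
* **Common k-means** across many fibrosis-focused images (1040–1425 cm⁻¹,
  the collagen window that avoids the paraffin bands) with one shared
  centroid set, Ward dendrogram of the centroids, Savitzky–Golay
  second-derivative band tables with built-in assignments, and the
  per-group fibrosis sub-cluster proportion table.
* **Trichrome DIA** — Beer–Lambert color deconvolution
  (`OD = −log10((I+1)/I₀)`, 3×3 stain-matrix inversion) of
  Masson's-trichrome scans; collagen/tissue area ratio as the reference
  fibrosis percentage.
* **Statistics** — Pearson r with exact-t p-values (`stats::cor.test`),
  explicit (never automatic) outlier exclusion, per-group means/SDs.
* **Synthetic phantoms** — paired hyperspectral cube + pure-paraffin cube
  + trichrome rendering with exact ground truth (nodules, ribbon-like
  septa with two collagen sub-variants, paraffin, baselines, scatter,
  noise), used by the tests and the acceptance script.

## Worked example

```r
library(spectrofibro)

# a synthetic two-group study: 10 samples with known fibrosis fractions
pm  <- phantom_manifest(n_per_group = 5, seed = 11)
rep <- run_whole_sample(pm$manifest, k = 2:5, seed = 0)
rep$comparison$correlations
#> # A tibble: 4 × 4
#>       k     r     p     n
#>   <int> <dbl> <dbl> <int>
#> 1     2     1     0    10
#> 2     3     1     0    10
#> 3     4     1     0    10
#> 4     5     1     0    10

head(rep$areas, 3)
#> # A tibble: 3 × 7
#>   sample_id        group         dia_percent spectral_k2 spectral_k3 spectral_k4 spectral_k5
#>   <chr>            <chr>               <dbl>       <dbl>       <dbl>       <dbl>       <dbl>
#> 1 uncomplicated_01 uncomplicated        8.04        8.04        8.04        8.04        8.04
#> 2 uncomplicated_02 uncomplicated       14.0        14.0        14.0        14.0        14.0
#> 3 uncomplicated_03 uncomplicated       20.0        20.0        20.0        20.0        20.0
```

Each row is one sample: `dia_percent` is the trichrome color-deconvolution
estimate and `spectral_k<k>` the k-means estimate at that class count; on
noise-controlled phantoms the two methods agree with the planted truth to
well under a percentage point, so their correlation is ~1 (on real tissue
the paired estimates track each other but not perfectly).

The fibrosis-focused analysis pools many small high-resolution regions
into one common clustering and compares the two collagen sub-signatures
between groups:

```r
pr <- phantom_regions(n_per_group = 6, seed = 21)
fr <- run_fibrosis_focus(pr$manifest, k = 4, seed = 0)
fr$proportions
#> # A tibble: 3 × 3
#>   class_id uncomplicated   hcc
#>      <int>         <dbl> <dbl>
#> 1        0          30.0 79.9
#> 2        2          35.8 10.4
#> 3        3          34.3  9.65
fr$dendrogram
#> <centroid_dendrogram> ward linkage; root split: {0,2,3} vs {1}
```

Class 0 is the advanced-collagen signature: its share of the fibrosis pool
rises from 30% to 80% between the groups (the generator planted 30% vs
80%), and the dendrogram's root split separates the nodule-like centroid
(class 1) from the three fibrosis-like centroids.

## Layout

* `R/` — implementation (I/O, phantom generator, EMSC, clustering, bands,
  DIA, statistics, pipelines, tidiers and autoplot methods)
* `tests/testthat/` — unit, property and end-to-end acceptance tests
* `vignettes/spectral-histopathology.Rmd` — the models, their assumptions,
  parameter defaults and limitations
* `inst/extdata/band_assignments.csv` — the infrared band assignment table
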