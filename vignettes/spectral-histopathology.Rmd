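---
title: "FTIR spectral histopathology of hepatic fibrosis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FTIR spectral histopathology of hepatic fibrosis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(spectrofibro)
```

## The problem

Cirrhosis reorganizes the liver into regeneration nodules — regrowing,
often glycogen-rich hepatocytes — separated by collagen-rich fibrous
septa. Both the *amount* of fibrous tissue and its *molecular quality*
(collagen maturation, crosslinking) carry prognostic information. FTIR
hyperspectral imaging measures an absorbance spectrum at every pixel of a
tissue section, so the fibrous compartment can be segmented and
characterized label-free. `spectrofibro` implements the complete analysis
chain for formalin-fixed, paraffin-embedded (FFPE) sections:

1. **EMSC digital dewaxing** — removing the paraffin contribution, the
   baseline, and the multiplicative scatter scale from every pixel
   spectrum;
2. **k-means segmentation** of the corrected image into spectral classes,
   annotated as fibrosis or nodule, giving a fibrosis-area percentage;
3. **common k-means** across many fibrosis-focused images with shared
   class identities, plus hierarchical clustering and second-derivative
   band analysis of the class centroids;
4. **trichrome digital image analysis (DIA)** — color deconvolution of
   the adjacent Masson's-trichrome section as the reference fibrosis
   measurement;
5. **statistics** — Pearson correlation between the two estimates, group
   summaries, and the fibrosis sub-cluster proportion table.

A synthetic phantom generator supplies paired inputs with exact ground
truth, which is how the package tests itself end to end.

## The EMSC model

Each pixel spectrum $s$ (absorbance vs wavenumber $\nu$, over the chosen
analysis window) is modelled by ordinary least squares as

$$ s \;=\; a\,m \;+\; P\,b \;+\; T\,c \;+\; H\,d \;+\; e $$

* $m$ — the tissue **reference spectrum**, normalized to unit mean over
  the window; $a$ is the pixel's multiplicative scale (scatter and
  sampling thickness).
* $P$ — the **paraffin interference** block: the mean spectrum of the
  pure-paraffin reference cube plus the leading principal components of
  its pixel-to-pixel variation (default $J = 10$ columns). The PCs are
  computed from baseline-stripped paraffin spectra so they carry
  paraffin-like structure only; the mean column keeps the full measured
  shape.
* $T$ — polynomial **baseline** columns, degree $0..D$ on the axis
  rescaled to $[-1, 1]$ (default $D = 4$).
* $H$ — an optional **tissue-heterogeneity subspace** (default $K = 5$
  principal directions of the provisionally corrected spectra, orthogonal
  to $[m\,|\,P\,|\,T]$).

The corrected spectrum is $(s - P b - T c)/a$: paraffin and baseline are
subtracted, the scale is divided out (this is the normalization — no
separate vector normalization is applied), and the tissue-subspace
contribution $H d$ is deliberately **retained**, since it is biology, not
nuisance. Without $H$, the residual of every pixel contains its class's
deviation from the single reference, and the residual-based outlier rule
would flag whichever tissue class is rare; with $H$, the residual is
essentially noise and the rule responds to genuinely unmodellable spectra.

### Reference estimation

No external reference exists, so $m$ is estimated from the image itself in
two passes: the mean valid spectrum, then the mean of the corrected
spectra. A mean computed from a contaminated image necessarily contains
paraffin, and any paraffin left in $m$ would be *retained* by the
correction (as part of $a\,m$). The estimate is therefore orthogonalized
against the paraffin subspace at both passes, with one refinement: the
projection **coefficients** are computed against the baseline-stripped
paraffin columns (which are orthogonal to the polynomial span, so the
broad tissue envelope cannot bias them), while the **subtraction** uses
the full paraffin shape. Estimating against the full shape would remove a
large part of the tissue envelope along with the paraffin; estimating
against the stripped shape but subtracting it too would leave the smooth
component of the contamination behind.

### Outlier rule

A pixel is flagged when its relative scale $a/\mathrm{median}(a)$ leaves
`a_bounds` (default $[0.2, 5]$) or its residual RMSE exceeds
$\mathrm{median} + \kappa\,\mathrm{MAD}$ (default $\kappa = 5$). The scale
test is applied to the *relative* coefficient because the correction
itself is scale-equivariant: multiplying every input spectrum by a
constant scales $a$ and leaves the corrected output unchanged, and the
outlier decision must be invariant under the same transformation.
Flagged pixels are removed from the mask of the corrected image.

### Common correction for pooled analyses

When corrected images are pooled (common k-means), every image must be
corrected against the *same* model: `dewax_common()` builds one paraffin
basis, one reference and one tissue subspace from the pooled pixels and
applies them to each image. Independently estimated references would
leave each image in its own corrected space, and pooled clustering would
segment images rather than tissue — we observed exactly this failure mode
when prototyping with per-image references.

## Clustering

`fit_kmeans()` is Lloyd's algorithm with Euclidean distance: k-means++
initialization (a `"random_spectra"` mode reproduces the classical
random-centroid start), best of `n_init = 10` seeded restarts by inertia,
convergence at relative inertia change below $10^{-6}$ or 300 iterations,
ties broken toward the lowest class id, and empty clusters reseeded to
the point farthest from its centroid. After the fit, classes are
relabeled by descending size and given fixed pseudo-colors, so ids are
stable across seeds and pooling orders. `fit_common_kmeans()` fits one
centroid set on the pooled spectra of many images and labels each image
against it, making class identities (and colors) comparable across
samples.

Class annotation correlates each centroid with named template spectra
(collagen mean for fibrosis, glycogen for nodule) and takes the best
match; a manual mapping always wins. Corrected spectra live in the
geometry of the EMSC model — their baseline- and interference-span
components are removed, and their component along the reference is
absorbed into the scale coefficient — so raw templates cannot be compared
to them directly. When the correction basis is available (the pipelines
pass it), each template is mapped through the very same correction a
pixel would receive before correlating; without a basis, both sides are
detrended by a common degree-4 polynomial so the comparison rests on band
structure. The two analysis windows follow standard practice: the
900–1800 cm⁻¹ fingerprint region for whole-sample maps, and
1040–1425 cm⁻¹ — which contains the main collagen bands and avoids the
strong paraffin bands — for fibrosis-focused maps.

## Band analysis

Centroid spectra are differentiated twice with a Savitzky–Golay filter
(default window 9 points, polynomial order 3, scaled by the axis spacing
so units are AU/cm⁻²). Absorption maxima become second-derivative minima;
`pick_bands()` reports minima deeper than a prominence floor and labels
them against a built-in assignment table (glycogen 1022/1045/1080/1155;
collagen 1174, amide III 1202–1304, CH₂ 1340, CH₃ 1404; paraffin
1378/1462; amide I/II), matching positions within ±6 cm⁻¹ to absorb the
range notation common in assignment tables. `cluster_centroids()` builds a
Ward (or average/complete) dendrogram over the centroids with a two-group
cut at the root — on cirrhotic material this separates glycogen-like from
collagen-like signatures.

## Trichrome DIA

Masson's trichrome renders collagen green, cytoplasm pink, nuclei black.
`deconvolve_stains()` converts each pixel to optical density
($OD_c = -\log_{10}((I_c + 1)/I_{0,c})$; the +1 guards 8-bit zeros) and
inverts the 3×3 Beer–Lambert stain matrix (Ruifrok–Johnston convention;
the default Masson vectors are package constants and fully overridable).
Segmentation first removes the near-white background (total OD below
0.15), then takes as collagen those tissue pixels where the collagen
concentration dominates the other channels and exceeds an Otsu threshold
computed within tissue. The fibrosis percentage is the collagen/tissue
area ratio — background is excluded from the denominator, matching the
binarization step that precedes the ratio.

## Statistics

`pearson_corr()` delegates to `stats::cor.test` (exact t transformation,
appropriate at n ≤ 10); exclusions are an explicit, logged, caller-supplied
id list, never automatic, so outlier handling stays auditable.
`pearson_p_value(r, n)` computes the two-sided p implied by a reported
(r, n) pair — useful for consistency checks of published tables. Group
comparison is descriptive only (means and SDs): with five samples per
group a significance test would be inappropriate, and none is offered.
`class_proportions()` pools fibrosis-class pixels per group and reports
each class's share of the pool; columns always sum to 100.

## The phantom generator

`synth_label_map()` emulates cirrhotic morphology: a smoothed Gaussian
random field is thresholded at its median contour, and the level-set band
around that contour — whose half-width is set by quantile so the achieved
fibrosis fraction lands within ±1 point of the target — forms a connected,
ribbon-like septa network separating blob-like nodules; a second field
splits septa into the two collagen sub-variants, and a third carves the
tissue outline from the background. `synth_cube()` renders each tissue
pixel as `scatter * (endmember + baseline + paraffin_amp * paraffin) +
noise` and produces the paired pure-paraffin cube. `synth_trichrome()`
renders the truth through the same Beer–Lambert stain model the DIA
module inverts.

Default endmembers: glycogen bands at 1022/1045/1080/1155 cm⁻¹ for
nodules; collagen bands at 1064, 1084, 1174, 1202, 1230, 1250, 1278,
1304, 1340 and 1404 cm⁻¹ for septa (sub-variant `collagen_b` scales the
1202/1230/1278 amide III amplitudes by 1.3 and shifts 1250→1244 and
1340→1342 cm⁻¹, emulating crosslinking-related profile changes); both
share the amide I/II envelope and a broad fingerprint absorption
(σ = 300 cm⁻¹) that keeps mean absorbance at a realistic ~0.4 AU — real
tissue fingerprints never drop to zero absorbance. Band widths are
σ = 8 cm⁻¹; paraffin contributes CH₃/CH₂ bands at 1378/1462 cm⁻¹. The
default axis spacing is 2 cm⁻¹ (the digitized grid of a 4 cm⁻¹
optical-resolution measurement). Amplitude ratios are free parameters of
the phantom, not literature claims.

What the phantom deliberately does **not** emulate: partial-volume mixing
at class boundaries (classes are hard), resonant Mie scattering,
within-class biochemical gradients, and realistic nuclear morphology.
Passing tests therefore demonstrate correctness of the *algorithms* under
the stated generative model, not clinical performance on real sections.

## Numerical choices and problem sizes

* Cube values are stored as 8-byte floats in every format (HDF5 canonical;
  ENVI BSQ and long CSV for interoperability), so write→read round-trips
  are exact; descending-axis files are normalized to ascending on read.
* Crop windows are closed intervals on both ends.
* PCA loadings get a deterministic sign (largest-magnitude element
  positive); k-means tie-breaks go to the lowest class id.
* All randomness flows from integer seeds; per-stage sub-seeds are derived
  deterministically, so every pipeline is reproducible bit-for-bit.
* Tests and the acceptance script use phantoms between 24×24 and 64×64
  pixels with the default 451-band axis — large enough for stable
  statistics, small enough to run comfortably on a laptop.

## Worked example

```{r example, eval = FALSE}
pm <- phantom_manifest(n_per_group = 5, seed = 1)
rep <- run_whole_sample(pm$manifest, k = 2:5, seed = 0)
rep$comparison$correlations   # r, p, n per k
autoplot(rep)                 # DIA vs spectral scatter, one panel per k

pr <- phantom_regions(n_per_group = 6, seed = 1)
fr <- run_fibrosis_focus(pr$manifest, k = 4, seed = 0)
fr$proportions                # fibrosis sub-cluster shares per group
fr$dendrogram                 # root split: nodule-like vs fibrosis-like
```

## Known limitations

* The EMSC reference is estimated from the image; on tissue whose *mean*
  composition is paraffin-like the anti-paraffin orthogonalization could
  remove genuine signal.
* The collagen sub-variants differ by a few cm⁻¹ shifts; distinguishing
  them reliably requires axis spacing ≤ 2 cm⁻¹.
* Stain vectors are fixed constants; strongly off-calibration scans
  require user-supplied vectors (no blind stain estimation is attempted).
* Region selection for the fibrosis-focused analysis is manifest-driven;
  no automatic region proposal is implemented.
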