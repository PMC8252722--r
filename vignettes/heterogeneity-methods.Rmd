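---
title: "Methods: entropy-based heterogeneity mapping with entrast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: entropy-based heterogeneity mapping with entrast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
library(entrast)
```

## The model

`entrast` maps spectral heterogeneity by evaluating a diversity index on
the multiset of pixel values inside a square moving window centred on
every raster cell. Within one window, the distinct values
$v_1 < \dots < v_N$ occur with relative abundances $p_i = n_i / n$,
where $n$ is the number of valid observations. The indices are then

* Shannon entropy $H = -\sum_i p_i \ln p_i$,
* Rényi generalized entropy
  $H_\alpha = \frac{1}{1-\alpha}\ln \sum_i p_i^\alpha$,
* Hill numbers $N_q = \exp(H_q)$, the "effective number of classes",
* Simpson dominance $D = \sum_i p_i^2$,
* Rao's quadratic entropy $Q = \sum_i \sum_j d_{ij}\, p_i p_j$ with
  $d_{ij}$ a pairwise distance between values.

All entropies are in nats (natural log; no base option). The Rényi
family interpolates the others: $H_0 = \ln N$ (log-richness),
$H_1 = H$ (the l'Hôpital limit, which we verify numerically in the test
suite rather than symbolically), and $H_2 = \ln(1/D)$. $H_\alpha$ is
non-increasing in $\alpha$, which is also a per-cell property of the map
profiles.

The abundance-only indices are blind to how far apart values are: nine
equally frequent values score $H=\ln 9$ whether they span 1–9 or 1–109.
Rao's $Q$ — the expected distance between two pixels drawn with
replacement — is the package's distance-aware complement, and the reason
8-bit inputs are recommended (float inputs make nearly every value
unique, so abundance indices saturate and reflect data binning rather
than ecology).

### Notational choices

The literature in this area overloads the symbol $N$: it appears both as
the number of pixels (in the $1/N^2$ pixel-pair reading of Rao's $Q$)
and as the number of distinct values (richness, in $H_0 = \ln N$).
`entrast` keeps the two explicit: `n_obs` is the observation count and
`richness()` the distinct-value count of an `abundance_distribution`.
Likewise, the index summations run over *distinct values*, not pixels;
for Rao's $Q$ the distinct-value form
$\sum_{ij} d_{ij} p_i p_j$ is algebraically identical to averaging
$d$ over all $n^2$ ordered pixel pairs, and the test suite enforces this
equivalence against brute-force enumeration instead of assuming it.

### Numerical choices

* **$\alpha \to 1$ routing.** $1/(1-\alpha)$ is catastrophically
  ill-conditioned near 1, so $|\alpha - 1| \le 10^{-9}$ is routed to the
  exact Shannon branch (and $q$ likewise for Hill numbers). The
  numerical-limit test checks $|H_{1\pm10^{-6}} - H| < 10^{-4}$ on
  random distributions.
* **Domain.** $\alpha, q \ge 0$ only; negative orders are rejected.
* **Distances.** Scalar values use absolute difference ("relative
  numerical distance" between reflectance classes); multi-layer tuples
  use Euclidean (default) or Manhattan distance. Requesting a scalar
  metric on tuples, or vice versa, is an error rather than a silent
  coercion.
* **Precision.** Everything accumulates in double precision; outputs are
  double regardless of input type. Tolerances in the tests (1e-12 for
  identities, 1e-10 for oracle equivalence) assume doubles.

## The moving-window engine

The window side $l$ must be odd so a central entry exists; the window is
centred on each focal cell in turn and the index value is written at
that position, for every cell of the grid. Design points where the
source description left room:

* **Edges are clipped.** Out-of-bounds positions are simply absent from
  the sample — no padding, no cropping of the output — so edge cells are
  computed from smaller windows and the output has exactly the input
  shape.
* **Nodata.** Invalid cells never contribute to any window. If the
  *focal* cell itself is invalid the output is nodata even when
  neighbours are valid: an index "for" a nonexistent observation is
  undefined. An all-invalid window is likewise nodata.
* **Determinism.** The traversal is a plain row-major double loop with
  no stateful shortcuts, so results are bit-identical across runs and
  independent of traversal order; the CLI additionally round-trips
  through a fixed-format text writer so whole files are byte-identical.
* **Indexing.** 1-based row/column indices, the R convention.
* **Profiles.** `renyi_profile()` extracts each window and builds its
  abundance distribution once, then evaluates all $\alpha$ values from
  it — a performance contract only; the maps are identical to per-α
  runs, which the tests assert.
* **Stacks.** Only Rao's $Q$ consumes multi-layer stacks (pixels become
  value tuples; a pixel is valid only if valid in every layer). The
  abundance-only indices are single-layer by construction.

## Pre-processing

`compute_ndvi()` implements $(NIR - red)/(NIR + red) \in [-1, 1]$, with
a zero denominator yielding nodata (no reflectance information, rather
than a fabricated 0). `rescale_to_8bit()` maps a range linearly onto
0–255 with half-away-from-zero rounding (chosen for cross-platform
bit-exactness; `round()`'s banker's rounding is not) and clipping. The
original workflow does not state its stretch, so both options are
explicit rather than one being inferred: `"observed"` (min–max of valid
cells, the common remote-sensing default; a constant input maps to 0)
and `"fixed"` (e.g. $(-1, 1)$ for NDVI maps comparable across scenes).

## File format

The environment this package targets has no GDAL-backed R package, so
raster I/O uses the plain-text ESRI ASCII grid format: single band per
file, `NODATA_value` sentinel honoured on read and written on output,
`xllcorner`/`yllcorner`/`cellsize` georeference carried through every
operation untouched (indices are geometry-agnostic). Multi-band input is
a vector of single-band files; `band=` selects one, `band=NULL` stacks
them. GeoTIFF support would be an additive change behind the same
`read_raster()`/`write_raster()` surface.

## What the synthetic generators emulate — and what they do not

The generators stand in for a satellite scene so that every index and
the full NDVI pipeline can be exercised without downloads, with
bit-reproducible output (Mersenne-Twister, locally seeded and restored,
so generation never perturbs the caller's RNG stream):

* `constant`, `checkerboard`, `gradient` — degenerate structures with
  closed-form window compositions. A unit checkerboard of 0/255 makes
  every interior 3×3 window a {5,4} split, so the Shannon map must be
  exactly $-(5/9)\ln(5/9) - (4/9)\ln(4/9)$ and the Rao map exactly
  $255 \cdot 40/81$; a unit-step column gradient makes interior windows
  translates of each other, so the Rao map is interior-constant.
* `categorical` — i.i.d. uniform classes; used for monotonicity and
  oracle sweeps.
* `fractal` — midpoint-displacement (diamond-square) surface with
  roughness $h \in (0,1)$, rescaled to 0–255. It is a
  heterogeneity-rich fixture with spatial autocorrelation, *not* a
  claim of ecological realism.
* `generate_band_pair()` — a two-region landscape: vegetation pixels
  with NIR (0.55 ± 0.04) well above red (0.08 ± 0.01), bare pixels with
  NIR exactly equal to red (one brightness draw ≈ 0.25 ± 0.03 used for
  both bands, so bare NDVI is exactly 0). The default split layout
  yields a sharp vertical ecotone. Noise levels were chosen once as
  plausible top-of-atmosphere reflectances with modest within-class
  variation; they are not tuned to any dataset.

A green test on these fixtures establishes that the *mechanics* —
formulas, window traversal, nodata rules, the qualitative
ecotone-maximum behaviour of Rao's $Q$ — are correct. It does not
establish anything about a real Sentinel-2 scene: real imagery has
sensor noise, mixed pixels, autocorrelated class mosaics and atmospheric
effects that none of these generators model, which is why the real-scene
maps of the original application are out of scope here.

## Known limitations

* Square windows only; no area-based (whole-extent) mode, no
  wrap-around edges, no parallel/tiled execution (the determinism
  contract is kept instead).
* ESRI ASCII grid is the only on-disk format; CRS is limited to what
  that format carries.
* No abundance-free (phylogenetic/functional) diversity, no entropy
  bases other than $e$, no Pielou/Berger–Parker/parametric-Rao
  variants.
* The CLI's configuration comes from flags and defaults only; there is
  no config-file layer.
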