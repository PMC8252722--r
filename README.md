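# entrast

Information-theoretic heterogeneity maps from raster grids.

`entrast` is for ecologists and remote-sensing analysts who want to map
**ecosystem heterogeneity** from imagery: the degree of non-uniformity in
land cover, proxied by the variability of pixel values (typically an
8-bit-rescaled NDVI layer) inside a moving window. It provides the
classical abundance-based diversity indices and, crucially, Rao's
quadratic entropy, which also accounts for *how far apart* pixel values
are — the property that lets it separate a gently varying forest canopy
from a sharp water/vegetation ecotone that plain Shannon entropy scores
identically.

## The indices

For the distinct values in a window with relative abundances
*p₁ … p_N* (all logs natural):

| index | formula | sensitive to |
|---|---|---|
| Shannon *H* | −Σ pᵢ ln pᵢ | abundances only |
| Rényi *H&alpha;* | ln(Σ pᵢ^α) / (1−α) | abundances, tunable by α |
| Hill number *N_q* | exp(*H_q*) | same, as an effective class count |
| Simpson dominance *D* | Σ pᵢ² | abundances (H₂ = ln 1/D) |
| Rao's *Q* | Σᵢ Σⱼ d(vᵢ,vⱼ) pᵢ pⱼ | abundances **and** spectral distance |

Special cases: *H₀* = ln(richness); *H₁* is the Shannon limit (routed
analytically); *H₂* = ln(1/D); *H&alpha;* is non-increasing in α. Rao's
*Q* is the expected distance between two pixels drawn with replacement,
and extends to multi-layer stacks by treating each pixel as a tuple
across layers (Euclidean or Manhattan distance).

Each index is evaluated under a square moving window of odd side *l*
centred on every cell; edge windows are clipped (out-of-bounds and
nodata cells simply do not contribute) and the result is written at the
focal position, so the output map has exactly the input shape.

## Worked example

The motivating contrast: two arrays of nine distinct values,
`A = (1,…,9)` close together and `B = (1,102,…,109)` spread apart.

```r
library(entrast)
A <- relative_abundances(1:9)
B <- relative_abundances(c(1, 102:109))
sprintf("Shannon H(A) = %.6f   H(B) = %.6f", shannon(A), shannon(B))
#> "Shannon H(A) = 2.197225   H(B) = 2.197225"
sprintf("Rao Q(A) = %.6f   Q(B) = %.6f", rao_q(A), rao_q(B))
#> "Rao Q(A) = 2.962963   Q(B) = 22.716049"
```

Both arrays hit the Shannon maximum ln 9 = 2.197225 — nine equally
abundant classes look identical to an abundance-only index — while Rao's
*Q* (the expected |difference| between two random pixels) is 7.7× larger
for the spread-out array.

The full pipeline on a synthetic half-vegetation / half-bare scene:

```r
bp  <- generate_band_pair(48, 48, veg_fraction = 0.5, seed = 8)
nd  <- compute_ndvi(bp$red, bp$nir)                  # (NIR−red)/(NIR+red)
b8  <- rescale_to_8bit(nd, "fixed", range = c(-1, 1))  # 256 classes
rao <- apply_moving_window(b8, 9, "rao")               # 9x9 window
prof <- renyi_profile(b8, 9, c(0, 1, 2))
sprintf("Rao mean at ecotone cols 21-28: %.2f   elsewhere: %.2f",
        mean(rao$data[, 21:28]), mean(rao$data[, -(17:32)]))
#> "Rao mean at ecotone cols 21-28: 36.76   elsewhere: 2.38"
```

The Rao map peaks on the windows straddling the vegetation/bare
interface (the ecotone) and stays near zero inside either homogeneous
patch; the Rényi maps (means 1.662, 1.431, 1.293 for α = 0, 1, 2 here)
decrease with α cell-by-cell.

## Command line

```sh
ENTRAST=$(Rscript -e 'cat(system.file("exec/entrast", package="entrast"))')
Rscript $ENTRAST fixture --kind categorical --rows 64 --cols 64 --seed 1 \
        --output scene.asc
Rscript $ENTRAST index --input scene.asc --index renyi --alpha 0,1,2 \
        --window 9 --output renyi.asc
Rscript $ENTRAST ndvi --red red.asc --nir nir.asc --rescale-8bit \
        --range=-1,1 --output ndvi.asc
```

Every run writes a `<output>.log` with the configuration, package
version and input checksums; identical configurations produce
bit-identical outputs.

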