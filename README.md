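# placodeQuant

Quantitative image analysis of apical constriction during epithelial tube
invagination, modelled on the *Drosophila* embryonic salivary-gland
placode. During invagination, the cells around the forming pit shrink
their apical surface, pulled by a pulsatile apicomedial actomyosin
network that is distinct from junction-associated myosin, while a
supracellular actomyosin cable smooths the tissue outline. placodeQuant
turns the measurements behind that picture into a reproducible R
pipeline for developmental biologists working with two-channel
(junctional marker + myosin reporter) micrographs or with per-cell
tables:

- **Segmentation and staging** — seeded-watershed segmentation of apical
  cell outlines along the junctional (E-Cadherin) signal; per-cell apical
  areas, centroids and polygons; invagination staging from
  internalization depth (deep invagination > 2 µm, beginning of
  invagination ≤ 2 µm) and from spatial clustering of constricted cells.
- **Area statistics** — frequency and cumulative distributions in 4 µm²
  bins, Mann–Whitney U and Kolmogorov–Smirnov comparisons, median-scaling
  normalization (`median(reference)/median(target)`), per-cell area heat
  maps.
- **Pit-relative dispersion** — A/P and D/V standard deviations of the
  lower-area-quantile cells around the invagination pit, plus a
  permutation test (mean pairwise distance under random relabelling) for
  whether constricted cells cluster in space.
- **Myosin intensity partitioning** — junctional band versus apicomedial
  interior integrated densities after background correction, their ratio,
  0–100 intensity rescaling, and the Pearson correlation of apical area
  with mean myosin intensity.
- **Boundary circularity** — sub-pixel tracing of the placode outline and
  its one-cell-layer outer/inner shifts, with the isoperimetric
  circularity `C = 4π·area/perimeter²` (1 for a perfect circle) as a
  tension/smoothness proxy, and unpaired t-tests across placodes.
- **Pulsation** — prominence-based peak detection on apicomedial
  intensity traces and pooled inter-pulse interval statistics
  (mean ± SD, cell and pulse counts).
- **Synthetic ground truth** — a placode generator (capacity-adjusted
  power-diagram tessellation, rendered channels with PSF blur and Poisson
  noise, pulsatile traces with truncated-normal inter-pulse intervals)
  that provides exact per-cell truth for every measurement above.

## Worked example

```r
library(placodeQuant)

cfg <- sceneConfig(nCells = 150, fieldMode = "clustered", seed = 1)
sc  <- renderChannels(generateScene(cfg))

seg <- segmentCells(junctionImage(sc), labelImage(sc) > 0,
                    pixelSize = cfg@pixelSize)
nrow(seg$cells)
#> [1] 150

ct  <- cellTable(sc)
sub <- lowerQuantileCells(ct, 0.3)
dispersionStats(pitRelativeCoordinates(sub, pitCenter(sc)))
#>    sd_AP    sd_DV
#> 6.916609 8.821072
clusteringPermutationTest(ct, q = 0.3, nPerm = 499)
#> [1] 0.002

traces <- generatePulseTraces(pulsationConfig(), nCells = 14, seed = 1)
st <- intervalStatistics(traces)
unlist(st[c("mean", "sd", "nCells", "nIntervals")])
#>      mean        sd    nCells nIntervals
#> 128.20225  41.86167  14.00000 178.00000
```

The segmented cell count matches the generated placode exactly; the
lower-30% (most constricted) cells scatter only ~7–9 µm around the pit
along either axis (versus ~15 µm for a dispersed field), and the
permutation test calls their clustering highly significant, as expected
for a clustered constriction field. The pooled inter-pulse interval
(mean ≈ 128 s, SD ≈ 42 s over 178 pulses from 14 cells) recovers the
generating pulsation statistics (131.7 ± 42.8 s) within sampling error.

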