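---
title: "Quantifying apical constriction in epithelial placodes"
author: "placodeQuant authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying apical constriction in epithelial placodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(placodeQuant)
```

## Scope and model

During epithelial tube formation by budding — the *Drosophila* embryonic
salivary gland is the model here — a flat placode of 100–200 cells
internalizes through an invagination pit. The cells nearest the pit reduce
their apical surface (apical constriction), driven by a pulsatile
apicomedial actomyosin network that is molecularly distinct from the
junction-associated myosin pool, while a supracellular actomyosin cable
rounds up and smooths the tissue outline. placodeQuant implements the
quantitative measurements this biology calls for:

* per-cell apical areas segmented from a junctional marker (E-Cadherin),
  with staging of invagination progress;
* binned apical-area frequency and cumulative distributions, two-sample
  comparisons (Mann–Whitney U, Kolmogorov–Smirnov) and median-scaling
  normalization;
* pit-relative scatter of the most constricted cells, with axis-wise
  standard deviations and a permutation test for spatial clustering;
* junctional versus apicomedial integrated myosin density per cell, their
  ratio, and the correlation of apical area with mean myosin intensity;
* tissue-boundary circularity `C = 4 * pi * area / perimeter^2` for the
  placode outline and its one-cell-layer shifted variants;
* prominence-based detection of apicomedial intensity pulses and pooled
  inter-pulse interval statistics.

Because suitable public ground-truth imaging data are not available for
this tissue, every operation is
validated against a synthetic placode generator that provides per-cell
ground truth.

## The synthetic placode generator

`generateScene()` tiles a disk with `nCells` polygonal cells using a
capacity-adjusted power diagram with Lloyd relaxation on the pixel raster:
pixels go to the seed minimising `|p - s|^2 - w`, seeds move to their cell
centroids for the first half of the iterations, and the weights `w` grow or
shrink each cell towards its target area throughout (80 iterations, step
0.4 of the area deficit). Exact area control is deliberately not attempted;
realised areas track targets to within a few percent (15% is the declared
contract), and all downstream checks compare measurements against the
*realised* ground truth.

Target areas follow the configured spatial field. In `clustered` mode the
expected area at distance `d` from the pit is
`baseArea * (1 - constrictionDepth * exp(-d^2 / (2 * constrictionSigma^2)))`
— a Gaussian constriction funnel around the pit, as in wild-type placodes.
`random` mode permutes the same target multiset across positions
(constriction without spatial organisation, the *fog*-mutant-like
condition), `uniform` is a flat field, and `expanded` scales the flat field
by `1 + constrictionDepth` (a mutant-like placode whose cells fail to
constrict; the exact factor is a free choice since only relative medians
matter downstream). Targets are rescaled by one common factor so they sum
to the disk area, which keeps the clustered and random multisets identical
and the tessellation feasible.

Default conditions: 150 cells of 20 µm² base area on 0.2 µm pixels,
constriction depth 0.5 over an 8 µm length scale, pit halfway between the
placode centre and its posterior edge. Coordinates are continuous
micrometres; pixel `(i, j)` is centred at `((i - 0.5), (j - 0.5)) *
pixelSize` with x running anterior→posterior and y dorsal→ventral.
`surroundCells > 0` adds an annulus of ordinary epithelial cells around
the placode, with the pixel partition fixed exactly at the placode disk —
this produces the smooth circular placode outline amid irregular
neighbours needed to exercise the boundary-circularity comparison.

`renderChannels()` draws a junctional ridge of width `junctionWidth`
(default 0.4 µm) along every cell interface in both channels, and adds to
the myosin channel a per-cell centred Gaussian apicomedial blob whose
integrated density equals the configured pool (either `medialDensity`
directly or junctional density over `medialRatio`). The blob is kept
`junctionWidth/2 + 3 * psfSigma` away from interfaces so the two pools
remain separable after blurring. Both channels are then blurred with a
Gaussian PSF (default sigma 0.15 µm, a realistic confocal scale), offset
by a background (default 5 a.u.), and Poisson shot noise is applied to the
expected counts — the simplest physically motivated noise model.

What the generator does *not* emulate: curved tissue and projection
artefacts, intensity gradients and bleaching, cell rearrangement and
tracking, segmentation-marker discontinuities, and out-of-plane signal.
Passing recovery tests on these scenes therefore demonstrates correctness
of the measurement pipeline, not robustness to every pathology of real
embryo imaging.

Pulse traces (`generatePulseTraces()`) are baseline plus Gaussian-in-time
bumps (sigma = `pulseWidth/4`) at event times whose gaps are drawn from
`Normal(meanInterval, sdInterval)` truncated by resampling to exceed
`pulseWidth`, so consecutive pulses never merge and peak detection stays
well-posed; each cell starts at an independent uniform phase, making
pulses asynchronous across cells. The defaults encode the reported
salivary-gland statistics — 131.7 s mean, 42.8 s SD, 5 s frames — with a
30 s pulse width, 50 a.u. amplitude over a 10 a.u. baseline and 2 a.u.
Gaussian measurement noise (signal-to-noise 25). Truncation at 30 s
shifts the generating mean by about +1 s and narrows the SD by about 3%;
the property tests compare against the analytic truncated-normal moments.

## Segmentation

Published analyses of this tissue segmented cells interactively in
commercial software; placodeQuant substitutes a deterministic, parameter-light seeded
watershed. The junction image is Gaussian-smoothed (sigma 1 px),
normalised, and thresholded (Otsu within the tissue mask) into junctional
ridges versus interiors; the distance transform of the interiors is
watershed-split (merge tolerance 1 px), and the basins are propagated
across the remaining junction-line pixels so every mask pixel is labelled.
Fragments below `minArea` (default 4 µm², well under any real apical
area) are dissolved into the neighbour sharing the longest border. Labels
are renumbered in raster order, making the whole procedure reproducible
bit for bit.

On the default noisy 150-cell scene this recovers the exact cell count and
a median absolute area error below 1%, far inside the ±5% count and 10%
area contracts.

Internalization depth cannot be inferred from a single projection, so
`classifyStage()` takes depth as an input column (from focal-plane offsets
in real data, ground truth in synthetic data) and applies the staging
thresholds: deep invagination above 2 µm, beginning of invagination for
any internalization up to 2 µm. The boundary between *before
invagination* and *clustered apical constriction* is described qualitatively in
the literature; this package operationalises it as significance of
the clustering permutation test on the lower-30% cells at alpha = 0.05
and flags that choice in its output metadata.

## Area statistics

Histograms use half-open bins `[k*w, (k+1)*w)` anchored at 0 µm² with the
conventional 4 µm² width; percentages use the pooled-cell denominator
(a per-gland denominator is the plausible alternative; the choice is
recorded in the output). The Kolmogorov–Smirnov D is
computed in-package as the maximum empirical-CDF gap — it is part of the
verifiable contract and is property-tested against brute-force evaluation
— while p-values (and the Mann–Whitney U test) are delegated to the
standard library routines. `medianScale()` multiplies every area by
`median(reference)/median(target)`, making the scaled median exactly equal
to the reference median; applying it twice is the identity.

## Spatial dispersion and clustering

Pit-relative coordinates are axis-aligned differences from the pit; the
dispersion measure is the sample (n−1) standard deviation per axis, suited
to the small cell counts of single placodes. The most constricted subset
is the `floor(q*n)` smallest-area cells with ties broken by cell id.
Dispersion SDs alone support only qualitative comparison; this package
adds, as its own contribution, a permutation test whose statistic
is the mean pairwise distance among the constricted cells and whose null
relabels which cells are constricted (add-one-corrected p-value, so p is
never 0). The test is calibrated — p-values are uniform on random-mode
scenes — and has >90% power on clustered-mode scenes at the defaults.

## Myosin intensity partitioning

Where manual workflows draw the junctional/apical regions by hand along
the inner and outer edges of the junctional signal, placodeQuant derives them
from the label image: the junctional band is all cell pixels within
`bandWidth/2` of the nearest interface (so bands shared between neighbours
split at the contour midline — a convention the output records), and the
apicomedial mask is the remainder. The default band width of 0.5 µm
mirrors the manual convention; for synthetic recovery experiments
`matchedBandWidth()` (`junctionWidth + 4 * psfSigma`) is the band that
captures essentially all of the PSF-spread ridge, and with it the
configured junctional:apicomedial ratios 0.5–4 are recovered within a few
percent under full noise. Integrated density subtracts a background level
(default: the mean outside the labelled tissue, overridable) and clips
negative pixels to zero, since integrated density is nonnegative. Because
the automated measurement is deterministic, the manual convention of
averaging three tracings does not apply and a single measurement is used.

## Boundary circularity

Boundaries are traced as sub-pixel marching-squares contours of the label
raster and simplified with a one-pixel tolerance; raw pixel-edge
perimeters would overestimate length badly enough to break the
isoperimetric bound `C <= 1`, while the traced contours respect it within
a 2% rasterisation allowance. "One cell layer" out or in is defined by
edge adjacency on the label graph (corner contact does not count): outer
adds every edge-neighbour of the placode, inner removes the placode's
boundary cells, and inner ⊂ placode ⊂ outer always holds when defined.
When a ventral midline is supplied and the placode reaches it, the contour
is closed by the straight midline chord; the chord is counted in the
perimeter by default (the conventional choice) with a
flag to exclude it. Group comparisons report means ± SEM and unpaired
two-tailed Welch t-tests, and tolerate a missing shifted group (as when
neighbouring epithelia are out of the focal plane).

## Pulse detection

`detectPeaks()` is deterministic: a 5-frame boxcar (25 s at the default sampling) suppresses short-timescale
noise (far shorter than any resolvable pulse, so apexes move at most one
frame), candidates are strict local maxima, topographic prominence is
computed exactly, candidates below `2 * MAD` of the trace are dropped (a
scale-free threshold tied to the noise level), and peaks closer than 30 s
to a taller accepted peak are suppressed. Peak time is the apex sample —
no sub-frame interpolation — which keeps the quantization error bound at
one frame interval for noiseless, well-separated pulses. Interval
statistics pool all inter-peak intervals across cells (pooling across cells is the convention
here, with per-cell means reported alongside). At the default
conditions (60 traces of 30 min, about 800 intervals) the pooled mean
recovers the generating 131.7 s within a few percent and detection
sensitivity and precision both exceed 0.95.

## Numerical choices and problem sizes

* Tessellation: 80 iterations (40 with Lloyd moves), capacity step 0.4,
  assignment restricted to each seed's 24 nearest neighbours after the
  first full scan (boundaries only move between spatial neighbours); the
  final iteration re-runs a full scan. Identical configuration and seed
  give bit-identical scenes.
* Watershed tie-breaks follow the deterministic raster-order flooding of
  the underlying image library; all label orders are raster-normalised.
* Contour simplification uses Ramer–Douglas–Peucker at 0.5 px for cell
  polygons and 1 px for tissue boundaries.
* Degenerate inputs fail loudly: empty masks, constant intensity vectors,
  zero apicomedial pools (flagged, not infinite), single-layer placodes
  without an inner boundary, missing depth columns.
* Monte-Carlo suites (mode discrimination across 100 seed pairs; null
  calibration across 200 seeds) run the generator geometry at 0.4 µm
  pixels, which preserves the spatial statistics while keeping each scene
  around a quarter second; rendered-image tests use the full 0.2 µm
  default.

## Worked example

```{r example, eval = FALSE}
cfg <- sceneConfig(nCells = 150, fieldMode = "clustered", seed = 1)
sc <- renderChannels(generateScene(cfg))

seg <- segmentCells(junctionImage(sc), labelImage(sc) > 0,
                    pixelSize = cfg@pixelSize)
nrow(seg$cells)

ct <- cellTable(sc)
sub <- lowerQuantileCells(ct, 0.3)
dispersionStats(pitRelativeCoordinates(sub, pitCenter(sc)))
clusteringPermutationTest(ct, q = 0.3, nPerm = 499)

traces <- generatePulseTraces(pulsationConfig(), nCells = 14, seed = 1)
intervalStatistics(traces)[c("mean", "sd", "nCells", "nIntervals")]
```

## Known limitations

The generator's polygonal cells are convex-ish power-diagram cells;
real apical outlines can be markedly non-convex under strong medial
pulling. Depth is an input, not an inference. The segmentation is tuned
for ridge-like junctional signal and will over-segment textured interiors
unless the watershed tolerance is raised. The pipeline analyses single
time points (plus 1D intensity traces); it does not track cells through
time or model the mechanics of invagination.
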