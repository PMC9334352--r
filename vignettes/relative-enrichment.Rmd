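---
title: "Density-based relative enrichment: model, design and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density-based relative enrichment: model, design and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retess)
```

## The model

`retess` quantifies colocalization between two SMLM channels as the
*relative enrichment* (RE) of a primary species across the local-density
distribution of a reference species.

The reference channel's localizations seed a Voronoi tessellation: region
$V_r$ of seed $L_r$ is the set of positions closer to $L_r$ than to any
other reference localization. The measure of $V_r$ (area in nm², volume in
nm³) is an inverse local-density estimate that requires no bandwidth or
radius parameter. Each primary localization belongs to the region of its
nearest reference seed — which is exactly membership in that seed's cell —
and every included region is scored

$$\mathrm{RE}_r \;=\; \frac{\text{observed}_r}{\text{expected}_r},
\qquad
\text{expected}_r \;=\; \frac{\mathrm{measure}_r}{\mathrm{measure}_{\mathrm{total}}}\; n_{\mathrm{primary}},$$

where $n_\mathrm{primary}$ counts the primary localizations that survive
the edge discard (below) and $\mathrm{measure}_{\mathrm{total}}$ is the sum
of included region measures, unless an ROI supplies the analysed area
instead. With the internal total, conservation is exact:
$\sum_r \text{expected}_r = \sum_r \text{observed}_r = n_\mathrm{primary}$,
so the measure-weighted mean RE is identically 1 and any enrichment in one
density range is necessarily balanced by depletion elsewhere. Under
complete spatial randomness of the primary channel,
$E[\mathrm{RE}_r] = 1$ for every region regardless of how the reference is
distributed — the null needs no simulation to define, only to check.

Assumptions worth keeping in mind: localizations are treated as points
(multi-blink artifacts must be corrected upstream — duplicated seeds are
rejected by default for this reason); the measure ignores where inside a
region a primary falls; and both channels are assumed to be observed over
the same field of view.

## Edge handling

Two kinds of region are discarded as *edge regions*, along with the primary
localizations they contain:

* cells of infinite extent (seeds on the convex hull of the reference set),
  flagged `finite = FALSE`; and
* finite cells that protrude beyond the observation window — by default the
  bounding box of the reference seeds, configurable via `window =` or an
  ROI.

The second rule is a minus-sampling border correction, and it is load
bearing. Seeds just inside the convex hull can own *finite* cells whose
vertices are circumcentres of sliver triangles far outside the imaged
region. Those measures are geometrically correct (we verified a sample of
them by Monte-Carlo integration) but describe space that was never
observed; in a 5000-point uniform field a handful of such cells can
multiply the total measure several-fold, which in turn scales every RE by
the same factor and destroys the RE = 1 null calibration. With the window
rule in place, two independent uniform fields calibrate to RE = 1 in every
density bin (this is asserted in the test suite over 20 replicate
simulations), at the cost of discarding a thin extra fringe of regions —
typically ~5% of a uniform field.

## Density axes and binning

Profiles bin included regions either by log10 measure or by **NND**, the
mean Euclidean distance from a seed to its Voronoi-adjacent seeds (natural
neighbours). NND is parameter-free, consistent with the tessellation,
scales as $\mathrm{measure}^{1/d}$, and reads in nanometres; it is the
default axis. Defaults: 40 bins, uniform from 0 to the 99th percentile of
NND (uniform in log10 measure for the area mode). Bin means are unweighted
over regions; empty bins are reported as absent (`NA`), never as zero. For
multi-image studies, `common_edges()` fixes one set of edges from pooled
data so per-image profiles are comparable; condition curves then average
*image* means, with SEM over images, rather than pooling regions — images,
not regions, are the independent replicates.

The dense-region summary (`dense_region_summary()`, default threshold
10 nm) condenses the high-density end into one number per image for
condition testing, which uses unpaired Student's t-tests per bin (or per
summary) with Bonferroni–Holm step-down control of the familywise error
rate. One-sided tests always require an explicit direction flag.

## Tessellation engine

No installed R package provides 3D Voronoi diagrams, so the package
computes cells directly (in C++) as intersections of half-spaces: each cell
starts from a far bounding box and is clipped by bisector planes towards
other seeds in order of increasing distance, stopping once no remaining
seed is closer than twice the farthest cell vertex (the security radius).
The same code serves 2D and 3D; measures come from the shoelace formula
(2D) or the facet-pyramid decomposition about the seed (3D), adjacency from
bisectors that contribute a facet, and the tests cross-check 2D areas and
adjacency against `deldir` and a brute-force empty-circumcircle Delaunay
oracle, and 3D volumes against analytic fixtures (the unit-cube-plus-centre
cell is an L1 ball of volume 0.5625).

Numerical choices: tolerances scale with each vertex's distance from its
seed (contact and merge slack $10^{-8}$, minimum facet extent $10^{-7}$ of
that scale), so far-reaching cells do not degrade near geometry; cells
still touching the working box are rebuilt with margins growing from 10 to
100 000 seed extents before being declared unbounded; exactly duplicated
seeds are an error unless `dedupe = TRUE`; collinear/coplanar seed sets and
sets smaller than $d + 2$ are rejected. Primary-assignment ties between
equidistant seeds break towards the lowest seed index, deterministically.

## Simulated validation scenes

`simulate_scene()` generates the fixtures the test suite and the acceptance
checks run on: independent uniform fields; Gaussian clusters with a uniform
background and an offset copy (colocalization with a known displacement);
anti-colocalized clusters whose centres are rejection-sampled at least
4 cluster-sd from every reference centre (our own default, chosen once);
duplicated point sets (perfect colocalization, with the closed-form
per-region RE $\mathrm{measure_{total}}/(P \cdot \mathrm{measure}_r)$); and
the 3D vesicle scene. Cluster counts are fixed rather than Poisson by
default so fixtures are exactly reproducible; a Poisson option exists.
Generating ground truth (cluster centres, memberships, true positions,
docked flags) is always returned for use as test oracles, and scenes
serialize to CSV plus a JSON sidecar.

The vesicle scene models twenty 20-nm-radius vesicles over a membrane
plane, half docked (touching the plane) and half floating above, with a
membrane-bound species uniform on each sphere (80 localizations), lumenal
cargo uniform in each ball (40), and an active-zone species of 60
localizations per *docked* vesicle, laterally Gaussian (sd 10 nm — a patch
about one vesicle wide) on the plane itself. All species receive Gaussian
localization jitter of 10 nm laterally and 20 nm axially — the doubled
axial uncertainty typical of astigmatic 3D SMLM. These counts and scales
were chosen to be realistic for dSTORM and were frozen before the
acceptance runs; sparser scenes make per-bin means outlier-dominated
(a single primary in a near-empty tiny cell yields RE in the hundreds).

Analysed with the vesicle membrane as reference, the scene reproduces a
known 2D blind spot: in the 2D projection the AZ folds into the vesicle
footprint and its profile is statistically indistinguishable from the
cargo's, while in 3D the cells beneath docked vesicles open into empty
sub-membrane space, are discarded as edge regions, and with them most
sub-vesicle AZ localizations — so the AZ peak enrichment drops below the
cargo's and shifts to intermediate NND. The property tests assert exactly
these comparisons over 20 replicate scenes.

What the simulations do *not* emulate: blinking photophysics and
multi-blink duplicates, detection inhomogeneity, drift, anisotropic or
non-Gaussian localization errors, and membrane topography. Passing tests
therefore validate the estimator and its null calibration, not robustness
to those acquisition artifacts — which must be handled in pre-processing.

## Comparison coefficients

`coloc_coefficients()` provides tessellation-based Spearman and Mander's
style coefficients purely for benchmarking against single-value methods:
per localization, its own cell density is paired with the density of the
other channel's cell containing it; the Mander's fraction counts
localizations in above-threshold cells of the other channel, with the
threshold defaulting to that channel's mean bounded-cell density. The
published definitions of these coefficients live outside this package and
leave threshold heuristics open, so ours are labelled approximations;
conclusions in this package rest on the RE profiles, not on them.

## Problem sizes and runtimes

The shipped test-suite and acceptance configurations use what a desk-scale
validation needs: uniform nulls at n = 5000 points per channel with 20
replicate simulations, clustered scenes of ~2400 reference points, vesicle
scenes of 1600 membrane seeds (times 20 replicates, 2D and 3D), and
100 random instances for the geometric oracle comparisons. A 5000-point 2D
tessellation takes ~0.5 s and a 1600-seed 3D scene ~0.5 s on one core; the
whole suite runs in about a minute.

## Known limitations

* Absolute RE values in 3D need care when a species is confined to
  structures (membranes, organelles) rather than free in the volume; the
  profile shape is then more informative than any single magnitude.
* The minus-sampling window is axis-aligned; irregular fields of view
  should be handled by passing the ROI, which both clips the channels and
  supplies the total measure.
* NND uses Voronoi-adjacent neighbours; other k-nearest conventions would
  shift the axis (not the RE values) and are not offered, to keep the
  method parameter-free.
* Region maps are 2D only; 3D data are visualized as RE-coloured point
  maps (top and side views) and depth profiles.
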