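# retess

Density-based relative enrichment (RE) colocalization analysis for
two-colour single-molecule localization microscopy (SMLM) point clouds, in
2D and 3D.

## The problem and the measure

SMLM (dSTORM, PALM, ...) produces coordinate lists of molecular positions,
not pixel images, and molecular distributions in membranes and cytoplasm are
strongly heterogeneous. Classical colocalization coefficients compress the
relationship between two labelled species into one number and ignore that
density context. `retess` instead asks, *for each local density of a
reference species, how enriched is the other (primary) species there?*

One channel is designated the **reference** and partitioned into Voronoi
regions, one per localization; each region's measure (area or volume) is a
parameter-free readout of local density. For every region the **primary**
channel is counted and compared with the count expected if primaries were
spread uniformly over the analysed area:

```
expected_r = (measure_r / total_measure) * n_primary
RE_r       = observed_r / expected_r
```

RE = 1 is the random expectation; RE > 1 means enrichment and RE < 1
depletion of the primary species around reference molecules of that local
density. Edge regions — cells of infinite extent, plus finite cells that
protrude beyond the observation window (a minus-sampling border correction)
— are discarded together with the primaries they contain, which makes the
measure-weighted mean RE exactly 1 by construction.

Per-region scores are summarised as a profile across the reference density
distribution, binned either by the mean distance from a seed to its
Voronoi-adjacent seeds (NND, in nm — the recommended, more interpretable
axis) or by log10 region measure. The analysis is deliberately asymmetric:
swapping reference and primary answers a different biological question, and
both directions are supported.

The package also bundles the point-pattern simulators used for validation
(uniform fields, offset / anti-colocalized Gaussian clusters, duplicated
sets, and a 3D docked-vesicle scene with three species and anisotropic
localization jitter), per-image condition statistics with Bonferroni–Holm
familywise error control, tessellation-based Spearman/Mander's comparison
coefficients, and RE colour-coded region/point maps.

## Worked example

Two offset clustered species (primary clusters displaced 50 nm from the
reference clusters) in a 2 x 2 µm field:

```r
library(retess)

scene <- simulate_scene(scene_config("offset_clusters", offset = c(50, 0),
                                     rng_seed = 1))
tess <- tessellate(scene$reference)
tess
#> <voronoi_tessellation> 2D, 2400 regions (2308 bounded, 92 edge),
#>   total measure 3.38956e+06 nm^2

enr <- region_enrichment(tess, scene$primary)
mean(enr$re[enr$bounded])
#> [1] 6.535                 # strong overall colocalization

dense_region_summary(enr, nnd_threshold = 10)
#> $mean_re  10.08           # mean RE of the 486 densest regions
#> $n_regions 486            # (seeds < 10 nm from their neighbours)

prof <- build_profile(enr, n_bins = 40)
head(prof[prof$region_count > 0, c("bin_mid", "mean_re", "region_count")])
#>     bin_mid   mean_re region_count
#> 1  1.602810  0.000000            2
#> 2  4.808429 10.252838           99
#> 3  8.014048 10.563515          344
#> 4 11.219667  9.438193          460
#> 5 14.425287  9.064982          335
#> 6 17.630906  6.554309          194
```

The profile reads: reference molecules whose neighbours are ~5–15 nm away
(the cluster cores, which hold most regions) carry a ~10-fold enrichment of
the primary species, decaying towards sparse background densities. For two
independent uniform species every bin sits at RE = 1 within sampling error.

`plot_profile(prof)` draws the standard presentation (mean RE on the left
axis, the reference density histogram on the right axis, dashed guide at
RE = 1); `render_region_map()` / `render_point_map()` colour regions or
localizations by RE on a diverging scale centred at RE = 1. The whole
pipeline, including CSV/JSON/plot outputs, is wrapped in
`run_enrichment()` / `run_swap()` and in a command-line script at
`inst/cli/retess.R` with `enrich`, `swap` and `simulate` subcommands.

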