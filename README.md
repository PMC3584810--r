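# rhizovec

Vectorized root system architecture for rhizotron phenotyping.

Root systems grown in thin transparent containers (rhizotrons) can be
digitized by *split-and-combine* scanning: the root system is separated
into fragments to reduce overlap, each fragment is scanned and traced as a
vector object (polylines with per-node diameters), and the tracings —
registered in a common frame — are recombined into one complete root
system. `rhizovec` implements the computational side of that workflow for
root biologists and phenotyping pipelines:

* **I/O** — read/write root systems as RSML 1.0; read plain-text or
  grayscale-PNG raster maps of soil water content.
* **Model & merge** — an S4 data model (`Root`, `RootSystem`,
  `PartialTracing`) with validation, plus `mergeTracings()`, which
  translates registered fragments into the common frame and attaches
  cross-fragment laterals to the nearest parent polyline (tolerance
  0.5 cm; unattachable laterals are kept and reported, never deleted).
* **Traits** — per-root length, surface and volume from conical frusta;
  distal cumulative measures (everything tipward of a position, laterals
  included); depth profiles by root order; per-order diameter statistics
  with Welch t-tests at p < 0.01 and compact letter display; orientation
  along the root axis (0° = plumb, 90° = horizontal); Fitter's topological
  indices (magnitude, altitude, exterior path length).
* **Root–soil crossing** — block-mean downsampling of water maps,
  per-pixel nearest-root-segment distance maps, a long soil × root table,
  distance-binned water-content time series, and recovery of the
  depletion length scale by fitting `W(d) = W0 − A·exp(−d/ℓ)`.
* **Synthetic generators** — seeded maize-like root systems (1 primary +
  2–3 seminal + 2–4 adventitious axes, laterals to order 3), their split
  into partial tracings, binary mask rendering, and water-depletion map
  series, so the full pipeline runs and is tested without any scan data.

See `vignettes/rhizovec-methods.Rmd` for the models, parameter defaults
and design choices.

## Worked example

```r
library(rhizovec)

sys <- generateRootSystem(seed = 42)
sys
#> RootSystem 'synthetic_seed42': 172 root(s) in a 50 x 50 cm rhizotron
#>   per order: 5@order1, 96@order2, 71@order3
```

Five first-order axes (the maize range is 5–8) carrying 96 second- and 71
third-order laterals. Per-root traits and per-order summaries:

```r
head(rootTraits(sys)[, c("id", "order", "length_cm", "surface_cm2",
                         "mean_diameter_cm", "tip_depth_cm")], 4)
#>       id order length_cm surface_cm2 mean_diameter_cm tip_depth_cm
#> 1    ax1     1     41.68       55.54            0.424        40.55
#> 2 ax1_01     2      2.90        1.29            0.142         4.30
#> 3 ax1_02     2      5.61        2.54            0.144         9.48
#> 4 ax1_03     2      5.86        2.31            0.126         8.63

round(surfaceProportions(sys), 3)
#>     1     2     3
#> 0.459 0.489 0.052

diameterStats(sys)
#>   order  n mean_diameter_cm sd_diameter_cm letter
#> 1     1  5            0.421        0.01889      a
#> 2     2 96            0.135        0.00818      b
#> 3     3 71            0.072        0.00405      c
```

Laterals (orders 2–3) carry the majority of the root surface, while the
five thick axes carry the depth: the letters show the three orders are
mutually distinct in diameter at p < 0.01. Crossing the architecture with
a synthetic three-day soil water series on a 1-cm grid:

```r
dm  <- distanceMap(sys, list(nrow = 50, ncol = 50, origin = c(0, 0),
                             pixelSize = 1))
ser <- generateWaterSeries(sys, dm, seed = 1)       # ground truth: ell = 2 cm
bn  <- distanceBinnedSeries(joinSoilRoot(ser, dm), 0:15)
head(bn[bn$time_h == 64, c("bin", "mean_water_content", "n")], 5)
#>       bin mean_water_content   n
#> 257 [0,1)              0.289 502
#> 258 [1,2)              0.440 166
#> 259 [2,3)              0.516 133
#> 260 [3,4)              0.562 118
#> 261 [4,5)              0.588 122

round(fitDepletionProfile(bn, 64), 3)
#>    W0     A   ell
#> 0.631 0.403 2.006
```

Water content dips sharply within the first centimeters of the roots; the
fitted depletion length scale (2.006 cm) recovers the generating value of
2 cm to within a fraction of a percent.

A command-line front end wraps the same functions:

```sh
Rscript inst/scripts/rootvec simulate --seed 42 --out run/
Rscript inst/scripts/rootvec traits --rsml run/system.rsml --out run/traits/
Rscript inst/scripts/rootvec soilcross --rsml run/system.rsml \
    --grids run/grids/ --pixel 1.0 --bins 0:15:1 --out run/cross/
```

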