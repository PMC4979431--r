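# rgcmosaic

Automated spatial and temporal analysis of retinal ganglion cell (RGC) loss
in whole-mount retina images.

In rodent models of glaucoma and optic nerve injury, the standard endpoint
is a flattened whole-mount retina with immunolabelled RGC nuclei, imaged as
an 8-bit maximum projection. `rgcmosaic` turns such an image — plus a
pixel-size calibration and the optic-nerve-head (ONH) centre — into
quantitative maps of where and how fast RGCs are lost:

* **Detection** — background flattening, a 130 grey-level threshold,
  distance-transform watershed to split touching somata, then size
  (7–21 µm equivalent diameter) and circularity (4πA/P² > 0.7) gates.
* **Mosaic statistics** — per-cell nearest-neighbour distances (NND) and
  the regularity index RI = x̄₍NND₎/σ₍NND₎ (≈ 1.9 for a random arrangement,
  higher for the quasi-regular mosaics of healthy retina), plus NND
  distribution skewness and tail fractions, which separate diffuse from
  clustered loss.
* **Sector segmentation** — every cell is gated by its ONH distance
  d = √((x−a)² + (y−b)²) into 15 concentric rings (0.3 mm) × 4 anatomical
  quadrants = 60 non-overlapping sectors, with per-sector count, area,
  density, mean NND and RI; counts and areas partition the retina exactly.
* **Degeneration kinetics** — per-sector density time courses are fit to a
  one-phase exponential decay with plateau,
  y = (Y₀ − Plateau)·e^(−KX) + Plateau (half-life, % loss), and to a
  two-phase decay with rates fixed at half-lives of 1.7 d (primary
  degeneration) and 16.3 d (secondary),
  y = Plateau + S_F·e^(−K_F X) + S_S·e^(−K_S X) with
  S_F = (Y₀ − Plateau)·P_F·0.01, which estimates P_F, the percentage of
  primary degeneration, per sector.
* **Synthetic retinas** — Poisson and Matérn-II hard-core mosaics with
  programmable density gradients and diffuse/clustered loss, rendered to
  8-bit images, so the whole pipeline is benchmarked against ground truth.

## Worked example

```r
library(rgcmosaic)

spec <- mosaic_spec(field_radius_mm = 1.5, target_density_per_mm2 = 1695,
                    exclusion_radius_um = 12, seed = 1)
retina <- simulate_retina(spec, pixel_size_um = 1)

cells <- detect_cells(retina$image, retina$geometry)
count_summary(cells, retina$geometry)
#> $total_cells     : 11864
#> $retina_area_mm2 : 7.07
#> $density_per_mm2 : 1678

nnd <- nearest_neighbour_distances(cells)
regularity_index(nnd)
#> [1] 4.399252

grid <- sector_grid(onh_xy_mm = retina$geometry$onh_xy_mm,
                    ring_width_mm = 0.3, n_rings = 5,
                    orientation_deg = 270)   # superior-up image
head(sector_table(cells, retina$geometry, grid, nnd), 3)
#>   ring quadrant cell_count area_mm2 density_per_mm2 mean_nnd_um    ri
#> 1    1 Superior        113  0.07067            1599       16.86 4.114
#> 2    2 Superior        355  0.21205            1674       16.37 4.735
#> 3    3 Superior        604  0.35341            1709       16.58 4.374
```

The detected density (1678/mm²) recovers the generator's target (1695/mm²)
to ~1 %; the regularity index ≈ 4.4 reflects the 12 µm hard-core spacing
(a Poisson mosaic would give ≈ 1.91). Sector densities are flat because
this synthetic retina has no density gradient or lesion; applying
`apply_loss()` with a clustered pattern in one quadrant reproduces the
superior-inferior asymmetries seen after partial optic nerve transection.

Kinetics, from a longitudinal per-sector density table:

```r
series <- read_series("series.csv")   # ring, quadrant, day, density
maps <- sector_kinetics_map(series)   # % loss, half-life, % primary
maps$table; maps$plots$primary
```

A thin command-line wrapper with `simulate`, `detect`, `segment`, `fit`
and `run` subcommands is installed at `inst/cli/rgcmosaic` (see
`run_pipeline()` for the config-driven end-to-end run).

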