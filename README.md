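# permalake

Object-based detection and analysis of **permafrost lake drainage** and the
**vegetation greening of drained lake basins (DLBs)**, for remote-sensing
landscape ecologists who work with annual surface-water and reflectance
rasters.

Lakes in the northern permafrost zone drain when thermally eroded outlets or
taliks breach them; the exposed basins are rapidly colonized by tundra
vegetation and become local greening hotspots. `permalake` implements the
full analysis chain for this phenomenon:

* **Lake delineation** — morphological opening (erosion + dilation, 1-pixel
  cross, 2 iterations) of a persistent-water mask, connected-component lake
  objects, and pixelwise union of two water-loss products (JRC-like and
  GLAD-like dialects). A lake is a **drainage event** iff its initial area
  exceeds 1 ha and more than 50 % of its footprint is lost
  (both strict); size classes are small [1, 10), medium [10, 100),
  large ≥ 100 ha.
* **Drainage dating** — continuous piecewise-linear segmentation of each
  lost pixel's annual AWEI series (despiking, exhaustive or greedy vertex
  search, parsimony selection); the pixel disturbance year is the end of the
  largest fitted decrease and the lake year is the modal pixel year.
* **DLB greenness** — annual 90th-percentile NDVI composites reduced to
  basin and surround medians (water and negative values masked; surround =
  disk of twice the lake's equivalent diameter minus all water bodies),
  aligned on years since drainage, with class-stratified median/quartile
  trajectories and a tenth-year reference summary.
* **Density and trends** — spatial density (events km⁻²) and lake-wise
  density (drained / all lakes) by stratum and size class; OLS trend test
  and Theil–Sen slopes for annual series.
* **Driver attribution** — gradient-boosted classification/regression with a
  70/30 split and CV random search, correlation-based feature pruning
  (|r| > 0.5), and natively implemented permutation importance and
  sampling-based Shapley values.
* **Synthetic scenes** — a seeded simulator (`simulate_scene()`,
  `simulate_lake_population()`) that generates lakes with a truncated-Pareto
  size spectrum, a logistic drainage model on climate covariates, per-product
  omission/commission noise, cloudy multi-observation reflectance and
  class-dependent exponential NDVI recovery
  (`N(t) = S + Δ∞ − (S + Δ∞ − N0)·e^(−t/τ)`), so the whole pipeline runs and
  is validated without any satellite downloads.

## A worked example

```r
library(permalake)

cfg    <- sim_config(grid_rows = 256, grid_cols = 256, n_lakes = 80, seed = 2)
bundle <- simulate_scene(cfg)
bundle
#> <scene_bundle> 256x256 px, years 2000-2020, 80 lakes (20 drained, 16 truth events)

lab    <- label_objects(clean_mask(bundle$permanent_water), 8, 30)
loss   <- union_loss(bundle$loss_masks$jrc_like, bundle$loss_masks$glad_like)
events <- date_events(detect_drainage_events(lab$objects, lab$pixels, loss),
                      lab$pixels, bundle$composites$awei, loss)
head(events[c("lake_id", "area_ha", "loss_fraction", "size_class", "detected_year")])
#>   lake_id area_ha loss_fraction size_class detected_year
#> 1       1    1.62     0.7777778      small          2013
#> 2       3    1.62     0.7777778      small          2007
#> 3       5    4.77     0.6981132      small          2002
#> 4       8    3.15     0.8857143      small          2018
#> 5       9    1.17     0.7692308      small          2009
#> 6      16   30.15     0.8656716     medium         2009
```

Sixteen events clear the >1 ha / >50 % thresholds; on this default-noise
scene all sixteen detected drainage years equal the simulator's truth.
Stratifying the basin-minus-surround NDVI trajectories by thermokarst
likelihood:

```r
traj <- build_trajectories(events, lab$pixels, bundle$composites$ndvi,
                           bundle$water_masks, 30)
traj$thermokarst <- bundle$truth$thermokarst[
  match_events_to_truth(lab$pixels[as.character(events$lake_id)],
                        bundle$footprints)[match(traj$lake_id, events$lake_id)]]
group_trajectories(traj, "thermokarst", reference_year = 8)$reference
#>       stratum n median_delta    q25_delta   q75_delta median_basin
#> 1      likely 2  0.009010236  0.002803259  0.01521721    0.5281512
#> 2    unlikely 7 -0.106510525 -0.110513961 -0.09983412    0.4040007
#> 3 very_likely 2  0.067895196  0.061198151  0.07459224    0.5581024
```

`median_delta` is the median basin NDVI minus surround NDVI at the reference
year after drainage: very-likely thermokarst basins end up greener than
their surroundings (≈ +0.07 here, planted asymptote +0.06), non-thermokarst
basins stay well below (≈ −0.11, planted −0.09 plus the documented
percentile-composite bias), and the likely class converges to its
surroundings.

The same chain runs end to end, with provenance and per-stage artifacts,
via `run_pipeline(default_pipeline_config(seed = 1), "all", "outdir")` or
the `inst/scripts/permalake` command-line wrapper.

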