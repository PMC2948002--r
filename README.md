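# ecotone

Tools for quantifying the flattening of rainforest-savanna tree-cover
gradients and testing whether phenotypic divergence between forest and
ecotone populations along those gradients has been lost.

Steep environmental gradients generate and maintain intraspecific
diversity: divergent selection across the rainforest-ecotone transition
can hold populations of a sedentary bird apart in fitness-related
morphology (wing, tail, tarsus, bill) despite gene flow. Deforestation
flattens the gradient -- forest sites come to resemble ecotone sites in
tree cover -- and the divergence can erode. `ecotone` implements the full
analysis chain for detecting this, for ecologists and evolutionary
biologists working with raster tree-cover products, field morphology, and
museum series:

* **Gradient**: mean percent tree cover per 5 km latitudinal band;
  regional alignment (2.5° southward shift); ANCOVA
  `cover ~ region * latitude`, whose interaction term tests for a
  flatter gradient; strict `>10%` change masks for recent deforestation.
* **Morphometrics**: log-log allometric size correction on tarsus;
  equality/proportionality tests of region covariance matrices (Flury
  hierarchy: Box's M and the ML proportionality fixed point) gating a
  pooled covariance PCA of log traits (PC1 = size, PC2 = shape);
  per-era PCAs and [-1, 1] within-era score normalization; strict
  pre-1935 historical filtering.
* **Divergence**: two-sided Wilcoxon rank-sum tests (exact enumeration
  for small untied groups, tie/continuity-corrected normal approximation
  otherwise) for forest-vs-ecotone and region-within-era contrasts, with
  Dunn-Šidák family-wise control: α' = 1 − (1 − α)^(1/m), i.e. 0.0085
  for the six-trait family at α = 0.05; between-habitat F_ST summaries.
* **Resampling**: a habitat-stratified bootstrap null for the *absence*
  of divergence -- B = 1000 resamples from the well-sampled reference
  region at the focal region's per-habitat sample sizes; p = proportion
  of replicates with |divergence| ≤ observed, reported `p < 1/B` at
  zero -- plus a whole-site population-level variant and a calibration
  harness.
* **Projection**: sample-size-weighted site-level regressions of each
  trait on percent cover, screened at α = 0.05, projected over rasters
  with block-mean aggregation and post-aggregation back-transform.
* **Synthetic data**: rasters, sites, and individuals with the exact
  statistical structure the analysis assumes (linear latitudinal cover
  trends, Bernoulli deforestation, multivariate-lognormal traits linear
  in cover, potential-forest habitat labeling, pre-shift historical
  cohorts), fully seeded.

Rasters are read and written as plain-text ESRI ASCII grids (`.asc`),
interchangeable with single-band GeoTIFF via GDAL/QGIS/terra.

## Worked example

```r
library(ecotone)

cfg <- run_config(seed = 7, B = 200, n_per_site = 6)
res <- run_full_analysis(cfg, out_dir = "demo_run")

res$ancova
#> Gradient ANCOVA on band_means
#>   slopes (% cover / deg lat): central = -11.943, west = -4.010
#>   region           F(1, 262) = 2929.52, p = 3.05e-144
#>   latitude         F(1, 262) = 12898.42, p = 7.41e-225
#>   region:latitude  F(1, 262) = 3189.36, p = 1.07e-148
```

The interaction F confirms the western gradient (true slope −4 %/deg) is
significantly flatter than the central one (−12 %/deg). Divergence
testing on the same run shows the morphological consequence -- every
screened trait divergent between forest and ecotone in the steep-gradient
region, none in the flattened one (n = 54/54 and 24/18 individuals):

```r
as.data.frame(res$divergence)[, c("trait", "region", "p_two_sided", "significant")]
#>      trait  region  p_two_sided significant
#> 1      PC1 central 6.990523e-09        TRUE
#> 2   tarsus central 1.896215e-03        TRUE
#> 3     wing central 1.100550e-11        TRUE
#> 4     tail central 4.494424e-09        TRUE
#> 5  wing_sc central 5.128552e-10        TRUE
#> 6  tail_sc central 2.556351e-06        TRUE
#> 7      PC1    west 3.600638e-02       FALSE
#> 8   tarsus    west 1.993066e-01       FALSE
#> ...
```

(`significant` is judged against the Dunn-Šidák threshold 0.0085, not
0.05.) The stratified bootstrap asks whether the western absence of
divergence could be a sampling artefact of its smaller n:

```r
res$bootstrap[["PC1"]]
#> Stratified bootstrap (individual level), trait PC1:
#>   observed |divergence| = 0.05779, B = 200, p = 0.055
```

i.e. only 5.5% of equally-sized resamples from the divergent reference
region show as little PC1 divergence as observed in the west; at the
production default `B = 1000` and with the full trait family the
corresponding evidence is summarized per trait in
`res$bootstrap[[trait]]$report`.

## Command line

```sh
inst/cli/ecotone all --out runs/demo --seed 7 --B 1000
inst/cli/ecotone gradient --raster west.asc --band-km 5 --out bands.csv
inst/cli/ecotone ancova --a west_bands.csv --b central_bands.csv --shift-deg 2.5
inst/cli/ecotone defmask --t0 t0.asc --t1 t1.asc --threshold 10
inst/cli/ecotone resample --individuals ind.csv --ref central --focal west \
    --trait PC1 --B 1000 --seed 1
```

See `vignettes/gradient-flattening-methods.Rmd` for the model, its
assumptions, all tunable constants, and known limitations.
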