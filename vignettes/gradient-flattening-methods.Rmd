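---
title: "Quantifying gradient flattening and the loss of morphological divergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gradient flattening and the loss of morphological divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecotone)
```

## The scientific problem

Ecological gradients -- here, the transition from lowland rainforest to
savanna across equatorial Africa, indexed by percent tree cover -- generate
and maintain intraspecific diversity: divergent selection across the
gradient can hold forest and ecotone populations of the same bird species
apart in fitness-related morphology despite ongoing gene flow. When
deforestation removes tree cover from the forest end of the gradient, the
gradient *flattens*: spatial turnover in tree cover per unit latitude
shrinks, forest sites come to resemble ecotone sites, and the divergent
selection that maintained phenotypic differences weakens. This package
implements the complete analysis chain for detecting that process:

1. **Gradient quantification** -- how steep is the tree-cover gradient in
   each region, and do the slopes differ?
2. **Phenotype-environment association** -- which morphological traits
   track tree cover across sites?
3. **Divergence testing** -- are forest and ecotone populations divergent
   in those traits, within each region, today and historically?
4. **Sampling artefact control** -- could an observed *absence* of
   divergence in the sparsely sampled region be a sampling accident?
5. **Projection** -- what does the fitted phenotype-cover relationship
   imply across the landscape?

A synthetic-data module generates rasters, sites, and individuals with the
statistical structure the analysis assumes, so every downstream stage is
testable without any download.

## Gradient analysis

Mean tree cover is computed for each 5 km latitudinal band of a
percent-tree-cover raster (`band_means()`). Bands are half-open intervals
anchored at the raster's southern edge, using 1 degree = 111.32 km; this
makes banding deterministic and order-independent, and band means are
invariant to tiling of the raster. Because the latitudinal position of the
forest-ecotone boundary differs between regions, one region's series can
be shifted southward (`align_regions()`, default 2.5 degrees) before
comparison.

Slope difference is tested by ANCOVA on the band means
(`gradient_ancova()`): `mean_cover ~ region + latitude + region:latitude`,
with the interaction term -- fitted last, so its sequential F is the
partial F -- testing whether one gradient is flatter. The unit of analysis
(band means, not pixels) is recorded in the result; fitting on raw pixels
would change both the F scale and the error structure, and the choice of
unit is deliberately explicit because headline F statistics are not
comparable across unit choices. Whether the alignment shift is applied
before the ANCOVA is a config flag (default: applied); the shift changes
only the region main effect, not the interaction, because it is a
per-region affine change of the latitude axis.

Recent deforestation is masked by strict thresholding of the cover change
between two epochs (`deforestation_mask()`): a pixel is masked when cover
dropped *more than* `threshold_pct` (default 10); a drop of exactly the
threshold does not qualify. Nodata propagates, and cross-epoch grids may
be aligned by nearest-neighbour resampling only (no interpolation is
invented).

Because no R geospatial stack is assumed, rasters are read and written as
ESRI ASCII grids -- a plain-text single-band format with identical
semantics to a single-band GeoTIFF (origin, cell size, nodata sentinel)
and readable by GDAL, QGIS, and terra.

## Morphometrics

All analyses run on log-transformed trait values (tarsus, wing, tail,
upper mandible length in mm). Size correction is the residual of
`log(trait)` on `log(tarsus)` (`size_correct()`); upper mandible length is
never size-corrected, because feeding performance depends on absolute bill
dimensions. The regression's slope p-value is returned because the
size-corrected versions of a trait are only meaningful when the allometric
regression itself is supported -- historical museum series are often too
small, in which case the size-corrected historical comparisons are
omitted.

### The pooling gate

Computing one PCA across two regions silently assumes the regions share a
trait covariance structure. `covariance_structure_test()` tests the two
lower levels of the Flury hierarchy: equality of the two covariance
matrices, and proportionality (`Sigma2 = rho * Sigma1`). Equality uses
Box's M with Box's small-sample scale correction; the uncorrected
likelihood-ratio statistic is markedly anti-conservative at field sample
sizes (tens of birds per region) and would close the gate spuriously.
Proportionality uses the maximum-likelihood fixed point
(`Sigma <- (n1*S1 + n2*S2/rho)/n`, `rho <- tr(Sigma^-1 S2)/p`, relative
tolerance 1e-10, max 200 iterations) with a chi-squared reference on
`p(p+1)/2 - 1` dof; at the ML solution the trace terms cancel, so the
statistic reduces to log-determinant differences. The verdict is
sequential at alpha = 0.05: *equal* if equality is not rejected, else
*proportional* if proportionality is not rejected, else *neither* -- and
`pooled_pca()` refuses to pool on *neither* unless overridden. Full
common-principal-components levels of the hierarchy are not implemented:
the gate only ever asks about equality and proportionality.

One subtlety matters in exactly the situation this analysis targets. The
region covariance matrix of raw pooled individuals contains the
between-site mean structure induced by the environmental gradient, and a
steep-gradient region necessarily carries more of it than a flattened one
(a rank-1 inflation along the direction of the trait-cover slopes). That
is an environmental difference, not a difference in trait covariance. The
gate therefore centers traits within sites before testing (when a
`site_id` column is present); the PCA itself stays uncentered, since
between-site size variation is part of the signal PC1 must carry.
Centering consumes one mean per site, so the test is run at Wishart
degrees of freedom `n - s` per region (not `n - 1`); without this
adjustment the gate rejects equal-covariance worlds at roughly twice the
nominal rate at typical per-site sample sizes.

Two operating characteristics follow from taking the gate seriously.
First, even in a world where the regions truly share a covariance matrix,
about 5% of datasets are refused -- that is the gate's type-I error doing
its job, and `run_full_analysis()` propagates the refusal as an error
rather than silently overriding it. Second, the gate is applied where the
verification protocol applies: to the pooled contemporary analysis.
The per-era PCAs inside `era_divergence()` do not re-apply it -- museum
series are far too small for the test to carry information, and the
era contrast never pools scores across eras anyway.

### PCA conventions

`pooled_pca()` eigendecomposes the covariance (not correlation) matrix of
log traits: the traits share units, the log scale matches every other
analysis, and covariance PCA keeps PC1 interpretable as overall size.
Eigenvector signs are arbitrary, so they are fixed deterministically: the
tarsus loading on PC1 is positive (larger PC1 = larger bird) and every
other component has its dominant loading positive. Scores are centered
log traits times loadings; their covariance is diagonal with the
eigenvalues on the diagonal, and the eigenvalue sum equals the total
input variance. Historical and contemporary data get *separate* PCA
models, and scores are never compared across eras directly; for display,
`normalize_scores()` rescales each era by its largest absolute score to
[-1, 1], which deliberately destroys cross-era ratios (it is a
visualization aid only).

The historical filter (`filter_historical()`) keeps specimens collected
strictly before 1935 (a bird labelled 1935 is excluded) and drops rows
without a usable habitat assignment, logging both counts.

## Divergence testing

`wilcoxon_rank_sum()` implements the two-sided rank-sum test with both
paths exposed: an exact p-value by enumeration of the Mann-Whitney null
distribution (used automatically when the smaller group has at most 10
observations and the pooled data are tie-free -- the smallest real group
in this design, 11 ecotone birds, sits just past the boundary), and the
normal approximation with tie correction and continuity correction
otherwise. The exact null is built by the standard partition recurrence,
and the test suite verifies it against brute-force enumeration of all
rank assignments and against `stats::wilcox.test`. Exhaustive comparison
of the two paths at m = n = 8 shows a supremum disagreement of 0.0109
(at the distribution's shoulder, p around 0.37); near the significance
thresholds that matter the paths agree much more closely.

Habitat contrasts (`habitat_divergence()`) test forest vs ecotone within
a region for six traits -- PC1, tarsus, wing, tail, and size-corrected
wing and tail; PC2 and upper mandible are excluded because they fail the
tree-cover association screen -- under Dunn-Sidak family-wise control:
the per-test threshold is `1 - (1 - alpha)^(1/6)` = 0.0085 at alpha =
0.05. Montane and island rows are a hard error, not a silent drop: the
contrast is defined for continental lowland sites only. Era contrasts
(`era_divergence()`) compare regions within each era on rainforest birds
only, with era-specific PCAs; they are uncorrected by default (a config
switch enables correction), since the within-era family is a different
design from the six-trait habitat family.

Between-habitat gene flow context is summarized by
`fst_between_habitat_summary()`: the mean, SE and range of pairwise F_ST
entries over population pairs whose habitats differ.

## The stratified bootstrap null

An absence of divergence in a sparsely sampled region is only meaningful
if the sampling design could have detected divergence. The test
(`stratified_bootstrap_null()` + `bootstrap_p()`) resamples, with
replacement, individuals from the *well-sampled* reference region --
stratified by habitat so that each replicate matches the focal region's
per-habitat sample sizes -- and computes the absolute difference in trait
means per replicate. The p-value is the proportion of replicates whose
divergence is less than or equal to the focal region's observed value;
when that proportion is zero it is reported as `p < 1/B` (so `p < 0.001`
at the default B = 1000). The divergence statistic is the absolute
difference of group means on the same scale used in divergence testing
(log mm, PC score, or residual); sampling is with replacement within
strata, the classical stratified bootstrap.

The population-level variant (`population_bootstrap_null()`) resamples
whole sites with replacement to match the focal region's per-habitat
*site* counts, addressing the chance sampling of atypical populations.
Its exact historical procedure is not recoverable from the published
record; the whole-site convention here is this package's declared choice,
isolated behind its own function. When every site holds exactly one
individual the two levels coincide exactly (they share an RNG substream
to make this property testable).

`calibrate_null()` validates the machinery: with focal and reference
regions simulated from one shared trait model, the rejection rate at
alpha = 0.05 should be nominal. The default reference pool (400 forest /
200 ecotone) is deliberately generous: the classical bootstrap is
anti-conservative when the reference pool is small, because the reference
habitat means are themselves noisy and the null distribution's center
then wobbles relative to the focal observation. With field-realistic
reference sizes (say 60/30) the test rejects somewhat more than 5% under
the null; users interpreting marginal bootstrap p-values on small
reference pools should know this limitation.

## Projection

`weighted_trait_regression()` fits site mean trait values (log or PC
scale) on site percent cover by weighted least squares with weights equal
to site sample sizes -- the site is the unit, and a site of n birds
carries exactly the weight of n singleton sites (a tested equivalence).
All habitats, including montane and island sites, enter this regression:
the phenotype-cover relationship is assumed general. The screen
(`trait_cover_association_screen()`) keeps traits whose slope is
significant at alpha = 0.05; only kept traits proceed to divergence
testing and projection.

`project_trait()` applies a fitted model per pixel, aggregates by block
mean to the target resolution (partial edge blocks average their
available pixels), and back-transforms log-scale traits by
exponentiation *after* aggregation by default -- aggregation happens on
the model's linear scale; exponentiating first is available as a flag,
and no smearing-type bias correction is applied. The projection is
affine-equivariant: rescaling cover by c while rescaling the slope by
1/c leaves the map unchanged.

## The synthetic world

The generator states one world and the tests live in it:

* **Rasters**: pixel cover = `clip(intercept + slope*(lat - lat_min) +
  N(0, noise_sd), 0, 100)`, then an independent Bernoulli fraction of
  pixels loses `deforestation_depth` points. The noise-free,
  pre-deforestation trend is attached as the *potential forest* layer.
  No spatial autocorrelation is modelled; independent pixel noise is
  sufficient to exercise band means and the ANCOVA, but a green test here
  says nothing about spatially correlated errors.
* **Habitat labels** depend only on the potential layer (forest:
  potential cover >= 60; ecotone: 20-60), never on realized cover -- so
  deforested potential-forest sites stay "forest", the convention that
  makes gradient flattening visible as within-habitat cover loss.
* **Individuals** are multivariate lognormal: log-trait means linear in
  site cover, shared covariance with log-scale SD 0.05 (CV about 5%,
  typical of passerine morphometrics) and exchangeable correlation 0.5,
  under which PC1 is an overall-size axis. Default slopes per percent
  cover: tarsus -0.0015, wing and tail -0.0025, upper mandible 0 -- birds
  larger in open habitat, wing/tail moving about 12% and tarsus about 7%
  across a 50-point forest-ecotone cover contrast, and the mandible
  deliberately cover-free so the screen excludes it. The second region's
  covariance can be scaled (proportional world) or replaced (unrelated
  world). Within-site random effects are supported implicitly through
  per-site covers but no extra site-level variance component is added by
  default: the stated world has individual-level noise only.
* **Historical cohorts** are forest-only (museum collections hold almost
  no ecotone specimens), generated at the *potential* cover of their
  sites -- museum birds sampled the pre-deforestation gradient -- with
  collection years in 1895-1934 and optional per-trait log offsets.
* **Seeding**: one global integer seed is propagated to named substreams
  (`raster`, `sites`, `individuals`, `historical`, `bootstrap`) so stages
  are independently reproducible; identical seeds give byte-identical
  artifacts.

Simulation-based tests state their tolerances up front (binomial 95% CIs
for rates, 3 standard errors for moment recovery) and use fixed seeds;
the ANCOVA simulations place the gradient mid-range (intercept 80%) so
that the [0, 100] clip never truncates the noise, which would otherwise
distort the nominal type-I rate.

## Known limitations

* The gradient ANCOVA's absolute F depends on the unit of analysis (band
  means here) and on the raster extent; only its qualitative verdict and
  the per-region slopes are transportable.
* The bootstrap null inherits finite-reference anti-conservatism (above).
* The deforestation mask is a difference threshold on co-registered
  epochs; no sensor harmonization or trend fitting is attempted.
* Habitat labeling in the generator is a threshold rule on a single
  potential layer; real land-cover classifications bring their own error
  structure, which is not modelled.
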