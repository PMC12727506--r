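---
title: "Methods: expert-based Biodiversity Intactness Index mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expert-based Biodiversity Intactness Index mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biimapr)
```

## The model

The Biodiversity Intactness Index (BII) of a pixel is the average remaining
fraction of the reference population abundance of the indigenous species
that should occur there, given the pixel's land use. With per-species
intactness scores $I_{sk}$ under land use $k$, the pixel index is the plain
species mean $\mathrm{BII} = \frac{1}{R}\sum_s I_{sk}$. Because per-species
scores are rarely available, the package works at the level of *functional
response groups* — sets of species assumed to respond identically to a land
use across their regional range — and weights each group's score by its
richness in the pixel's ecoregion:

$$\mathrm{BII}_{\mathrm{pixel}}
  = \frac{\sum_i R_i\, I_{ik}}{\sum_i R_i},$$

where $R_i$ is the number (or proportional share) of species of group $i$
in the ecoregion and $I_{ik}\in[0,2]$ the group's intactness under land use
$k$ (values above 1 describe species that thrive under human modification;
scores are capped at 2 so such species cannot dominate aggregation). With
every $R_i = 1$ the group form collapses to the species mean — `bii_pixel()`
is tested against that brute-force equivalence to $10^{-12}$. Area
summaries average pixel scores, unweighted, over equal-area pixels:
$\mathrm{BII} = \frac{1}{n}\sum \mathrm{BII}_{\mathrm{pixel}}$. Internally
BII is a fraction; `as_percent()` converts to percent only at the reporting
boundary.

## Expert scores and uncertainty

Intactness scores come from structured expert elicitation: each expert
scores each (group, specific land use) combination — and each biome, for
plant groups, since floras differ strongly among biomes. `aggregate_scores()`
uses the arithmetic mean across experts and a Student-t 95% interval
$\bar x \pm t_{0.975,\,n-1}\, s/\sqrt{n}$, clipped to the $[0,2]$ score
domain. The t interval was chosen because expert counts per combination are
small (around 10); a normal interval would be anti-conservative at such
sizes. Combinations scored by a single expert keep a degenerate interval
equal to the mean and carry a flag, rather than being dropped — the pipeline
must stay total. The variance is computed with a centred two-pass formula so
that perfectly agreeing experts yield an exactly zero-width interval.

Uncertainty propagates by linearity: the lower- and upper-limit score
columns travel through the same interpolation and richness weighting as the
mean, giving per-pixel lower- and upper-limit BII layers whose ordering
(lower ≤ mean ≤ upper) is asserted on every map.

Mosaic ecoregions belong to two biomes; `resolve_mosaic_scores()` gives them
the unweighted mean of the two biomes' mean and bound columns. For the
mosaic's expert count we keep the *smaller* of the two biomes' counts, a
conservative choice the upstream tables do not dictate.

## Land-use classes and the allocation tree

Experts score nine *specific* land uses: mixed settlements (1a), dense
urban (1b), timber plantations (2), smallholder croplands (3a/4a — the
shared low-intensity endpoint of both cultivated continua), tree croplands
(3b), intensive croplands (4b), strictly protected areas (5), near-natural
lands (6a) and intensive rangelands (6b). These fold into six broad
classes; four (settlement, tree crops, crops, untransformed) span an
intensity continuum between a low- and a high-intensity specific land use.

`allocate_land_use()` applies a priority decision tree: settlement first,
then timber, tree crops, crops, then protected; anything unclaimed is
unprotected untransformed land. Because protection is evaluated *after* the
transformed classes, cultivated or built land inside a reserve is never
labelled protected — the allocation deliberately treats such reserves as
ineffective. The numeric thresholds (population density, cover fractions)
are configuration data, not code: they ship in
`inst/extdata/allocation_config.yaml` with documented defaults and are
expected to be revised against whichever input layers a study uses.
Protection itself enters as a precomputed 0/1 layer (strict categories
I–III, with any per-country overrides applied when that layer is built).

## Intensity

Within each continuum class, each configured pressure proxy is minmax
scaled over the class's pixels, the scaled proxies are averaged per pixel,
and the average is minmax-rescaled, so $\theta = 0$ and $\theta = 1$ are the
least and most intensive pixels of the class. Unbounded proxies (population
density, livestock density, nitrogen input) are capped at their 90th
percentile before scaling so single outliers cannot compress everyone else
to zero; the quantile is the linear-interpolation (R type 7) definition,
stated explicitly because quantile conventions differ. Constant input maps
to all zeros — the least-intensive value — rather than NaN, keeping
$\theta$ defined everywhere. `scale_minmax()` is idempotent and invariant
under positive affine transforms, both property-tested.

Livestock density means different things in different environments: an
animal load that degrades a dry, dystrophic landscape is unremarkable in a
mesic, eutrophic one. Before scaling, `contextual_bin()` groups pixels into
comparable sets by mean annual rainfall in half-open 400 mm bins
($[0,400), [400,800), \dots$ — the half-open convention is ours; only the
bin width is inherited) crossed with soil-nutrient class (high/medium/low),
and livestock density is minmax-scaled within each bin.

Pixel intactness interpolates linearly between the class's endpoints,
applied identically to the mean and both bounds:
$I(\theta) = (1-\theta)\,I_{\mathrm{low}} + \theta\, I_{\mathrm{high}}$, so
$\theta = 0$ reproduces the low-intensity score row exactly and
$\theta = 1$ the high-intensity row (bit-equality is tested).

Supporting raster plumbing: `resample_overlap()` moves variables between
grid resolutions, summing land-cover fractions (mass-conserving) and
overlap-weighted-averaging everything else; `impute_missing()` fills gaps
from the nearest provided pixel (Euclidean distance in grid coordinates,
ties broken by row-major donor order, a deterministic rule chosen so runs
are bit-reproducible).

## Richness tables

Vertebrate richness is a count: species lists per ecoregion (range
polygons intersected with the ecoregion layer — any overlap counts, with an
area-fraction option; or a precomputed membership table), each species
mapped to exactly one group. Large-mammal groups are scored at species
level; their mapping target is the species' own identifier, so they receive
richness 1 wherever present. Plant richness is proportional: the share of
each broad plant group (graminoids by family — Poaceae, Cyperaceae,
Juncaceae, Restionaceae, taking precedence over growth form; trees/shrubs
by growth form tree, shrub, liana, epiphyte; forbs by herb, shrublet, vine)
in the biome's flora, times the ecoregion's total vascular-plant richness.
Mosaic ecoregions average the two biomes' proportion vectors and
renormalise — the renormalisation is our own symmetric extension of the
mosaic score-averaging rule, flagged as an assumption. Conservation
($\sum_i R_i$ equals the total) is asserted in tests. Ecoregions with no
species of a subset yield *undefined* pixels, excluded from zonal means —
reporting 0 would claim total loss where there are simply no species to
lose.

## Zonal summaries and the contribution decomposition

`contribution_decomposition()` splits each pixel into remaining
$\min(\mathrm{BII}, 1)$ and lost $\max(0, 1-\mathrm{BII})$ intactness. The
caps matter: group scores above 1 would otherwise produce negative loss,
and capping both sides makes remaining + lost = 1 per pixel so the three
share columns (extent, remaining, lost) each sum to 1 within a zone — an
invariant asserted on every run. Whether to cap is a genuine choice the
index definition leaves open; we cap, prominently, because the
decomposition is meaningless otherwise. A zone that has lost nothing
reports zero lost shares and a flag rather than 0/0. Strata split the four
continuum classes at $\theta = 0.25$ (low below, medium–high at or above;
the boundary value goes up).

## Corroboration statistics

Three structural checks, all on synthetic data with known truth (external
pressure layers are not bundled):

* `spearman_vs_index()`: rank correlation (average-rank ties) of
  ecoregion-mean BII against an external index; intactness should fall as
  mapped pressure rises.
* `hotspot_test()`: two-sided Mann–Whitney U comparing hotspot vs other
  ecoregions. The U statistic uses average-rank tie handling; p is exact by
  complete enumeration up to a combined n of 12 (extremeness measured by
  $\min(U, n_1 n_2 - U)$, which remains valid under ties) and a
  tie-corrected normal approximation with continuity correction beyond;
  both methods are exposed. The switch point is ours — the enumeration is
  exact wherever it is feasible.
* `threat_category_model()`: the Gaussian mixed model
  `bii ~ iucn_category + range_scaled + (1 | class/group_id)`, fitted by
  REML, with random intercepts for taxonomic class and for functional
  group nested in class. Data-deficient and extinct species are excluded
  (and counted); range size is scaled and centred; LC is the reference
  level; the category effect gets a Satterthwaite omnibus F and all ten
  pairwise contrasts are Tukey-adjusted. REML is stated explicitly because
  omnibus tests differ under ML. Singular fits are reported with a warning,
  never silently dropped.

## The synthetic-data generators

`bii_scenario()` fixes everything: landscape (grid size, class mixture,
per-class $\theta$ distribution, ecoregion bands with biomes and mosaics),
scores (truth table, expert count, noise sd) and species records. Every
generator is a pure function of the scenario seed, restores the session RNG
state, and round-trips through the package's file formats.

Design choices that make the generators usable as oracles:

* **Exact quota composition.** Classes are assigned by largest-remainder
  quota, not sampled, so the landscape composition is exactly the
  configured mixture and expected BII has a closed form; a multinomial
  sampling mode exists behind a flag for stochastic tests.
* **Quantile-assigned intensity.** Continuum pixels receive
  $\theta_j = F^{-1}((j-\tfrac12)/m)$ over the $m$ pixels of a class.
  Because the interpolation is linear in $\theta$, expected BII depends on
  the $\theta$ distribution only through its mean; midpoint quantiles
  reproduce that mean *exactly* for point-mass and uniform laws, and to
  discretisation error (shrinking with class size) for Beta laws, which is
  why the machine-precision pipeline-vs-oracle tests use point/uniform
  intensities and Beta landscapes are checked at a coarser tolerance
  ($10^{-3}$ at a 60×60 grid).
* **Independent expectation.** `expected_bii()` evaluates
  $\sum_e w_e \sum_c w_c\,[(1-\bar\theta_c)\,s^{\mathrm{low}}_{ec} +
  \bar\theta_c\, s^{\mathrm{high}}_{ec}]$ directly from the truth table and
  richness, sharing no code with the map engine.

Default conditions (chosen once, as the study conditions the generators
emulate): 10 experts per combination with sd 0.1 estimation noise; class
mixture 80% untransformed, 13% crops, 6% protected and traces of
settlement, timber and tree crops; right-skewed Beta(1, 4) intensity in all
four continuum classes (non-intensive use is more common than intensive
use); truth intactness anchored at realistic per-land-use levels (strictly
protected 0.95, near-natural 0.85, intensive rangeland 0.51, smallholder
cropland 0.54, intensive cropland 0.26, tree cropland 0.38, settlement
0.45/0.20, timber 0.29) with seeded per-group (sd 0.06) and per-biome
(sd 0.03) offsets clipped to (0, 2). Expert noise is clipped to $[0,2]$;
truth values sit well inside the interior, so clipping bias is negligible
at sd 0.1. Species records use category effects (LC 0, NT −0.05, VU −0.10,
EN −0.15, CR −0.30), a range-size slope of 0.02 on the log scale, and
variance components of 0.05 (class), 0.05 (group) and 0.08 (residual).

What the generators do *not* emulate: spatial autocorrelation of real land
use, systematic (shared) expert bias, taxonomic gaps in range maps, or
correlated errors between the BII and external indices. Passing tests
therefore demonstrate that the pipeline computes its definitions correctly
and recovers known structure — not that a real elicitation is unbiased.

## Problem sizes and runtime choices

The bundled analysis runs a 60×60-pixel landscape with 3 ecoregions and 11
functional groups (153 score combinations), and a 48×48 landscape with 24
ecoregions for the rank-based checks; the species model uses 1,000
simulated species. These sizes give stable estimates while keeping the full
workflow and test suite fast. Property tests use 20–1,000 replicates per
invariant; the coverage study uses 500 expert-noise replicates on a fixed
landscape.

## Known limitations

* Grids are in-memory matrices with CSV serialisation; geometry is a
  simple pixel-registered, equal-area record. Continental 1-km production
  runs would want a tiled raster backend.
* Decision-tree thresholds and proxy sets ship as illustrative defaults;
  they must be calibrated against real input layers before any empirical
  use.
* The polygon rasterizer handles simple polygons and multipolygons by
  pixel-centre membership; holes are not supported and zones must
  partition the domain.
* Mosaic handling averages exactly two biomes; ecoregions spanning three
  or more biomes are not representable.
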