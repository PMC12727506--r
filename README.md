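# biimapr

Expert-based Biodiversity Intactness Index (BII) mapping for regional
assessments.

Regional biodiversity assessments in data-poor regions often cannot rely on
field abundance data. An alternative is structured expert elicitation:
experts estimate, for functional response groups of species, the fraction
of reference population abundance remaining under each characteristic land
use. `biimapr` turns such expert score tables — together with land-use and
intensity grids and per-ecoregion species richness — into per-pixel BII
maps with uncertainty bounds, zonal summaries, and a decomposition of where
intactness remains and where it has been lost. It is aimed at
conservation-macroecology analysts building or auditing such assessments,
and ships a synthetic-data module with closed-form expected outputs so the
entire pipeline can be run and verified offline.

## The index

Per pixel, with richness $R_i$ of functional response group $i$ in the
pixel's ecoregion and intactness score $I_{ik} \in [0,2]$ of that group
under the pixel's land use $k$:

$$\mathrm{BII}_{\mathrm{pixel}} = \frac{\sum_i R_i I_{ik}}{\sum_i R_i},
\qquad
\mathrm{BII}_{\mathrm{area}} = \frac{1}{n} \sum_{\mathrm{pixels}}
\mathrm{BII}_{\mathrm{pixel}}.$$

Scores are expert means per (group, land use[, biome]) with 95% t
confidence bounds that propagate linearly to per-pixel lower/upper BII
limits. On the four land-use classes with an intensity continuum
(settlements, tree crops, crops, untransformed land), the score
interpolates between the class's low- and high-intensity endpoints:
$I(\theta) = (1-\theta) I_{\mathrm{low}} + \theta I_{\mathrm{high}}$, where
$\theta \in [0,1]$ is a per-pixel intensity built from minmax-scaled
pressure proxies (capped at the 90th percentile for unbounded variables;
livestock density scaled within rainfall-by-soil contextual bins).

## Worked example

The numbered scripts under `analysis/` run the full workflow on the bundled
synthetic scenario (a 60×60-pixel landscape, 3 ecoregions including one
biome mosaic, 11 functional groups, 10 experts per score combination):

```sh
Rscript analysis/01_simulate_inputs.R    # synthetic study inputs -> results/data/
Rscript analysis/02_aggregate_scores.R   # expert means + 95% CIs
Rscript analysis/03_map_landuse.R        # decision-tree allocation + intensity
Rscript analysis/04_compute_bii.R        # BII maps per taxon subset
Rscript analysis/05_summarize.R          # zonal + contribution tables
Rscript analysis/06_validate.R           # corroboration statistics
```

Stage 4 prints the regional assessment (percent, with propagated 95%
bounds):

```
      subset bii_pct lower_pct upper_pct
         all    82.8      76.2      89.3
 vertebrates    81.1      74.6      87.5
      plants    82.9      76.3      89.4
```

meaning that across the synthetic region, indigenous populations retain on
average 82.8% of their reference abundance (the generating truth for this
landscape is 83.8%; the gap is one draw of expert estimation noise).
Stage 5 prints the contribution analysis — which land uses hold the
remaining intactness and which drove the losses:

```
      land_use extent remaining lost
          crop   13.0       9.2 31.4
     protected    6.0       7.3  0.0
    settlement    0.4       0.2  1.1
        timber    0.3       0.1  1.0
     tree_crop    0.3       0.2  0.6
 untransformed   80.0      83.0 65.9
```

Read: croplands cover 13% of the region but account for 31% of all lost
intactness, while unprotected untransformed land holds 83% of what remains
— each column sums to 100%. Stage 6 fits the threat-category mixed model
`bii ~ iucn_category + range_scaled + (1 | class/group_id)` on 1,000
simulated species and recovers the generating category effects (e.g.
CR −0.277 ± 0.012 against a simulated −0.30).

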