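# pikathresh

Quantifying how alpine grassland vegetation responds to plateau pika
(*Ochotona curzoniae*) disturbance, and where the disturbance threshold
lies.

Plateau pikas are burrowing small herbivores of the Qinghai–Tibet Plateau
whose density — proxied in the field by counts of *effective* (active)
burrow entrances per hectare — acts as a disturbance gradient on the
surrounding plant community. Alpine meadow (AM) and alpine steppe (AS)
respond very differently: diversity typically rises, peaks, then falls
along the gradient (the intermediate-disturbance pattern), and the density
at which the fitted response peaks is a natural management threshold.
`pikathresh` packages that entire analysis chain for plot/quadrat survey
data, for community ecologists and rangeland managers who need
type-specific pika control targets rather than a single uniform standard.

## What it computes

Given per-quadrat species abundances (with edibility flags), cover, height,
biomass, and per-plot effective burrow density and coordinates:

* **Community metrics** — Shannon–Wiener diversity `H = −Σ pᵢ ln pᵢ`
  (nats), species richness (quadrats pooled per plot), proportion of edible
  forage, and plot means of the structural metrics.
* **Grassland health index (GHI)** — `GHI = Σ vᵢ wᵢ` over the seven
  min–max standardized indicators `vᵢ` (VC, AB, EH, CH, SR, HB, SW; EH
  reversed, since more burrows mean less health), with weights `wᵢ` derived
  from a PCA of the indicator correlation matrix (variance-explained ×
  |loading| over Kaiser-retained components), plus KMO and Bartlett
  sphericity adequacy diagnostics. Plots are classified into disturbance
  levels I–IV (no significant → heavy) by Ward clustering of the scores.
* **Disturbance thresholds** — loess (tricube local polynomial) curves of
  Shannon diversity and richness against burrow density; each curve's peak
  density is a candidate threshold, and the adopted threshold is the
  *minimum* candidate (conservative rule), reported as
  "negligible-difference" instead when candidates agree within 0.5%.
* **Relative change rates** — percentage change of each metric at the
  highest-density stratum relative to the level-I (least disturbed) state.
* **Spatial/permutation statistics** — haversine distance matrices,
  distance-based Moran's eigenvector maps (dbMEM), Moran's I, seeded
  permutation Mantel tests screening spatial/climate/soil/disturbance
  predictors of diversity, and Wilcoxon rank-sum comparisons.
* **Synthetic surveys** — a fully seeded generator emulating the 30 AM +
  26 AS plot / 3 quadrat design with configurable hump-shaped responses, so
  the whole pipeline is testable without field data.

## Worked example

```r
library(pikathresh)

survey <- generate_survey(generator_config(seed = 2024))
ind    <- plot_indicators(survey)

am <- ind[ind$type == "AM", ]
ghi_analysis(am)
#> Grassland health index (30 plots)
#>   KMO = 0.801  Bartlett chi2 = 247.11  (p = <2e-16 )
#>   weights:
#>     SW     SR     AB     CH     VC     HB     EH
#> 0.1308 0.1423 0.1207 0.1544 0.1553 0.1403 0.1561
#> levels
#>   I  II III  IV
#>   5  16   4   5
```

The KMO of 0.80 says the indicator correlations are adequate for PCA
weighting; the seven weights are near-uniform because every indicator loads
on the retained components; and Ward clustering of the scores splits the 30
meadow plots into the four disturbance levels.

```r
extract_thresholds(am)
#> Threshold decision (AM)
#>   candidates: SW 643.5, SR 701.8
#>   adopted: 643.5 holes/ha  [ conservative ]

extract_thresholds(ind[ind$type == "AS", ])
#> Threshold decision (AS)
#>   candidates: SW 311.7, SR 287.4
#>   adopted: 287.4 holes/ha  [ conservative ]
```

The fitted Shannon and richness peaks are the candidate thresholds; the
lower one is adopted so that both diversity dimensions are still protected.
The steppe threshold sits far below the meadow one — steppe communities
degrade at burrow densities meadows tolerate — which is exactly the
type-specific management message the analysis is built to deliver. The whole
chain (index → levels → thresholds → change rates → Mantel screen) runs as
one call: `run_pipeline(pipeline_config(seed = 1, out_dir = "out"))`.

A thin command-line front end is included:

```sh
Rscript inst/scripts/pikathresh.R run --seed 42 --perms 999 --out out/
```

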