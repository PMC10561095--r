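# epirisknet

Regional epidemic risk classification on directed weighted networks.

When a new infectious disease emerges, the regions of the affected area
need to be graded quickly into high, medium and low risk so that
prevention and control measures can be targeted. `epirisknet` implements a
deterministic, one-shot grading method for analysts and public-health
modellers:

* **Network model.** Regions are nodes of an undirected weighted network;
  each edge carries a correlation strength *L*<sub>m,s</sub> ∈ [0, 1]
  measuring how strongly an epidemic in region *m* would be felt in
  region *s*. A seeded preferential-attachment generator
  (`generate_scale_free()`) produces scale-free topologies with attachment
  probability *P*(*k*<sub>s</sub>) = *k*<sub>s</sub> / Σ<sub>m</sub>*k*<sub>m</sub>.
* **CRITIC weighting.** Correlation strengths are derived from raw
  per-pair indicators (distance, personnel flow, economic traffic,
  transport convenience, logistics intensity) via the CRITIC objective
  weighting method: each indicator is min–max normalised, scored by its
  dispersion *P*<sub>i</sub> and conflict
  *R*<sub>i</sub> = Σ<sub>j</sub>(1 − *r*<sub>ij</sub>), and weighted by
  *w*<sub>i</sub> = *P*<sub>i</sub>*R*<sub>i</sub> / Σ*P*<sub>j</sub>*R*<sub>j</sub>;
  then *L*<sub>m,s</sub> = Σ<sub>i</sub> *w*<sub>i</sub> *s*<sub>i(ms)</sub>.
* **Risk propagation.** Outbreak regions get risk *p* = 1. Other regions
  are layered by shortest-path distance to the nearest outbreak, edges are
  oriented down the layers, and risk attenuates along them:
  *p*<sub>s</sub> = *p*<sub>m</sub>*L*<sub>m,s</sub> for a single parent, and
  *p*<sub>s</sub> = Σ<sub>n</sub> *p*<sub>n</sub>*l*<sub>n</sub>*L*<sub>n</sub>
  with *l*<sub>n</sub> = *L*<sub>n</sub>/ΣL for several. Same-layer "loop"
  edges are resolved by a documented two-pass rule (see the vignette).
* **Classification.** Each region is graded high (*p* ≥ 0.7), medium
  (0.4 ≤ *p* < 0.7) or low, thresholds configurable, with half-up rounding
  to 2 decimals before comparison.

## Worked example

```r
library(epirisknet)

bm  <- benchmark_network(1)          # bundled 50-region benchmark, group 1
fit <- epirisk(bm, sources = 1)      # outbreak at region 1
summary(fit)
#> Regional epidemic risk classification
#>   network : 50 regions, 52 edges
#>   sources : 1
#>   levels  : high 2 | medium 11 | low 37
#> Risk thresholds: high >= 0.7, medium >= 0.4, low below
#>   rounding: 2 dp
#>
#> Risk report (high >= 0.7 | medium >= 0.4 ):
#>   high     2  1 2
#>   medium  11  4 5 6 8 9 14 15 22 25 26 27
#>   low     37  3 7 10 11 12 13 16 17 18 19 20 21 23 24 28 29 30 31 32 ...
#>
#> Layers: 4 (max); unreached regions: 0
```

Region 2 sits directly beside the outbreak, so its risk equals the edge's
correlation strength, 1 × 0.7117 = 0.7117 — high. Region 22, two steps
out, gets 0.7117 × 0.8179 = 0.5821 — medium. With two simultaneous
outbreaks the multi-parent rule combines contributions:

```r
fit2 <- epirisk(bm, sources = c(1, 22))
risk_values(fit2)[c("2", "8")]
#>         2         8
#> 0.7684867 0.8328000
```

The full pipeline — raw indicators → CRITIC weights → network → risk →
levels — is available as `run_pipeline()` from a JSON config, and as a
thin command-line wrapper:

```sh
Rscript inst/cli/epirisknet.R run --edges inst/extdata/group1_edges.csv --sources 1,22
Rscript inst/cli/epirisknet.R reproduce --group 1 --case 2
```

Synthetic indicator data for experiments come from
`generate_synthetic_indicators(h, seed)`; see the vignette
(`vignettes/regional-risk-classification.Rmd`) for the model details, the
loop-node rule, and a documented inconsistency in the group-2 benchmark
reference lists.

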