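# dyadMove

Spatial–social analysis of simultaneously radio-tracked animal dyads.

Field studies of nocturnal, pair-living mammals (sportive lemurs are the
motivating case) ask two linked questions about a male and a female that
share a range: *statically*, how much do their home ranges overlap, and
*dynamically*, do their simultaneous positions show attraction, avoidance,
or independent movement? `dyadMove` implements that full analysis for
planar telemetry data — dusk-to-dawn focal follows of both pair members by
two observers — plus the sleeping-site and social-interaction tallies that
complete the picture of a "dispersed pair" social organization. Because
such raw telemetry is rarely deposited, the package also ships a coupled
movement simulator that generates study-shaped data with known
attraction/avoidance, so every stage is testable end to end.

## Methods at a glance

* **Home ranges.** Fixed-kernel utilization distributions on a regular
  grid (fixes subsampled to 5-min intervals), bandwidth from the bivariate
  reference rule h = σ_pooled · n^(−1/6) with *ad hoc* shrinkage: the
  smallest multiplier c ∈ {1.0, …, 0.1} of h whose 95% isopleth remains a
  single connected region. Range = 95% isopleth polygon, area in ha; a
  minimum convex polygon is the fallback for sparse single nights.
* **Static overlap.** Directional percent overlap,
  100·area(A∩B)/area(A), via exact polygon clipping; pair overlap and
  same-sex neighbor overlap (neighbors = ranges within 50 m).
* **Dynamic interaction.** Three complementary tests per dyad:
  * random gas encounter model, f = (4ρv/π)(2d + s);
  * Hutchinson's instantaneous-sampling correction, f = Nρπd²;
  * Doncaster's contingency test: the N observed simultaneous distances
    against all N² cross-pairings, below/above d, χ² with df = 1.

  Here ρ = 1/(pair's union 95% range, m²), v = mean distance covered per
  observation period, d = 15 m, s = 0 by default. Observed-vs-expected
  values are compared across dyads by an **exact** Wilcoxon signed-rank
  test (full enumeration of sign assignments). Proximity time (% of
  aligned fixes within 10/15/20 m) supports cross-study comparison.
* **Social metrics.** Interaction events classified agonistic (chase,
  charge, bite, grab, flee, displace, jump_away), affiliative (groom or
  ≤1 m) or neutral (≤5 m); rates per in-sight hour per dyad.
  Sleeping-site records tallied into exclusive/shared trees and days of
  simultaneous use.
* **Simulator.** Each animal is a discrete Ornstein–Uhlenbeck walk around
  its own range center; within a perception radius each step gains η
  meters along the partner direction (η < 0 avoidance). The `"paper"`
  preset emulates a 7-dyad, 8-night study with female ≈ 0.18 ha and male
  ≈ 0.33 ha ranges, high pair but near-zero neighbor overlap, avoidance
  coupling, zero simultaneous tree-sharing, and ~0.14 interactions/h.

## Worked example

```r
library(dyadMove)

study <- simulateStudy(simConfig("paper"), seed = 1)
d1 <- study$dyads[[1]]

hrM <- homeRange(d1$male)    # 5-min subsample -> ad hoc kernel -> 95% isopleth
hrF <- homeRange(d1$female)
hrM
#> RangePolygon 'm1': 95% isopleth, 1 ring(s), 0.3566 ha
hrF
#> RangePolygon 'f1': 95% isopleth, 2 ring(s), 0.1737 ha

percentOverlap(hrF, hrM)
#>   id_a id_b pct_a_in_b pct_b_in_a area_a_ha area_b_ha
#> 1   f1   m1       98.7       47.8     0.173     0.357

rep1 <- dyadInteraction(d1$series, hrM, hrF, d1$male, d1$female, nights = 8)
#> gas:        observed 34.75 vs expected 16.95 encounters/night
#> hutchinson: observed 601 vs expected 1039.6 associations
#> doncaster:  chi2 = 16.68, p = 4.43e-05, direction = avoidance
#> proximity:  3.8% within 10 m, 23.0% within 20 m

sleepingTally(study$sleep, study$pairs)[1, c("shared_trees",
                                             "simultaneous_days")]
#>   shared_trees simultaneous_days
#> 1            2                 0
```

The female range is the smaller one and sits almost entirely inside the
male's (98.7% vs 47.8%) — the directional asymmetry expected when ranges
are nested. The three dynamic tests disagree by design: the ballistic gas
model *underestimates* encounters for tortuous, discretely sampled paths
(observed 34.8/night vs 17.0 expected), while Hutchinson's
point-sampling model, which is calibrated for instantaneous fixes, shows
fewer associations than chance (601 vs 1039.6) — active avoidance, which
Doncaster's per-dyad test confirms (χ² = 16.7, avoidance). Despite two
shared sleeping trees, the partners never slept in one simultaneously.

The same pipeline runs from the shell:

```sh
inst/scripts/dyadmove simulate --out sim --preset paper --seed 1
inst/scripts/dyadmove analyze --trajectories sim/trajectories.csv \
    --sleeping sim/sleeping.csv --interactions sim/interactions.csv \
    --hours sim/dyad_hours.csv --out results/run1
```

writing `ranges.geojson`, `overlap_pairs.tsv`, `overlap_neighbors.tsv`,
`dyads.json`, `sleeping_tally.tsv`, `interaction_rates.tsv` and a
parameter log.

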