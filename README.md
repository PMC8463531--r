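# funscape

Microbial communities can be treated as dynamical systems: their
*functional composition* — the relative abundances of the gene functions
(KEGG orthologs, GO terms) carried by a community — moves on a landscape
that may hold several discrete, locally stable configurations.  Whether
such **metastable attractors** exist, whether hosts' communities succeed
toward them over time, and whether simple pairwise species interactions
are enough to generate them are central questions for microbiome
ecology, host–microbiota inheritance and animal breeding.

`funscape` is an R package for researchers who have sample-by-function
(or sample-by-taxon) abundance tables and want to answer those
questions.  It provides:

* **Landscape analysis** — Jensen–Shannon divergence between samples,
  JSD(p, q) = H((p+q)/2) − (H(p) + H(q))/2 in bits; principal
  coordinate analysis with relative-eigenvalue reporting; the **Mapper**
  algorithm on the first two principal coordinates (15 intervals per
  axis, 70 % overlap, 10 histogram bins by default); and attractor/basin
  detection from a k-nearest-neighbour density potential on the Mapper
  graph, with occupancy summaries across generations, timepoints or any
  metadata grouping.
* **Community simulation** — an individual-based stochastic simulator
  with compiled inner loops: the neutral Hubbell model and the
  self-organized instability (SOI) model with a pairwise interaction
  matrix (connectivity, positive-edge-percentage cap, per-species
  migration probabilities), with shared interaction matrices and fixed
  founders per parameter combination.
* **Beta-diversity statistics** — classic Morisita overlap
  C = 2Σxᵢyᵢ / ((λₓ + λᵧ)XY) on disjoint random replicate pairs, gamma
  GLMs with an inverse link, AICc = −2ℓ + 2k + 2k(k+1)/(n−k−1) model
  ranking with Akaike weights, and scaled-deviance tests between nested
  models.
* **Synthetic data generators** — cross-sectional, longitudinal and
  multi-generation tables with *known* attractor structure, so the full
  chain is testable without any external download.

## Worked example

Plant three archetypal functional profiles, sample 100 noisy communities
around each, and recover the attractors:

```r
library(funscape)

spec <- synthetic_spec(K = 3, F = 200, n_per_group = 100,
                       concentration = 1000, seed = 42)
xs <- sample_cross_sectional(spec)

D     <- jsd_matrix(xs$table)        # 300 x 300 Jensen-Shannon divergences
ord   <- pcoa(D)
glance(ord)
#> # A tibble: 1 × 4
#>   n_samples n_axes pco1_pct pco2_pct
#>       <int>  <int>    <dbl>    <dbl>
#> 1       300    148     49.9     49.9

graph <- prune_singletons(mapper(ord, D))
part  <- find_attractors(graph, D)
part
#> <attractor_partition> 3 attractor(s); 300/300 samples assigned (knn_k = 18)

occupancy_summary(part, xs$labels, "archetype")
#> # A tibble: 3 × 3
#>   attractor archetype      n
#>   <chr>     <chr>      <int>
#> 1 A1        archetype1   100
#> 2 A2        archetype3   100
#> 3 A3        archetype2   100
```

The two leading principal coordinates each carry ~50 % of the variance
(three equidistant archetypes), the Mapper graph resolves exactly three
attractors, and every sample's basin matches its generating archetype.

Model-selection arithmetic works on published summaries too: a model
with log-likelihood 618.674 and 3 parameters fitted to 2025 pairs has

```r
aicc(618.674, k = 3, n = 2025)
#> [1] -1231.336
akaike_weights(c(0, 0.85, 1.77, 2.38, 3.23))
#> [1] 0.38916625 0.25442514 0.16061443 0.11839265 0.07740154
```

i.e. AICc ≈ −1231.3 and an Akaike weight of 0.389 for the best model —
the support for a connectivity-only model against its four competitors.

The simulation study runs end to end with
`run_simulation_workflow(out_dir, seed = 1)` (3 connectivities × 3
fixed-founder counts × 450 replicates of 600 timesteps, then pairing,
Morisita, AICc ranking and the nested deviance test), and
`run_landscape_workflow()` does the same for the landscape chain on any
abundance table; both write self-describing run directories
(distance/ordination tables, GraphML Mapper graph, attractor JSON,
occupancy TSVs, resolved configuration and log).  A thin command-line
wrapper lives at `inst/cli/funscape.R`.

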