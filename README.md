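# fctopo — graph invariants of functional neocortical circuit topologies

`fctopo` analyzes spontaneous population activity in large neocortical
recordings as directed, weighted graphs and extracts **graph invariants** —
properties unchanged by relabeling the neurons — so functional circuitry can
be compared across slices, animals and cortical areas. It is written for
systems neuroscientists working with event-structured spike rasters from
wide-field two-photon imaging (hundreds of cells, ~1 mm fields of view,
~86 ms frames).

## The model

Given a spike raster segmented into *circuit events* (epochs > 500 ms of
population spiking bounded by quiescence; ≥ 4 events for a field of view to
be included), the functional topology has an edge A → B whenever B fired in
the frame after A within one event, weighted by the number of such lag-1
coincidences normalized to the event count:

    w(A→B) = #{ t : A fires at t, B fires at t+1, both frames in one event } / n_events

On this graph `fctopo` computes:

- **Eigenvector centrality** — the Perron eigenvector of the adjacency
  matrix A (power iteration, out-convention: λ vᵢ = Σⱼ wᵢⱼ vⱼ), with
  log-normal/normal distribution fits for centrality and degree scores.
- **Normalized algebraic connectivity** — λ₂(L)/n for L = D − W of the
  symmetrized graph; positive iff the circuit is connected (1 = complete).
- **Walk counts** via matrix powers — open sequences Σ_{i≠j}(Aᵏ)ᵢⱼ (lengths
  1–10) and closed sequences tr(Aᵏ) (lengths 2–10), their O–C ratio, and the
  slope/R² of the log-linear growth curves.
- **Null-model capture** — spatially matched random (p = 0.5) and k-nearest
  neighbors (k = 10) topologies, with P(data edge | null edge) via Bayes'
  rule, plus reciprocal-connection percentages.
- **Spatial statistics** — connection-distance distributions, laminar
  between/within fractions, polar flow maps with circular variance
  (1 − mean resultant length), FOV-error curves P(distance > d | edge),
  minimum field of view for < 10 % error, connectivity surfaces over FOV ×
  weight threshold, and cumulative neuron density.

A synthetic generator (`sample_positions`, `sample_ground_truth`,
`simulate_raster`) produces cell maps, distance-dependent ground-truth
circuits and propagating event rasters with known connectivity, so the whole
pipeline is testable without recordings.

## Worked example

```r
library(fctopo)
cfg     <- sim_config(n_cells = 700, n_events = 10, seed = 42)
cellmap <- sample_positions(cfg)
circuit <- sample_ground_truth(cellmap, seed = 43)
sim     <- simulate_raster(circuit, cfg)
events  <- detect_events(sim$raster)          # 10 events, field included
topo    <- build_topology(sim$raster, events, cellmap)
print(topo)
#> <functional_topology> 700 cells, 36768 edges, 10 events, with cell map
invariant_report(topo)
#> <invariant_report> 700 cells, 36768 edges (100 isolated)
#>   lambda2/n (or): 0.0000
#>   reciprocal pairs: 1.62%
#>   open slope 4.470 (R2 1.0000), closed slope 4.469 (R2 1.0000)
#>   mean O-C ratio (finite lengths): 419.3
capture_probability(topo, knn_topology(cellmap, 10))
#> <capture_result> P(data edge | null edge) = 0.0791 (554 shared / 7000 null; 36768 data edges)
capture_probability(topo, random_topology(cellmap, 0.5, seed = 44))
#> <capture_result> P(data edge | null edge) = 0.0751 (18329 shared / 244088 null; 36768 data edges)
circular_variance(flow_map(topo)$theta)
#> [1] 0.990
min_fov_for_error(fov_error_curve(topo, seq(0, 1100, by = 10)))
#> [1] 790
recovery_auc(topo, circuit)
#> [1] 0.816
```

Reading the output: the simulated field yields ~3.7 × 10⁴ functional edges;
both null models explain only ~8 % of them, so the topology is neither
purely random nor purely local. Walk counts grow exponentially (R² = 1.00)
with ~420 open sequences per closed one; λ₂/n is 0 here because 100 silent
cells remain as isolated nodes (flagged in the report). Flow covers angular
space almost uniformly (circular variance 0.99), a 790 µm field of view
captures > 90 % of connections, and the builder ranks true ground-truth
edges above non-edges with AUC 0.82.

`run_pipeline(run_config(out_dir, ...))` orchestrates all stages end to end
and writes delimited tables plus a JSON summary with seed and config hash;
`inst/scripts/fctopo.R` wraps `simulate` and `report` for shell use.

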