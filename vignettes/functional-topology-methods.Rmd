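---
title: "Methods: functional circuit topologies and their graph invariants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: functional circuit topologies and their graph invariants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fctopo)
```

## The problem

Large two-photon recordings of neocortical slices capture spontaneous
*circuit events*: discrete epochs (longer than 500 ms) in which subsets of
hundreds of neurons fire in a correlated fashion, separated by quiescence.
`fctopo` models the flow of activity in such recordings as a directed,
weighted graph — the *functional topology* — and asks which properties of
that graph are **invariants**: functions of the adjacency matrix unchanged by
any relabeling (permutation) of the neurons. Invariants let circuits from
different animals and cortical areas be compared without matching individual
cells.

The package takes two inputs: a spike raster (cells x frames spike counts
with a frame duration, typically ~86 ms) and a cell map (2-D positions in
micrometers, optional laminar labels, and the in-plane direction of the pia).
No recordings ship with the package; a synthetic generator (below) produces
both inputs with known ground truth so every stage is testable.

## From raster to graph

`detect_events()` segments the raster into circuit events: maximal runs of
frames in which the network is active, kept when they last at least 500 ms.
"Active" is operationalized as at least `min_active_cells` (default 1) cells
spiking in the frame — the threshold is exposed because the raw definition
("the network of cells was active") does not quantify it. Runs separated by
short gaps can be merged via `max_gap_frames`, but merging is off by default
since events are bounded by quiescence. Frames are 0-based and event bounds
inclusive throughout. A field of view enters analysis only with at least 4
events (`validate_fov()`).

`build_topology()` applies the lag-1 edge rule: cell A is functionally
connected to cell B if B fired in the frame after A, with both frames inside
the same event. Firing is binarized per frame, so a double spike in one frame
still counts once. The weight of A -> B is the number of such coincidences
over all events divided by the number of events; weights times the event
count are therefore always integer coincidence counts. Pairs straddling an
event boundary never contribute — real inter-event gaps are quiescent so
this cannot occur in data, but the synthetic edge case is handled explicitly.
Simultaneous (lag-0) firing contributes nowhere; only the one-frame lag is
part of the rule.

## Null models and capture probability

Two spatially matched nulls bound the data from above and below in spatial
constraint (`random_topology()`, `knn_topology()`): each keeps the measured
cell positions and replaces the edges — independent directed edges with
probability 0.5, or a directed edge from each cell to its k = 10 nearest
neighbors. Nulls are unweighted because only edge existence is modeled.
kNN distance ties are broken toward the earlier cell id; ties have measure
zero for continuous synthetic positions but can occur in file-based input.

`capture_probability()` evaluates P(data edge | null edge) via Bayes' rule,
which reduces to shared edges over null edges when both graphs are binarized
at weight > 0. It is 1 exactly when null edges are a subset of data edges.
Both a per-graph value and the counts behind it are returned so that either
per-graph or pooled summaries can be formed.

## Graph invariants

**Eigenvector centrality** (`eigenvector_centrality()`) scores cells by the
Perron eigenvector of the weighted adjacency, normalized to unit Euclidean
norm. The *out-convention* is used — the score of i is proportional to the
weighted sum of scores of the cells i projects to — because the quantity is
meant to capture drive: an upstream neuron that reliably ignites influential
neurons is itself influential, and empirically the measure tracks out-degree,
not in-degree. Implementation is power iteration on the shifted matrix
A + cI (c = max weight): the shift leaves eigenvectors unchanged but makes
the iteration primitive, so periodic graphs (pure cycles) converge instead of
oscillating. If the iteration does not reach a strictly positive fixed point
— the Perron–Frobenius guarantee only holds for irreducible graphs — scores
are computed on the largest strongly connected component, zeros elsewhere,
and flagged `converged = FALSE`. Score distributions are conventionally
summarized by a log-normal fit, degree fractions by a normal fit
(`fit_distribution()`, maximum likelihood, with an approximate one-sample KS
p-value; approximate because the parameters are estimated from the data).

**Algebraic connectivity** (`algebraic_connectivity()`): directed edges are
first made undirected, then lambda_2 of the Laplacian L = D - W is divided by
the number of nodes; positivity is equivalent to connectedness, and the
complete graph attains exactly 1. Three symmetrizations are provided because
"transforming all directed edges to undirected ones" is ambiguous: `or`
(default; keeps every edge, undirected weight = max of the two directions),
`and` (keeps only reciprocated edges), `mean`. The reference value reported
for dense ER nulls (~0.24) is closer to the `and` prediction than to `or`
(~0.7 for unweighted ER at p = 0.5), so neither is asserted as ground truth;
the choice is a flagged parameter. lambda_2 is computed on the full node set:
isolated cells (which force the value to 0) are counted and reported rather
than silently dropped.

**Walk counts** (`count_walks()`): the (i, j) entry of A^k counts walks of
length k, so open sequences (distinct endpoints) are off-diagonal sums and
closed sequences are traces, for lengths 1..10 and 2..10 respectively (a
closed sequence of length 1 does not exist). The adjacency is binarized by
default because the counting theorem concerns unweighted edges; a weighted
variant is exposed for sensitivity analysis. Counts are accumulated in
double precision, which is exact up to 2^53 and overflow-safe far beyond the
sizes used here. `oc_ratio()` forms open/closed per length (infinite when no
closed walks exist, missing when both counts are zero), and
`growth_slope()` fits OLS to natural-log counts versus length — natural logs
rather than base-10 is a constant factor on the slope and documented here
once. For a complete digraph the open counts are
(n-1)((n-1)^k - (-1)^k): geometric only up to O((n-1)^-k), so the fit's R^2
approaches but does not exactly equal 1 even in this extreme case.
`reciprocal_percent()` counts bidirected pairs over all n(n-1)/2 pairs; for
binary graphs it equals trace(A^2)/2 rescaled, which the tests cross-check.

## Spatial statistics

`flow_map()` expresses every edge as (r, theta): source-to-sink distance and
angle in a frame rotated so the pia direction lies at pi/2. Angles are
radians internally; the pia direction is configuration metadata in degrees.
`circular_variance()` is the standard 1 minus the mean resultant length —
0 for perfectly clustered angles, 1 for balanced sets; the per-radius-band
summary (`flow_variance_by_band()`, default 200 um bands) tests whether flow
covers angular space at every spatial scale. The exact band widths of the
original analyses are not specified anywhere, so they are a documented,
configurable default.

FOV error (`fov_error_curve()`) is operationalized as P(distance > d | edge):
the fraction of true functional connections a field of view of size d cannot
resolve, i.e. the probability of falsely characterizing two connected neurons
as independent. The curve is monotone non-increasing, 1 at d = 0 and 0 at the
maximum edge length; `min_fov_for_error()` reads off the smallest evaluated
size with error below 10%. For a uniform-connectivity graph the curve equals
the pairwise-distance survival function exactly, a cross-check in the tests.
`connectivity_surface()` composes FOV restriction (centered discs —
the original sub-field selection is unspecified, so the center is
configurable) with weight thresholding and reports normalized lambda_2 on
each grid cell; `cumulative_density()` converts FOV sizes to expected neuron
counts (0 at d = 0 by convention, excluding the degenerate disc).

## The synthetic generator

`sample_positions()` places cells uniformly in a 1.1 mm disc and labels
laminae by depth bands along the pia axis (defaults 0-100 um L1, 100-400
L2/3, 400-600 L4, deeper L5). `sample_ground_truth()` draws directed edges
with probability `base_prob * ((1 - f) exp(-d/s) + f)` — an exponential
kernel with a distance-independent floor, the simplest shape with a proximal
skew plus occasional distal connections; present edges transmit with
probability `edge_strength` (default 0.5). `simulate_raster()` runs
activity-propagation dynamics at a one-frame lag, deliberately matching the
lag-1 edge rule so ground truth and inferred graphs live on the same support
and parameter recovery is a meaningful test: each event ignites a small
random seed population; thereafter a cell spikes with probability
1 - prod(1 - A[i, j]) over presynaptic cells that spiked in the previous
frame, plus an event-gated background rate (inter-event frames are exactly
quiescent). Three stabilizers keep per-frame participation at realistic
sparse levels instead of letting supercritical percolation saturate the
field: a 1-frame refractory period, a per-event spike budget of 3 (the few
spikes a neuron fires per UP state), and re-ignition of one fresh cell when
an event frame would otherwise fall silent — so event windows stay
contiguously active and detection is unambiguous. With `background_rate = 0`
the dynamics are pure propagation and exactly reproduce deterministic
chains, used by the ground-truth tests.

Defaults were fixed once, scale-matched to the recordings the analysis
targets: 700 cells (reported means 595-734 per area), 86 ms frames, 10
events of 14-18 frames (1.2-1.6 s), and kernel parameters
(`base_prob = 0.017`, `local_scale_um = 150`, `distal_fraction = 0.05`,
background 0.005) chosen so a default field of view yields roughly 3-4 x
10^4 functional edges (the reported median) at ~2% per-frame participation.
What the generator does **not** emulate: calcium-indicator dynamics, imaging
noise and spike-inference errors; firing-rate heterogeneity across cells;
and the full strength of the proximal bias in real connection-distance
distributions — simulated events spread through the field, so synthetic
edge distances are only moderately skewed toward short distances. Passing
tests therefore demonstrate correctness of the graph machinery and
recoverability under the stated generative model, not fidelity of the model
to cortex. Quantities that depend on the empirical geometry of the
recordings (e.g. the printed minimum-FOV values of 583-676 um, or the kNN
and random thresholds of 93 and 884 um) are reproduced only as orderings,
not as numbers.

## Numerical choices and degenerate inputs

Power iteration: tolerance 1e-10 on the max score change, 10,000 iterations,
positivity threshold 1e-12. lambda_2 values within 1e-9 of zero are clamped
to zero before normalization. Histograms close bins on the right with the
left edge of the first bin included. Cells with no spikes remain as isolated
nodes; analyses that become degenerate on them either error with a clear
message (centrality on an empty graph, laminar fractions with no labels,
capture against an edgeless null) or report the degeneracy (isolated-node
counts alongside lambda_2 = 0; missing cells in the connectivity surface).
Distribution fits require at least 8 strictly positive values and reject
constant samples rather than returning a zero scale.

## Problem sizes used by the tests

The shipped test-suite and acceptance script run at desk scale, chosen to
exercise the same regimes as the study while completing in minutes on one
core: ER reciprocity at n = 700 over 20 replicates; walk-growth fits on ten
300-cell simulated fields; exhaustive walk enumeration on all 3-node and
sampled 4/5-node digraphs; Perron-vector comparisons on 100 small strongly
connected graphs; connectivity-theorem checks on 200 random graphs;
parameter recovery at 300 cells and 20 events; and full-scale (700-cell)
fields for the centrality-degree and flow-coverage checks.
```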