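#' Simulation configuration
#'
#' Parameters of the synthetic recording generator. Defaults emulate the
#' experimental regime the analysis targets: ~700 cells in a 1.1 mm circular
#' field of view spanning L1-L5, ~86 ms frames, around ten circuit events per
#' field of view, each lasting roughly 1.2-1.6 s, with quiescent gaps between
#' events.
#'
#' @param n_cells number of cells (default 700).
#' @param fov_diameter_um field-of-view diameter in micrometers (default 1100).
#' @param layer_boundaries_um depths (along the pia->white-matter axis, from
#'   the pial edge of the field of view) separating consecutive laminar bands.
#'   Default `c(100, 400, 600)` for labels L1, L2/3, L4, L5.
#' @param layer_labels labels of the laminar bands, one more than boundaries.
#' @param pia_angle_deg direction toward pia, degrees CCW from +x (default 90).
#' @param frame_duration_ms frame duration in ms (default 86).
#' @param n_events number of circuit events (default 10).
#' @param event_duration_frames integer vector of admissible event durations
#'   in frames; each event samples one uniformly. Default `14:18`
#'   (1204-1548 ms at 86 ms frames).
#' @param gap_frames quiescent frames between events (default 12, ~1 s).
#' @param background_rate per-cell per-frame probability of a spike unrelated
#'   to propagation, active only inside event windows (default 0.005).
#' @param n_seed_cells cells ignited in the first frame of each event
#'   (default `max(3, round(0.01 * n_cells))`).
#' @param refractory_frames frames after a spike during which a cell cannot
#'   spike again (default 1).
#' @param max_spikes_per_event per-cell spike budget within a single event
#'   (default 3), mimicking the few spikes a neuron fires per UP state.
#' @param seed RNG seed making every generator call deterministic.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cells = 700, fov_diameter_um = 1100,
                       layer_boundaries_um = c(100, 400, 600),
                       layer_labels = c("L1", "L2/3", "L4", "L5"),
                       pia_angle_deg = 90,
                       frame_duration_ms = 86, n_events = 10,
                       event_duration_frames = 14:18, gap_frames = 12,
                       background_rate = 0.005,
                       n_seed_cells = max(3L, round(0.01 * n_cells)),
                       refractory_frames = 1, max_spikes_per_event = 3,
                       seed = 1) {
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (n_events < 0) stop("n_events must be >= 0")
  if (background_rate < 0 || background_rate > 1)
    stop("background_rate must be in [0, 1]")
  if (length(layer_labels) != length(layer_boundaries_um) + 1)
    stop("need one more layer label than boundary")
  if (is.unsorted(layer_boundaries_um, strictly = TRUE))
    stop("layer_boundaries_um must be strictly increasing")
  event_duration_frames <- as.integer(event_duration_frames)
  if (n_events > 0 && any(event_duration_frames < 1))
    stop("event_duration_frames must be at least 1 frame")
  structure(
    list(n_cells = as.integer(n_cells), fov_diameter_um = fov_diameter_um,
         layer_boundaries_um = layer_boundaries_um,
         layer_labels = layer_labels, pia_angle_deg = pia_angle_deg,
         frame_duration_ms = frame_duration_ms,
         n_events = as.integer(n_events),
         event_duration_frames = event_duration_frames,
         gap_frames = as.integer(gap_frames),
         background_rate = background_rate,
         n_seed_cells = as.integer(min(n_seed_cells, n_cells)),
         refractory_frames = as.integer(refractory_frames),
         max_spikes_per_event = as.integer(max_spikes_per_event),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Sample cell positions uniformly in the field of view
#'
#' Positions are uniform on a disc of the configured diameter, centered at the
#' origin. Laminar labels are assigned from the depth of each cell along the
#' pia axis: depth 0 is the pial edge of the field of view, and the configured
#' boundaries split depth into consecutive laminar bands.
#'
#' @param config a [sim_config()].
#' @return A [cell_map()].
#' @export
sample_positions <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_cells
  R <- config$fov_diameter_um / 2
  r <- R * sqrt(stats::runif(n))
  th <- 2 * pi * stats::runif(n)
  x <- r * cos(th); y <- r * sin(th)
  a <- config$pia_angle_deg * pi / 180
  depth <- R - (x * cos(a) + y * sin(a))
  layer <- config$layer_labels[findInterval(depth, config$layer_boundaries_um) + 1L]
  cell_map(sprintf("c%05d", seq_len(n)), x, y, layer,
           pia_angle_deg = config$pia_angle_deg,
           fov_diameter_um = config$fov_diameter_um)
}

#' Sample a ground-truth circuit
#'
#' Draws a directed connectivity skeleton whose presence probability decays
#' with pairwise distance but keeps a distance-independent floor, the simplest
#' kernel with the qualitative features of functional cortical wiring: a
#' strong proximal skew plus occasional distal connections. For the ordered
#' pair (i, j),
#' \deqn{P(i \to j) = p_0 \left[(1 - f)\, e^{-d_{ij}/s} + f\right]}
#' with `base_prob` \eqn{p_0}, `distal_fraction` \eqn{f}, `local_scale_um`
#' \eqn{s}. Each present edge carries propagation probability `edge_strength`
#' in the activity model of [simulate_raster()].
#'
#' Defaults are scale-matched to large-field recordings: at ~700 cells they
#' give a mean ground-truth out-degree of a few connections and simulated
#' functional graphs in the tens of thousands of edges.
#'
#' @param cellmap a [cell_map()].
#' @param local_scale_um decay length of the proximal kernel (default 150).
#' @param distal_fraction distance-independent floor fraction in \[0, 1\]
#'   (default 0.05).
#' @param base_prob presence probability at zero distance (default 0.017).
#' @param edge_strength propagation probability of a present edge (default 0.5).
#' @param seed RNG seed.
#' @return A `ground_truth_circuit`: list with `cellmap`, `true_adjacency`
#'   (zero-diagonal matrix of propagation probabilities) and `kernel_params`.
#' @export
sample_ground_truth <- function(cellmap, local_scale_um = 150,
                                distal_fraction = 0.05, base_prob = 0.017,
                                edge_strength = 0.5, seed = 1) {
  stopifnot(inherits(cellmap, "cell_map"))
  if (local_scale_um <= 0) stop("local_scale_um must be positive")
  if (distal_fraction < 0 || distal_fraction > 1)
    stop("distal_fraction must be in [0, 1]")
  if (base_prob < 0 || base_prob > 1) stop("base_prob must be in [0, 1]")
  if (edge_strength < 0 || edge_strength > 1)
    stop("edge_strength must be in [0, 1]")
  set.seed(seed)
  n <- nrow(cellmap)
  d <- as.matrix(stats::dist(cbind(cellmap$x_um, cellmap$y_um)))
  p <- base_prob * ((1 - distal_fraction) * exp(-d / local_scale_um) +
                      distal_fraction)
  diag(p) <- 0
  present <- matrix(stats::runif(n * n) < p, n, n)
  diag(present) <- FALSE
  A <- present * edge_strength
  dimnames(A) <- list(cellmap$cell_id, cellmap$cell_id)
  structure(
    list(cellmap = cellmap, true_adjacency = A,
         kernel_params = list(local_scale_um = local_scale_um,
                              distal_fraction = distal_fraction,
                              base_prob = base_prob,
                              edge_strength = edge_strength)),
    class = "ground_truth_circuit"
  )
}

#' Simulate a circuit-event spike raster
#'
#' Generates activity-propagation dynamics on the ground-truth circuit, not a
#' biophysical model: transmission acts at a one-frame lag so that the
#' generative connectivity and the inferred functional topology live on the
#' same support. Each event ignites a small random seed population; in every
#' subsequent frame of the event, cell j spikes with probability
#' \eqn{1 - \prod_{i\ \mathrm{spiked\ at}\ t-1}(1 - A_{ij})}, combined with an
#' independent background rate that is gated to event windows (inter-event
#' frames are fully quiescent by construction). Two refinements keep per-frame
#' participation at the sparse levels seen in population recordings: a cell
#' cannot spike again within `refractory_frames` frames, and it fires at most
#' `max_spikes_per_event` spikes per event. An event is by definition an epoch
#' in which the network is active, so whenever background spiking is enabled
#' (`background_rate > 0`) and propagation plus background would leave a frame
#' inside an intended event window silent, one fresh cell with remaining spike
#' budget is ignited instead; event windows then remain contiguously active
#' and event detection is unambiguous by construction. With
#' `background_rate = 0` the dynamics are pure propagation, used for
#' deterministic ground-truth checks, and no re-seeding occurs.
#'
#' @param circuit a [sample_ground_truth()] circuit.
#' @param config a [sim_config()]; its `seed` makes output deterministic.
#' @return A list with `raster` (a [spike_raster()]), `events` (the
#'   [detect_events()] segmentation of the generated raster with default
#'   parameters) and `windows` (the intended event windows, a
#'   [circuit_events()] data frame).
#' @export
simulate_raster <- function(circuit, config) {
  stopifnot(inherits(circuit, "ground_truth_circuit"),
            inherits(config, "sim_config"))
  n <- nrow(circuit$true_adjacency)
  if (n != config$n_cells)
    stop("circuit and config disagree on the number of cells")
  set.seed(config$seed)
  gap <- max(config$gap_frames, 1L)
  if (config$n_events == 0) {
    counts <- matrix(0L, n, gap)
    raster <- spike_raster(counts, config$frame_duration_ms,
                           circuit$cellmap$cell_id)
    return(list(raster = raster, events = circuit_events(),
                windows = circuit_events()))
  }
  durations <- config$event_duration_frames[
    sample.int(length(config$event_duration_frames), config$n_events,
               replace = TRUE)]
  starts <- gap + cumsum(c(0L, durations[-length(durations)] + gap))
  total <- starts[length(starts)] + durations[length(durations)] + gap
  counts <- matrix(0L, n, total)
  A <- circuit$true_adjacency
  log1mA <- log1p(-pmin(A, 1 - 1e-12))  # propagation prob 1 maps to ~certainty
  bg <- config$background_rate
  for (e in seq_len(config$n_events)) {
    budget <- rep(config$max_spikes_per_event, n)
    last <- rep(-1e9, n)
    seeds <- sample.int(n, config$n_seed_cells)
    counts[seeds, starts[e] + 1L] <- 1L
    budget[seeds] <- budget[seeds] - 1L
    last[seeds] <- 0
    prev <- logical(n); prev[seeds] <- TRUE
    if (durations[e] > 1) {
      for (t in seq_len(durations[e] - 1L)) {
        eligible <- budget > 0 & (t - last) > config$refractory_frames
        p <- if (any(prev)) {
          1 - exp(colSums(log1mA[prev, , drop = FALSE]))
        } else numeric(n)
        p <- 1 - (1 - p) * (1 - bg)
        fire <- eligible & (stats::runif(n) < p)
        if (!any(fire) && bg > 0) {
          # keep the event window contiguously active: ignite one fresh cell
          cand <- which(budget > 0)
          if (length(cand) > 0) {
            pick <- cand[sample.int(length(cand), 1L)]
            fire[pick] <- TRUE
          }
        }
        if (any(fire)) {
          counts[fire, starts[e] + t + 1L] <- 1L
          budget[fire] <- budget[fire] - 1L
          last[fire] <- t
        }
        prev <- fire
      }
    }
  }
  raster <- spike_raster(counts, config$frame_duration_ms,
                         circuit$cellmap$cell_id)
  windows <- circuit_events(starts, starts + durations - 1L)
  list(raster = raster, events = detect_events(raster), windows = windows)
}

#' Ranking quality of a functional topology against ground truth
#'
#' Area under the ROC curve for ranking ordered cell pairs by functional
#' weight, with ground-truth edges as positives: the probability that a
#' randomly chosen true edge outweighs a randomly chosen non-edge (ties count
#' half). 0.5 is chance; 1 is perfect recovery.
#'
#' @param topology a [functional_topology()].
#' @param circuit the generating [sample_ground_truth()] circuit.
#' @return AUC in \[0, 1\].
#' @export
recovery_auc <- function(topology, circuit) {
  stopifnot(inherits(topology, "functional_topology"),
            inherits(circuit, "ground_truth_circuit"))
  if (!identical(topology$cell_ids, circuit$cellmap$cell_id))
    stop("topology and circuit must share cell ids and ordering")
  n <- length(topology$cell_ids)
  off <- !diag(n)
  w <- topology$weights[off]
  truth <- circuit$true_adjacency[off] > 0
  n_pos <- as.numeric(sum(truth)); n_neg <- as.numeric(sum(!truth))
  if (n_pos == 0 || n_neg == 0) stop("need both edges and non-edges in truth")
  r <- rank(w)
  (sum(r[truth]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
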