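# Fixture builders and independent brute-force oracles used across the suite.

# uniform-disc cell map without going through the generator
make_cellmap <- function(n, seed = 1, fov = 1100, layer = NULL,
                         pia_angle_deg = 90) {
  set.seed(seed)
  R <- fov / 2
  r <- R * sqrt(runif(n)); th <- 2 * pi * runif(n)
  cell_map(sprintf("c%03d", seq_len(n)), r * cos(th), r * sin(th), layer,
           pia_angle_deg = pia_angle_deg, fov_diameter_um = fov)
}

# topology from a bare weight matrix
topo_from_weights <- function(W, cellmap = NULL, n_events = 1,
                              ids = paste0("c", seq_len(nrow(W)))) {
  functional_topology(W, ids, n_events, cellmap)
}

# random binary digraph adjacency (zero diagonal)
rand_digraph <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(as.numeric(runif(n * n) < p), n, n)
  diag(A) <- 0
  A
}

# random strongly connected binary digraph (igraph as the connectivity oracle)
rand_strong_digraph <- function(n, p = 0.4, seed = 1) {
  for (s in seed + 0:200) {
    A <- rand_digraph(n, p, s)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "directed")
    if (igraph::components(g, mode = "strong")$no == 1) return(A)
  }
  stop("no strongly connected graph found")
}

# exhaustive walk enumeration by depth-first search: counts all length-k walks
# independently of matrix powers
enum_walks <- function(A, k) {
  n <- nrow(A)
  counts <- matrix(0, n, n)
  nbrs <- lapply(seq_len(n), function(i) which(A[i, ] > 0))
  rec <- function(start, cur, len) {
    if (len == k) {
      counts[start, cur] <<- counts[start, cur] + 1
      return(invisible())
    }
    for (j in nbrs[[cur]]) rec(start, j, len + 1)
  }
  for (s in seq_len(n)) rec(s, s, 0)
  counts
}

# run-length event segmentation oracle: brute-force scan, no merging
scan_events <- function(active, min_frames) {
  out <- list()
  i <- 1
  while (i <= length(active)) {
    if (active[i]) {
      j <- i
      while (j < length(active) && active[j + 1]) j <- j + 1
      if (j - i + 1 >= min_frames) out[[length(out) + 1]] <- c(i - 1, j - 1)
      i <- j + 1
    } else i <- i + 1
  }
  if (length(out) == 0) return(circuit_events())
  m <- do.call(rbind, out)
  circuit_events(m[, 1], m[, 2])
}

# permute the nodes of a topology (rows+columns, ids, map)
permute_topology <- function(topology, perm) {
  cm <- topology$cellmap
  if (!is.null(cm)) {
    cm <- cell_map(cm$cell_id[perm], cm$x_um[perm], cm$y_um[perm],
                   cm$layer[perm],
                   pia_angle_deg = attr(cm, "pia_angle_deg"),
                   fov_diameter_um = attr(cm, "fov_diameter_um"))
  }
  functional_topology(topology$weights[perm, perm],
                      topology$cell_ids[perm], topology$n_events, cm)
}

# small end-to-end synthetic field of view used by several files
sim_fixture <- function(n = 120, n_events = 6, seed = 5, ...) {
  cfg <- sim_config(n_cells = n, n_events = n_events, seed = seed, ...)
  cm <- sample_positions(cfg)
  gt <- sample_ground_truth(cm, seed = seed + 1)
  sim <- simulate_raster(gt, cfg)
  list(config = cfg, cellmap = cm, circuit = gt, sim = sim,
       topology = build_topology(sim$raster, sim$events, cm))
}
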