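#' Histogram of pairwise cell distances
#'
#' Normalized histogram of the distances between all unordered cell pairs in
#' the field of view; the reference distribution against which connection
#' distances are judged.
#'
#' @param cellmap a [cell_map()] with at least 2 cells.
#' @param bins either a single bin count or a vector of break points covering
#'   the data range. Default: 22 bins of 50 um up to the field-of-view
#'   diameter.
#' @return A `distance_histogram`: list with `breaks`, `mids`, `prob`
#'   (probabilities summing to 1) and `n` (pair count).
#' @export
pairwise_distance_distribution <- function(cellmap, bins = NULL) {
  stopifnot(inherits(cellmap, "cell_map"))
  if (nrow(cellmap) < 2) stop("need at least 2 cells")
  d <- as.numeric(stats::dist(cbind(cellmap$x_um, cellmap$y_um)))
  distance_histogram(d, bins, attr(cellmap, "fov_diameter_um"))
}

#' Histogram of functional-connection distances
#'
#' Normalized histogram of the source-to-sink distance of every directed edge;
#' optionally each edge contributes its weight instead of a unit count.
#'
#' @param topology a [functional_topology()] with a cell map and at least one
#'   edge.
#' @param bins as in [pairwise_distance_distribution()].
#' @param weight_by_edge weight edges by their functional weight
#'   (default `FALSE`).
#' @return A `distance_histogram`.
#' @export
connection_distance_distribution <- function(topology, bins = NULL,
                                             weight_by_edge = FALSE) {
  d <- edge_distances(topology)
  w <- if (weight_by_edge) {
    ed <- topology$weights[topology$weights > 0]
    ed
  } else NULL
  distance_histogram(d, bins, attr(topology$cellmap, "fov_diameter_um"), w)
}

# shared histogram builder; prob sums to 1
distance_histogram <- function(d, bins, fov_diameter, w = NULL) {
  if (is.null(bins)) bins <- seq(0, max(fov_diameter, max(d)) + 50, by = 50)
  if (length(bins) == 1)
    bins <- seq(0, max(fov_diameter, max(d)) * (1 + 1e-9), length.out = bins + 1)
  if (min(d) < min(bins) || max(d) > max(bins))
    stop("bins do not cover the distance range")
  bin <- findInterval(d, bins, rightmost.closed = TRUE, left.open = TRUE)
  bin[d == bins[1]] <- 1L  # left edge of the first bin is included
  counts <- numeric(length(bins) - 1)
  if (is.null(w)) w <- rep(1, length(d))
  for (i in seq_along(d)) counts[bin[i]] <- counts[bin[i]] + w[i]
  structure(
    list(breaks = bins, mids = (bins[-1] + bins[-length(bins)]) / 2,
         prob = counts / sum(counts), n = length(d)),
    class = "distance_histogram")
}

# source->sink Euclidean distance of every directed edge (weights > 0)
edge_distances <- function(topology) {
  stopifnot(inherits(topology, "functional_topology"))
  if (is.null(topology$cellmap)) stop("topology has no cell positions")
  idx <- which(topology$weights > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("topology has no edges")
  cm <- topology$cellmap
  sqrt((cm$x_um[idx[, 2]] - cm$x_um[idx[, 1]])^2 +
         (cm$y_um[idx[, 2]] - cm$y_um[idx[, 1]])^2)
}

#' Laminar composition of functional connections
#'
#' Percentage of directed edges whose endpoints lie in different labeled
#' layers (between), in the same labeled layer (within), or touch at least one
#' unlabeled cell (unassigned). The three percentages sum to 100.
#'
#' @param topology a [functional_topology()] with a layer-labeled cell map and
#'   at least one edge.
#' @return List with `between_percent`, `within_percent`, `unassigned_percent`.
#' @export
laminar_fractions <- function(topology) {
  stopifnot(inherits(topology, "functional_topology"))
  if (is.null(topology$cellmap)) stop("topology has no cell map")
  cm <- topology$cellmap
  if (all(cm$layer == "unknown"))
    stop("all cells are unlabeled; laminar fractions are undefined")
  idx <- which(topology$weights > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("topology has no edges")
  src <- cm$layer[idx[, 1]]
  dst <- cm$layer[idx[, 2]]
  unassigned <- src == "unknown" | dst == "unknown"
  within <- !unassigned & src == dst
  between <- !unassigned & src != dst
  n <- nrow(idx)
  list(between_percent = 100 * sum(between) / n,
       within_percent = 100 * sum(within) / n,
       unassigned_percent = 100 * sum(unassigned) / n)
}

#' Flow map of directed functional connections
#'
#' For every directed edge, the polar coordinates of the source-to-sink
#' displacement relative to the pia orientation: `r` is the Euclidean distance
#' and `theta` the angle in a frame rotated so that the pia direction points
#' to pi/2 ("up"). Angles are in \[0, 2*pi).
#'
#' @param topology a [functional_topology()] with a cell map (whose
#'   `pia_angle_deg` attribute must be set) and at least one edge.
#' @return A `flow_map` data frame with columns `r`, `theta`.
#' @export
flow_map <- function(topology) {
  stopifnot(inherits(topology, "functional_topology"))
  if (is.null(topology$cellmap)) stop("topology has no cell map")
  pia <- attr(topology$cellmap, "pia_angle_deg")
  if (is.null(pia) || !is.finite(pia)) stop("cell map has no pia angle")
  idx <- which(topology$weights > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("topology has no edges")
  cm <- topology$cellmap
  dx <- cm$x_um[idx[, 2]] - cm$x_um[idx[, 1]]
  dy <- cm$y_um[idx[, 2]] - cm$y_um[idx[, 1]]
  r <- sqrt(dx^2 + dy^2)
  theta <- (atan2(dy, dx) - pia * pi / 180 + pi / 2) %% (2 * pi)
  out <- data.frame(r = r, theta = theta)
  class(out) <- c("flow_map", "data.frame")
  out
}

#' Circular variance of a set of angles
#'
#' One minus the mean resultant length,
#' \eqn{V = 1 - \frac{1}{N}\left\lVert\sum_i(\cos\theta_i,
#' \sin\theta_i)\right\rVert}: 0 when all angles coincide, 1 when the angles
#' balance out (no directional preference).
#'
#' @param thetas numeric vector of angles in radians, at least one.
#' @return Scalar in \[0, 1\].
#' @export
circular_variance <- function(thetas) {
  thetas <- as.numeric(thetas)
  if (length(thetas) < 1) stop("need at least one angle")
  if (anyNA(thetas)) stop("angles must not contain NA")
  1 - sqrt(mean(cos(thetas))^2 + mean(sin(thetas))^2)
}

#' Circular variance of a flow map by radius band
#'
#' Splits the flow-map points into bands of connection distance and reports
#' the circular variance of the angles within each band; near-1 values in
#' every band mean circuit flow covers angular space at all spatial scales.
#'
#' @param fmap a [flow_map()].
#' @param breaks radius band boundaries in micrometers. Default: 200 um bands
#'   covering the data.
#' @return Data frame with `r_lo`, `r_hi`, `n`, `circular_variance` (NA for
#'   empty bands).
#' @export
flow_variance_by_band <- function(fmap, breaks = NULL) {
  stopifnot(inherits(fmap, "flow_map"))
  if (is.null(breaks))
    breaks <- seq(0, max(fmap$r) * (1 + 1e-9) + 1e-9, by = 200)
  if (max(fmap$r) > max(breaks)) stop("breaks do not cover the radii")
  band <- findInterval(fmap$r, breaks, rightmost.closed = TRUE, left.open = TRUE)
  band[fmap$r == breaks[1]] <- 1L
  nb <- length(breaks) - 1
  out <- data.frame(r_lo = breaks[-length(breaks)], r_hi = breaks[-1],
                    n = 0L, circular_variance = NA_real_)
  for (b in seq_len(nb)) {
    th <- fmap$theta[band == b]
    out$n[b] <- length(th)
    if (length(th) > 0) out$circular_variance[b] <- circular_variance(th)
  }
  out
}

#' Field-of-view error curve
#'
#' FOV error at size d is the fraction of directed functional connections
#' whose source-to-sink distance exceeds d: the connections an imaging window
#' of that size cannot resolve, i.e. the probability of falsely characterizing
#' two connected neurons as independent. The curve is monotone non-increasing,
#' equals 1 at d = 0 (every positive-length edge is missed) and 0 at the
#' maximum edge length.
#'
#' @param topology a [functional_topology()] with a cell map and at least one
#'   edge.
#' @param distances increasing vector of FOV sizes (um) at which to evaluate.
#' @return A `fov_error_curve`: list with `distances`, `error`.
#' @export
fov_error_curve <- function(topology, distances) {
  d <- edge_distances(topology)
  distances <- as.numeric(distances)
  if (length(distances) < 1 || is.unsorted(distances))
    stop("distances must be a non-empty increasing vector")
  err <- vapply(distances, function(x) mean(d > x), numeric(1))
  structure(list(distances = distances, error = err),
            class = "fov_error_curve")
}

#' Minimum field of view achieving a target error
#'
#' Smallest evaluated FOV size whose error is below `max_error`
#' (default 0.10, i.e. less than 10 percent of connections missed).
#'
#' @param curve a [fov_error_curve()].
#' @param max_error error bound in \[0, 1\] (default 0.10).
#' @return FOV size in micrometers.
#' @export
min_fov_for_error <- function(curve, max_error = 0.10) {
  stopifnot(inherits(curve, "fov_error_curve"))
  ok <- which(curve$error < max_error)
  if (length(ok) == 0)
    stop("no evaluated field of view achieves the requested error")
  curve$distances[ok[1]]
}

#' Connectivity surface over FOV size and weight threshold
#'
#' Normalized algebraic connectivity of the topology after restricting to a
#' centered field of view of each size and pruning edges below each weight
#' threshold; quantifies how spatial subsampling and reliability thresholds
#' jointly disconnect the circuit. Degenerate restrictions (fewer than 2
#' cells) are reported as NA.
#'
#' @param topology a [functional_topology()] with a cell map.
#' @param fov_grid FOV sizes (um), rows of the result.
#' @param weight_grid weight thresholds, columns of the result.
#' @param symmetrization,weighted passed to [algebraic_connectivity()].
#' @return Matrix of lambda_2/n values with the grids as dimnames.
#' @export
connectivity_surface <- function(topology, fov_grid, weight_grid,
                                 symmetrization = "or", weighted = TRUE) {
  stopifnot(inherits(topology, "functional_topology"))
  if (length(fov_grid) == 0 || length(weight_grid) == 0)
    stop("grids must be non-empty")
  out <- matrix(NA_real_, length(fov_grid), length(weight_grid),
                dimnames = list(as.character(fov_grid),
                                as.character(weight_grid)))
  for (a in seq_along(fov_grid)) {
    sub <- tryCatch(restrict_fov(topology, fov_grid[a]),
                    error = function(e) NULL)
    if (is.null(sub) || length(sub$cell_ids) < 2) next
    for (b in seq_along(weight_grid)) {
      out[a, b] <- algebraic_connectivity(
        threshold_weights(sub, weight_grid[b]),
        symmetrization = symmetrization, weighted = weighted)
    }
  }
  out
}

#' Cumulative neuron count by field-of-view size
#'
#' Expected number of cells captured by a centered disc of each diameter;
#' links a minimum FOV size to the minimum numerical sample of neurons it
#' implies. By convention the count at d = 0 is 0 (the degenerate disc is
#' excluded).
#'
#' @param cellmap a [cell_map()] with at least one cell.
#' @param distances vector of disc diameters (um).
#' @param center `"centroid"` or a numeric `c(x, y)` point.
#' @return Integer vector of cell counts, one per distance.
#' @export
cumulative_density <- function(cellmap, distances, center = "centroid") {
  stopifnot(inherits(cellmap, "cell_map"))
  if (nrow(cellmap) < 1) stop("need at least one cell")
  if (identical(center, "centroid")) {
    cx <- mean(cellmap$x_um); cy <- mean(cellmap$y_um)
  } else if (is.numeric(center) && length(center) == 2) {
    cx <- center[1]; cy <- center[2]
  } else stop("center must be \"centroid\" or a numeric c(x, y)")
  r <- sqrt((cellmap$x_um - cx)^2 + (cellmap$y_um - cy)^2)
  vapply(as.numeric(distances), function(d) {
    if (d <= 0) 0L else sum(r <= d / 2)
  }, integer(1))
}
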