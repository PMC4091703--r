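#' Functional topology
#'
#' The central object of the analysis: a directed, weighted graph over the
#' imaged cells. Entry (i, j) of `weights` is the weight of the edge i -> j,
#' i.e. the number of one-frame-lagged firing coincidences (cell i fired at
#' frame t, cell j at t + 1, both frames inside one circuit event) divided by
#' the number of events in the field of view. Null-model topologies reuse the
#' container with unit weights and `n_events = 1`.
#'
#' @param weights non-negative cells x cells matrix with zero diagonal. For
#'   topologies built from rasters, `weights * n_events` is integer-valued
#'   (lag-coincidence counts); the container itself also accepts general
#'   non-negative weights for null models and sensitivity analyses.
#' @param cell_ids character vector of unique identifiers, one per row.
#' @param n_events positive integer used for weight normalization.
#' @param cellmap optional [cell_map()] aligned with `cell_ids`.
#' @return A `functional_topology` list.
#' @export
functional_topology <- function(weights, cell_ids, n_events, cellmap = NULL) {
  weights <- as.matrix(weights)
  cell_ids <- as.character(cell_ids)
  n <- length(cell_ids)
  if (nrow(weights) != n || ncol(weights) != n)
    stop("weights must be square with one row per cell_id")
  if (anyDuplicated(cell_ids)) stop("cell_ids must be unique")
  if (anyNA(weights) || any(weights < 0)) stop("weights must be non-negative")
  if (any(diag(weights) != 0)) stop("weights must have a zero diagonal")
  if (!is.numeric(n_events) || length(n_events) != 1 || n_events < 1 ||
      n_events != round(n_events))
    stop("n_events must be a positive integer")
  if (!is.null(cellmap)) {
    stopifnot(inherits(cellmap, "cell_map"))
    if (!identical(cellmap$cell_id, cell_ids))
      stop("cellmap cell ids must match cell_ids (same order)")
  }
  dimnames(weights) <- list(cell_ids, cell_ids)
  structure(
    list(weights = weights, cell_ids = cell_ids,
         n_events = as.integer(n_events), cellmap = cellmap),
    class = "functional_topology"
  )
}

#' @export
print.functional_topology <- function(x, ...) {
  cat(sprintf("<functional_topology> %d cells, %d edges, %d events%s\n",
              length(x$cell_ids), sum(x$weights > 0), x$n_events,
              if (is.null(x$cellmap)) "" else ", with cell map"))
  invisible(x)
}

#' Build a functional topology from an event-segmented raster
#'
#' Implements the one-frame-lag edge rule: cell A is functionally connected to
#' cell B if B fired in the frame after A, both frames lying inside the same
#' circuit event. Per-frame firing is binary (a cell spiking twice in a frame
#' contributes one coincidence). The weight of A -> B is the number of such
#' coincidences accumulated over all events, divided by the number of events.
#' Frame pairs straddling an event boundary never contribute.
#'
#' @param raster a [spike_raster()].
#' @param events a non-empty [circuit_events()] segmentation of `raster`.
#' @param cellmap optional [cell_map()]; must carry exactly the raster's cell
#'   ids in the same order.
#' @return A [functional_topology()].
#' @export
build_topology <- function(raster, events, cellmap = NULL) {
  stopifnot(inherits(raster, "spike_raster"), inherits(events, "circuit_events"))
  if (nrow(events) == 0)
    stop("at least one circuit event is required (weights are per-event)")
  if (any(events$end_frame >= n_frames(raster)))
    stop("events extend past the end of the raster")
  if (!is.null(cellmap)) {
    stopifnot(inherits(cellmap, "cell_map"))
    if (!identical(cellmap$cell_id, raster$cell_ids))
      stop("raster and cellmap cell ids are misaligned")
  }
  n <- nrow(raster$counts)
  B <- (raster$counts > 0) * 1
  W <- matrix(0, n, n)
  for (e in seq_len(nrow(events))) {
    f <- (events$start_frame[e]:events$end_frame[e]) + 1L
    if (length(f) < 2) next
    X <- B[, f, drop = FALSE]
    W <- W + X[, -ncol(X), drop = FALSE] %*% t(X[, -1, drop = FALSE])
  }
  diag(W) <- 0
  functional_topology(W / nrow(events), raster$cell_ids, nrow(events), cellmap)
}

#' Prune weak edges from a functional topology
#'
#' Sets every edge with weight below `min_weight` to zero; all nodes are
#' retained. Raising the threshold prunes the least reliably observed
#' spike-lag correlations first.
#'
#' @param topology a [functional_topology()].
#' @param min_weight non-negative weight threshold.
#' @return A [functional_topology()] on the same node set.
#' @export
threshold_weights <- function(topology, min_weight) {
  stopifnot(inherits(topology, "functional_topology"))
  if (!is.numeric(min_weight) || length(min_weight) != 1 || min_weight < 0)
    stop("min_weight must be a single non-negative number")
  W <- topology$weights
  W[W < min_weight] <- 0
  functional_topology(W, topology$cell_ids, topology$n_events, topology$cellmap)
}

#' Restrict a functional topology to a smaller field of view
#'
#' Field-of-view size is the maximum pairwise distance between any two cells
#' investigated, so a field of view of size d is a closed disc of diameter d.
#' This keeps exactly the cells inside that disc (default center: centroid of
#' all positions) and the edges among them; every retained pairwise distance
#' is at most `max_pairwise_um`.
#'
#' @param topology a [functional_topology()] with a cell map.
#' @param max_pairwise_um disc diameter in micrometers.
#' @param center `"centroid"` or a numeric `c(x, y)` point.
#' @return A [functional_topology()] on the retained cells.
#' @export
restrict_fov <- function(topology, max_pairwise_um, center = "centroid") {
  stopifnot(inherits(topology, "functional_topology"))
  if (is.null(topology$cellmap))
    stop("restrict_fov requires a topology with cell positions")
  if (!is.numeric(max_pairwise_um) || max_pairwise_um <= 0)
    stop("max_pairwise_um must be positive")
  cm <- topology$cellmap
  if (identical(center, "centroid")) {
    cx <- mean(cm$x_um); cy <- mean(cm$y_um)
  } else if (is.numeric(center) && length(center) == 2) {
    cx <- center[1]; cy <- center[2]
  } else stop("center must be \"centroid\" or a numeric c(x, y)")
  keep <- sqrt((cm$x_um - cx)^2 + (cm$y_um - cy)^2) <= max_pairwise_um / 2
  if (!any(keep)) stop("no cells inside the requested field of view")
  sub_map <- cell_map(cm$cell_id[keep], cm$x_um[keep], cm$y_um[keep],
                      cm$layer[keep],
                      pia_angle_deg = attr(cm, "pia_angle_deg"),
                      fov_diameter_um = attr(cm, "fov_diameter_um"))
  functional_topology(topology$weights[keep, keep, drop = FALSE],
                      topology$cell_ids[keep], topology$n_events, sub_map)
}

#' Edge list of a functional topology
#'
#' @param topology a [functional_topology()].
#' @return data frame with columns `src`, `dst`, `weight`, one row per
#'   non-zero directed edge.
#' @export
topology_edges <- function(topology) {
  stopifnot(inherits(topology, "functional_topology"))
  idx <- which(topology$weights > 0, arr.ind = TRUE)
  out <- data.frame(src = topology$cell_ids[idx[, 1]],
                    dst = topology$cell_ids[idx[, 2]],
                    weight = topology$weights[idx],
                    stringsAsFactors = FALSE)
  out[order(match(out$src, topology$cell_ids),
            match(out$dst, topology$cell_ids)), , drop = FALSE]
}

#' Write a topology edge list to delimited text
#'
#' Writes `src,dst,weight` rows with full precision.
#'
#' @param topology a [functional_topology()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(topology, path) {
  ed <- topology_edges(topology)
  lines <- c("src,dst,weight",
             sprintf("%s,%s,%.17g", ed$src, ed$dst, ed$weight))
  writeLines(lines, path)
  invisible(path)
}
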