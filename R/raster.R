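#' Spike raster
#'
#' Container for a cells x frames matrix of per-frame spike counts, the raw
#' input of the pipeline. Rows are cells, columns are imaging frames; the
#' frame duration (ms) fixes the time base for event segmentation.
#'
#' @param counts matrix of non-negative integer spike counts, cells x frames.
#' @param frame_duration_ms positive frame duration in milliseconds.
#' @param cell_ids character vector of unique cell identifiers, one per row.
#'   Defaults to the row names of `counts`, or `c1, c2, ...` when absent.
#'
#' @return An object of class `spike_raster`: a list with elements `counts`
#'   (integer matrix with `cell_ids` as row names), `frame_duration_ms` and
#'   `cell_ids`.
#' @export
#' @examples
#' r <- spike_raster(matrix(c(0, 1, 0, 0, 0, 2), 2, byrow = TRUE), 86)
#' n_frames(r)
spike_raster <- function(counts, frame_duration_ms, cell_ids = rownames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(cell_ids)) cell_ids <- paste0("c", seq_len(nrow(counts)))
  cell_ids <- as.character(cell_ids)
  if (length(cell_ids) != nrow(counts))
    stop("length(cell_ids) must equal nrow(counts)")
  if (anyDuplicated(cell_ids))
    stop("cell_ids must be unique")
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (!is.numeric(frame_duration_ms) || length(frame_duration_ms) != 1 ||
      !is.finite(frame_duration_ms) || frame_duration_ms <= 0)
    stop("frame_duration_ms must be a single positive number")
  storage.mode(counts) <- "integer"
  rownames(counts) <- cell_ids
  colnames(counts) <- NULL
  structure(
    list(counts = counts, frame_duration_ms = as.numeric(frame_duration_ms),
         cell_ids = cell_ids),
    class = "spike_raster"
  )
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("<spike_raster> %d cells x %d frames (%.1f ms/frame), %d spikes\n",
              nrow(x$counts), ncol(x$counts), x$frame_duration_ms,
              sum(x$counts)))
  invisible(x)
}

#' Number of frames in a spike raster
#' @param raster a [spike_raster()].
#' @return integer frame count.
#' @export
n_frames <- function(raster) ncol(raster$counts)

#' Cell map
#'
#' Per-cell 2-D positions in the imaging plane (micrometers), with an optional
#' laminar label per cell and a single in-plane direction toward the pia.
#' All spatial analyses (laminar fractions, flow maps, field-of-view
#' restriction) are anchored to this object.
#'
#' @param cell_ids character vector of unique identifiers.
#' @param x_um,y_um numeric coordinates in micrometers.
#' @param layer optional laminar label per cell, one of
#'   `"L1", "L2/3", "L4", "L5", "unknown"`. Defaults to `"unknown"`.
#' @param pia_angle_deg direction toward the pia in the imaging plane,
#'   degrees counter-clockwise from the +x axis. Default 90 (pia "up").
#' @param fov_diameter_um field-of-view diameter; all pairwise distances must
#'   not exceed it. Default 1100.
#'
#' @return A `cell_map`: a data frame with columns `cell_id`, `x_um`, `y_um`,
#'   `layer` and attributes `pia_angle_deg`, `fov_diameter_um`.
#' @export
cell_map <- function(cell_ids, x_um, y_um, layer = NULL,
                     pia_angle_deg = 90, fov_diameter_um = 1100) {
  cell_ids <- as.character(cell_ids)
  n <- length(cell_ids)
  if (anyDuplicated(cell_ids)) stop("cell_ids must be unique")
  if (length(x_um) != n || length(y_um) != n)
    stop("x_um and y_um must have one value per cell_id")
  if (!all(is.finite(x_um)) || !all(is.finite(y_um)))
    stop("coordinates must be finite")
  if (is.null(layer)) layer <- rep("unknown", n)
  layer <- as.character(layer)
  if (length(layer) == 1) layer <- rep(layer, n)
  allowed <- c("L1", "L2/3", "L4", "L5", "unknown")
  if (!all(layer %in% allowed))
    stop("layer labels must be one of: ", paste(allowed, collapse = ", "))
  if (!is.numeric(fov_diameter_um) || fov_diameter_um <= 0)
    stop("fov_diameter_um must be positive")
  if (n >= 2 && max_pairwise_distance(cbind(x_um, y_um)) > fov_diameter_um + 1e-6)
    stop("pairwise distances exceed the configured field-of-view diameter")
  out <- data.frame(cell_id = cell_ids, x_um = as.numeric(x_um),
                    y_um = as.numeric(y_um), layer = layer,
                    stringsAsFactors = FALSE)
  attr(out, "pia_angle_deg") <- as.numeric(pia_angle_deg)
  attr(out, "fov_diameter_um") <- as.numeric(fov_diameter_um)
  class(out) <- c("cell_map", "data.frame")
  out
}

# Max pairwise distance; via convex hull for large point sets (the maximum is
# attained between hull vertices).
max_pairwise_distance <- function(pts) {
  if (nrow(pts) > 1500) {
    hull <- tryCatch(grDevices::chull(pts), error = function(e) seq_len(nrow(pts)))
    pts <- pts[hull, , drop = FALSE]
  }
  max(stats::dist(pts))
}

#' Circuit events
#'
#' A sorted, non-overlapping list of circuit events: contiguous epochs of
#' population spiking bounded by quiescence. Frames are 0-based and both
#' bounds are inclusive, a convention used everywhere in the package.
#'
#' @param start_frame,end_frame non-negative integer frame indices (0-based,
#'   inclusive) with `end_frame >= start_frame` per event.
#' @return A `circuit_events` data frame with columns `start_frame`,
#'   `end_frame`.
#' @export
circuit_events <- function(start_frame = integer(), end_frame = integer()) {
  start_frame <- as.integer(start_frame)
  end_frame <- as.integer(end_frame)
  if (length(start_frame) != length(end_frame))
    stop("start_frame and end_frame must have equal length")
  if (any(start_frame < 0) || any(end_frame < start_frame))
    stop("events need 0 <= start_frame <= end_frame")
  if (length(start_frame) > 1) {
    o <- order(start_frame)
    start_frame <- start_frame[o]; end_frame <- end_frame[o]
    if (any(start_frame[-1] <= end_frame[-length(end_frame)]))
      stop("events must be non-overlapping")
  }
  out <- data.frame(start_frame = start_frame, end_frame = end_frame)
  class(out) <- c("circuit_events", "data.frame")
  out
}

#' Detect circuit events in a spike raster
#'
#' Segments the raster into circuit events: maximal runs of "active" frames
#' (frames in which at least `min_active_cells` cells spike), optionally
#' merging runs separated by short quiescent gaps, and keeping only runs at
#' least `min_duration_ms` long. The default 500 ms floor reflects the
#' operational definition of a circuit event as a sustained epoch of
#' population spiking bounded by quiescence.
#'
#' @param raster a [spike_raster()].
#' @param min_duration_ms minimum event duration in ms (default 500).
#' @param min_active_cells number of simultaneously spiking cells required for
#'   a frame to count as active (default 1).
#' @param max_gap_frames active runs separated by at most this many inactive
#'   frames are merged (default 0: no merging).
#' @return A [circuit_events()] data frame (possibly empty).
#' @export
detect_events <- function(raster, min_duration_ms = 500, min_active_cells = 1,
                          max_gap_frames = 0) {
  stopifnot(inherits(raster, "spike_raster"))
  if (!is.numeric(min_duration_ms) || min_duration_ms <= 0)
    stop("min_duration_ms must be positive")
  active <- colSums(raster$counts > 0) >= min_active_cells
  if (!any(active)) return(circuit_events())
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge runs separated by <= max_gap_frames inactive frames
  if (max_gap_frames > 0 && nrow(runs) > 1) {
    keep_start <- runs$start[1]; merged <- list(); cur_end <- runs$end[1]
    for (i in 2:nrow(runs)) {
      if (runs$start[i] - cur_end - 1 <= max_gap_frames) {
        cur_end <- runs$end[i]
      } else {
        merged[[length(merged) + 1]] <- c(keep_start, cur_end)
        keep_start <- runs$start[i]; cur_end <- runs$end[i]
      }
    }
    merged[[length(merged) + 1]] <- c(keep_start, cur_end)
    m <- do.call(rbind, merged)
    runs <- data.frame(start = m[, 1], end = m[, 2])
  }
  dur_ms <- (runs$end - runs$start + 1) * raster$frame_duration_ms
  runs <- runs[dur_ms >= min_duration_ms, , drop = FALSE]
  circuit_events(runs$start - 1L, runs$end - 1L)
}

#' Field-of-view inclusion rule
#'
#' A field of view enters the analysis only if it produced at least
#' `min_events` circuit events (default 4).
#'
#' @param events a [circuit_events()] data frame.
#' @param min_events minimum number of events (default 4).
#' @return `TRUE` or `FALSE`.
#' @export
validate_fov <- function(events, min_events = 4) {
  stopifnot(inherits(events, "circuit_events"))
  nrow(events) >= min_events
}
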