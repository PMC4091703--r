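#' Read a spike raster from delimited text
#'
#' Two dialects are supported. `dense`: header `cell_id,f0,f1,...` and one
#' row of integer counts per cell. `triplet`: header `cell_id,frame,count`
#' with one line per non-zero entry (0-based frames); the total frame count
#' and, optionally, the full cell roster are declared by the caller, and
#' entries absent from the file are zero.
#'
#' @param path file to read.
#' @param dialect `"dense"` or `"triplet"`.
#' @param frame_duration_ms frame duration in ms (sidecar metadata; the files
#'   carry counts only).
#' @param n_frames declared number of frames (required for `triplet`).
#' @param cell_ids declared cell roster for `triplet` files; cells without
#'   any triplet get all-zero rows. Defaults to the cells present in the file,
#'   in order of first appearance.
#' @param sep field separator (default `","`).
#' @return A [spike_raster()].
#' @export
read_raster <- function(path, dialect = c("dense", "triplet"),
                        frame_duration_ms, n_frames = NULL, cell_ids = NULL,
                        sep = ",") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty file: ", path)
  fields <- strsplit(lines, sep, fixed = TRUE)
  header <- fields[[1]]

  if (dialect == "dense") {
    if (length(header) < 1 || header[1] != "cell_id")
      stop("dense raster header must start with 'cell_id' (line 1)")
    nf <- length(header) - 1L
    body <- fields[-1]
    ids <- character(length(body))
    counts <- matrix(0L, length(body), nf)
    for (i in seq_along(body)) {
      f <- body[[i]]
      if (length(f) != nf + 1L)
        stop(sprintf("malformed row at line %d: expected %d fields, got %d",
                     i + 1L, nf + 1L, length(f)))
      ids[i] <- f[1]
      v <- suppressWarnings(as.numeric(f[-1]))
      if (anyNA(v) || any(v != round(v)))
        stop(sprintf("non-integer count at line %d", i + 1L))
      if (any(v < 0))
        stop(sprintf("negative count at line %d", i + 1L))
      counts[i, ] <- as.integer(v)
    }
    return(spike_raster(counts, frame_duration_ms, ids))
  }

  # triplet
  if (length(header) != 3 || !identical(header, c("cell_id", "frame", "count")))
    stop("triplet raster header must be 'cell_id,frame,count' (line 1)")
  if (is.null(n_frames))
    stop("n_frames must be declared for triplet rasters")
  body <- fields[-1]
  trip_id <- character(length(body))
  trip_frame <- integer(length(body))
  trip_count <- integer(length(body))
  for (i in seq_along(body)) {
    f <- body[[i]]
    if (length(f) != 3)
      stop(sprintf("malformed triplet at line %d", i + 1L))
    fr <- suppressWarnings(as.numeric(f[2]))
    ct <- suppressWarnings(as.numeric(f[3]))
    if (is.na(fr) || is.na(ct) || fr != round(fr) || ct != round(ct))
      stop(sprintf("malformed triplet at line %d", i + 1L))
    if (ct < 0) stop(sprintf("negative count at line %d", i + 1L))
    if (fr < 0 || fr >= n_frames)
      stop(sprintf("frame out of range at line %d", i + 1L))
    trip_id[i] <- f[1]; trip_frame[i] <- as.integer(fr); trip_count[i] <- as.integer(ct)
  }
  key <- paste(trip_id, trip_frame)
  if (anyDuplicated(key)) {
    line <- which(duplicated(key))[1] + 1L
    stop(sprintf("duplicate (cell, frame) triplet at line %d", line))
  }
  if (is.null(cell_ids)) cell_ids <- unique(trip_id)
  cell_ids <- as.character(cell_ids)
  if (!all(trip_id %in% cell_ids))
    stop("triplet file names cells absent from the declared cell_ids")
  counts <- matrix(0L, length(cell_ids), n_frames)
  if (length(body) > 0) {
    ri <- match(trip_id, cell_ids)
    counts[cbind(ri, trip_frame + 1L)] <- trip_count
  }
  spike_raster(counts, frame_duration_ms, cell_ids)
}

#' Write a spike raster to delimited text
#'
#' Inverse of [read_raster()]: `read_raster(write_raster(r))` reproduces `r`
#' exactly (integer round trip). The triplet dialect writes only non-zero
#' entries, ordered by cell then frame; an all-zero raster yields a
#' header-only file.
#'
#' @param raster a [spike_raster()].
#' @param path destination file.
#' @param dialect `"dense"` or `"triplet"`.
#' @param sep field separator (default `","`).
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path, dialect = c("dense", "triplet"),
                         sep = ",") {
  dialect <- match.arg(dialect)
  stopifnot(inherits(raster, "spike_raster"))
  nf <- ncol(raster$counts)
  if (dialect == "dense") {
    header <- paste(c("cell_id", paste0("f", seq_len(nf) - 1L)), collapse = sep)
    rows <- vapply(seq_len(nrow(raster$counts)), function(i) {
      paste(c(raster$cell_ids[i], raster$counts[i, ]), collapse = sep)
    }, character(1))
    writeLines(c(header, rows), path)
  } else {
    nz <- which(t(raster$counts) > 0)  # transposed: cell-major then frame
    header <- paste(c("cell_id", "frame", "count"), collapse = sep)
    if (length(nz) == 0) {
      writeLines(header, path)
    } else {
      cell <- (nz - 1L) %/% nf + 1L
      frame <- (nz - 1L) %% nf
      cnt <- t(raster$counts)[nz]
      rows <- paste(raster$cell_ids[cell], frame, cnt, sep = sep)
      writeLines(c(header, rows), path)
    }
  }
  invisible(path)
}

#' Read a cell map from delimited text
#'
#' Expects columns `cell_id,x_um,y_um` and optionally `layer`. The pia
#' orientation and field-of-view diameter are configuration metadata, not
#' file columns.
#'
#' @param path file to read.
#' @param pia_angle_deg,fov_diameter_um metadata passed to [cell_map()].
#' @return A [cell_map()].
#' @export
read_cellmap <- function(path, pia_angle_deg = 90, fov_diameter_um = 1100) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "x_um", "y_um")
  if (!all(need %in% names(df)))
    stop("cell map must have columns cell_id, x_um, y_um")
  layer <- if ("layer" %in% names(df)) df$layer else NULL
  cell_map(df$cell_id, df$x_um, df$y_um, layer,
           pia_angle_deg = pia_angle_deg, fov_diameter_um = fov_diameter_um)
}

#' Write a cell map to delimited text
#' @param cellmap a [cell_map()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_cellmap <- function(cellmap, path) {
  utils::write.csv(as.data.frame(cellmap), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
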