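#' Matched random null topology
#'
#' Preserves the cell positions of a field of view and assigns every ordered
#' pair of distinct cells a directed edge independently with probability `p`
#' (default 0.5, the spatially unconstrained upper bound among the null
#' models). Null edges are unweighted (weight 1).
#'
#' @param cellmap a [cell_map()] with at least 2 cells.
#' @param p edge probability in \[0, 1\] (default 0.5).
#' @param seed RNG seed; output is deterministic per seed.
#' @return A [functional_topology()] with `n_events = 1`.
#' @export
random_topology <- function(cellmap, p = 0.5, seed = 1) {
  stopifnot(inherits(cellmap, "cell_map"))
  n <- nrow(cellmap)
  if (n < 2) stop("need at least 2 cells")
  if (!is.numeric(p) || length(p) != 1 || p < 0 || p > 1)
    stop("p must be in [0, 1]")
  set.seed(seed)
  W <- matrix(as.numeric(stats::runif(n * n) < p), n, n)
  diag(W) <- 0
  functional_topology(W, cellmap$cell_id, 1L, cellmap)
}

#' Matched k-nearest-neighbors null topology
#'
#' Preserves the cell positions and connects every cell A to exactly its `k`
#' nearest neighbors (directed A -> B edges), the spatially restricted lower
#' bound among the null models. Distance ties at the k-th neighbor are broken
#' toward the cell appearing earlier in the map's cell-id order. Edges are
#' unweighted (weight 1).
#'
#' @param cellmap a [cell_map()] with more than `k` cells.
#' @param k neighbors per cell (default 10).
#' @return A [functional_topology()] with every out-degree exactly `k`.
#' @export
knn_topology <- function(cellmap, k = 10) {
  stopifnot(inherits(cellmap, "cell_map"))
  n <- nrow(cellmap)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k))
    stop("k must be a positive integer")
  if (n <= k) stop("need more cells than k")
  d <- as.matrix(stats::dist(cbind(cellmap$x_um, cellmap$y_um)))
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    cand <- setdiff(seq_len(n), i)
    nb <- cand[order(d[i, cand], cand)][seq_len(k)]
    W[i, nb] <- 1
  }
  functional_topology(W, cellmap$cell_id, 1L, cellmap)
}

#' Capture probability of a null model
#'
#' How well a null topology explains the data topology: the conditional
#' probability that a functional connection exists in the data given that the
#' null predicts one for the same ordered pair, evaluated over all ordered
#' pairs of distinct cells via Bayes' rule,
#' \deqn{P(F_{data} \mid F_{null}) =
#'   \frac{P(F_{null} \mid F_{data})\, P(F_{data})}{P(F_{null})}
#'   = \frac{n_{shared}}{n_{null}}.}
#' Both graphs are binarized at weight > 0. The value is 1 exactly when null
#' edges are a subset of data edges (one-to-one prediction), 0 when they are
#' disjoint.
#'
#' @param data,null [functional_topology()] objects on the same node set and
#'   ordering.
#' @return A `capture_result`: list with `p_capture`, `n_data_edges`,
#'   `n_null_edges`, `n_shared`.
#' @export
capture_probability <- function(data, null) {
  stopifnot(inherits(data, "functional_topology"),
            inherits(null, "functional_topology"))
  if (!identical(data$cell_ids, null$cell_ids))
    stop("data and null must share the same cell ids and ordering")
  D <- data$weights > 0
  N <- null$weights > 0
  n_null <- sum(N)
  if (n_null == 0)
    stop("null topology has no edges; capture probability is undefined")
  n_data <- sum(D)
  n_shared <- sum(D & N)
  structure(
    list(p_capture = n_shared / n_null,
         n_data_edges = n_data, n_null_edges = n_null, n_shared = n_shared),
    class = "capture_result"
  )
}

#' @export
print.capture_result <- function(x, ...) {
  cat(sprintf(
    "<capture_result> P(data edge | null edge) = %.4f (%d shared / %d null; %d data edges)\n",
    x$p_capture, x$n_shared, x$n_null_edges, x$n_data_edges))
  invisible(x)
}
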