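#' Eigenvector centrality by power iteration
#'
#' Scores every cell by the corresponding entry of the Perron (leading)
#' eigenvector of the weighted adjacency matrix, normalized to unit Euclidean
#' norm. The out-convention is used: the score of cell i is proportional to
#' the weighted sum of the scores of the cells i projects to,
#' \eqn{\lambda v_i = \sum_j w_{ij} v_j}, so an upstream driver of
#' high-scoring cells itself scores high. For strongly connected graphs
#' Perron-Frobenius guarantees a unique positive solution, which power
#' iteration from a uniform positive start reaches. If the iteration fails to
#' converge to a strictly positive fixed point (reducible or nilpotent
#' graphs), scores are computed on the largest strongly connected component
#' with zeros elsewhere and `converged` is `FALSE`.
#'
#' @param topology a [functional_topology()] with at least 2 cells.
#' @param tol convergence tolerance on the max score change (default 1e-10).
#' @param max_iter iteration cap (default 10000).
#' @return A `centrality_result`: list with `scores` (unit-norm, non-negative),
#'   `kind = "eigenvector"`, `leading_eigenvalue` (Rayleigh quotient) and
#'   `converged`.
#' @export
eigenvector_centrality <- function(topology, tol = 1e-10, max_iter = 10000) {
  stopifnot(inherits(topology, "functional_topology"))
  A <- topology$weights
  n <- nrow(A)
  if (n < 2) stop("eigenvector centrality needs at least 2 cells")
  pi_res <- power_iterate(A, tol, max_iter)
  if (pi_res$converged && min(pi_res$v) > 1e-12) {
    return(structure(
      list(scores = as.numeric(pi_res$v), kind = "eigenvector",
           leading_eigenvalue = pi_res$lambda, converged = TRUE),
      class = "centrality_result"))
  }
  # reducible / nilpotent fallback: Perron vector of the largest strongly
  # connected component, zeros elsewhere
  g <- igraph::graph_from_adjacency_matrix((A > 0) * 1, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  big <- which.max(tabulate(comp$membership, comp$no))
  idx <- which(comp$membership == big)
  scores <- numeric(n)
  if (length(idx) >= 2) {
    sub <- power_iterate(A[idx, idx, drop = FALSE], tol, max_iter)
    scores[idx] <- sub$v
    lambda <- sub$lambda
  } else {
    scores[idx] <- 1
    lambda <- 0
  }
  structure(
    list(scores = scores, kind = "eigenvector",
         leading_eigenvalue = lambda, converged = FALSE),
    class = "centrality_result")
}

# Power iteration on the shifted matrix A + cI from a uniform positive start.
# The shift (c = max weight) leaves the eigenvectors of A unchanged but makes
# the iteration matrix primitive on irreducible graphs, so periodic graphs
# (e.g. pure cycles) converge instead of oscillating.
power_iterate <- function(A, tol, max_iter) {
  n <- nrow(A)
  shift <- max(A)
  if (shift <= 0)
    return(list(v = rep(1 / sqrt(n), n), lambda = 0, converged = FALSE))
  v <- rep(1 / sqrt(n), n)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- as.numeric(A %*% v) + shift * v
    nw <- sqrt(sum(w * w))
    if (nw < 1e-300) return(list(v = v, lambda = 0, converged = FALSE))
    w <- w / nw
    if (max(abs(w - v)) < tol) {
      v <- w
      converged <- TRUE
      break
    }
    v <- w
  }
  lambda <- as.numeric(t(v) %*% A %*% v)  # Rayleigh quotient, ||v|| = 1
  list(v = v, lambda = lambda, converged = converged)
}

#' Degree centrality
#'
#' Classical hub measure: the fraction of possible partners a cell is
#' connected to. In-degree of i counts cells j with an edge j -> i, out-degree
#' counts edges i -> j, both normalized by (n - 1); total degree is their
#' average. Edge presence is weight > 0.
#'
#' @param topology a [functional_topology()] with at least 2 cells.
#' @param kind `"total"`, `"in"` or `"out"`.
#' @return A `centrality_result` with scores in \[0, 1\].
#' @export
degree_centrality <- function(topology, kind = c("total", "in", "out")) {
  stopifnot(inherits(topology, "functional_topology"))
  kind <- match.arg(kind)
  B <- topology$weights > 0
  n <- nrow(B)
  if (n < 2) stop("degree centrality needs at least 2 cells")
  indeg <- colSums(B); outdeg <- rowSums(B)
  scores <- switch(kind,
    "in" = indeg / (n - 1),
    "out" = outdeg / (n - 1),
    "total" = (indeg + outdeg) / (2 * (n - 1)))
  structure(
    list(scores = as.numeric(scores),
         kind = paste0(kind, "_degree"),
         leading_eigenvalue = NA_real_, converged = TRUE),
    class = "centrality_result")
}

#' Fit a log-normal or normal distribution to scores
#'
#' Maximum-likelihood location/scale fit plus a one-sample Kolmogorov-Smirnov
#' test of the data against the fitted distribution (the KS p-value is
#' approximate because the parameters are estimated from the same data).
#' Eigenvector-centrality scores are conventionally summarized by a log-normal
#' fit, degree fractions by a normal fit.
#'
#' @param values numeric vector, at least 8 values; strictly positive for the
#'   log-normal family.
#' @param family `"lognormal"` or `"normal"`.
#' @return A `distribution_fit`: list with `family`, `location`, `scale`,
#'   `ks_p`.
#' @export
fit_distribution <- function(values, family = c("lognormal", "normal")) {
  family <- match.arg(family)
  values <- as.numeric(values)
  if (length(values) < 8) stop("need at least 8 values")
  if (anyNA(values)) stop("values must not contain NA")
  if (family == "lognormal" && any(values <= 0))
    stop("lognormal fits require strictly positive values")
  if (stats::sd(values) == 0)
    stop("degenerate (constant) sample: scale would be zero")
  if (family == "lognormal") {
    fit <- MASS::fitdistr(values, "log-normal")
    location <- unname(fit$estimate["meanlog"])
    scale <- unname(fit$estimate["sdlog"])
    ks <- suppressWarnings(
      stats::ks.test(values, "plnorm", meanlog = location, sdlog = scale))
  } else {
    fit <- MASS::fitdistr(values, "normal")
    location <- unname(fit$estimate["mean"])
    scale <- unname(fit$estimate["sd"])
    ks <- suppressWarnings(
      stats::ks.test(values, "pnorm", mean = location, sd = scale))
  }
  if (scale <= 0) stop("degenerate fit: non-positive scale")
  structure(
    list(family = family, location = location, scale = scale,
         ks_p = unname(ks$p.value)),
    class = "distribution_fit")
}

#' Normalized algebraic connectivity
#'
#' Second-smallest eigenvalue of the Laplacian of the symmetrized graph,
#' divided by the number of nodes. The graph is connected if and only if the
#' value is positive; values near 1 indicate strong connectivity (the complete
#' graph attains exactly 1). Directed edges are first transformed to
#' undirected ones: `or` keeps every edge (undirected weight is the max of the
#' two directions, the default reading of dropping directedness), `and` keeps
#' only reciprocated edges (min), `mean` averages the two directions. The
#' Laplacian is L = D - W with D the diagonal of row sums of the undirected
#' weights W.
#'
#' @param topology a [functional_topology()] with at least 2 cells.
#' @param symmetrization `"or"`, `"and"` or `"mean"`.
#' @param weighted use edge weights (`TRUE`, default) or binarize first.
#' @return Non-negative scalar lambda_2(L) / n; exactly 0 (within 1e-9) iff
#'   the undirected graph is disconnected.
#' @export
algebraic_connectivity <- function(topology,
                                   symmetrization = c("or", "and", "mean"),
                                   weighted = TRUE) {
  stopifnot(inherits(topology, "functional_topology"))
  symmetrization <- match.arg(symmetrization)
  W <- topology$weights
  if (!weighted) W <- (W > 0) * 1
  n <- nrow(W)
  if (n < 2) stop("algebraic connectivity needs at least 2 cells")
  U <- switch(symmetrization,
              or = pmax(W, t(W)),
              and = pmin(W, t(W)),
              mean = (W + t(W)) / 2)
  L <- diag(rowSums(U)) - U
  ev <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  lambda2 <- ev[2]
  if (abs(lambda2) < 1e-9) lambda2 <- 0
  lambda2 / n
}

#' Count open and closed walk sequences via adjacency powers
#'
#' The (i, j) entry of the k-th power of the adjacency matrix counts walks of
#' length k from i to j. Open sequences (distinct endpoints) are the
#' off-diagonal sum of A^k, counted for lengths 1..K; closed sequences (equal
#' endpoints) are the trace of A^k, counted for lengths 2..K since a closed
#' sequence of length 1 does not exist. The adjacency is binarized by default
#' because the walk-counting theorem concerns unweighted edges; the weighted
#' variant is available for sensitivity analysis. Accumulation is in floating
#' point, which is overflow-safe at the sizes and lengths used here.
#'
#' @param topology a [functional_topology()].
#' @param K maximum path length, at least 2 (default 10).
#' @param binarize count walks on edge presence (default `TRUE`).
#' @return A `walk_counts`: list with `open` (named, lengths 1..K), `closed`
#'   (named, lengths 2..K) and `K`.
#' @export
count_walks <- function(topology, K = 10, binarize = TRUE) {
  stopifnot(inherits(topology, "functional_topology"))
  if (!is.numeric(K) || length(K) != 1 || K < 2 || K != round(K))
    stop("K must be an integer >= 2")
  A <- topology$weights
  if (binarize) A <- (A > 0) * 1
  open <- numeric(K); closed <- numeric(K - 1)
  P <- A
  open[1] <- sum(P) - sum(diag(P))
  for (k in 2:K) {
    P <- P %*% A
    tr <- sum(diag(P))
    open[k] <- sum(P) - tr
    closed[k - 1] <- tr
  }
  names(open) <- as.character(1:K)
  names(closed) <- as.character(2:K)
  structure(list(open = open, closed = closed, K = as.integer(K)),
            class = "walk_counts")
}

#' Open-to-closed sequence ratio
#'
#' Ratio of open to closed walk counts at each path length 2..K (length 1 is
#' excluded since closed sequences of length 1 do not exist). The ratio is
#' `Inf` where closed counts are zero but open counts are not, and `NA`
#' (undefined) where both are zero.
#'
#' @param counts a [count_walks()] result.
#' @return Named numeric vector over lengths 2..K.
#' @export
oc_ratio <- function(counts) {
  stopifnot(inherits(counts, "walk_counts"))
  open <- counts$open[as.character(2:counts$K)]
  closed <- counts$closed
  ratio <- ifelse(closed > 0, open / closed,
                  ifelse(open > 0, Inf, NA_real_))
  names(ratio) <- names(closed)
  ratio
}

#' Slope of the exponential sequence growth curve
#'
#' Walk counts grow exponentially with path length, so their logarithms are
#' linear in length; the slope of that line summarizes how fast the number of
#' possible activation sequences explodes (for large strongly connected graphs
#' it approaches the log of the leading adjacency eigenvalue). Ordinary least
#' squares of natural-log counts against path length; zero counts are dropped,
#' and at least 3 positive counts are required.
#'
#' @param counts a [count_walks()] result.
#' @param which `"open"` or `"closed"`.
#' @return List with `slope` and `r_squared`.
#' @export
growth_slope <- function(counts, which = c("open", "closed")) {
  stopifnot(inherits(counts, "walk_counts"))
  which <- match.arg(which)
  y <- if (which == "open") counts$open else counts$closed
  x <- as.numeric(names(y))
  keep <- y > 0
  if (sum(keep) < 3)
    stop("need at least 3 strictly positive counts to fit a growth slope")
  fit <- stats::lm(log(y[keep]) ~ x[keep])
  list(slope = unname(stats::coef(fit)[2]),
       r_squared = summary(fit)$r.squared)
}

#' Percentage of reciprocally connected pairs
#'
#' The percent of unordered cell pairs with both directed edges present
#' (closed sequences of length 2), out of all n(n-1)/2 possible pairs.
#'
#' @param topology a [functional_topology()] with at least 2 cells.
#' @return Scalar in \[0, 100\].
#' @export
reciprocal_percent <- function(topology) {
  stopifnot(inherits(topology, "functional_topology"))
  B <- topology$weights > 0
  n <- nrow(B)
  if (n < 2) stop("reciprocal_percent needs at least 2 cells")
  n_recip <- sum(B & t(B)) / 2
  100 * n_recip / (n * (n - 1) / 2)
}

#' Full invariant report for one topology
#'
#' Convenience wrapper computing every graph invariant of the analysis for a
#' single topology: normalized algebraic connectivity, walk counts with O-C
#' ratios and growth slopes, reciprocal-connection percentage, eigenvector and
#' total-degree centrality with their conventional distribution fits
#' (log-normal for eigenvector scores, normal for degree fractions). Fits are
#' computed on the strictly positive scores and skipped (NULL, with a count of
#' the cells excluded) when fewer than 8 remain, as happens on tiny or
#' degenerate graphs.
#'
#' @param topology a [functional_topology()].
#' @param K maximum walk length (default 10).
#' @param symmetrization passed to [algebraic_connectivity()].
#' @param weighted_connectivity use weights in the Laplacian (default `TRUE`).
#' @return An `invariant_report` list.
#' @export
invariant_report <- function(topology, K = 10,
                             symmetrization = c("or", "and", "mean"),
                             weighted_connectivity = TRUE) {
  stopifnot(inherits(topology, "functional_topology"))
  symmetrization <- match.arg(symmetrization)
  B <- topology$weights > 0
  n_isolated <- sum(rowSums(B) + colSums(B) == 0)
  counts <- count_walks(topology, K = K)
  ec <- eigenvector_centrality(topology)
  dg <- degree_centrality(topology, "total")
  safe_fit <- function(values, family) {
    values <- values[values > 0]
    if (length(values) < 8 || stats::sd(values) == 0) return(NULL)
    fit_distribution(values, family)
  }
  safe_slope <- function(which) {
    tryCatch(growth_slope(counts, which),
             error = function(e) list(slope = NA_real_, r_squared = NA_real_))
  }
  structure(
    list(
      algebraic_connectivity_normalized =
        algebraic_connectivity(topology, symmetrization,
                               weighted = weighted_connectivity),
      walk_counts = counts,
      oc_ratio = oc_ratio(counts),
      open_slope = safe_slope("open"),
      closed_slope = safe_slope("closed"),
      reciprocal_percent = reciprocal_percent(topology),
      eigenvector = ec,
      eigenvector_fit = safe_fit(ec$scores, "lognormal"),
      degree = dg,
      degree_fit = safe_fit(dg$scores, "normal"),
      n_isolated = n_isolated,
      n_cells = length(topology$cell_ids),
      n_edges = sum(B),
      symmetrization = symmetrization
    ),
    class = "invariant_report")
}

#' @export
print.invariant_report <- function(x, ...) {
  cat(sprintf("<invariant_report> %d cells, %d edges (%d isolated)\n",
              x$n_cells, x$n_edges, x$n_isolated))
  cat(sprintf("  lambda2/n (%s): %.4f\n", x$symmetrization,
              x$algebraic_connectivity_normalized))
  cat(sprintf("  reciprocal pairs: %.2f%%\n", x$reciprocal_percent))
  cat(sprintf("  open slope %.3f (R2 %.4f), closed slope %.3f (R2 %.4f)\n",
              x$open_slope$slope, x$open_slope$r_squared,
              x$closed_slope$slope, x$closed_slope$r_squared))
  oc <- x$oc_ratio[is.finite(x$oc_ratio)]
  if (length(oc))
    cat(sprintf("  mean O-C ratio (finite lengths): %.1f\n", mean(oc)))
  invisible(x)
}
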