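#' Pipeline run configuration
#'
#' Collects every parameter of an end-to-end run. Input comes either from
#' files (`raster_path`, `cellmap_path`) or, when both are `NULL`, from the
#' synthetic generator under `sim`.
#'
#' @param out_dir directory to write tables and the run summary into.
#' @param raster_path,cellmap_path input files (see [read_raster()],
#'   [read_cellmap()]), or `NULL` to simulate.
#' @param dialect raster file dialect.
#' @param frame_duration_ms,n_frames raster metadata for file input.
#' @param pia_angle_deg,fov_diameter_um cell-map metadata for file input.
#' @param sim a [sim_config()] used when simulating.
#' @param min_duration_ms,min_active_cells,max_gap_frames event detection
#'   parameters (see [detect_events()]).
#' @param min_events field-of-view inclusion rule (see [validate_fov()]).
#' @param p_random,k_nn null-model parameters.
#' @param K_walks,symmetrization invariant parameters.
#' @param fov_grid,weight_grid connectivity-surface grids; defaults span the
#'   field of view and the observed weight range.
#' @param fov_distances FOV-error evaluation grid; default 0 to the FOV
#'   diameter in 10 um steps.
#' @param radius_band_um width of flow-map radius bands (default 200).
#' @param max_fov_error target for [min_fov_for_error()] (default 0.10).
#' @param seed seed for the stochastic stages (null models; and the simulator
#'   via `sim$seed`).
#' @param log_level `"info"` or `"quiet"`.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir,
                       raster_path = NULL, cellmap_path = NULL,
                       dialect = "dense", frame_duration_ms = 86,
                       n_frames = NULL, pia_angle_deg = 90,
                       fov_diameter_um = 1100,
                       sim = sim_config(),
                       min_duration_ms = 500, min_active_cells = 1,
                       max_gap_frames = 0, min_events = 4,
                       p_random = 0.5, k_nn = 10,
                       K_walks = 10, symmetrization = "or",
                       fov_grid = NULL, weight_grid = NULL,
                       fov_distances = NULL, radius_band_um = 200,
                       max_fov_error = 0.10,
                       seed = 1, log_level = "info") {
  if (p_random < 0 || p_random > 1) stop("p_random must be in [0, 1]")
  if (max_fov_error <= 0 || max_fov_error >= 1)
    stop("max_fov_error must be in (0, 1)")
  structure(
    list(out_dir = out_dir, raster_path = raster_path,
         cellmap_path = cellmap_path, dialect = dialect,
         frame_duration_ms = frame_duration_ms, n_frames = n_frames,
         pia_angle_deg = pia_angle_deg, fov_diameter_um = fov_diameter_um,
         sim = sim, min_duration_ms = min_duration_ms,
         min_active_cells = min_active_cells,
         max_gap_frames = max_gap_frames, min_events = min_events,
         p_random = p_random, k_nn = k_nn, K_walks = K_walks,
         symmetrization = symmetrization, fov_grid = fov_grid,
         weight_grid = weight_grid, fov_distances = fov_distances,
         radius_band_um = radius_band_um, max_fov_error = max_fov_error,
         seed = as.integer(seed), log_level = log_level),
    class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates events -> graph construction -> null models -> invariants ->
#' spatial statistics -> field-of-view analysis for one field of view, writing
#' delimited tables plus a structured JSON summary (with the seed and a config
#' hash for provenance) into `config$out_dir`. Fields of view failing the
#' minimum-event inclusion rule are excluded: the run writes an exclusion
#' record and returns early with `excluded = TRUE`.
#'
#' @param config a [run_config()].
#' @return The report bundle (a list), invisibly. Key elements: `topology`,
#'   `events`, `captures`, `report`, `spatial`, `fov`, `excluded`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_info <- function(...) {
    if (identical(config$log_level, "info")) message(sprintf(...))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  config_hash <- rlang::hash(unclass(config))
  provenance <- list(seed = config$seed, config_hash = config_hash,
                     package_version = as.character(utils::packageVersion("fctopo")))

  # --- input stage -----------------------------------------------------------
  simulated <- is.null(config$raster_path)
  if (simulated) {
    log_info("stage input: simulating (%d cells, %d events, seed %d)",
             config$sim$n_cells, config$sim$n_events, config$sim$seed)
    cm <- sample_positions(config$sim)
    gt <- sample_ground_truth(cm, seed = config$sim$seed + 1L)
    simr <- simulate_raster(gt, config$sim)
    raster <- simr$raster
  } else {
    if (is.null(config$cellmap_path) || !file.exists(config$cellmap_path))
      stop("stage input: cell map not found: ",
           if (is.null(config$cellmap_path)) "(no path)" else config$cellmap_path)
    log_info("stage input: reading %s", config$raster_path)
    raster <- read_raster(config$raster_path, config$dialect,
                          config$frame_duration_ms, n_frames = config$n_frames)
    cm <- read_cellmap(config$cellmap_path, config$pia_angle_deg,
                       config$fov_diameter_um)
    if (!identical(cm$cell_id, raster$cell_ids))
      stop("stage input: raster and cell map cell ids are misaligned")
    gt <- NULL
  }

  # --- event stage -----------------------------------------------------------
  events <- detect_events(raster, config$min_duration_ms,
                          config$min_active_cells, config$max_gap_frames)
  log_info("stage events: %d cells, %d frames, %d events",
           length(raster$cell_ids), n_frames(raster), nrow(events))
  utils::write.csv(as.data.frame(events),
                   file.path(config$out_dir, "events.csv"), row.names = FALSE)
  if (!validate_fov(events, config$min_events)) {
    log_info("stage events: field of view EXCLUDED (%d < %d events)",
             nrow(events), config$min_events)
    summary <- c(provenance,
                 list(excluded = TRUE, n_events = nrow(events),
                      min_events = config$min_events))
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(list(excluded = TRUE, events = events,
                          provenance = provenance)))
  }

  # --- graph stage -----------------------------------------------------------
  topo <- build_topology(raster, events, cm)
  log_info("stage build: %d directed edges over %d events",
           sum(topo$weights > 0), topo$n_events)
  write_edgelist(topo, file.path(config$out_dir, "edges.csv"))

  # --- null stage ------------------------------------------------------------
  rnd <- random_topology(cm, config$p_random, seed = config$seed)
  knn <- knn_topology(cm, config$k_nn)
  captures <- list(random = capture_probability(topo, rnd),
                   knn = capture_probability(topo, knn))
  log_info("stage nulls: capture random %.3f, knn %.3f",
           captures$random$p_capture, captures$knn$p_capture)
  cap_df <- data.frame(
    graph = c("random", "knn"),
    n_edges = c(captures$random$n_null_edges, captures$knn$n_null_edges),
    p_capture = c(captures$random$p_capture, captures$knn$p_capture))
  utils::write.csv(cap_df, file.path(config$out_dir, "capture.csv"),
                   row.names = FALSE)

  # --- invariant stage -------------------------------------------------------
  report <- invariant_report(topo, K = config$K_walks,
                             symmetrization = config$symmetrization)
  null_connectivity <- c(
    random = algebraic_connectivity(rnd, config$symmetrization),
    knn = algebraic_connectivity(knn, config$symmetrization))
  log_info("stage invariants: lambda2/n data %.3f, random %.3f, knn %.3f",
           report$algebraic_connectivity_normalized,
           null_connectivity[["random"]], null_connectivity[["knn"]])
  utils::write.csv(
    data.frame(cell_id = topo$cell_ids,
               eigenvector = report$eigenvector$scores,
               total_degree = report$degree$scores),
    file.path(config$out_dir, "centrality.csv"), row.names = FALSE)

  # --- spatial stage ---------------------------------------------------------
  pd <- pairwise_distance_distribution(cm)
  cd <- connection_distance_distribution(topo)
  lam <- tryCatch(laminar_fractions(topo), error = function(e) NULL)
  fm <- flow_map(topo)
  bands <- flow_variance_by_band(
    fm, breaks = seq(0, attr(cm, "fov_diameter_um") + config$radius_band_um,
                     by = config$radius_band_um))
  log_info("stage spatial: %d flow points, overall circular variance %.3f",
           nrow(fm), circular_variance(fm$theta))
  utils::write.csv(data.frame(mid_um = pd$mids, pairwise = pd$prob,
                              connection = cd$prob),
                   file.path(config$out_dir, "distance_histograms.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(fm), file.path(config$out_dir, "flow_map.csv"),
                   row.names = FALSE)
  utils::write.csv(bands, file.path(config$out_dir, "flow_variance.csv"),
                   row.names = FALSE)

  # --- fov stage -------------------------------------------------------------
  fov_distances <- config$fov_distances
  if (is.null(fov_distances))
    fov_distances <- seq(0, attr(cm, "fov_diameter_um"), by = 10)
  curve <- fov_error_curve(topo, fov_distances)
  min_fov <- tryCatch(min_fov_for_error(curve, config$max_fov_error),
                      error = function(e) NA_real_)
  fov_grid <- config$fov_grid
  if (is.null(fov_grid))
    fov_grid <- seq(200, attr(cm, "fov_diameter_um"), length.out = 4)
  weight_grid <- config$weight_grid
  if (is.null(weight_grid)) {
    wmax <- max(topo$weights)
    weight_grid <- if (wmax > 0) seq(0, wmax / 2, length.out = 3) else 0
  }
  surface <- connectivity_surface(topo, fov_grid, weight_grid,
                                  symmetrization = config$symmetrization)
  dens <- cumulative_density(cm, fov_distances)
  log_info("stage fov: minimum FOV for <%.0f%% error: %s um",
           100 * config$max_fov_error,
           if (is.na(min_fov)) "unachieved" else format(min_fov))
  utils::write.csv(data.frame(distance_um = curve$distances,
                              fov_error = curve$error,
                              cumulative_cells = dens),
                   file.path(config$out_dir, "fov_error.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(surface),
                   file.path(config$out_dir, "connectivity_surface.csv"))

  # --- summary ---------------------------------------------------------------
  finite_oc <- report$oc_ratio[is.finite(report$oc_ratio)]
  summary <- c(provenance, list(
    excluded = FALSE, simulated = simulated,
    n_cells = length(topo$cell_ids), n_events = nrow(events),
    n_edges = report$n_edges,
    capture_random = captures$random$p_capture,
    capture_knn = captures$knn$p_capture,
    algebraic_connectivity_normalized = report$algebraic_connectivity_normalized,
    algebraic_connectivity_random = unname(null_connectivity[["random"]]),
    algebraic_connectivity_knn = unname(null_connectivity[["knn"]]),
    reciprocal_percent = report$reciprocal_percent,
    mean_oc_ratio = if (length(finite_oc)) mean(finite_oc) else NA,
    open_slope = report$open_slope$slope,
    open_r_squared = report$open_slope$r_squared,
    closed_slope = report$closed_slope$slope,
    closed_r_squared = report$closed_slope$r_squared,
    circular_variance = circular_variance(fm$theta),
    min_fov_um = min_fov,
    laminar = lam))
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(
    excluded = FALSE, raster = raster, cellmap = cm, events = events,
    topology = topo, ground_truth = gt, nulls = list(random = rnd, knn = knn),
    captures = captures, report = report,
    null_connectivity = null_connectivity,
    spatial = list(pairwise = pd, connection = cd, laminar = lam,
                   flow_map = fm, flow_bands = bands),
    fov = list(curve = curve, min_fov_um = min_fov, surface = surface,
               cumulative_cells = dens),
    provenance = provenance))
}

#' Report-level group comparisons
#'
#' Thin wrappers around the standard nonparametric tests used when comparing
#' invariant values between areas or models: the Kruskal-Wallis rank test for
#' two or more groups and the two-sample Kolmogorov-Smirnov test for exactly
#' two groups. Significance is flagged at p < 0.05.
#'
#' @param values_by_group named list of numeric vectors, one per group.
#' @param test `"kruskal_wallis"` (default) or `"ks_two_sample"`.
#' @return List with `statistic`, `p_value`, `test`, `significant`.
#' @export
compare_groups <- function(values_by_group,
                           test = c("kruskal_wallis", "ks_two_sample")) {
  test <- match.arg(test)
  if (!is.list(values_by_group) || length(values_by_group) < 2)
    stop("need at least 2 groups")
  sizes <- lengths(values_by_group)
  if (test == "kruskal_wallis") {
    if (any(sizes < 2)) stop("each group needs at least 2 values")
    ht <- stats::kruskal.test(values_by_group)
  } else {
    if (length(values_by_group) != 2)
      stop("the two-sample KS test needs exactly 2 groups")
    if (any(sizes < 2)) stop("each group needs at least 2 values")
    ht <- suppressWarnings(
      stats::ks.test(values_by_group[[1]], values_by_group[[2]]))
  }
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value),
       test = test, significant = ht$p.value < 0.05)
}
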