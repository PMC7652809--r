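#' Benchmark community detectors over an LFR grid
#'
#' Runs each detector on each generated network, recording NMI, ARI,
#' modularity, the detected and true community counts, and aggregates mean
#' and standard deviation per mixing level. Individual run failures are
#' recorded and the harness continues.
#'
#' Detectors: `"scd-netmf"` and `"scd-ppr"` are the package's own method;
#' `"louvain"` and `"label-propagation"` are thin adapters around igraph
#' baselines (non-core, for comparison only).
#'
#' @param grid data frame of LFR specs as from [lfr_benchmark_grid()].
#' @param detectors character vector of detector names.
#' @param seed master seed; run `r` of spec `i` derives its own seed.
#' @param K_max cap on the maximum community count searched (default
#'   `n / 4`).
#' @param out_dir optional directory: writes `runs.csv` and `summary.csv`.
#' @param verbose print per-run progress.
#' @return list with `runs` (one row per network x detector), `summary`
#'   (mean +/- sd by mixing and detector) and `k_diff` (detected minus true
#'   community counts).
#' @export
scd_benchmark <- function(grid, detectors = "scd-netmf", seed = 42L,
                          K_max = NULL, out_dir = NULL, verbose = FALSE) {
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    sp <- grid[i, ]
    net <- tryCatch(
      generate_lfr(sp$n, sp$avg_degree, sp$max_degree, sp$mixing,
                   sp$degree_exponent, sp$community_exponent,
                   seed = derive_seed(seed, 3L, i)),
      error = function(e) e)
    if (inherits(net, "error")) {
      rows[[length(rows) + 1L]] <- data.frame(
        spec = i, n = sp$n, mixing = sp$mixing, detector = NA_character_,
        nmi = NA_real_, ari = NA_real_, modularity = NA_real_,
        k_detected = NA_integer_, k_true = NA_integer_,
        error = conditionMessage(net))
      next
    }
    k_true <- n_communities(net$truth)
    for (det in detectors) {
      if (verbose) message(sprintf("spec %d/%d (n=%d, mu=%.1f): %s",
                                   i, nrow(grid), sp$n, sp$mixing, det))
      res <- tryCatch(
        run_detector(net$graph, det, seed = derive_seed(seed, 5L, i),
                     K_max = K_max),
        error = function(e) e)
      if (inherits(res, "error")) {
        rows[[length(rows) + 1L]] <- data.frame(
          spec = i, n = sp$n, mixing = sp$mixing, detector = det,
          nmi = NA_real_, ari = NA_real_, modularity = NA_real_,
          k_detected = NA_integer_, k_true = k_true,
          error = conditionMessage(res))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        spec = i, n = sp$n, mixing = sp$mixing, detector = det,
        nmi = nmi(net$truth, res), ari = ari(net$truth, res),
        modularity = modularity(net$graph, res),
        k_detected = n_communities(res), k_true = k_true, error = NA_character_)
    }
  }
  runs <- do.call(rbind, rows)
  ok <- runs[is.na(runs$error), , drop = FALSE]
  summary <- do.call(rbind, lapply(split(ok, list(ok$mixing, ok$detector), drop = TRUE),
    function(g) data.frame(mixing = g$mixing[1], detector = g$detector[1],
                           n_runs = nrow(g),
                           nmi_mean = mean(g$nmi), nmi_sd = stats::sd(g$nmi),
                           ari_mean = mean(g$ari), ari_sd = stats::sd(g$ari),
                           modularity_mean = mean(g$modularity),
                           modularity_sd = stats::sd(g$modularity))))
  summary <- summary[order(summary$mixing, summary$detector), , drop = FALSE]
  rownames(summary) <- NULL
  k_diff <- ok[, c("spec", "detector", "k_true", "k_detected")]
  k_diff$k_diff <- k_diff$k_detected - k_diff$k_true
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(runs, file.path(out_dir, "runs.csv"), row.names = FALSE)
    utils::write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
    utils::write.csv(k_diff, file.path(out_dir, "k_diff.csv"), row.names = FALSE)
  }
  list(runs = runs, summary = summary, k_diff = k_diff)
}

run_detector <- function(G, detector, seed, K_max = NULL, gamma = 10L) {
  if (detector %in% c("scd-netmf", "scd-ppr")) {
    # benchmark protocol: candidate range [5, |N|] in strides of 10
    K <- if (is.null(K_max)) G$n_nodes - 1L else as.integer(K_max)
    grid <- if (detector == "scd-netmf")
      list(embedding_setting("netmf", T_window = 3L, b = 1L,
                             d = min(32L, G$n_nodes)))
    else list(embedding_setting("ppr"))
    cfg <- scd_config(K = min(K, G$n_nodes - 1L), k_min = 5L, gamma = gamma,
                      w = 5L, embedding_grid = grid, seed = seed)
    return(scd_detect(G, cfg)$partition)
  }
  ig <- igraph::graph_from_adjacency_matrix(G$A, mode = "undirected",
                                            weighted = TRUE)
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  comm <- switch(detector,
    "louvain" = igraph::cluster_louvain(ig),
    "label-propagation" = igraph::cluster_label_prop(ig),
    stop("unknown detector: ", detector))
  scd_partition(igraph::membership(comm), G$node_ids)
}

#' Sensitivity of the community count to the sampling interval
#'
#' Runs the silhouette search with several coarse-phase intervals
#' \eqn{\gamma} (always including the exhaustive reference \eqn{\gamma = 1})
#' on one network and records the selected k and its silhouette for each.
#'
#' @param G an [scd_graph()].
#' @param gammas integer vector of intervals to test; 1 is added if missing.
#' @param K maximum community count searched.
#' @param k_min smallest k.
#' @param setting an [embedding_setting()]; the same embedding is reused for
#'   every gamma.
#' @param seed master seed.
#' @param w stopping window (default 5).
#' @return data frame with columns `gamma`, `selected_k`, `silhouette`,
#'   `n_evaluations`.
#' @export
scd_gamma_experiment <- function(G, gammas = c(1L, 2L, 5L), K,
                                 k_min = 2L,
                                 setting = embedding_setting("netmf"),
                                 seed = 42L, w = 5L) {
  gammas <- sort(unique(c(1L, as.integer(gammas))))
  X <- embed_with_setting(G, modifyList(setting, list(d = min(setting$d %||% 32L, G$n_nodes))), seed)
  out <- lapply(gammas, function(g) {
    cfg <- scd_config(K = K, k_min = k_min, gamma = g, w = w,
                      embedding_grid = list(setting), seed = seed)
    co <- coarse_search(X, cfg, setting_idx = 1L)
    fi <- fine_search(X, cfg, co$k_star, setting_idx = 1L, coarse = co)
    best_row <- fi$trace[which.max(fi$trace$silhouette), ]
    data.frame(gamma = g, selected_k = best_row$k_realized,
               silhouette = fi$best_sil, n_evaluations = nrow(fi$trace))
  })
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
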