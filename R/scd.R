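#' Embedding settings and grids
#'
#' An embedding setting names the embedder and its parameters; a grid (list
#' of settings) is the space \eqn{\mathcal{P}} the community search
#' traverses. `embedding_grid("benchmark-grid")` is the full NetMF sweep of
#' the benchmark design (negative samples {1,5,20} x window {1,3,5,10,30,50}
#' x dimension {16,32,64,128,256}); `"fast-grid"` is a small default for
#' desk-scale runs.
#'
#' @param method `"netmf"` or `"ppr"`.
#' @param ... embedder parameters: for netmf `T_window`, `b`, `d`; for ppr
#'   `alpha`, `tol`, `normalize`.
#' @return an `scd_setting` (named list).
#' @export
embedding_setting <- function(method = c("netmf", "ppr"), ...) {
  method <- match.arg(method)
  p <- list(...)
  s <- if (method == "netmf") {
    modifyList(list(method = "netmf", T_window = 3L, b = 1L, d = 32L), p)
  } else {
    modifyList(list(method = "ppr", alpha = 0.85, tol = 1e-6, normalize = FALSE), p)
  }
  structure(s, class = "scd_setting")
}

#' @rdname embedding_setting
#' @param name grid preset name.
#' @export
embedding_grid <- function(name = c("fast-grid", "benchmark-grid")) {
  name <- match.arg(name)
  if (name == "fast-grid") {
    return(list(embedding_setting("netmf", T_window = 3L, b = 1L, d = 16L),
                embedding_setting("netmf", T_window = 3L, b = 1L, d = 32L)))
  }
  grid <- expand.grid(b = c(1L, 5L, 20L), T_window = c(1L, 3L, 5L, 10L, 30L, 50L),
                      d = c(16L, 32L, 64L, 128L, 256L))
  lapply(seq_len(nrow(grid)), function(i)
    embedding_setting("netmf", T_window = grid$T_window[i], b = grid$b[i], d = grid$d[i]))
}

setting_id <- function(s) {
  if (s$method == "netmf") sprintf("netmf(T=%d,b=%d,d=%d)", s$T_window, s$b, s$d)
  else sprintf("ppr(alpha=%g%s)", s$alpha, if (isTRUE(s$normalize)) ",l2" else "")
}

#' Search configuration for Silhouette community detection
#'
#' @param K maximum number of clusters considered (`k_min <= K <= n`).
#' @param k_min smallest candidate k (default 5; lowered to 2 automatically
#'   when `K < 5`).
#' @param gamma coarse sampling interval: positive integer or `"auto"` for
#'   the analytic estimate \eqn{\gamma = \lceil K^{2/3} \rceil}.
#' @param w stopping window: a search phase halts after `w` consecutive
#'   evaluations without silhouette improvement (default 5).
#' @param embedding_grid list of [embedding_setting()]s.
#' @param seed master seed for all stochastic steps.
#' @param batch_size mini-batch size for k-means (default `min(n, 1024)`).
#' @param n_init k-means restarts per evaluation.
#' @param subsample silhouette subsample size; default: full computation up
#'   to 5000 points, subsample of 5000 above that.
#' @param normalize_across_dims min-max normalize silhouettes within each
#'   embedding dimension before the cross-grid argmax (see vignette); set
#'   `FALSE` to compare raw silhouettes.
#' @return an `scd_config` list.
#' @export
scd_config <- function(K, k_min = 5L, gamma = "auto", w = 5L,
                       embedding_grid = scdnet::embedding_grid("fast-grid"),
                       seed = 42L, batch_size = NULL, n_init = 3L,
                       subsample = NULL, normalize_across_dims = TRUE) {
  k_min <- as.integer(max(2L, min(k_min, K)))
  stopifnot(K >= k_min, w >= 1, length(embedding_grid) >= 1)
  if (!identical(gamma, "auto")) {
    gamma <- as.integer(gamma)
    stopifnot(gamma >= 1)
  }
  structure(list(K = as.integer(K), k_min = k_min, gamma = gamma, w = as.integer(w),
                 embedding_grid = embedding_grid, seed = as.integer(seed),
                 batch_size = batch_size, n_init = as.integer(n_init),
                 subsample = subsample,
                 normalize_across_dims = isTRUE(normalize_across_dims)),
            class = "scd_config")
}

#' Analytic coarse-search interval
#'
#' \eqn{\gamma = \sqrt[3]{K^2}}, the interval between candidate k values that
#' balances coarse-search cost against resolution when at most `K` communities
#' are expected; rounded up (never more coarse evaluations than the floor)
#' and at least 1.
#'
#' @param K maximum number of communities expected.
#' @return positive integer `ceil(K^(2/3))`.
#' @export
gamma_estimate <- function(K) {
  stopifnot(K >= 1)
  max(1L, as.integer(ceiling(K^(2 / 3) - 1e-9)))
}

#' Candidate k values of the coarse phase
#'
#' Arithmetic sequence `k_min, k_min + gamma, ...` up to `K`, with `K`
#' appended when the stride does not land on it.
#'
#' @param k_min smallest k.
#' @param K largest k.
#' @param gamma stride (positive integer or `"auto"`).
#' @return increasing integer vector, never empty.
#' @export
valid_range <- function(k_min, K, gamma = "auto") {
  if (identical(gamma, "auto")) gamma <- gamma_estimate(K)
  stopifnot(k_min >= 2, K >= k_min, gamma >= 1)
  ks <- seq.int(k_min, K, by = gamma)
  if (ks[length(ks)] != K) ks <- c(ks, as.integer(K))
  as.integer(ks)
}

resolve_gamma <- function(config) {
  if (identical(config$gamma, "auto")) gamma_estimate(config$K) else config$gamma
}

# cluster the embedding at one k and score it; silhouette NA if < 2 realized
# clusters
evaluate_k <- function(X, k, config, setting_idx) {
  km <- suppressWarnings(
    minibatch_kmeans(X, k, seed = derive_seed(config$seed, setting_idx, k),
                     batch_size = config$batch_size, n_init = config$n_init))
  sil <- if (km$k < 2) NA_real_ else
    silhouette_global(km$labels, X, subsample = effective_subsample(config, nrow(X)),
                      seed = config$seed)
  list(k = k, k_realized = km$k, silhouette = sil, labels = km$labels)
}

effective_subsample <- function(config, n) {
  if (!is.null(config$subsample)) return(config$subsample)
  if (n > 5000) 5000L else NULL
}

run_phase <- function(X, config, setting_idx, ks, phase, best_sil = -Inf) {
  rows <- list(); evaluated <- integer(0)
  no_improve <- 0L
  for (k in ks) {
    ev <- evaluate_k(X, k, config, setting_idx)
    rows[[length(rows) + 1L]] <- data.frame(phase = phase, k = k,
                                            k_realized = ev$k_realized,
                                            silhouette = ev$silhouette)
    evaluated <- c(evaluated, k)
    if (!is.na(ev$silhouette) && ev$silhouette > best_sil) {
      best_sil <- ev$silhouette
      no_improve <- 0L
    } else no_improve <- no_improve + 1L
    if (no_improve >= config$w) break
  }
  list(trace = do.call(rbind, rows), evaluated = evaluated, best_sil = best_sil)
}

#' Coarse sweep over candidate k values
#'
#' Evaluates the clustering silhouette over [valid_range()] in ascending
#' order, halting the phase after `w` consecutive non-improving evaluations.
#'
#' @param X embedding matrix.
#' @param config an [scd_config()].
#' @param setting_idx index of the embedding setting (seeds the k-means).
#' @return list with `trace` (data frame of evaluations), `k_star` (argmax k)
#'   and `best_sil`.
#' @export
coarse_search <- function(X, config, setting_idx = 1L) {
  ks <- valid_range(config$k_min, min(config$K, nrow(X)), config$gamma)
  ph <- run_phase(X, config, setting_idx, ks, "coarse")
  if (all(is.na(ph$trace$silhouette)))
    stop("no candidate k produced at least 2 non-empty clusters")
  best <- which.max(ph$trace$silhouette)
  list(trace = ph$trace, k_star = ph$trace$k[best],
       best_sil = ph$trace$silhouette[best])
}

#' Fine-grained neighborhood search around the coarse optimum
#'
#' Exhaustively inspects integer k in `[max(2, k* - gamma), min(K, k* + gamma)]`
#' not yet evaluated, scanning outward from `k*` (alternating `k*-1`, `k*+1`,
#' `k*-2`, ...) so the stopping window acts near the optimum; same stopping
#' rule as the coarse phase.
#'
#' @inheritParams coarse_search
#' @param k_star coarse-phase optimum.
#' @param coarse result of [coarse_search()] (for the merged trace/stopping
#'   baseline); optional.
#' @return list with merged `trace`, global `k_star`, `best_sil`.
#' @export
fine_search <- function(X, config, k_star, setting_idx = 1L, coarse = NULL) {
  gamma <- resolve_gamma(config)
  lo <- max(2L, k_star - gamma); hi <- min(config$K, nrow(X), k_star + gamma)
  order_ks <- k_star             # outward: k*-1, k*+1, k*-2, ...
  for (o in seq_len(max(k_star - lo, hi - k_star))) {
    if (k_star - o >= lo) order_ks <- c(order_ks, k_star - o)
    if (k_star + o <= hi) order_ks <- c(order_ks, k_star + o)
  }
  already <- if (is.null(coarse)) k_star else unique(c(coarse$trace$k, k_star))
  ks <- setdiff(order_ks, already)
  base_sil <- if (is.null(coarse)) -Inf else coarse$best_sil
  ph <- run_phase(X, config, setting_idx, ks, "fine", best_sil = base_sil)
  trace <- rbind(if (!is.null(coarse)) coarse$trace, ph$trace)
  ok <- !is.na(trace$silhouette)
  best <- which(ok)[which.max(trace$silhouette[ok])]
  list(trace = trace, k_star = trace$k[best], best_sil = trace$silhouette[best])
}

#' Silhouette community detection
#'
#' For every embedding setting in the grid: embed the nodes, run the coarse
#' sweep over candidate community counts, then refine around the coarse
#' optimum. The final partition maximizes the global silhouette over
#' \eqn{(k, p)}; when the grid spans several embedding dimensions the
#' silhouettes are min-max normalized within each dimension before the
#' cross-grid argmax (disable via `normalize_across_dims = FALSE`). Ties
#' break toward smaller k, then smaller dimension, then earlier grid order.
#'
#' @param G an [scd_graph()].
#' @param config an [scd_config()].
#' @param verbose print per-setting progress.
#' @return an `scd_result`: list with `partition` ([scd_partition()] labeled
#'   by external node ids), `k`, `silhouette`, `normalized_silhouette`,
#'   `setting`, `trace` (data frame over all evaluations), `config`.
#' @export
scd_detect <- function(G, config, verbose = FALSE) {
  stopifnot(inherits(G, "scd_graph"), inherits(config, "scd_config"))
  grid <- config$embedding_grid
  ids <- vapply(grid, setting_id, "")
  keep <- !duplicated(ids)
  grid <- grid[keep]; ids <- ids[keep]
  if (length(grid) == 0) stop("embedding grid is empty")
  traces <- vector("list", length(grid))
  for (gi in seq_along(grid)) {
    s <- grid[[gi]]
    if (verbose) message("embedding setting ", ids[gi])
    X <- embed_with_setting(G, s, config$seed)
    co <- coarse_search(X, config, setting_idx = gi)
    fi <- fine_search(X, config, co$k_star, setting_idx = gi, coarse = co)
    tr <- fi$trace
    tr$setting <- ids[gi]; tr$setting_idx <- gi
    tr$d <- ncol(X)
    traces[[gi]] <- tr
  }
  trace <- do.call(rbind, traces)
  trace$norm_silhouette <- normalize_by_dim(trace$silhouette, trace$d,
                                            config$normalize_across_dims)
  ok <- which(!is.na(trace$norm_silhouette))
  ord <- ok[order(-trace$norm_silhouette[ok], trace$k[ok], trace$d[ok],
                  trace$setting_idx[ok])]
  win <- trace[ord[1L], ]
  ws <- grid[[win$setting_idx]]
  Xw <- embed_with_setting(G, ws, config$seed)
  ev <- evaluate_k(Xw, win$k, config, win$setting_idx)
  P <- scd_partition(ev$labels, G$node_ids)
  structure(list(partition = P, k = ev$k_realized,
                 silhouette = ev$silhouette,
                 normalized_silhouette = win$norm_silhouette,
                 setting = ws, setting_id = win$setting,
                 trace = trace, config = config),
            class = "scd_result")
}

embed_with_setting <- function(G, s, seed) {
  if (s$method == "netmf")
    embed_netmf(G, T_window = s$T_window, b = s$b, d = min(s$d, G$n_nodes),
                seed = seed)
  else
    embed_ppr(G, alpha = s$alpha, tol = s$tol, normalize = isTRUE(s$normalize))
}

normalize_by_dim <- function(sil, d, enabled) {
  if (!enabled || length(unique(d)) < 2) return(sil)
  out <- sil
  for (dd in unique(d)) {
    m <- d == dd & !is.na(sil)
    if (!any(m)) next
    rng <- range(sil[m])
    out[m] <- if (diff(rng) > 0) (sil[m] - rng[1]) / diff(rng) else 0.5
  }
  out
}

#' @export
print.scd_result <- function(x, ...) {
  cat(sprintf("<scd_result> k = %d communities, silhouette = %.4f (%s)\n",
              x$k, x$silhouette, x$setting_id))
  cat(sprintf("  %d evaluations (%d coarse, %d fine)\n", nrow(x$trace),
              sum(x$trace$phase == "coarse"), sum(x$trace$phase == "fine")))
  invisible(x)
}

#' Serialize a detection result
#'
#' Writes the membership TSV and a JSON report with the selected k, embedding
#' parameters, silhouettes and the full search trace.
#'
#' @param res an `scd_result`.
#' @param prefix output path prefix (`<prefix>.membership.tsv`,
#'   `<prefix>.report.json`).
#' @export
write_scd_result <- function(res, prefix) {
  write_membership(res$partition, paste0(prefix, ".membership.tsv"))
  report <- list(selected_k = res$k,
                 selected_embedding_params = res$setting[names(res$setting) != "method"],
                 embedding_method = res$setting$method,
                 silhouette = res$silhouette,
                 normalized_silhouette = res$normalized_silhouette,
                 trace = res$trace[, c("phase", "setting", "k", "silhouette")],
                 seed = res$config$seed)
  jsonlite::write_json(report, paste0(prefix, ".report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(prefix)
}
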