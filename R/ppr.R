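#' Personalized PageRank vector by power iteration
#'
#' Stationary distribution of a random walk that, at each step, follows a
#' weight-proportional outgoing edge with probability `alpha` and restarts at
#' the seed node `u` with probability `1 - alpha`:
#' \deqn{\gamma_u(i)^{(k+1)} = \alpha \sum_{j \to i}
#'   \frac{w_{ji}}{d_j^{out}}\,\gamma_u(j)^{(k)} + (1-\alpha)\, v_u(i),}
#' with restart vector \eqn{v_u} the indicator of `u`. Undirected edges are
#' treated as two directed edges and \eqn{d_j^{out}} is the weighted degree.
#' The iteration is restricted ("shrinking") to the connected component of
#' `u`, which changes nothing numerically: unreachable nodes receive exactly
#' zero mass. Dangling mass (possible only for isolated seeds) restarts to
#' \eqn{v_u}, preserving \eqn{\sum_i \gamma_u(i) = 1}.
#'
#' @param G an [scd_graph()].
#' @param u seed node: internal index (1-based) or external id string.
#' @param alpha damping factor in (0, 1).
#' @param tol convergence threshold on the L1 difference of successive
#'   iterates.
#' @param max_iter iteration cap; non-convergence is an error reporting the
#'   last residual.
#' @return numeric probability vector over all nodes (named by node id).
#' @export
ppr_vector <- function(G, u, alpha = 0.85, tol = 1e-6, max_iter = 1e5) {
  stopifnot(inherits(G, "scd_graph"), alpha > 0, alpha < 1, tol > 0, max_iter >= 1)
  if (is.character(u)) {
    ui <- match(u, G$node_ids)
    if (is.na(ui)) stop("unknown seed node: ", u)
  } else ui <- as.integer(u)
  if (ui < 1 || ui > G$n_nodes) stop("seed index out of range")
  comp <- reachable_set(G, ui)
  A <- G$A[comp, comp, drop = FALSE]
  d <- Matrix::rowSums(A)
  n <- length(comp)
  seed_pos <- match(ui, comp)
  v <- numeric(n); v[seed_pos] <- 1
  g <- v
  dangling <- d == 0
  dsafe <- ifelse(dangling, 1, d)
  for (k in seq_len(max_iter)) {
    # t(P) %*% g with P = D^-1 A; A symmetric so t(P) = A D^-1
    walk <- as.numeric(A %*% (g / dsafe))
    loss <- sum(g[dangling])              # dangling mass restarts at the seed
    g_new <- alpha * (walk + loss * v) + (1 - alpha) * v
    res <- sum(abs(g_new - g))
    g <- g_new
    if (res < tol) {
      out <- numeric(G$n_nodes)
      out[comp] <- g / sum(g)
      names(out) <- G$node_ids
      return(out)
    }
  }
  stop(sprintf("PPR power iteration did not converge in %d iterations (last L1 residual %.3e)",
               as.integer(max_iter), res))
}

# indices of nodes reachable from ui (BFS over the sparse adjacency)
reachable_set <- function(G, ui) {
  seen <- logical(G$n_nodes)
  seen[ui] <- TRUE
  frontier <- ui
  At <- G$A
  while (length(frontier)) {
    nb <- unique(At[, frontier, drop = FALSE]@i + 1L)
    frontier <- nb[!seen[nb]]
    seen[frontier] <- TRUE
  }
  which(seen)
}

#' Personalized PageRank embedding
#'
#' One PPR vector per node, stacked into an `n x n` matrix whose row `u` is
#' `ppr_vector(G, u)`. Rows are independent, so computation is embarrassingly
#' parallel and deterministic: `n_jobs = 1` and `n_jobs > 1` yield identical
#' matrices.
#'
#' @inheritParams ppr_vector
#' @param n_jobs number of worker processes (forked; falls back to serial on
#'   platforms without fork).
#' @param normalize L2-normalize rows before clustering (off by default; raw
#'   PPR rows are simplex vectors).
#' @return `scd_embedding` of dimension `n x n`.
#' @export
embed_ppr <- function(G, alpha = 0.85, tol = 1e-6, max_iter = 1e5,
                      n_jobs = 1L, normalize = FALSE) {
  idx <- seq_len(G$n_nodes)
  fun <- function(u) ppr_vector(G, u, alpha = alpha, tol = tol, max_iter = max_iter)
  rows <- if (n_jobs > 1L && .Platform$OS.type == "unix")
    parallel::mclapply(idx, fun, mc.cores = n_jobs)
  else lapply(idx, fun)
  E <- do.call(rbind, rows)
  rownames(E) <- G$node_ids
  colnames(E) <- NULL
  if (normalize) {
    nrm <- sqrt(rowSums(E^2))
    E <- E / ifelse(nrm == 0, 1, nrm)
  }
  new_embedding(E, list(method = "ppr", alpha = alpha, tol = tol,
                        d = ncol(E), normalized = normalize))
}
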