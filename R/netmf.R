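#' Closed-form DeepWalk matrix
#'
#' DeepWalk with window size `T` and `b` negative samples implicitly
#' factorizes
#' \deqn{M = \log\Big(\frac{vol(G)}{b}\Big(\frac{1}{T}\sum_{r=1}^{T}
#'   (D^{-1}A)^r\Big) D^{-1}\Big),}
#' where \eqn{A} is the weighted adjacency matrix, \eqn{D} the diagonal of
#' generalized degrees and \eqn{vol(G)=\sum_{ij}A_{ij}}. Entries below 1 are
#' clipped to 1 before the logarithm (truncated log), so `M` is non-negative
#' and finite everywhere; this matches the standard NetMF construction and
#' absorbs the \eqn{-\log b} term for entries above the clip.
#'
#' @param G an [scd_graph()]; must have no zero-degree node.
#' @param T_window context window size (positive integer).
#' @param b number of negative samples (positive integer).
#' @return dense `n x n` matrix with non-negative finite entries.
#' @export
deepwalk_matrix <- function(G, T_window = 3L, b = 1L) {
  stopifnot(inherits(G, "scd_graph"), T_window >= 1, b >= 1)
  d <- Matrix::rowSums(G$A)
  if (any(d == 0))
    stop("graph has isolated (zero-degree) nodes; remove them before embedding")
  vol <- sum(d)
  A <- as.matrix(G$A)
  P <- A / d                       # D^-1 A, row-stochastic
  S <- P
  if (T_window > 1) {
    Pr <- P
    for (r in 2:T_window) {
      Pr <- Pr %*% P
      S <- S + Pr
    }
  }
  S <- S / T_window
  M_raw <- (vol / b) * sweep(S, 2L, d, "/")   # vol * S * D^-1 / b
  M <- log(pmax(M_raw, 1))
  dimnames(M) <- list(G$node_ids, G$node_ids)
  M
}

#' Factorize a matrix into a d-dimensional embedding
#'
#' Rank-`d` truncated SVD \eqn{M \approx U_d \Sigma_d V_d^T}; the embedding is
#' \eqn{U_d \sqrt{\Sigma_d}} (standard NetMF scaling). The LAPACK solver is
#' deterministic; `seed` is accepted for interface uniformity with stochastic
#' solvers and recorded in provenance.
#'
#' @param M square numeric matrix, finite entries.
#' @param d embedding dimension, `1 <= d <= nrow(M)`.
#' @param seed recorded in provenance (the dense SVD itself is deterministic).
#' @return `scd_embedding` matrix (`n x d`) with node ids as row names and a
#'   `provenance` attribute.
#' @export
factorize <- function(M, d, seed = 42L) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) stop("M must be square")
  if (any(!is.finite(M))) stop("M must be finite")
  if (d < 1 || d > nrow(M)) stop("embedding dimension d must satisfy 1 <= d <= n")
  s <- svd(M, nu = d, nv = 0)
  E <- s$u * rep(sqrt(s$d[seq_len(d)]), each = nrow(M))
  rownames(E) <- rownames(M)
  new_embedding(E, list(method = "svd", d = d, scaling = "U*sqrt(Sigma)", seed = seed))
}

new_embedding <- function(E, provenance) {
  stopifnot(is.matrix(E), all(is.finite(E)))
  structure(E, provenance = provenance, class = c("scd_embedding", "matrix", "array"))
}

#' @export
print.scd_embedding <- function(x, ...) {
  p <- attr(x, "provenance")
  cat(sprintf("<scd_embedding> %d nodes x %d dims (%s)\n",
              nrow(x), ncol(x), paste(names(p), unlist(p), sep = "=", collapse = ", ")))
  invisible(x)
}

#' NetMF node embedding
#'
#' Composes [deepwalk_matrix()] and [factorize()]: builds the closed-form
#' DeepWalk matrix and embeds the nodes by truncated SVD.
#'
#' @param G an [scd_graph()].
#' @param T_window context window size.
#' @param b number of negative samples.
#' @param d embedding dimension.
#' @param seed passed to [factorize()].
#' @param verbose log the density of the truncated matrix.
#' @return `scd_embedding` (`n x d`), rows aligned with `G$node_ids`.
#' @export
embed_netmf <- function(G, T_window = 3L, b = 1L, d = 32L, seed = 42L,
                        verbose = FALSE) {
  if (d > G$n_nodes) stop("embedding dimension exceeds number of nodes")
  M <- deepwalk_matrix(G, T_window = T_window, b = b)
  if (verbose)
    message(sprintf("deepwalk matrix density after truncated log: %.3f",
                    mean(M > 0)))
  E <- factorize(M, d, seed = seed)
  attr(E, "provenance") <- list(method = "netmf", T_window = T_window, b = b,
                                d = d, scaling = "U*sqrt(Sigma)",
                                log_clip = 1, seed = seed)
  E
}

#' Persist / load an embedding as TSV + JSON sidecar
#'
#' TSV columns: node id followed by the `d` embedding coordinates; the JSON
#' sidecar (`<path>.json`) records the provenance parameters.
#'
#' @param E an `scd_embedding`.
#' @param path TSV output path.
#' @export
write_embedding <- function(E, path) {
  df <- data.frame(node = rownames(E), as.data.frame(unclass(E)[, , drop = FALSE]))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(attr(E, "provenance"), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = c("character", rep(NA, -1 + ncol(
                            utils::read.table(path, sep = "\t", nrows = 1)))))
  E <- as.matrix(df[, -1, drop = FALSE])
  rownames(E) <- df[[1]]
  colnames(E) <- NULL
  prov <- if (file.exists(paste0(path, ".json")))
    jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  else list(method = "unknown")
  new_embedding(E, prov)
}
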