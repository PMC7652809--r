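#' Silhouette score of a single point
#'
#' For point `i` in cluster \eqn{C_i}, cohesion is the average Euclidean
#' distance to the rest of its cluster,
#' \eqn{a(i) = \frac{1}{|C_i|-1}\sum_{j \in C_i} dist(i,j)}, and separation is
#' the smallest average distance to another cluster,
#' \eqn{b(i) = \min_{C_j \ne C_i} \frac{1}{|C_j|}\sum_{k \in C_j} dist(i,k)}.
#' Then \eqn{s(i) = (b(i) - a(i)) / \max(a(i), b(i))}, with \eqn{s(i) = 0}
#' when `i` is alone in its cluster (where `a(i)` is undefined) and 0 when
#' both `a` and `b` vanish.
#'
#' @param i point index (row of `X`).
#' @param labels cluster label per row of `X` (at least 2 distinct).
#' @param X numeric matrix of points.
#' @return silhouette value in `[-1, 1]`.
#' @export
silhouette_point <- function(i, labels, X) {
  silhouette_values(labels, X)[i]
}

#' Per-point silhouette values (vectorized)
#'
#' @inheritParams silhouette_point
#' @return numeric vector of `s(i)` for every row of `X`.
#' @export
silhouette_values <- function(labels, X) {
  X <- as.matrix(unclass(X))
  labels <- as.character(labels)
  n <- nrow(X)
  if (length(labels) != n) stop("one label per row required")
  cl <- unique(labels)
  if (length(cl) < 2) stop("silhouette requires at least 2 clusters (b(i) undefined otherwise)")
  D <- as.matrix(stats::dist(X))
  sizes <- table(labels)[cl]
  # column c of sums = total distance from each point to cluster c
  sums <- vapply(cl, function(c) rowSums(D[, labels == c, drop = FALSE]), numeric(n))
  li <- match(labels, cl)
  own_size <- as.numeric(sizes[li])
  a <- sums[cbind(seq_len(n), li)] / pmax(own_size - 1, 1)
  other <- sweep(sums, 2L, as.numeric(sizes), "/")
  other[cbind(seq_len(n), li)] <- Inf
  b <- apply(other, 1L, min)
  s <- ifelse(pmax(a, b) > 0, (b - a) / pmax(a, b), 0)
  s[own_size == 1] <- 0
  unname(s)
}

#' Global silhouette score of a clustering
#'
#' Mean of the per-point silhouettes over all points, or over a seeded
#' uniform subsample when `subsample` is smaller than `n` (the full
#' computation costs \eqn{O(|N|^2 d)}).
#'
#' @inheritParams silhouette_point
#' @param subsample optional number of points to score (default: all);
#'   `subsample >= n` is identical to the full computation.
#' @param seed seed for the subsample draw.
#' @return mean silhouette in `[-1, 1]`.
#' @export
silhouette_global <- function(labels, X, subsample = NULL, seed = 42L) {
  X <- as.matrix(unclass(X))
  n <- nrow(X)
  if (!is.null(subsample) && subsample < n) {
    old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
    set.seed(derive_seed(seed, 11L))
    idx <- sort(sample.int(n, subsample))
    # a(i)/b(i) computed within the subsample: standard subsampled silhouette
    return(mean(silhouette_values(labels[idx], X[idx, , drop = FALSE])))
  }
  mean(silhouette_values(labels, X))
}
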