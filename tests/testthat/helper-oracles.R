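# Independent brute-force oracles and small fixture builders.
# Deliberately naive implementations: plain loops over the definitions,
# sharing no code with the package internals they check.

# O(N^2) per-point silhouette straight from the definition
brute_silhouette <- function(labels, X) {
  n <- nrow(X)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- 0
    for (j in setdiff(own, i)) a <- a + sqrt(sum((X[i, ] - X[j, ])^2))
    a <- a / (length(own) - 1)
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i])) {
      mem <- which(labels == cl)
      d <- 0
      for (j in mem) d <- d + sqrt(sum((X[i, ] - X[j, ])^2))
      b <- min(b, d / length(mem))
    }
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  s
}

# literal O(n^2) modularity double sum
brute_modularity <- function(G, P) {
  A <- as.matrix(G$A)
  lab <- unclass(P)[G$node_ids]
  k <- rowSums(A)
  two_m <- sum(k)
  q <- 0
  for (v in seq_len(nrow(A))) for (w in seq_len(nrow(A)))
    if (lab[v] == lab[w]) q <- q + A[v, w] - k[v] * k[w] / two_m
  unname(q / two_m)
}

# well-separated Gaussian blobs with known assignment
make_blobs <- function(n_per, centers, sd = 0.1, seed = 1) {
  set.seed(seed)
  k <- nrow(centers)
  X <- do.call(rbind, lapply(seq_len(k), function(j)
    matrix(stats::rnorm(n_per * ncol(centers), sd = sd), n_per) +
      matrix(centers[j, ], n_per, ncol(centers), byrow = TRUE)))
  list(X = X, labels = rep(seq_len(k), each = n_per))
}

# tiny deterministic graphs
path_graph <- function(ids = c("a", "b", "c")) {
  n <- length(ids)
  scd_graph(cbind(seq_len(n - 1), 2:n), rep(1, n - 1), ids)
}

triangle_graph <- function(ids = c("a", "b", "c")) {
  scd_graph(rbind(c(1, 2), c(2, 3), c(1, 3)), rep(1, 3), ids)
}

two_triangles_graph <- function() {
  scd_graph(rbind(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6)),
            rep(1, 6), as.character(1:6))
}

two_cliques_bridge <- function(m = 4) {
  ids <- as.character(seq_len(2 * m))
  e1 <- t(combn(seq_len(m), 2))
  e2 <- t(combn(m + seq_len(m), 2))
  scd_graph(rbind(e1, e2, c(m, m + 1)), rep(1, nrow(e1) + nrow(e2) + 1), ids)
}

tmp_edge_file <- function(lines) {
  f <- withr::local_tempfile(fileext = ".edg", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

random_partition_pair <- function(n, k1, k2, seed) {
  set.seed(seed)
  ids <- as.character(seq_len(n))
  list(p1 = scd_partition(sample(k1, n, replace = TRUE), ids),
       p2 = scd_partition(sample(k2, n, replace = TRUE), ids))
}
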