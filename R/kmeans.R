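#' k-means++ center initialization
#'
#' First center uniform at random; each subsequent center sampled with
#' probability proportional to the squared Euclidean distance to the nearest
#' center already chosen. Uses the calling R session's RNG stream.
#'
#' @param X numeric matrix (rows = points).
#' @param k number of centers.
#' @return `k x ncol(X)` matrix of initial centers.
#' @export
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  first <- sample.int(n, 1L)
  centers[1L, ] <- X[first, ]
  if (k == 1L) return(centers)
  d2 <- rowSums(sweep(X, 2L, centers[1L, ])^2)
  for (j in 2:k) {
    tot <- sum(d2)
    nxt <- if (tot <= 0) sample.int(n, 1L) else sample.int(n, 1L, prob = d2 / tot)
    centers[j, ] <- X[nxt, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[j, ])^2))
  }
  centers
}

# squared Euclidean distances points x centers
dist2_to_centers <- function(X, C) {
  cross <- X %*% t(C)
  sweep(sweep(-2 * cross, 2L, rowSums(C^2), "+"), 1L, rowSums(X^2), "+")
}

#' Mini-batch k-means clustering
#'
#' Sculley-style mini-batch k-means with k-means++ initialization and
#' per-center learning rates `1/count`. When `batch_size >= n` the updates
#' reduce to full-batch Lloyd iterations. Restarted `n_init` times; the run
#' with the lowest total within-cluster sum of squared Euclidean distances is
#' returned. Empty clusters are allowed by the optimizer; the returned `k`
#' counts non-empty clusters only.
#'
#' If `k` exceeds the number of distinct rows, the distinct rows are
#' clustered (one cluster each) with a warning.
#'
#' @param X numeric matrix or `scd_embedding` (rows = nodes).
#' @param k requested number of clusters (`>= 1`).
#' @param seed integer seed controlling initialization and batch sampling.
#' @param batch_size mini-batch size; default `min(n, 1024)`.
#' @param n_init number of independent restarts.
#' @param max_iter update iterations per restart.
#' @return list with `labels` (integer in `1..k`, named by row names),
#'   `centers`, `k` (non-empty clusters), `inertia`.
#' @export
minibatch_kmeans <- function(X, k, seed = 42L, batch_size = NULL,
                             n_init = 3L, max_iter = 100L) {
  X <- unclass(X); attr(X, "provenance") <- NULL
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(k >= 1, n >= 1)
  if (k > n) stop("k cannot exceed the number of points")
  n_distinct <- nrow(unique(X))
  if (k > n_distinct) {
    warning(sprintf("k = %d exceeds %d distinct rows; clustering distinct rows", k, n_distinct))
    k <- n_distinct
  }
  if (is.null(batch_size)) batch_size <- min(n, 1024L)
  best <- NULL
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  for (r in seq_len(n_init)) {
    set.seed(derive_seed(seed, 7L, r))
    C <- kmeanspp_init(X, k)
    if (batch_size >= n) {
      C <- lloyd_iterate(X, C, max_iter)
    } else {
      counts <- numeric(k)
      for (it in seq_len(max_iter)) {
        idx <- sample.int(n, batch_size)
        B <- X[idx, , drop = FALSE]
        assign_b <- max.col(-dist2_to_centers(B, C), ties.method = "first")
        for (ci in unique(assign_b)) {
          pts <- B[assign_b == ci, , drop = FALSE]
          for (p in seq_len(nrow(pts))) {
            counts[ci] <- counts[ci] + 1
            eta <- 1 / counts[ci]
            C[ci, ] <- (1 - eta) * C[ci, ] + eta * pts[p, ]
          }
        }
      }
    }
    lab <- max.col(-dist2_to_centers(X, C), ties.method = "first")
    inertia <- sum((X - C[lab, , drop = FALSE])^2)
    if (is.null(best) || inertia < best$inertia)
      best <- list(labels = lab, centers = C, inertia = inertia)
  }
  keep <- sort(unique(best$labels))
  labels <- match(best$labels, keep)       # compact to 1..k_nonempty
  names(labels) <- rownames(X)
  list(labels = labels, centers = best$centers[keep, , drop = FALSE],
       k = length(keep), inertia = best$inertia)
}

lloyd_iterate <- function(X, C, max_iter) {
  k <- nrow(C)
  lab_prev <- NULL
  for (it in seq_len(max_iter)) {
    lab <- max.col(-dist2_to_centers(X, C), ties.method = "first")
    if (identical(lab, lab_prev)) break
    lab_prev <- lab
    for (ci in seq_len(k)) {
      m <- lab == ci
      if (any(m)) C[ci, ] <- colMeans(X[m, , drop = FALSE])
    }
  }
  C
}

# small deterministic seed derivation, kept below 2^31
derive_seed <- function(seed, ...) {
  parts <- c(as.integer(seed), as.integer(unlist(list(...))))
  h <- 0
  for (p in parts) h <- (h * 1000003 + (p %% 65536) + 1) %% 2147483629
  as.integer(h)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}
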