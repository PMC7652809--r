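#' Contingency table of two partitions
#'
#' Counts `n_ij` of nodes with truth class i and predicted cluster j, after
#' aligning the two partitions on their (identical) node sets.
#'
#' @param truth,pred [scd_partition()]s over the same node set.
#' @return integer matrix of counts.
#' @export
contingency <- function(truth, pred) {
  al <- align_partitions(truth, pred)
  table(truth = al$a, pred = al$b)
}

#' Normalized mutual information between two partitions
#'
#' \deqn{NMI(Y, C) = \frac{2\, I(Y;C)}{H(Y) + H(C)}} with natural-log
#' entropies (the base cancels in the ratio). Degenerate cases: if both
#' labelings have zero entropy (each a single cluster) they are necessarily
#' identical and the score is 1; if exactly one has zero entropy the mutual
#' information is 0 and so is the score.
#'
#' @param truth,pred [scd_partition()]s (or named label vectors) over the
#'   same node set.
#' @return value in `[0, 1]`.
#' @export
nmi <- function(truth, pred) {
  tab <- contingency(truth, pred)
  n <- sum(tab)
  pi_ <- rowSums(tab) / n
  pj <- colSums(tab) / n
  hy <- entropy_nat(pi_); hc <- entropy_nat(pj)
  if (hy == 0 && hc == 0) return(1)
  if (hy == 0 || hc == 0) return(0)
  pij <- tab / n
  nz <- pij > 0
  I <- sum(pij[nz] * log(pij[nz] / outer(pi_, pj)[nz]))
  2 * I / (hy + hc)
}

entropy_nat <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Adjusted Rand index between two partitions
#'
#' Pair-counting agreement corrected for chance (Hubert-Arabie):
#' \deqn{ARI = \frac{\sum_{ij}\binom{n_{ij}}{2} - E}{\tfrac12\big[\sum_i
#'   \binom{a_i}{2} + \sum_j \binom{b_j}{2}\big] - E}, \quad
#'   E = \sum_i \binom{a_i}{2} \sum_j \binom{b_j}{2} \Big/ \binom{n}{2}.}
#' Permutation-invariant; 1 iff the partitions are identical up to
#' relabeling.
#'
#' @inheritParams nmi
#' @return value in `[-1, 1]`.
#' @export
ari <- function(truth, pred) {
  tab <- contingency(truth, pred)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)   # both partitions trivial (all-singletons/one cluster)
  (sum_ij - expected) / (maxi - expected)
}

#' Weighted modularity of a partition
#'
#' \deqn{Q = \frac{1}{2m} \sum_{v,w} \Big[A_{vw} - \frac{k_v k_w}{2m}\Big]
#'   \delta(c_v, c_w),}
#' with weighted adjacency `A`, generalized degrees `k`, and
#' \eqn{2m = vol(G)}. Computed by the equivalent per-community aggregation
#' \eqn{Q = \sum_c \big[ \Sigma^{in}_c / 2m - (\Sigma^{tot}_c / 2m)^2 \big]}.
#'
#' @param G an [scd_graph()].
#' @param P an [scd_partition()] covering every node of `G`.
#' @return modularity value (at most 1 on simple graphs).
#' @export
modularity <- function(G, P) {
  stopifnot(inherits(G, "scd_graph"))
  lab <- unclass(P)[G$node_ids]
  if (anyNA(lab)) stop("partition does not cover all graph nodes: ",
                       paste(utils::head(G$node_ids[is.na(lab)], 5), collapse = ", "))
  deg <- Matrix::rowSums(G$A)
  two_m <- sum(deg)
  if (two_m == 0) stop("graph has no edges")
  q <- 0
  for (c in unique(lab)) {
    m <- lab == c
    sigma_in <- sum(G$A[m, m])       # counts each internal edge twice
    sigma_tot <- sum(deg[m])
    q <- q + sigma_in / two_m - (sigma_tot / two_m)^2
  }
  q
}

#' Evaluate a predicted partition against ground truth
#'
#' @param G an [scd_graph()] (needed for modularity).
#' @param pred,truth [scd_partition()]s.
#' @param metrics subset of `c("nmi", "ari", "modularity")`.
#' @return named list of scores.
#' @export
evaluate_partition <- function(G, pred, truth = NULL,
                               metrics = c("nmi", "ari", "modularity")) {
  out <- list()
  if ("nmi" %in% metrics) out$nmi <- if (is.null(truth)) NA_real_ else nmi(truth, pred)
  if ("ari" %in% metrics) out$ari <- if (is.null(truth)) NA_real_ else ari(truth, pred)
  if ("modularity" %in% metrics) out$modularity <- modularity(G, pred)
  out
}
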