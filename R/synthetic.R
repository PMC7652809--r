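#' Stochastic block model with planted partition
#'
#' Bernoulli edges with probability `p_in` inside a block and `p_out`
#' between blocks (sampling delegated to `igraph::sample_sbm`). Deterministic
#' per seed. Used as a fast, well-conditioned fixture with planted ground
#' truth.
#'
#' @param block_sizes positive integer vector of community sizes.
#' @param p_in,p_out within/between edge probabilities, `0 <= p_out < p_in <= 1`.
#' @param seed integer seed.
#' @return list with `graph` ([scd_graph()]) and `truth` ([scd_partition()]).
#' @export
generate_sbm <- function(block_sizes, p_in, p_out, seed = 42L) {
  if (any(block_sizes < 1)) stop("empty SBM block")
  stopifnot(p_out >= 0, p_out < p_in, p_in <= 1)
  kb <- length(block_sizes)
  n <- sum(block_sizes)
  pref <- matrix(p_out, kb, kb); diag(pref) <- p_in
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  g <- igraph::sample_sbm(n, pref.matrix = pref, block.sizes = block_sizes)
  el <- igraph::as_edgelist(g, names = FALSE)
  ids <- as.character(seq_len(n))
  G <- scd_graph(el, rep(1, nrow(el)), ids)
  truth <- scd_partition(rep(paste0("B", seq_len(kb)), block_sizes), ids)
  list(graph = G, truth = truth)
}

#' LFR benchmark graph with planted communities
#'
#' Lancichinetti-Fortunato-Radicchi construction: node degrees follow a
#' truncated power law with exponent `degree_exponent`, community sizes a
#' power law with exponent `community_exponent`, and each node places a
#' fraction `1 - mixing` of its edges inside its community and `mixing`
#' outside. Built by configuration-model stub matching (internal stubs per
#' community, external stubs globally) with duplicate/self-loop rejection;
#' a small fraction of stubs that cannot be matched is dropped, so realized
#' degrees approximate the sampled sequence.
#'
#' @param n number of nodes.
#' @param avg_degree,max_degree target mean and maximum degree.
#' @param mixing mixing parameter in `[0, 1]`.
#' @param degree_exponent power-law exponent of the degree distribution
#'   (`> 1`).
#' @param community_exponent power-law exponent of the community-size
#'   distribution (`>= 1`).
#' @param seed integer seed; same seed reproduces the identical edge set.
#' @return list with `graph` and planted `truth`, plus the realized
#'   `community_sizes`.
#' @export
generate_lfr <- function(n, avg_degree, max_degree, mixing,
                         degree_exponent = 2, community_exponent = 1,
                         seed = 42L) {
  if (avg_degree > max_degree)
    stop(sprintf("infeasible LFR spec: avg_degree %g > max_degree %g",
                 avg_degree, max_degree))
  if (max_degree >= n) stop("max_degree must be smaller than n")
  stopifnot(mixing >= 0, mixing <= 1, degree_exponent > 1, community_exponent >= 1)
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))

  deg <- sample_powerlaw_degrees(n, avg_degree, max_degree, degree_exponent)
  int_deg <- round((1 - mixing) * deg)
  sizes <- sample_community_sizes(n, deg, int_deg, community_exponent)
  # no community can absorb an internal degree >= its size
  cap <- max(sizes) - 1L
  over <- int_deg > cap
  int_deg[over] <- cap
  membership <- assign_nodes_to_communities(int_deg, sizes)
  int_deg <- pmin(int_deg, sizes[membership] - 1L)
  ext_deg <- deg - int_deg

  edges <- matrix(integer(0), 0, 2)
  for (c in seq_along(sizes)) {
    members <- which(membership == c)
    edges <- rbind(edges, match_stubs(members, int_deg[members]))
  }
  # external stubs matched globally, rejecting within-community pairs
  edges <- rbind(edges, match_stubs(seq_len(n), ext_deg, forbid_group = membership,
                                    existing = edges))
  if (nrow(edges) == 0) stop("LFR construction produced no edges; spec too sparse")
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  edges <- edges[!duplicated(key), , drop = FALSE]
  ids <- as.character(seq_len(n))
  isolated <- setdiff(seq_len(n), unique(as.vector(edges)))
  if (length(isolated)) {
    # LFR graphs have no isolated nodes: attach each to a random community peer
    for (v in isolated) {
      peers <- setdiff(which(membership == membership[v]), v)
      if (!length(peers)) peers <- setdiff(seq_len(n), v)
      edges <- rbind(edges, c(v, sample(peers, 1L)))
    }
  }
  G <- scd_graph(edges, rep(1, nrow(edges)), ids)
  truth <- scd_partition(paste0("C", membership), ids)
  list(graph = G, truth = truth, community_sizes = as.integer(table(membership)))
}

# continuous truncated power-law sampler, lower cut chosen to hit the mean
sample_powerlaw_degrees <- function(n, avg_degree, max_degree, tau) {
  mean_pl <- function(xmin, xmax, tau) {
    if (abs(tau - 2) < 1e-12)
      log(xmax / xmin) / (1 / xmin - 1 / xmax)
    else if (abs(tau - 1) < 1e-12)
      (xmax - xmin) / log(xmax / xmin)
    else {
      num <- (xmax^(2 - tau) - xmin^(2 - tau)) / (2 - tau)
      den <- (xmax^(1 - tau) - xmin^(1 - tau)) / (1 - tau)
      num / den
    }
  }
  f <- function(xmin) mean_pl(xmin, max_degree, tau) - avg_degree
  if (f(1) > 0) stop("infeasible LFR spec: avg_degree below the power-law minimum")
  if (f(max_degree - 1e-9) < 0)
    stop("infeasible LFR spec: avg_degree unreachable under max_degree")
  xmin <- stats::uniroot(f, c(1, max_degree - 1e-9))$root
  u <- stats::runif(n)
  x <- if (abs(tau - 1) < 1e-12) xmin * (max_degree / xmin)^u
  else (xmin^(1 - tau) + u * (max_degree^(1 - tau) - xmin^(1 - tau)))^(1 / (1 - tau))
  deg <- pmax(1L, pmin(as.integer(round(x)), as.integer(max_degree)))
  if (sum(deg) %% 2 == 1) {
    i <- which.min(deg)
    deg[i] <- deg[i] + 1L
  }
  deg
}

sample_community_sizes <- function(n, deg, int_deg, tau2) {
  smin <- max(3L, as.integer(stats::quantile(int_deg, 0.5)) + 1L)
  smax <- max(smin + 1L, min(n, as.integer(max(int_deg)) + smin))
  sizes <- integer(0)
  while (sum(sizes) < n) {
    u <- stats::runif(1)
    s <- if (abs(tau2 - 1) < 1e-12) smin * (smax / smin)^u
    else (smin^(1 - tau2) + u * (smax^(1 - tau2) - smin^(1 - tau2)))^(1 / (1 - tau2))
    sizes <- c(sizes, as.integer(round(s)))
  }
  excess <- sum(sizes) - n
  last <- length(sizes)
  if (sizes[last] - excess >= smin) {
    sizes[last] <- sizes[last] - excess
  } else {
    sizes <- sizes[-last]
    short <- n - sum(sizes)
    # spread the remainder over the largest communities
    while (short > 0) {
      i <- which.max(sizes)
      add <- min(short, smax - sizes[i])
      if (add == 0) { sizes <- c(sizes, short); break }
      sizes[i] <- sizes[i] + add
      short <- short - add
    }
  }
  sizes
}

assign_nodes_to_communities <- function(int_deg, sizes) {
  n <- length(int_deg)
  membership <- integer(n)
  occupancy <- integer(length(sizes))
  homeless <- sample.int(n)
  guard <- 0L
  while (length(homeless) && guard < 50L * n) {
    guard <- guard + 1L
    v <- homeless[1L]; homeless <- homeless[-1L]
    fits <- which(sizes > int_deg[v])
    if (!length(fits)) fits <- which.max(sizes)
    c_pick <- if (length(fits) == 1L) fits else sample(fits, 1L)
    if (occupancy[c_pick] < sizes[c_pick]) {
      membership[v] <- c_pick
      occupancy[c_pick] <- occupancy[c_pick] + 1L
    } else {
      # kick a random member, take its slot (standard LFR assignment step)
      members <- which(membership == c_pick)
      out <- if (length(members) == 1L) members else sample(members, 1L)
      membership[out] <- 0L
      membership[v] <- c_pick
      homeless <- c(homeless, out)
    }
  }
  if (any(membership == 0L)) {
    # place leftovers wherever space remains
    for (v in which(membership == 0L)) {
      open <- which(occupancy < sizes)
      c_pick <- if (length(open)) open[which.max(sizes[open] - occupancy[open])] else which.max(sizes)
      membership[v] <- c_pick
      occupancy[c_pick] <- occupancy[c_pick] + 1L
    }
  }
  membership
}

# configuration-model matching of stubs with rejection of self-loops,
# duplicates and (optionally) pairs inside the same forbidden group
match_stubs <- function(nodes, stub_counts, forbid_group = NULL, existing = NULL,
                        rounds = 12L) {
  stubs <- rep(nodes, stub_counts)
  if (length(stubs) < 2) return(matrix(integer(0), 0, 2))
  seen <- if (is.null(existing) || nrow(existing) == 0) character(0)
  else paste(pmin(existing[, 1], existing[, 2]), pmax(existing[, 1], existing[, 2]))
  out <- matrix(integer(0), 0, 2)
  for (r in seq_len(rounds)) {
    if (length(stubs) < 2) break
    stubs <- sample(stubs)
    if (length(stubs) %% 2 == 1) stubs <- stubs[-1]
    u <- stubs[c(TRUE, FALSE)]; v <- stubs[c(FALSE, TRUE)]
    key <- paste(pmin(u, v), pmax(u, v))
    ok <- u != v & !duplicated(key) & !(key %in% seen)
    if (!is.null(forbid_group)) ok <- ok & forbid_group[u] != forbid_group[v]
    out <- rbind(out, cbind(u[ok], v[ok]))
    seen <- c(seen, key[ok])
    stubs <- c(u[!ok], v[!ok])
  }
  # final pass: allow within-group pairs rather than dropping all leftovers
  if (!is.null(forbid_group) && length(stubs) >= 2) {
    stubs <- sample(stubs)
    if (length(stubs) %% 2 == 1) stubs <- stubs[-1]
    u <- stubs[c(TRUE, FALSE)]; v <- stubs[c(FALSE, TRUE)]
    key <- paste(pmin(u, v), pmax(u, v))
    ok <- u != v & !duplicated(key) & !(key %in% seen)
    out <- rbind(out, cbind(u[ok], v[ok]))
  }
  out
}

#' Benchmark parameter grid of LFR specifications
#'
#' Cross-product of node counts {100, 500, 750, 1000, 2500, 5000, 10000},
#' average degrees {15, 30, 50}, maximum degrees {10, 50, 100, 500} and
#' mixing {0.1, 0.2, 0.5, 0.7, 0.9}, with degree exponent 2 and community
#' exponent 1 (420 combinations before feasibility filtering). Combinations
#' with `avg_degree > max_degree` or `max_degree >= n` are infeasible and
#' filtered out with a message. `scale = "reduced"` restricts node counts to
#' {100, 500, 1000} for desk-scale runs.
#'
#' @param scale `"full"` or `"reduced"`.
#' @param filter drop infeasible combinations (default `TRUE`).
#' @return data frame of LFR specifications (one row per spec).
#' @export
lfr_benchmark_grid <- function(scale = c("full", "reduced"), filter = TRUE) {
  scale <- match.arg(scale)
  nodes <- if (scale == "full") c(100, 500, 750, 1000, 2500, 5000, 10000)
  else c(100, 500, 1000)
  grid <- expand.grid(n = nodes, avg_degree = c(15, 30, 50),
                      max_degree = c(10, 50, 100, 500),
                      mixing = c(0.1, 0.2, 0.5, 0.7, 0.9),
                      KEEP.OUT.ATTRS = FALSE)
  grid$degree_exponent <- 2
  grid$community_exponent <- 1
  if (filter) {
    feasible <- grid$avg_degree <= grid$max_degree & grid$max_degree < grid$n
    if (any(!feasible))
      message(sprintf("filtered %d infeasible LFR combinations", sum(!feasible)))
    grid <- grid[feasible, , drop = FALSE]
    rownames(grid) <- NULL
  }
  grid
}
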