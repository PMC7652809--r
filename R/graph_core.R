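#' Weighted undirected network
#'
#' An `scd_graph` is an undirected, optionally weighted network with
#' contiguous internal node indices `1..n` and a preserved map to external
#' node identifiers. Unweighted inputs are treated as weighted networks with
#' every weight equal to 1. The adjacency matrix is stored sparse and
#' symmetric; the graph volume is \eqn{vol(G) = \sum_{ij} A_{ij}}, i.e. twice
#' the total edge weight.
#'
#' @param edges two-column integer matrix of node indices (1-based), one row
#'   per undirected edge, or a two/three-column data frame of external ids
#'   (plus optional weight).
#' @param weights positive numeric vector, one per edge (recycled 1 if NULL).
#' @param node_ids character vector of external node identifiers; defines the
#'   node universe (isolated nodes allowed).
#' @return an object of class `scd_graph` with elements `node_ids`, `A`
#'   (sparse symmetric `dgCMatrix`), `n_nodes`, `n_edges`.
#' @export
scd_graph <- function(edges, weights = NULL, node_ids) {
  node_ids <- as.character(node_ids)
  if (anyDuplicated(node_ids)) stop("duplicate node identifiers")
  n <- length(node_ids)
  edges <- as.matrix(edges)
  if (nrow(edges) > 0) {
    storage.mode(edges) <- "integer"
    if (any(edges < 1L | edges > n)) stop("edge endpoint outside node universe")
    if (any(edges[, 1] == edges[, 2])) stop("self-loops must be removed before construction")
  }
  if (is.null(weights)) weights <- rep(1, nrow(edges))
  if (length(weights) != nrow(edges)) stop("one weight per edge required")
  if (any(!is.finite(weights)) || any(weights <= 0)) stop("edge weights must be positive and finite")
  # canonical order, reject duplicates
  i <- pmin(edges[, 1], edges[, 2]); j <- pmax(edges[, 1], edges[, 2])
  if (anyDuplicated(cbind(i, j))) stop("duplicate undirected edge")
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(weights, weights),
                            dims = c(n, n), dimnames = list(node_ids, node_ids))
  structure(list(node_ids = node_ids, A = A,
                 n_nodes = n, n_edges = length(i)),
            class = "scd_graph")
}

#' @export
print.scd_graph <- function(x, ...) {
  cat(sprintf("<scd_graph> %d nodes, %d undirected edges, vol(G) = %g\n",
              x$n_nodes, x$n_edges, sum(x$A)))
  invisible(x)
}

#' Read a whitespace-separated edge list
#'
#' Accepts the SNAP dialect: one edge per line as `u v [w]`, lines starting
#' with `#` ignored. Duplicate undirected edges collapse keeping the last
#' weight (with a warning); self-loops are dropped with a warning. Nodes are
#' defined by edge endpoints unless `nodes` supplies the universe (admitting
#' isolated nodes).
#'
#' @param path file path.
#' @param weighted if `TRUE` a third column is required and parsed as a
#'   positive weight; if `FALSE` any third column is an error.
#' @param nodes optional character vector (or path to a one-column file) of
#'   node ids defining the node universe.
#' @return an [scd_graph()].
#' @export
read_edgelist <- function(path, weighted = FALSE, nodes = NULL) {
  if (!file.exists(path)) stop("edge list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lineno <- seq_along(lines)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]; lineno <- lineno[keep]
  if (length(lines) == 0) stop("empty edge list: ", path)
  toks <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(toks)
  want <- if (weighted) 3L else 2L
  bad <- which(nf != want)
  if (length(bad)) stop(sprintf("malformed line %d in %s: expected %d fields, got %d",
                                lineno[bad[1]], path, want, nf[bad[1]]))
  u <- vapply(toks, `[[`, "", 1L)
  v <- vapply(toks, `[[`, "", 2L)
  if (weighted) {
    w <- suppressWarnings(as.numeric(vapply(toks, `[[`, "", 3L)))
    badw <- which(is.na(w) | w <= 0)
    if (length(badw)) stop(sprintf("non-positive or unparseable weight on line %d in %s",
                                   lineno[badw[1]], path))
  } else {
    w <- rep(1, length(u))
  }
  loops <- u == v
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop(s)", sum(loops)))
    u <- u[!loops]; v <- v[!loops]; w <- w[!loops]
  }
  if (length(u) == 0) stop("edge list contains only self-loops: ", path)
  if (!is.null(nodes)) {
    if (length(nodes) == 1 && file.exists(nodes)) nodes <- readLines(nodes, warn = FALSE)
    node_ids <- unique(as.character(trimws(nodes)))
    missing <- setdiff(unique(c(u, v)), node_ids)
    if (length(missing)) stop("edge endpoints absent from node list: ",
                              paste(utils::head(missing, 5), collapse = ", "))
  } else {
    node_ids <- unique(c(rbind(u, v)))
  }
  ui <- match(u, node_ids); vi <- match(v, node_ids)
  key <- paste(pmin(ui, vi), pmax(ui, vi))
  if (anyDuplicated(key)) {
    warning(sprintf("collapsed %d duplicate edge line(s), keeping the last weight",
                    sum(duplicated(key))))
    last <- !duplicated(key, fromLast = TRUE)
    ui <- ui[last]; vi <- vi[last]; w <- w[last]
  }
  scd_graph(cbind(ui, vi), w, node_ids)
}

#' Write a graph back to an edge list
#'
#' @param G an [scd_graph()].
#' @param path output path.
#' @param weighted include the weight column.
#' @export
write_edgelist <- function(G, path, weighted = TRUE) {
  TA <- Matrix::triu(G$A, 1)
  tri <- Matrix::summary(TA)
  o <- order(tri$i, tri$j)
  u <- G$node_ids[tri$i][o]; v <- G$node_ids[tri$j][o]
  lines <- if (weighted) paste(u, v, formatC(tri$x[o], digits = 17, format = "g"))
  else paste(u, v)
  writeLines(lines, path)
  invisible(path)
}

#' Adjacency matrix, generalized degrees and volume
#'
#' @param G an [scd_graph()].
#' @return list with `A` (sparse symmetric matrix), `degrees`
#'   (\eqn{d_i = \sum_j A_{ij}}) and `vol` (\eqn{\sum_{ij} A_{ij}}).
#' @export
adjacency <- function(G) {
  stopifnot(inherits(G, "scd_graph"))
  d <- Matrix::rowSums(G$A)
  list(A = G$A, degrees = d, vol = sum(d))
}

#' Community membership vectors
#'
#' A partition assigns every node exactly one community label. Represented as
#' a named character vector: names are external node ids, values community
#' labels.
#'
#' @param labels vector of community labels.
#' @param node_ids node identifiers (defaults to `names(labels)`).
#' @return named character vector of class `scd_partition`.
#' @export
scd_partition <- function(labels, node_ids = names(labels)) {
  if (is.null(node_ids)) stop("partition requires node identifiers")
  labels <- as.character(labels)
  if (length(labels) != length(node_ids)) stop("one label per node required")
  if (anyDuplicated(node_ids)) stop("duplicate node in partition")
  structure(stats::setNames(labels, as.character(node_ids)), class = "scd_partition")
}

#' Number of non-empty communities in a partition
#' @param P an [scd_partition()].
#' @export
n_communities <- function(P) length(unique(unclass(P)))

#' Read / write community membership TSV
#'
#' Two-column TSV `node_id<TAB>community_label`, UTF-8, no header. Labels are
#' preserved verbatim so `read_membership(write_membership(P))` is the
#' identity. When `graph` is supplied the node sets are validated both ways.
#'
#' @param path TSV path.
#' @param graph optional [scd_graph()] to validate against.
#' @return an [scd_partition()].
#' @export
read_membership <- function(path, graph = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                          colClasses = "character", comment.char = "")
  if (ncol(df) != 2) stop("membership file must have exactly two tab-separated columns")
  P <- scd_partition(df[[2]], df[[1]])
  if (!is.null(graph)) {
    extra <- setdiff(names(P), graph$node_ids)
    if (length(extra)) stop("membership nodes absent from graph: ",
                            paste(utils::head(extra, 5), collapse = ", "))
    unlabeled <- setdiff(graph$node_ids, names(P))
    if (length(unlabeled)) stop("graph nodes missing a label: ",
                                paste(utils::head(unlabeled, 5), collapse = ", "))
    P <- scd_partition(unclass(P)[graph$node_ids], graph$node_ids)
  }
  P
}

#' @rdname read_membership
#' @param P an [scd_partition()].
#' @export
write_membership <- function(P, path) {
  utils::write.table(data.frame(node = names(P), community = unclass(P)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# align two partitions on a common node set; error on mismatch
align_partitions <- function(P1, P2) {
  n1 <- names(P1); n2 <- names(P2)
  if (length(n1) != length(n2) || !setequal(n1, n2))
    stop("partitions cover different node sets")
  list(a = as.character(unclass(P1)[n1]), b = as.character(unclass(P2)[n1]))
}
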