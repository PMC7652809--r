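#!/usr/bin/env Rscript
# External-data benchmark: community detection on the e-mail network of a
# European research institution (SNAP "email-Eu-core"), whose 1005 members
# each belong to one of 42 departments. The data are NOT shipped with the
# package; download them first:
#
#   curl -LO https://snap.stanford.edu/data/email-Eu-core.txt.gz
#   curl -LO https://snap.stanford.edu/data/email-Eu-core-department-labels.txt.gz
#   gunzip email-Eu-core*.gz
#
# Usage:
#   Rscript scripts/email_benchmark.R --edges email-Eu-core.txt \
#       --labels email-Eu-core-department-labels.txt \
#       [--seed 42] [--out results/email.json]

suppressPackageStartupMessages(library(scdnet))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
edges_path <- get_arg("--edges")
labels_path <- get_arg("--labels")
if (is.null(edges_path) || is.null(labels_path))
  stop("usage: Rscript scripts/email_benchmark.R --edges <file> --labels <file>")
seed <- as.integer(get_arg("--seed", "42"))
out_path <- get_arg("--out", "results/email.json")
dir.create(dirname(out_path), showWarnings = FALSE, recursive = TRUE)

# the raw file lists directed sends; read_edgelist symmetrizes and dedups
G <- suppressWarnings(read_edgelist(edges_path))
message(sprintf("network: %d nodes, %d undirected edges", G$n_nodes, G$n_edges))

raw <- utils::read.table(labels_path, colClasses = "character")
truth <- scd_partition(raw[[2]], raw[[1]])
truth <- scd_partition(unclass(truth)[G$node_ids], G$node_ids)
message(sprintf("ground truth: %d departments", n_communities(truth)))

# the two embedding settings reported for this network, plus a PPR run
grid <- list(embedding_setting("netmf", T_window = 5, b = 1, d = 128),
             embedding_setting("netmf", T_window = 3, b = 1, d = 32))
cfg <- scd_config(K = 300, k_min = 5, gamma = 10, w = 5,
                  embedding_grid = grid, seed = seed)
res <- scd_detect(G, cfg, verbose = TRUE)
scores <- evaluate_partition(G, res$partition, truth)
message(sprintf("selected k = %d | NMI %.3f ARI %.3f Q %.3f",
                res$k, scores$nmi, scores$ari, scores$modularity))

jsonlite::write_json(list(selected_k = res$k, setting = res$setting_id,
                          silhouette = res$silhouette, nmi = scores$nmi,
                          ari = scores$ari, modularity = scores$modularity),
                     out_path, auto_unbox = TRUE, digits = NA)
message("wrote ", out_path)
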