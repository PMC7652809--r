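blob_embedding <- function(k, n_per = 20, sep = 8, sd = 0.15, seed = 1) {
  ang <- 2 * pi * seq_len(k) / k
  centers <- cbind(sep * cos(ang), sep * sin(ang))
  make_blobs(n_per, centers, sd = sd, seed = seed)
}

test_that("valid_range is the stride sequence with K appended", {
  expect_equal(valid_range(5, 50, 10), c(5, 15, 25, 35, 45, 50))
  expect_equal(valid_range(5, 5, 10), 5L)
  expect_equal(valid_range(5, 45, 10), c(5, 15, 25, 35, 45))
  expect_equal(valid_range(2, 1000, "auto"), c(seq(2, 902, by = 100), 1000))
})

test_that("gamma estimate is the ceiling of K^(2/3)", {
  expect_equal(gamma_estimate(1000), 100L)
  expect_equal(gamma_estimate(8), 4L)
  expect_equal(gamma_estimate(100), 22L)   # 100^(2/3) = 21.54...
  expect_equal(gamma_estimate(1), 1L)
})

test_that("coarse search finds the planted blob count on an exhaustive grid", {
  bl <- blob_embedding(4, seed = 2)
  cfg <- scd_config(K = 10, k_min = 2, gamma = 1, w = 10,
                    embedding_grid = embedding_grid("fast-grid"), seed = 2)
  co <- coarse_search(bl$X, cfg)
  # exhaustive oracle over the same range
  oracle <- vapply(2:10, function(k) {
    km <- minibatch_kmeans(bl$X, k, seed = scdnet:::derive_seed(2, 1, k))
    silhouette_global(km$labels, bl$X)
  }, numeric(1))
  expect_equal(co$k_star, (2:10)[which.max(oracle)])
  expect_equal(co$k_star, 4L)
  expect_equal(co$best_sil, max(oracle), tolerance = 1e-12)
})

test_that("stopping window halts a phase after w non-improving evaluations", {
  bl <- blob_embedding(2, seed = 3)   # silhouette peaks at the first k = 2
  cfg <- scd_config(K = 12, k_min = 2, gamma = 1, w = 1, seed = 3)
  co <- coarse_search(bl$X, cfg)
  expect_equal(nrow(co$trace), 2L)
  expect_equal(co$k_star, 2L)
})

test_that("fine search recovers an optimum the coarse grid skipped", {
  bl <- blob_embedding(7, seed = 4)
  cfg <- scd_config(K = 20, k_min = 5, gamma = 10, w = 5, seed = 4)
  co <- coarse_search(bl$X, cfg)           # grid {5, 15, 20}
  expect_true(all(co$trace$k %in% c(5, 15, 20)))
  fi <- fine_search(bl$X, cfg, co$k_star, coarse = co)
  expect_equal(fi$k_star, 7L)
  expect_gte(fi$best_sil, co$best_sil)
})

test_that("an exhaustive sweep contains every strided sweep's evaluations", {
  bl <- blob_embedding(3, seed = 5)
  cfg1 <- scd_config(K = 9, k_min = 2, gamma = 1, w = 20, seed = 5)
  cfg3 <- scd_config(K = 9, k_min = 2, gamma = 3, w = 20, seed = 5)
  ks1 <- coarse_search(bl$X, cfg1)$trace$k
  ks3 <- coarse_search(bl$X, cfg3)$trace$k
  expect_true(all(ks3 %in% ks1))
  # gamma = 1 fine phase adds at most 2 evaluations around the optimum
  co <- coarse_search(bl$X, cfg1)
  fi <- fine_search(bl$X, cfg1, co$k_star, coarse = co)
  expect_lte(nrow(fi$trace) - nrow(co$trace), 2L)
})

test_that("scd_detect recovers a planted 3-block partition exactly", {
  net <- generate_sbm(c(30, 30, 30), 0.9, 0.02, seed = 6)
  cfg <- scd_config(K = 10, k_min = 2, gamma = 1, w = 10,
                    embedding_grid = list(embedding_setting("netmf", d = 16)),
                    seed = 6)
  res <- scd_detect(net$graph, cfg)
  expect_equal(res$k, 3L)
  expect_equal(nmi(net$truth, res$partition), 1.0)
  expect_named(res$partition)
  expect_setequal(names(res$partition), net$graph$node_ids)
})

test_that("duplicate grid entries do not change the result", {
  net <- generate_sbm(c(20, 20), 0.9, 0.05, seed = 7)
  s <- embedding_setting("netmf", d = 8)
  cfg1 <- scd_config(K = 6, k_min = 2, gamma = 1, embedding_grid = list(s), seed = 7)
  cfg2 <- scd_config(K = 6, k_min = 2, gamma = 1, embedding_grid = list(s, s), seed = 7)
  r1 <- scd_detect(net$graph, cfg1)
  r2 <- scd_detect(net$graph, cfg2)
  expect_identical(unclass(r1$partition), unclass(r2$partition))
  expect_identical(r1$silhouette, r2$silhouette)
})

test_that("the full pipeline is deterministic given config and seed", {
  net <- generate_sbm(c(15, 15, 15), 0.8, 0.05, seed = 8)
  cfg <- scd_config(K = 8, k_min = 2, gamma = 2, seed = 8)
  r1 <- scd_detect(net$graph, cfg)
  r2 <- scd_detect(net$graph, cfg)
  expect_identical(unclass(r1$partition), unclass(r2$partition))
  expect_identical(r1$trace, r2$trace)
})

test_that("exhaustive search never scores below a strided search", {
  net <- generate_sbm(c(20, 20, 20), 0.8, 0.05, seed = 9)
  E <- embed_netmf(net$graph, d = 16, seed = 9)
  best <- sapply(c(1, 3, 5), function(g) {
    cfg <- scd_config(K = 12, k_min = 2, gamma = g, w = 12, seed = 9)
    co <- coarse_search(E, cfg)
    fine_search(E, cfg, co$k_star, coarse = co)$best_sil
  })
  expect_gte(best[1], max(best[-1]) - 1e-12)
})

test_that("reported silhouettes stay in [-1, 1] and the trace is consistent", {
  net <- generate_sbm(c(12, 12, 12), 0.7, 0.1, seed = 10)
  cfg <- scd_config(K = 8, k_min = 2, gamma = 2, seed = 10)
  res <- scd_detect(net$graph, cfg)
  sil <- res$trace$silhouette
  expect_true(all(sil[!is.na(sil)] >= -1 & sil[!is.na(sil)] <= 1))
  expect_equal(res$normalized_silhouette,
               max(res$trace$norm_silhouette, na.rm = TRUE))
})

test_that("cross-dimension normalization rescales within each dimension", {
  sil <- c(0.2, 0.4, 0.6, 0.1, 0.3)
  d <- c(16, 16, 16, 32, 32)
  norm <- scdnet:::normalize_by_dim(sil, d, TRUE)
  expect_equal(norm[1:3], c(0, 0.5, 1))
  expect_equal(norm[4:5], c(0, 1))
  # disabled or single-dimension: untouched
  expect_equal(scdnet:::normalize_by_dim(sil, d, FALSE), sil)
  expect_equal(scdnet:::normalize_by_dim(sil[1:3], d[1:3], TRUE), sil[1:3])
})

test_that("detection result serializes to membership TSV and JSON report", {
  net <- generate_sbm(c(15, 15), 0.9, 0.05, seed = 11)
  cfg <- scd_config(K = 6, k_min = 2, gamma = 1,
                    embedding_grid = list(embedding_setting("netmf", d = 8)),
                    seed = 11)
  res <- scd_detect(net$graph, cfg)
  prefix <- withr::local_tempfile()
  write_scd_result(res, prefix)
  P <- read_membership(paste0(prefix, ".membership.tsv"), net$graph)
  expect_equal(unclass(P)[names(res$partition)], unclass(res$partition))
  rep <- jsonlite::read_json(paste0(prefix, ".report.json"), simplifyVector = TRUE)
  expect_equal(rep$selected_k, res$k)
  expect_equal(nrow(rep$trace), nrow(res$trace))
})
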