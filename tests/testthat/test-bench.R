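small_grid <- function() {
  data.frame(n = c(100, 100), avg_degree = 15, max_degree = 50,
             mixing = 0.1, degree_exponent = 2, community_exponent = 1)
}

test_that("benchmark harness produces per-run rows and per-mixing summaries", {
  bm <- scd_benchmark(small_grid(), detectors = "scd-netmf", seed = 5)
  expect_equal(nrow(bm$runs), 2L)   # networks x detectors
  expect_true(all(is.na(bm$runs$error)))
  expect_equal(nrow(bm$summary), 1L)   # one distinct mixing level
  expect_gte(bm$summary$nmi_mean, 0.8)
  expect_equal(bm$k_diff$k_diff, bm$k_diff$k_detected - bm$k_diff$k_true)
})

test_that("individual run failures are recorded and the harness continues", {
  grid <- rbind(small_grid()[1, ],
                data.frame(n = 100, avg_degree = 15, max_degree = 10,
                           mixing = 0.1, degree_exponent = 2,
                           community_exponent = 1))
  bm <- scd_benchmark(grid, detectors = "scd-netmf", seed = 6)
  expect_equal(sum(!is.na(bm$runs$error)), 1L)
  expect_match(bm$runs$error[!is.na(bm$runs$error)], "infeasible")
  expect_equal(sum(is.na(bm$runs$error)), 1L)
})

test_that("baseline adapters delegate to igraph and score reasonably", {
  net <- generate_sbm(c(25, 25, 25), 0.8, 0.02, seed = 7)
  for (det in c("louvain", "label-propagation")) {
    P <- scdnet:::run_detector(net$graph, det, seed = 7)
    expect_setequal(names(P), net$graph$node_ids)
    expect_gte(nmi(net$truth, P), 0.9)
  }
  expect_error(scdnet:::run_detector(net$graph, "infomap-nope", seed = 7),
               "unknown detector")
})

test_that("gamma experiment includes the exhaustive reference and tracks truth", {
  net <- generate_sbm(rep(25, 5), 0.8, 0.02, seed = 8)
  tab <- scd_gamma_experiment(net$graph, gammas = c(2, 5), K = 15, seed = 8)
  expect_true(1 %in% tab$gamma)
  expect_true(all(abs(tab$selected_k - 5) <= 1))
  expect_gte(tab$silhouette[tab$gamma == 1], max(tab$silhouette) - 1e-12)
})

test_that("cli generate/detect/eval round-trip on an SBM fixture", {
  dir <- withr::local_tempdir()
  prefix <- file.path(dir, "net")
  st <- scd_cli(c("generate", "--model", "sbm", "--block-sizes", "30,30,30",
                  "--p-in", "0.9", "--p-out", "0.02", "--seed", "3",
                  "--out", prefix))
  expect_equal(st, 0L)
  expect_true(file.exists(paste0(prefix, ".edg")))

  out <- file.path(dir, "res")
  st <- scd_cli(c("detect", "--input", paste0(prefix, ".edg"), "--out", out,
                  "--seed", "3", "--K", "10", "--k-min", "2", "--gamma", "1"))
  expect_equal(st, 0L)
  report <- jsonlite::read_json(paste0(out, ".report.json"), simplifyVector = TRUE)
  expect_equal(report$selected_k, 3L)

  ev <- file.path(dir, "scores.json")
  st <- scd_cli(c("eval", "--pred", paste0(out, ".membership.tsv"),
                  "--truth", paste0(prefix, ".truth.tsv"),
                  "--graph", paste0(prefix, ".edg"), "--out", ev))
  expect_equal(st, 0L)
  scores <- jsonlite::read_json(ev, simplifyVector = TRUE)
  expect_equal(scores$nmi, 1.0)
  expect_equal(scores$ari, 1.0)
})

test_that("cli reruns with the same seed reproduce identical artifacts", {
  dir <- withr::local_tempdir()
  prefix <- file.path(dir, "net")
  scd_cli(c("generate", "--model", "sbm", "--out", prefix, "--seed", "4"))
  for (tag in c("a", "b"))
    scd_cli(c("detect", "--input", paste0(prefix, ".edg"),
              "--out", file.path(dir, tag), "--seed", "4",
              "--K", "8", "--k-min", "2"))
  expect_identical(readLines(file.path(dir, "a.membership.tsv")),
                   readLines(file.path(dir, "b.membership.tsv")))
})

test_that("cli fails cleanly on missing input without partial outputs", {
  dir <- withr::local_tempdir()
  out <- file.path(dir, "never")
  expect_message(st <- scd_cli(c("detect", "--input",
                                 file.path(dir, "absent.edg"),
                                 "--out", out)), "error")
  expect_equal(st, 1L)
  expect_false(file.exists(paste0(out, ".membership.tsv")))
  expect_message(st2 <- scd_cli(character(0)), "usage")
  expect_equal(st2, 1L)
})

test_that("config file supplies defaults and explicit flags win", {
  dir <- withr::local_tempdir()
  cfgf <- file.path(dir, "scd.conf")
  writeLines(c("# defaults", "model=sbm", "seed=5", "block-sizes=10,10"), cfgf)
  prefix <- file.path(dir, "net")
  st <- scd_cli(c("generate", "--config", cfgf, "--out", prefix,
                  "--block-sizes", "12,12"))
  expect_equal(st, 0L)
  spec <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  expect_equal(spec$block_sizes, c(12L, 12L))   # flag beat the config file
  expect_equal(spec$seed, 5L)                   # config supplied the default
})

test_that("a department-labeled network read from disk is scored end to end", {
  # synthetic stand-in for an externally downloaded social network:
  # SNAP-style edge list plus a node-to-department membership TSV
  dir <- withr::local_tempdir()
  net <- generate_sbm(rep(15, 6), 0.7, 0.02, seed = 12)
  edg <- file.path(dir, "mail.edg"); dep <- file.path(dir, "depts.tsv")
  writeLines(c("# synthetic stand-in network", readLines({
    f <- tempfile(); write_edgelist(net$graph, f, weighted = FALSE); f
  })), edg)
  write_membership(net$truth, dep)
  G <- read_edgelist(edg)
  truth <- read_membership(dep, G)
  expect_equal(n_communities(truth), 6L)
  res <- scd_detect(G, scd_config(K = 12, k_min = 2, gamma = 2,
    embedding_grid = list(embedding_setting("netmf", d = 16)), seed = 12))
  expect_gte(nmi(truth, res$partition), 0.9)
})
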