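make_zc_tables <- function(atlas, mean_k0, mean_k, sds) {
  list(
    k0 = toy_table(atlas, mean_k0, sds, stage_id = 1L),
    k = toy_table(atlas, mean_k, sds, stage_id = 2L)
  )
}

test_that("standardized change is delta over the chosen dispersion", {
  atlas <- toy_atlas(2)
  t <- make_zc_tables(atlas, c(1, 1, 1), c(1.2, 0.9, 1), c(0.1, 0.2, 0.1))
  zc <- zscore_change(t$k, t$k0, atlas)
  expect_equal(zc$z, c(2, -0.5, 0))
  # comparison-stage and pooled dispersions
  t$k$sd_suvr <- c(0.2, 0.2, 0.1)
  zc2 <- zscore_change(t$k, t$k0, atlas, sd_source = "comparison_voxel_sd")
  expect_equal(zc2$z[1], 1)
  zc3 <- zscore_change(t$k, t$k0, atlas, sd_source = "pooled")
  expect_equal(zc3$s[1], sqrt((0.1^2 + 0.2^2) / 2))
})

test_that("zero dispersion is an error naming the region", {
  atlas <- toy_atlas(2)
  t <- make_zc_tables(atlas, c(1, 1, 1), c(1.2, 0.9, 1), c(0, 0.2, 0.1))
  expect_error(zscore_change(t$k, t$k0, atlas), "zero dispersion: Region_1")
})

test_that("ESd matrix is antisymmetric with the concurrency mask", {
  atlas <- toy_atlas(2)
  t <- make_zc_tables(atlas, c(1, 1, 1), c(1.2, 0.99, 1), c(0.1, 0.1, 0.1))
  zc <- zscore_change(t$k, t$k0, atlas)
  esd <- esd_matrix(zc, atlas, stage_pair = c(2L, 1L))
  expect_equal(esd$values, -t(esd$values))
  expect_equal(diag(esd$values), rep(0, 3), ignore_attr = TRUE)
  # region 2 decreased: any pair with it fails the concurrency condition
  expect_false(esd$mask[1, 2])
  expect_false(esd$mask[2, 3])
  # ESd(1,2) = z1 - z2
  expect_equal(esd$values[1, 2], zc$z[1] - zc$z[2])
})

test_that("vectorized R' equals the scalar double-loop oracle", {
  set.seed(101)
  for (rep in 1:5) {
    atlas <- toy_atlas(7)  # 8 regions including the reference
    n <- nrow(atlas)
    mean_k0 <- runif(n, 0.8, 1.2)
    mean_k <- mean_k0 + runif(n, -0.3, 0.3)
    sds <- runif(n, 0.05, 0.3)
    mean_k0[n] <- mean_k[n] <- 1  # reference fixed
    t <- make_zc_tables(atlas, mean_k0, mean_k, sds)
    conn <- build_connectivity(t$k, t$k0, atlas)
    expected <- oracle_rprime(mean_k, mean_k0, sds)
    expect_lt(max(abs(conn$rprime - expected)), 1e-12)
  }
})

test_that("R' satisfies its structural properties", {
  set.seed(7)
  atlas <- toy_atlas(9)
  n <- nrow(atlas)
  mean_k0 <- runif(n, 0.8, 1.2)
  mean_k <- mean_k0 + runif(n, -0.2, 0.4)
  sds <- runif(n, 0.05, 0.3)
  t <- make_zc_tables(atlas, mean_k0, mean_k, sds)
  conn <- build_connectivity(t$k, t$k0, atlas)
  m <- conn$rprime
  expect_equal(m, t(m))
  expect_true(all(m >= 0 & m <= 1))
  expect_equal(diag(m), rep(0, n), ignore_attr = TRUE)

  # scale equivariance: scaling all means and SDs jointly leaves R' unchanged
  t2 <- make_zc_tables(atlas, 2 * mean_k0, 2 * mean_k, 2 * sds)
  conn2 <- build_connectivity(t2$k, t2$k0, atlas)
  expect_equal(conn2$rprime, m)
})

test_that("R' decreases strictly in |ESd| and matches the closed form", {
  # evaluate the transform over a ladder of gaps via two-region tables
  atlas <- toy_atlas(2)
  gaps <- c(0, 0.01, 0.1, 0.5, 1, 2, 5)
  vals <- vapply(gaps, function(g) {
    t <- make_zc_tables(atlas, c(1, 1, 1), c(1.1, 1.1 + g * 0.1, 1),
                        c(0.1, 0.1, 0.1))
    build_connectivity(t$k, t$k0, atlas)$rprime[1, 2]
  }, numeric(1))
  expect_equal(vals, 1 - (exp(2 * gaps) - 1) / (exp(2 * gaps) + 1))
  expect_true(all(diff(vals) < 0))
  # ESd = 0 gives maximal connectivity 1; |ESd| = 5 is near zero
  expect_equal(vals[1], 1)
  expect_equal(vals[length(vals)], 2 / (exp(10) + 1), tolerance = 1e-12)
  expect_lt(vals[length(vals)], 1e-4)
})

test_that("mask policies zero or NA the non-concurrent pairs", {
  atlas <- toy_atlas(2)
  t <- make_zc_tables(atlas, c(1, 1, 1), c(1.1, 0.9, 1), c(0.1, 0.1, 0.1))
  zc <- zscore_change(t$k, t$k0, atlas)
  esd <- esd_matrix(zc, atlas)
  zero <- esd_to_rprime(esd, mask_policy = "zero_masked")
  expect_equal(zero$rprime[1, 2], 0)
  nan <- esd_to_rprime(esd, mask_policy = "nan_masked")
  expect_true(is.na(nan$rprime[1, 2]))
  expect_equal(nan$rprime[1, 1], 0)  # diagonal stays 0
  # raw sign policy keeps the signed transform (antisymmetric around 1)
  t2 <- make_zc_tables(atlas, c(1, 1, 1), c(1.1, 1.3, 1), c(0.1, 0.1, 0.1))
  esd2 <- esd_matrix(zscore_change(t2$k, t2$k0, atlas), atlas)
  raw <- esd_to_rprime(esd2, sign_policy = "raw", mask_policy = "zero_masked")
  expect_equal(raw$rprime[1, 2] + raw$rprime[2, 1], 2)
})

test_that("binarization is strict and bounded", {
  atlas <- toy_atlas(2)
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 0.96
  m[1, 3] <- m[3, 1] <- 0.5
  m[2, 3] <- m[3, 2] <- 0.7
  conn <- as_connectivity(m, atlas)
  expect_equal(binarize(conn, 0.95)$edge_count, 1)
  expect_equal(binarize(conn, 1)$edge_count, 0)     # strict >
  expect_equal(binarize(conn, 0)$edge_count, 3)     # all positive pairs
  expect_equal(binarize(conn, 0.5)$edge_count, 2)
  expect_error(binarize(conn, 1.2), "\\[0, 1\\]")
})

test_that("threshold sweep has 101 points and matches brute-force counts", {
  set.seed(11)
  atlas <- toy_atlas(9)
  n <- nrow(atlas)
  mean_k0 <- runif(n, 0.8, 1.2)
  t <- make_zc_tables(atlas, mean_k0, mean_k0 + runif(n, -0.1, 0.3),
                      runif(n, 0.05, 0.3))
  conn <- build_connectivity(t$k, t$k0, atlas)
  sweep <- threshold_sweep(conn)
  expect_equal(nrow(sweep), 101)
  expect_equal(sweep$tau, seq(0, 1, by = 0.01))
  expect_true(all(diff(sweep$edge_count) <= 0))
  for (tau in c(0, 0.3, 0.7, 0.95, 1)) {
    expect_equal(sweep$edge_count[which.min(abs(sweep$tau - tau))],
                 oracle_edge_count(conn$rprime, sweep$tau[
                   which.min(abs(sweep$tau - tau))]))
  }
  # the all-masked matrix sweeps to zero everywhere
  flat <- as_connectivity(matrix(0, n, n), atlas)
  expect_true(all(threshold_sweep(flat)$edge_count == 0))
})

test_that("stage-pair schemes produce the documented pairings", {
  atlas <- toy_atlas(3)
  set.seed(5)
  tables <- dplyr::bind_rows(lapply(1:4, function(k) {
    toy_table(atlas, runif(4, 0.9, 1.3), rep(0.1, 4), stage_id = k)
  }))
  vs <- connectivity_matrices(tables, atlas, scheme = "vs_first")
  expect_equal(names(vs), c("2-1", "3-1", "4-1"))
  cons <- connectivity_matrices(tables, atlas, scheme = "consecutive")
  expect_equal(names(cons), c("2-1", "3-2", "4-3"))
  expect_equal(vs[["2-1"]]$rprime, cons[["2-1"]]$rprime)
  one_stage <- tables[tables$stage_id == 1, ]
  expect_error(connectivity_matrices(one_stage, atlas), "at least 2 stages")
})

test_that("connectivity matrices round-trip through dense CSV", {
  set.seed(13)
  atlas <- toy_atlas(5)
  n <- nrow(atlas)
  t <- make_zc_tables(atlas, runif(n, 0.9, 1.1), runif(n, 0.9, 1.3),
                      runif(n, 0.05, 0.2))
  conn <- build_connectivity(t$k, t$k0, atlas)
  path <- withr::local_tempfile(fileext = ".csv")
  write_conn_csv(conn, path)
  back <- read_conn_csv(path, atlas, stage_pair = conn$stage_pair)
  expect_equal(back$rprime, conn$rprime, tolerance = 1e-12)
})

test_that("BrainNet export writes well-formed node and edge files", {
  atlas <- default_atlas()
  n <- nrow(atlas)
  m <- matrix(0, n, n)
  m[1, 2] <- m[2, 1] <- 0.99
  conn <- as_connectivity(m, atlas)
  node <- withr::local_tempfile(fileext = ".node")
  edge <- withr::local_tempfile(fileext = ".edge")
  write_brainnet(conn, node, edge, tau = 0.95)
  node_tbl <- utils::read.table(node, sep = "\t")
  expect_equal(dim(node_tbl), c(120, 6))
  expect_true(all(node_tbl$V4 %in% 1:6))
  edge_mat <- as.matrix(utils::read.table(edge, sep = "\t"))
  expect_equal(dim(edge_mat), c(120, 120))
  expect_equal(sum(edge_mat > 0), 2)  # the single suprathreshold edge
})
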