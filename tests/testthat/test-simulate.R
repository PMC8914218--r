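test_that("generation is deterministic for a fixed seed", {
  cfg <- synth_config(seed = 11)
  a <- simulate_suvr_tables(cfg)
  b <- simulate_suvr_tables(cfg)
  expect_identical(a$tables, b$tables)
  c <- simulate_suvr_tables(synth_config(seed = 12))
  expect_false(identical(a$tables, c$tables))
})

test_that("contradictory coupling configuration is rejected", {
  expect_error(synth_config(epsilon_couple = 2, decoupled_z_gap = 2),
               "contradictory")
  expect_error(synth_config(n_stages = 1), ">= 2")
  expect_error(synth_config(noise_sd = -1), ">= 0")
})

test_that("the generated tables respect the structural invariants", {
  sim <- simulate_suvr_tables(synth_config(noise_sd = 0.05, seed = 4))
  atlas <- sim$config$atlas
  expect_true(all(sim$tables$mean_suvr > 0))
  ref <- sim$tables[sim$tables$region_id == reference_region(atlas), ]
  expect_true(all(ref$mean_suvr == 1))
  for (k in 1:4) {
    expect_silent(validate_suvr_table(
      sim$tables[sim$tables$stage_id == k, ], atlas
    ))
  }
})

test_that("noise-free coupled pairs reach R' = 1 and gaps the closed form", {
  sim <- simulate_suvr_tables(synth_config(noise_sd = 0, seed = 1))
  atlas <- sim$config$atlas
  conn <- connectivity_matrices(sim$tables, atlas,
                                scheme = "vs_first")[["4-1"]]
  pairs <- sim$truth$coupled_pairs
  idx <- cbind(match(pairs$region_i, atlas$region_id),
               match(pairs$region_j, atlas$region_id))
  expect_equal(unname(conn$rprime[idx]), rep(1, nrow(pairs)))

  # adjacent ladder levels differ by the configured z gap: R' follows the
  # printed transform evaluated at that gap
  g <- sim$config$decoupled_z_gap
  design <- sim$truth$design
  singles <- design[design$role == "singleton", ]
  s1 <- match(singles$region_id[1], atlas$region_id)
  s2 <- match(singles$region_id[2], atlas$region_id)
  expect_equal(conn$rprime[s1, s2], 1 - (exp(2 * g) - 1) / (exp(2 * g) + 1),
               tolerance = 1e-12)
})

test_that("noise-free binarization at 0.95 recovers exactly the coupled pairs", {
  sim <- simulate_suvr_tables(synth_config(noise_sd = 0, seed = 8))
  atlas <- sim$config$atlas
  for (scheme in c("vs_first", "consecutive")) {
    conns <- connectivity_matrices(sim$tables, atlas, scheme = scheme)
    for (conn in conns) {
      rec <- edge_recovery(conn, sim$truth$edges, tau = 0.95)
      expect_equal(rec$precision, 1)
      expect_equal(rec$recall, 1)
    }
  }
})

test_that("rank-based recovery stays accurate under measurement noise", {
  f1 <- vapply(1:50, function(s) {
    sim <- simulate_suvr_tables(synth_config(noise_sd = 0.05, seed = s))
    conn <- connectivity_matrices(sim$tables, sim$config$atlas,
                                  scheme = "vs_first")[["4-1"]]
    edge_recovery(conn, sim$truth$edges, k = nrow(sim$truth$edges))$f1
  }, numeric(1))
  expect_gte(mean(f1), 0.9)
})

test_that("edge recovery scoring itself is correct on known sets", {
  atlas <- toy_atlas(4)
  m <- matrix(0, 5, 5)
  m[1, 2] <- m[2, 1] <- 0.99
  m[3, 4] <- m[4, 3] <- 0.97
  m[1, 3] <- m[3, 1] <- 0.5
  conn <- as_connectivity(m, atlas)
  truth <- tibble::tibble(region_i = c(1L, 2L), region_j = c(2L, 3L))
  rec <- edge_recovery(conn, truth, tau = 0.95)
  expect_equal(rec$precision, 0.5)  # found {1-2, 3-4}; true {1-2, 2-3}
  expect_equal(rec$recall, 0.5)
  rec_k <- edge_recovery(conn, truth, k = 1)
  expect_equal(rec_k$precision, 1)
  expect_equal(rec_k$recall, 0.5)
  expect_error(edge_recovery(conn, truth), "exactly one")
  expect_error(edge_recovery(conn, truth, tau = 0.5, k = 2), "exactly one")
})

test_that("phantom parcellation recovers the configured means", {
  atlas <- toy_atlas(7)
  means <- c(seq(0.7, 1.6, length.out = 7), 1)
  tbl <- toy_table(atlas, means, rep(0.2, 8))

  # degenerate voxel noise: exact recovery
  ph0 <- simulate_phantom(tbl, atlas, n_voxels = 30, voxel_sd = 0, seed = 1)
  rec0 <- suvr_from_image(ph0$activity, ph0$labels, atlas,
                          ph0$injected_dose, ph0$body_weight)
  expect_equal(rec0$mean_suvr, means, tolerance = 1e-12)
  expect_equal(sort(unique(as.integer(ph0$labels[ph0$labels != 0]))),
               sort(atlas$region_id))

  # noisy voxels: per-region recovery within 3 standard errors, checked as a
  # coverage fraction over seeds (the bound is a 99.73% interval)
  n_vox <- 120
  sdv <- 0.15
  inside <- unlist(lapply(1:30, function(s) {
    ph <- simulate_phantom(tbl, atlas, n_voxels = n_vox, voxel_sd = sdv,
                           seed = s)
    rec <- suvr_from_image(ph$activity, ph$labels, atlas,
                           ph$injected_dose, ph$body_weight)
    err <- abs(rec$mean_suvr - means)
    err[atlas$region_id != reference_region(atlas)] <= 3 * sdv / sqrt(n_vox)
  }))
  expect_gte(mean(inside), 0.99)
})
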