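# strengths vectors index the 76 cortical targets in registry order
atlas <- default_atlas()
n_t <- length(cortical_targets(atlas))

test_that("connected fraction counts suprathreshold thalamic targets", {
  all_on <- seed_fixture_conn(atlas, rep(1, n_t))
  res <- seed_connectivity(all_on, tau_seed = 0.95)
  expect_equal(res$connected_count, 76)
  expect_equal(res$connected_fraction, 1)

  all_off <- seed_fixture_conn(atlas, rep(0, n_t))
  expect_equal(seed_connectivity(all_off, tau_seed = 0.95)$connected_count, 0)

  # engineered 45-of-76 pattern, checked against the brute-force oracle
  s <- c(rep(0.97, 45), rep(0.5, n_t - 45))
  res45 <- seed_connectivity(seed_fixture_conn(atlas, s), tau_seed = 0.95)
  expect_equal(res45$connected_count, oracle_connected_count(s, 0.95))
  expect_equal(res45$connected_count, 45)
  expect_equal(round(100 * res45$connected_fraction, 1), 59.2)
  expect_error(seed_connectivity(all_on, tau_seed = 1.5), "\\[0, 1\\]")
})

test_that("connectivity is taken as the max over thalamic seeds", {
  n <- nrow(atlas)
  m <- matrix(0, n, n)
  tl <- match("Thalamus_L", atlas$name)
  tr <- match("Thalamus_R", atlas$name)
  first_target <- match(cortical_targets(atlas)[1], atlas$region_id)
  m[tl, first_target] <- m[first_target, tl] <- 0.3
  m[tr, first_target] <- m[first_target, tr] <- 0.97
  res <- seed_connectivity(as_connectivity(m, atlas), tau_seed = 0.95)
  expect_equal(res$targets$strength[1], 0.97)
  expect_true(res$targets$connected[1])
  expect_equal(res$connected_count, 1)
})

test_that("raising the threshold never adds connected targets", {
  set.seed(23)
  s <- runif(n_t)
  conn <- seed_fixture_conn(atlas, s)
  taus <- seq(0, 1, by = 0.1)
  counts <- vapply(
    taus, function(tau) seed_connectivity(conn, tau_seed = tau)$connected_count,
    integer(1)
  )
  expect_true(all(diff(counts) <= 0))
})

test_that("the relay chain reports dentate and red-nucleus links", {
  n <- nrow(atlas)
  m <- matrix(0, n, n)
  dn <- match("Dentate_L", atlas$name)
  rn <- match("Red_Nucleus", atlas$name)
  m[dn, rn] <- m[rn, dn] <- 0.98
  res <- seed_connectivity(as_connectivity(m, atlas))
  link <- res$chain[res$chain$link == "dentate-red_nucleus" &
                      res$chain$from == "Dentate_L", ]
  expect_equal(link$rprime, 0.98)
  expect_true(all(c("red_nucleus-thalamus", "dentate-thalamus") %in%
                    res$chain$link))
})

test_that("delta classification partitions the connected sets", {
  set.seed(41)
  s_e <- runif(n_t)
  s_l <- runif(n_t)
  e <- seed_connectivity(seed_fixture_conn(atlas, s_e, c(2L, 1L)),
                         tau_seed = 0.6)
  l <- seed_connectivity(seed_fixture_conn(atlas, s_l, c(3L, 2L)),
                         tau_seed = 0.6)
  d <- classify_delta(e, l)
  c_ <- d$counts
  expect_equal(c_$n_stronger + c_$n_weaker, c_$n_both)
  expect_equal(c_$n_both + c_$n_newly_connected, c_$n_connected_later)
  expect_equal(c_$n_both + c_$n_lost, sum(e$targets$connected))
  expect_equal(c_$n_later_stronger + c_$n_later_weaker, c_$n_connected_later)
  # brute-force check of the later-connected direction counts
  up <- sum(s_l > 0.6 & s_l > s_e)
  expect_equal(c_$n_later_stronger, up)
})

test_that("uniform strengthening and ties behave as documented", {
  s <- runif(n_t, 0.7, 0.9)
  e <- seed_connectivity(seed_fixture_conn(atlas, s), tau_seed = 0.5)
  l <- seed_connectivity(seed_fixture_conn(atlas, s + 0.05), tau_seed = 0.5)
  d <- classify_delta(e, l)
  expect_equal(d$counts$n_stronger, n_t)
  expect_equal(d$counts$n_weaker, 0)

  tie <- classify_delta(e, e)
  expect_equal(tie$counts$n_stronger, 0)       # ties count as weaker
  expect_equal(tie$counts$n_weaker, n_t)
  tie2 <- classify_delta(e, e, ties = "stronger")
  expect_equal(tie2$counts$n_stronger, n_t)
})

test_that("the published-style bookkeeping patterns are reproduced", {
  tau <- 0.95
  # stage 2-1: 45 of 76 connected
  s1 <- c(seq(0.960, 0.9644, length.out = 45), rep(0.5, 31))
  # stage 3-2: 74 connected; 29 weaker and 45 stronger than stage 2-1
  s2 <- c(s1[1:29] - 5e-4, s1[30:45] + 1e-3, rep(0.96, 29), 0.5, 0.5)
  # stage 4-3: all 76 connected; exactly 12 targets improve again
  s3 <- s2
  s3[30:41] <- s2[30:41] + 1e-3          # the 12 continuously improving
  s3[42:74] <- s2[42:74] - 5e-4
  s3[1:29] <- s2[1:29] + 1e-3
  s3[75:76] <- 0.96

  r1 <- seed_connectivity(seed_fixture_conn(atlas, s1, c(2L, 1L)), tau_seed = tau)
  r2 <- seed_connectivity(seed_fixture_conn(atlas, s2, c(3L, 2L)), tau_seed = tau)
  r3 <- seed_connectivity(seed_fixture_conn(atlas, s3, c(4L, 3L)), tau_seed = tau)

  expect_equal(r1$connected_count, 45)
  expect_equal(round(100 * r1$connected_fraction, 1), 59.2)
  expect_equal(r2$connected_count, 74)
  expect_equal(round(100 * r2$connected_fraction, 1), 97.4)
  expect_equal(r3$connected_count, 76)

  d1 <- classify_delta(r1, r2)
  expect_equal(d1$counts$n_later_weaker, 29)
  expect_equal(d1$counts$n_later_stronger, 45)
  g1 <- glance(d1)
  expect_equal(round(100 * g1$frac_later_weaker, 1), 39.2)
  expect_equal(round(100 * g1$frac_later_stronger, 1), 60.8)

  d2 <- classify_delta(r2, r3)
  ci <- continuously_improving(list(d1, d2))
  expect_equal(ci$n, 12)
  expect_equal(round(100 * ci$fraction, 1), 15.8)
  # cross-check against exhaustive enumeration on the raw strengths
  manual <- sum((s2 > tau) & (s2 > s1) & (s3 > tau) & (s3 > s2))
  expect_equal(ci$n, manual)
})

test_that("mismatched results are rejected", {
  s <- runif(n_t)
  e <- seed_connectivity(seed_fixture_conn(atlas, s), tau_seed = 0.5)
  l <- seed_connectivity(seed_fixture_conn(atlas, s), tau_seed = 0.6)
  expect_error(classify_delta(e, l), "different tau_seed")
  expect_error(continuously_improving(list()), "at least one")
})
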