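# Independent scalar oracles and fixture builders shared across tests.
# Everything here is deliberately naive (double loops, closed forms) so it
# cannot share code paths with the package implementation.

# Scalar double-loop implementation of the two connectivity equations:
# ESd(i,j) = (m_k,i - m_1,i)/s_i - (m_k,j - m_1,j)/s_j,
# R = (exp(2*ESd) - 1)/(exp(2*ESd) + 1), R' = 1 - R, with the absolute-value
# sign policy and zero masking of non-concurrently-increasing pairs.
oracle_rprime <- function(mean_k, mean_k0, s) {
  n <- length(mean_k)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      di <- mean_k[i] - mean_k0[i]
      dj <- mean_k[j] - mean_k0[j]
      if (!(di > 0 && dj > 0)) next
      esd <- abs(di / s[i] - dj / s[j])
      r <- (exp(2 * esd) - 1) / (exp(2 * esd) + 1)
      out[i, j] <- 1 - r
    }
  }
  out
}

# Brute-force edge count at threshold tau over the upper triangle.
oracle_edge_count <- function(m, tau) {
  n <- nrow(m)
  cnt <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (!is.na(m[i, j]) && m[i, j] > tau) cnt <- cnt + 1L
    }
  }
  cnt
}

# Closed-form one-way ANOVA p-value for two groups (pooled variance).
oracle_anova2_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
  f <- (mean(a) - mean(b))^2 / (sp2 * (1 / na + 1 / nb))
  stats::pf(f, 1, na + nb - 2, lower.tail = FALSE)
}

# Small ad-hoc atlas: n paired regions plus a pons reference. Not strict.
toy_atlas <- function(n = 6) {
  reg <- tibble::tibble(
    region_id = c(seq_len(n), 9001L),
    name = c(paste0("Region_", seq_len(n)), "Pons"),
    hemisphere = "midline",
    lobe = c(rep("frontal", n), "brainstem"),
    source = c(rep("aal116", n), "added"),
    subnetwork = NA_character_,
    is_seed = FALSE,
    is_cortical_target = c(rep(TRUE, n), FALSE)
  )
  as_metconn_atlas(reg, reference = "Pons", strict = FALSE)
}

# Stage SUVR table for an atlas from explicit means/SDs.
toy_table <- function(atlas, means, sds, stage_id = 1L, n_voxels = 50L) {
  tibble::tibble(
    stage_id = as.integer(stage_id),
    region_id = atlas$region_id,
    mean_suvr = means,
    sd_suvr = sds,
    n_voxels = n_voxels
  )
}

# Connectivity fixture on the default atlas: thalamo-cortical strengths set
# explicitly per target; everything else stays 0.
seed_fixture_conn <- function(atlas, strengths, stage_pair = c(2L, 1L)) {
  n <- nrow(atlas)
  m <- matrix(0, n, n)
  thal <- match("Thalamus_L", atlas$name)
  targets <- cortical_targets(atlas)
  ti <- match(targets, atlas$region_id)
  stopifnot(length(strengths) == length(ti))
  for (k in seq_along(ti)) {
    m[thal, ti[k]] <- strengths[k]
    m[ti[k], thal] <- strengths[k]
  }
  m[thal, thal] <- 0
  as_connectivity(m, atlas, stage_pair = stage_pair)
}

# Brute-force pathway accounting oracle straight from a strengths vector.
oracle_connected_count <- function(strengths, tau) {
  cnt <- 0L
  for (s in strengths) if (s > tau) cnt <- cnt + 1L
  cnt
}
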