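#' Configuration for the longitudinal SUVR generator
#'
#' Defines the synthetic study conditions: a four-stage longitudinal regional
#' SUVR dataset over the 120-region registry with (i) *coupled* region pairs
#' whose standardized changes rise concordantly (these are the ground-truth
#' network edges), (ii) decoupled recovering regions whose standardized
#' changes are separated by at least `decoupled_z_gap` z units at full
#' development, (iii) transiently dipping regions (fronto-parietal and
#' occipital members, emulating the early worsening of those subnetworks),
#' and (iv) non-recovering regions with a clear monotone decline so that the
#' concurrent-increase mask remains identifiable under measurement noise.
#' The reference region (pons) is held at SUVR 1 across stages.
#'
#' Magnitudes are chosen for identifiability of the designed edge structure,
#' not for numeric fidelity to any particular scan.
#'
#' @param atlas A `metconn_atlas` (default [default_atlas()]).
#' @param n_stages Number of stages (default 4).
#' @param baseline_mean Baseline regional SUVR level (default 1).
#' @param region_voxel_sd Voxelwise SUVR dispersion per region; this is the
#'   s_i that standardizes changes (default 0.25).
#' @param n_voxels Voxels per region reported in the tables (default 100).
#' @param noise_sd SD of additive Gaussian measurement noise on regional
#'   means (default 0.05; set 0 for the noise-free limit).
#' @param epsilon_couple Maximum |z_i - z_j| within a coupled pair (default
#'   0.02; the generator produces exactly concordant pairs, well within it).
#' @param decoupled_z_gap Minimum |z_i - z_j| between decoupled recovering
#'   regions at full development (default 2).
#' @param seed RNG seed.
#' @return Object of class `metconn_synth_config`.
#' @export
synth_config <- function(atlas = default_atlas(), n_stages = 4L,
                         baseline_mean = 1, region_voxel_sd = 0.25,
                         n_voxels = 100L, noise_sd = 0.05,
                         epsilon_couple = 0.02, decoupled_z_gap = 2,
                         seed = 1L) {
  stopifnot(inherits(atlas, "metconn_atlas"))
  if (n_stages < 2) abort("n_stages must be >= 2")
  if (region_voxel_sd <= 0) abort("region_voxel_sd must be > 0")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  if (epsilon_couple >= decoupled_z_gap) {
    abort("contradictory config: epsilon_couple must be < decoupled_z_gap")
  }
  structure(
    list(
      atlas = atlas, n_stages = as.integer(n_stages),
      baseline_mean = baseline_mean, region_voxel_sd = region_voxel_sd,
      n_voxels = as.integer(n_voxels), noise_sd = noise_sd,
      epsilon_couple = epsilon_couple, decoupled_z_gap = decoupled_z_gap,
      seed = as.integer(seed)
    ),
    class = "metconn_synth_config"
  )
}

# Role assignment for the default design: coupled pairs and recovering
# singletons drawn from the six subnetworks plus thalamo-cortical and
# dentato-rubral pairs; remaining FPN/OCC members dip then partially
# recover; everything else (bar the reference) declines.
synth_design <- function(config) {
  atlas <- config$atlas
  gap <- config$decoupled_z_gap

  nm <- function(id) region_names(atlas, id)
  take <- function(sn, idx) subnetwork_members(atlas, sn)[idx]
  by_name <- function(x) atlas$region_id[match(x, atlas$name)]

  pair_members <- list(
    take("SMN", 1:2), take("SMN", 3:4), take("SMN", 5:6),
    take("CON", 1:2), take("CON", 3:4),
    take("DMN", 1:2), take("DMN", 3:4),
    take("FPN", 1:2), take("FPN", 3:4),
    take("OCC", 1:2), take("OCC", 3:4),
    take("CEREBELLUM", 1:2),
    by_name(c("Thalamus_L", "Rolandic_Oper_L")),
    by_name(c("Thalamus_R", "Rolandic_Oper_R")),
    by_name(c("Dentate_L", "Red_Nucleus"))
  )
  singles <- c(
    take("SMN", 7:8), take("CON", 5:6), take("DMN", 5:6),
    take("FPN", 5:6), take("OCC", 5:6), take("CEREBELLUM", 3)
  )
  pair_members <- Filter(function(p) !anyNA(p), pair_members)
  singles <- singles[!is.na(singles)]

  ladder_ids <- c(unlist(pair_members), singles)
  if (anyDuplicated(ladder_ids)) abort("design regions overlap")

  n_pairs <- length(pair_members)
  levels_pairs <- gap * seq_len(n_pairs)
  levels_singles <- gap * (n_pairs + seq_along(singles))

  design <- tibble::tibble(
    region_id = atlas$region_id,
    role = "decline",
    level = NA_real_,
    pair_id = NA_integer_
  )
  for (p in seq_along(pair_members)) {
    idx <- match(pair_members[[p]], design$region_id)
    design$role[idx] <- "coupled"
    design$level[idx] <- levels_pairs[p]
    design$pair_id[idx] <- p
  }
  idx <- match(singles, design$region_id)
  design$role[idx] <- "singleton"
  design$level[idx] <- levels_singles

  dip_ids <- setdiff(
    c(subnetwork_members(atlas, "FPN"), subnetwork_members(atlas, "OCC")),
    ladder_ids
  )
  design$role[match(dip_ids, design$region_id)] <- "dip"
  design$role[design$region_id == reference_region(atlas)] <- "reference"
  design
}

# Noise-free delta (mean SUVR change vs stage 1) per region and stage.
synth_deltas <- function(config, design) {
  n <- nrow(design)
  K <- config$n_stages
  s <- config$region_voxel_sd
  ramp <- (seq_len(K) - 1) / (K - 1)
  deltas <- matrix(0, nrow = n, ncol = K)

  ladder <- design$role %in% c("coupled", "singleton")
  deltas[ladder, ] <- outer(design$level[ladder] * s, ramp)

  dip <- which(design$role == "dip")
  for (j in seq_along(dip)) {
    depth <- -(0.35 + 0.01 * j)
    traj <- c(0, depth, rep(depth + 0.014 * j, max(K - 2, 0)))
    deltas[dip[j], ] <- traj[seq_len(K)]
  }

  decl <- design$role == "decline"
  deltas[decl, ] <- outer(rep(-0.3, sum(decl)), ramp)
  deltas
}

#' Generate a longitudinal SUVR dataset with ground truth
#'
#' Deterministic for a fixed config (including seed). Coupled pair members
#' receive exactly concordant standardized changes; decoupled recovering
#' regions sit on a `decoupled_z_gap`-spaced ladder, so at the default
#' policies and the 0.95 cerebral threshold the noise-free stage-versus-
#' baseline networks contain exactly the coupled pairs as edges.
#'
#' @param config A `metconn_synth_config`.
#' @return List with elements
#'   * `tables`: long SUVR table over all stages;
#'   * `truth`: list with `coupled_pairs` (tibble `pair_id`, `region_i`,
#'     `region_j`, `level`), `edges` (expected edge tibble, valid for every
#'     stage pair under both schemes), `connected_targets` (cortical targets
#'     expected to connect to the thalamus), and `design` / `deltas` for
#'     audit;
#'   * `config`.
#' @export
simulate_suvr_tables <- function(config) {
  stopifnot(inherits(config, "metconn_synth_config"))
  atlas <- config$atlas
  design <- synth_design(config)
  deltas <- synth_deltas(config, design)
  n <- nrow(design)
  K <- config$n_stages

  set.seed(config$seed)
  noise <- matrix(rnorm(n * K, 0, config$noise_sd), nrow = n, ncol = K)
  if (config$noise_sd == 0) noise[] <- 0
  ref_row <- which(design$role == "reference")
  noise[ref_row, ] <- 0

  means <- config$baseline_mean + deltas + noise
  means[ref_row, ] <- 1
  means <- pmax(means, 0.01)

  tables <- dplyr::bind_rows(lapply(seq_len(K), function(k) {
    tibble::tibble(
      stage_id = k,
      region_id = atlas$region_id,
      mean_suvr = means[, k],
      sd_suvr = config$region_voxel_sd,
      n_voxels = config$n_voxels
    )
  }))

  coupled <- design[design$role == "coupled", ]
  pairs <- coupled |>
    dplyr::group_by(.data$pair_id) |>
    dplyr::summarise(
      region_i = min(.data$region_id),
      region_j = max(.data$region_id),
      level = .data$level[1],
      .groups = "drop"
    )
  thal_pairs <- pairs[
    region_names(atlas, pairs$region_i) %in% c("Thalamus_L", "Thalamus_R") |
      region_names(atlas, pairs$region_j) %in% c("Thalamus_L", "Thalamus_R"),
  ]
  targets <- cortical_targets(atlas)
  connected_targets <- intersect(
    c(thal_pairs$region_i, thal_pairs$region_j), targets
  )

  list(
    tables = tables,
    truth = list(
      coupled_pairs = pairs,
      edges = pairs[, c("region_i", "region_j")],
      connected_targets = connected_targets,
      design = design,
      deltas = deltas
    ),
    config = config
  )
}

#' Score edge recovery against ground truth
#'
#' Compares the edges recovered from a connectivity matrix with a ground-
#' truth edge set, either by strict thresholding (`tau`; the noise-free
#' recovery rule) or by taking the `k` strongest unmasked pairs (the rule
#' used under measurement noise, where no fixed threshold is meaningful).
#' Exactly one of `tau` and `k` must be given.
#'
#' @param conn A `metconn_conn`.
#' @param truth_edges Tibble with columns `region_i`, `region_j` (unordered
#'   pairs).
#' @param tau Threshold for rule-based recovery.
#' @param k Number of top-ranked pairs for rank-based recovery.
#' @return Tibble with columns `precision`, `recall`, `f1`, `n_true`,
#'   `n_found`.
#' @export
edge_recovery <- function(conn, truth_edges, tau = NULL, k = NULL) {
  stopifnot(inherits(conn, "metconn_conn"))
  if (is.null(tau) == is.null(k)) {
    abort("supply exactly one of tau or k")
  }
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  truth <- unique(key(truth_edges$region_i, truth_edges$region_j))
  long <- tidy(conn)
  long <- long[!is.na(long$rprime), ]
  if (!is.null(tau)) {
    found <- long[long$rprime > tau, ]
  } else {
    found <- long[order(-long$rprime), ]
    found <- head(found, k)
  }
  found_keys <- key(found$region_i, found$region_j)
  tp <- length(intersect(found_keys, truth))
  precision <- if (length(found_keys) == 0) 1 else tp / length(found_keys)
  recall <- if (length(truth) == 0) 1 else tp / length(truth)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  tibble::tibble(
    precision = precision, recall = recall, f1 = f1,
    n_true = length(truth), n_found = length(found_keys)
  )
}

#' Build a voxel-level phantom for one stage
#'
#' Constructs a 3-D activity volume and matching integer label volume whose
#' parcellation reproduces a stage SUVR table: each region gets `n_voxels`
#' voxels drawn from N(mean_suvr * A0, voxel_sd * A0) where A0 =
#' injected_dose / body_weight, so that [compute_suv()] then [parcellate()]
#' then [to_suvr()] recovers the configured regional means up to the
#' sampling error voxel_sd / sqrt(n_voxels). The reference region's voxels
#' are held exactly at A0 (its SUVR is 1 by construction), so recovered
#' ratios carry only the target region's sampling error.
#'
#' @param stage_table Single-stage SUVR table.
#' @param atlas A `metconn_atlas`.
#' @param n_voxels Voxels per region.
#' @param voxel_sd Voxelwise SD on the SUVR scale (0 gives exact recovery).
#' @param injected_dose,body_weight Acquisition parameters stored with the
#'   phantom.
#' @param seed RNG seed.
#' @return List with `activity` and `labels` (3-D arrays of equal dims),
#'   `injected_dose`, `body_weight`.
#' @export
simulate_phantom <- function(stage_table, atlas, n_voxels = 100L,
                             voxel_sd = 0.1, injected_dose = 185,
                             body_weight = 37, seed = 1L) {
  stage_table <- validate_suvr_table(stage_table, atlas)
  if (n_voxels < 1) abort("n_voxels must be >= 1")
  set.seed(seed)
  a0 <- injected_dose / body_weight
  n_reg <- nrow(atlas)
  total <- n_reg * n_voxels
  nx <- 16L
  nz <- as.integer(ceiling(total / (nx * nx)))
  dims <- c(nx, nx, nz)

  labels <- integer(prod(dims))
  activity <- numeric(prod(dims))
  ref_id <- reference_region(atlas)
  for (i in seq_len(n_reg)) {
    idx <- ((i - 1) * n_voxels + 1):(i * n_voxels)
    labels[idx] <- atlas$region_id[i]
    mu <- stage_table$mean_suvr[i] * a0
    if (atlas$region_id[i] == ref_id || voxel_sd == 0) {
      activity[idx] <- mu
    } else {
      activity[idx] <- rnorm(n_voxels, mu, voxel_sd * a0)
    }
  }
  list(
    activity = array(activity, dim = dims),
    labels = array(labels, dim = dims),
    injected_dose = injected_dose,
    body_weight = body_weight
  )
}
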