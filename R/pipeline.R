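#' Configuration for an end-to-end pipeline run
#'
#' Validates paths and policy enums up front (fail-fast, before any
#' computation).
#'
#' @param out_dir Output directory (created if absent).
#' @param mode `"simulate"` (generate synthetic stage tables) or `"tables"`
#'   (load SUVR tables from `tables_path`).
#' @param registry_path Optional registry TSV; `NULL` uses the packaged
#'   default registry.
#' @param tables_path SUVR table file (required for `mode = "tables"`).
#' @param timeline_path Optional symptom-timeline TSV; `NULL` uses the
#'   packaged demonstration timeline.
#' @param sd_source,sign_policy,mask_policy Connectivity policies, see
#'   [build_connectivity()].
#' @param tau_cerebrum,tau_cerebellum Display thresholds (defaults 0.95 and
#'   0.65).
#' @param tau_seed Seed-pathway threshold (default 0.95).
#' @param seed RNG seed for simulation mode.
#' @return Object of class `metconn_run_config`.
#' @export
pipeline_config <- function(out_dir, mode = c("simulate", "tables"),
                            registry_path = NULL, tables_path = NULL,
                            timeline_path = NULL,
                            sd_source = "baseline_voxel_sd",
                            sign_policy = "absolute",
                            mask_policy = "zero_masked",
                            tau_cerebrum = 0.95, tau_cerebellum = 0.65,
                            tau_seed = 0.95, seed = 1L) {
  mode <- match.arg(mode)
  if (!sd_source %in% c("baseline_voxel_sd", "comparison_voxel_sd", "pooled")) {
    abort(paste0("unknown sd_source: ", sd_source))
  }
  if (!sign_policy %in% c("absolute", "raw")) {
    abort(paste0("unknown sign_policy: ", sign_policy))
  }
  if (!mask_policy %in% c("zero_masked", "nan_masked")) {
    abort(paste0("unknown mask_policy: ", mask_policy))
  }
  for (tau in c(tau_cerebrum, tau_cerebellum, tau_seed)) {
    if (tau < 0 || tau > 1) abort("thresholds must lie in [0, 1]")
  }
  for (p in c(registry_path, tables_path, timeline_path)) {
    if (!is.null(p) && !file.exists(p)) {
      abort(paste0("configured input does not exist: ", p))
    }
  }
  if (mode == "tables" && is.null(tables_path)) {
    abort("mode = 'tables' requires tables_path")
  }
  structure(
    list(
      out_dir = out_dir, mode = mode, registry_path = registry_path,
      tables_path = tables_path, timeline_path = timeline_path,
      sd_source = sd_source, sign_policy = sign_policy,
      mask_policy = mask_policy, tau_cerebrum = tau_cerebrum,
      tau_cerebellum = tau_cerebellum, tau_seed = tau_seed,
      seed = as.integer(seed)
    ),
    class = "metconn_run_config"
  )
}

#' Run the full single-subject network analysis
#'
#' Executes the whole pipeline: registry load, SUVR tables (simulated or
#' loaded), stage-versus-baseline and consecutive connectivity matrices,
#' threshold sweeps, subnetwork dynamics with stage comparisons, seed-based
#' pathway accounting with per-transition classification and continuous-
#' improvement set, symptom-timeline stage alignment, and BrainNet exports.
#' All outputs are plain text under `out_dir`, and a `manifest.json` lists
#' every file written together with the configuration echo; runs are
#' deterministic for a fixed configuration.
#'
#' @param config A `metconn_run_config`.
#' @return The manifest (named list), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "metconn_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  files <- character(0)
  add <- function(path) files <<- c(files, path)

  atlas <- if (is.null(config$registry_path)) default_atlas() else
    read_registry(config$registry_path)
  write_registry(atlas, out("registry.tsv"))
  add(out("registry.tsv"))

  if (config$mode == "simulate") {
    sim <- simulate_suvr_tables(synth_config(atlas = atlas,
                                             seed = config$seed))
    tables <- sim$tables
  } else {
    tables <- read_suvr_table(config$tables_path, atlas)
  }
  write_suvr_table(tables, out("suvr_tables.tsv"))
  add(out("suvr_tables.tsv"))

  conns <- list(
    vs_first = connectivity_matrices(
      tables, atlas, scheme = "vs_first", sd_source = config$sd_source,
      sign_policy = config$sign_policy, mask_policy = config$mask_policy
    ),
    consecutive = connectivity_matrices(
      tables, atlas, scheme = "consecutive", sd_source = config$sd_source,
      sign_policy = config$sign_policy, mask_policy = config$mask_policy
    )
  )

  for (scheme in names(conns)) {
    for (pair in names(conns[[scheme]])) {
      conn <- conns[[scheme]][[pair]]
      base <- paste0(scheme, "_", pair)
      write_conn_csv(conn, out(paste0("conn_", base, ".csv")))
      add(out(paste0("conn_", base, ".csv")))
      readr::write_tsv(threshold_sweep(conn),
                       out(paste0("sweep_", base, ".tsv")), progress = FALSE)
      add(out(paste0("sweep_", base, ".tsv")))
    }
  }

  for (pair in names(conns$vs_first)) {
    conn <- conns$vs_first[[pair]]
    paths <- write_brainnet(
      conn, out(paste0("brainnet_", pair, ".node")),
      out(paste0("brainnet_", pair, ".edge")), tau = config$tau_cerebrum
    )
    add(paths[["node"]]); add(paths[["edge"]])
  }

  stats <- subnetwork_stats(tables, atlas)
  readr::write_tsv(
    dplyr::select(stats, -"observations"), out("subnetwork_stats.tsv"),
    progress = FALSE
  )
  add(out("subnetwork_stats.tsv"))
  cmp <- compare_subnetworks(tables, atlas)
  pairwise <- tidyr::unnest(
    dplyr::select(cmp, "subnetwork", "pairwise"), "pairwise"
  )
  readr::write_tsv(pairwise, out("subnetwork_comparisons.tsv"),
                   progress = FALSE)
  add(out("subnetwork_comparisons.tsv"))

  seedpaths <- lapply(conns$consecutive, seed_connectivity, atlas = atlas,
                      tau_seed = config$tau_seed)
  for (pair in names(seedpaths)) {
    readr::write_tsv(tidy(seedpaths[[pair]]),
                     out(paste0("seed_targets_", pair, ".tsv")),
                     progress = FALSE)
    add(out(paste0("seed_targets_", pair, ".tsv")))
  }
  deltas <- list()
  if (length(seedpaths) >= 2) {
    for (i in seq_len(length(seedpaths) - 1)) {
      d <- classify_delta(seedpaths[[i]], seedpaths[[i + 1]])
      deltas[[length(deltas) + 1]] <- d
      lbl <- paste0(names(seedpaths)[i + 1], "_vs_", names(seedpaths)[i])
      readr::write_tsv(tidy(d), out(paste0("pathway_delta_", lbl, ".tsv")),
                       progress = FALSE)
      add(out(paste0("pathway_delta_", lbl, ".tsv")))
    }
    ci <- continuously_improving(deltas)
    jsonlite::write_json(
      list(
        continuously_improving = ci[c("region_id", "name", "n", "n_targets",
                                      "fraction")],
        fractions = lapply(deltas, function(d) glance(d))
      ),
      out("pathway_summary.json"), auto_unbox = TRUE, digits = NA
    )
    add(out("pathway_summary.json"))
  }

  timeline <- if (is.null(config$timeline_path)) demo_timeline() else
    read_timeline(config$timeline_path)
  readr::write_tsv(align_stages(timeline), out("stage_alignment.tsv"),
                   progress = FALSE)
  add(out("stage_alignment.tsv"))

  add(out("manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("metconn")),
    config = config[setdiff(names(config), "atlas")],
    files = files
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}
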