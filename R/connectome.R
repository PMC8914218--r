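#' Standardized regional SUVR change between two stages
#'
#' For each region i, computes z_i = (mean_k,i - mean_k0,i) / s_i: the
#' change in mean regional SUVR from a baseline stage to a comparison stage,
#' standardized by a per-region dispersion s_i. In a single subject there is
#' no across-subject SD, so s_i is taken from the voxelwise SD of the region:
#' by default the baseline stage's (`"baseline_voxel_sd"`), with the
#' comparison stage's or the pooled value (root mean square of the two) as
#' alternatives. This choice is the main methodological ambiguity of the
#' approach and is therefore explicit.
#'
#' @param table_k Comparison-stage SUVR table.
#' @param table_k0 Baseline-stage SUVR table.
#' @param atlas A `metconn_atlas` shared by both tables.
#' @param sd_source One of `"baseline_voxel_sd"`, `"comparison_voxel_sd"`,
#'   `"pooled"`.
#' @return Tibble in registry order with columns `region_id`, `name`,
#'   `delta` (raw SUVR change), `s` (dispersion used) and `z`.
#' @export
zscore_change <- function(table_k, table_k0, atlas,
                          sd_source = c("baseline_voxel_sd",
                                        "comparison_voxel_sd", "pooled")) {
  sd_source <- match.arg(sd_source)
  table_k <- validate_suvr_table(table_k, atlas)
  table_k0 <- validate_suvr_table(table_k0, atlas)
  s <- switch(
    sd_source,
    baseline_voxel_sd = table_k0$sd_suvr,
    comparison_voxel_sd = table_k$sd_suvr,
    pooled = sqrt((table_k0$sd_suvr^2 + table_k$sd_suvr^2) / 2)
  )
  zero <- which(s == 0)
  if (length(zero) > 0) {
    abort(paste0(
      "zero dispersion: ",
      paste(region_names(atlas, table_k0$region_id[zero]), collapse = ", ")
    ))
  }
  delta <- table_k$mean_suvr - table_k0$mean_suvr
  tibble::tibble(
    region_id = table_k0$region_id,
    name = region_names(atlas, table_k0$region_id),
    delta = delta,
    s = s,
    z = delta / s
  )
}

#' Effect-size-difference (ESd) matrix for one stage pair
#'
#' ESd(i, j) = z_i - z_j: the difference between the standardized SUVR
#' changes of regions i and j. The raw matrix is antisymmetric with zero
#' diagonal. A concurrency mask records where both regions increased
#' (delta_i > 0 and delta_j > 0); only such concurrently hypermetabolic
#' pairs are analysed as network edges.
#'
#' @param zc Tibble from [zscore_change()].
#' @param atlas A `metconn_atlas`.
#' @param stage_pair Length-2 integer vector `c(comparison, baseline)`, e.g.
#'   `c(2, 1)` for the "2-1" network.
#' @return An object of class `metconn_esd` with elements `values` (N x N
#'   antisymmetric matrix), `mask` (N x N logical concurrency mask), `atlas`,
#'   `stage_pair`.
#' @export
esd_matrix <- function(zc, atlas, stage_pair = c(2L, 1L)) {
  stopifnot(inherits(atlas, "metconn_atlas"))
  if (!all(is.finite(zc$z))) abort("z scores must be finite")
  if (!identical(zc$region_id, atlas$region_id)) {
    abort("z-score table must be in registry order (use zscore_change())")
  }
  values <- outer(zc$z, zc$z, "-")
  up <- zc$delta > 0
  mask <- outer(up, up, "&")
  diag(values) <- 0
  diag(mask) <- FALSE
  dimnames(values) <- dimnames(mask) <- list(atlas$name, atlas$name)
  structure(
    list(
      values = values, mask = mask, atlas = atlas,
      stage_pair = as.integer(stage_pair)
    ),
    class = "metconn_esd"
  )
}

#' Transform an ESd matrix into the connectivity matrix R'
#'
#' Applies the Fisher-type transform
#' R = (exp(2 ESd) - 1) / (exp(2 ESd) + 1) = tanh(ESd) and the adjustment
#' R' = 1 - R, so that a small |ESd| (two regions changing concordantly)
#' yields a connectivity value near 1 and a large discordance a value near 0.
#'
#' Under the default `sign_policy = "absolute"` the transform is applied to
#' |ESd|, making R' symmetric with all entries in \[0, 1\] (the bound the
#' method asserts); `"raw"` applies it to the signed ESd for audit, in which
#' case values lie in (0, 2) and the matrix is not symmetric. Pairs failing
#' the concurrent-increase condition are set to 0 (`"zero_masked"`, default,
#' so they never survive a positive threshold) or to `NA`
#' (`"nan_masked"`, for audit). The diagonal is always 0.
#'
#' @param esd A `metconn_esd`.
#' @param sign_policy `"absolute"` (default) or `"raw"`.
#' @param mask_policy `"zero_masked"` (default) or `"nan_masked"`.
#' @return An object of class `metconn_conn` with elements `rprime` (N x N
#'   matrix), `masked` (logical matrix, TRUE where the concurrency condition
#'   failed), `atlas`, `stage_pair`, `sign_policy`, `mask_policy`.
#' @export
esd_to_rprime <- function(esd, sign_policy = c("absolute", "raw"),
                          mask_policy = c("zero_masked", "nan_masked")) {
  sign_policy <- match.arg(sign_policy)
  mask_policy <- match.arg(mask_policy)
  stopifnot(inherits(esd, "metconn_esd"))
  e <- if (sign_policy == "absolute") abs(esd$values) else esd$values
  rprime <- 1 - tanh(e)
  masked <- !esd$mask
  diag(masked) <- FALSE
  rprime[masked] <- if (mask_policy == "zero_masked") 0 else NA_real_
  diag(rprime) <- 0
  structure(
    list(
      rprime = rprime, masked = masked, atlas = esd$atlas,
      stage_pair = esd$stage_pair, sign_policy = sign_policy,
      mask_policy = mask_policy
    ),
    class = "metconn_conn"
  )
}

#' Build a stage-pair connectivity matrix from two SUVR tables
#'
#' Convenience chain: [zscore_change()] then [esd_matrix()] then
#' [esd_to_rprime()].
#'
#' @inheritParams zscore_change
#' @inheritParams esd_to_rprime
#' @return A `metconn_conn`.
#' @export
build_connectivity <- function(table_k, table_k0, atlas,
                               sd_source = c("baseline_voxel_sd",
                                             "comparison_voxel_sd", "pooled"),
                               sign_policy = c("absolute", "raw"),
                               mask_policy = c("zero_masked", "nan_masked")) {
  zc <- zscore_change(table_k, table_k0, atlas, sd_source = match.arg(sd_source))
  pair <- c(unique(table_k$stage_id), unique(table_k0$stage_id))
  esd <- esd_matrix(zc, atlas, stage_pair = pair)
  esd_to_rprime(esd, sign_policy = match.arg(sign_policy),
                mask_policy = match.arg(mask_policy))
}

#' Connectivity matrices for a sequence of stages
#'
#' Builds one connectivity matrix per stage pair under one of two schemes:
#' `"vs_first"` compares every later stage against the first (pairs 2-1,
#' 3-1, 4-1), as used for the stage-versus-baseline matrices; `"consecutive"`
#' compares each stage against its predecessor (2-1, 3-2, 4-3), as used for
#' the seed-pathway evolution.
#'
#' @param tables A long SUVR table covering >= 2 stages (or a list of
#'   single-stage tables).
#' @param atlas A `metconn_atlas`.
#' @param scheme `"vs_first"` or `"consecutive"`.
#' @inheritParams build_connectivity
#' @return Named list of `metconn_conn` objects; names are `"k-k0"` labels
#'   such as `"2-1"`.
#' @export
connectivity_matrices <- function(tables, atlas,
                                  scheme = c("vs_first", "consecutive"),
                                  sd_source = c("baseline_voxel_sd",
                                                "comparison_voxel_sd",
                                                "pooled"),
                                  sign_policy = c("absolute", "raw"),
                                  mask_policy = c("zero_masked",
                                                  "nan_masked")) {
  scheme <- match.arg(scheme)
  sd_source <- match.arg(sd_source)
  sign_policy <- match.arg(sign_policy)
  mask_policy <- match.arg(mask_policy)
  if (is.data.frame(tables)) {
    tables <- split(tables, tables$stage_id)
  }
  names(tables) <- vapply(
    tables, function(t) as.character(unique(t$stage_id)), character(1)
  )
  stages <- sort(as.integer(names(tables)))
  if (length(stages) < 2) abort("need at least 2 stages to build networks")
  pairs <- switch(
    scheme,
    vs_first = lapply(stages[-1], function(k) c(k, stages[1])),
    consecutive = lapply(seq_along(stages)[-1],
                         function(i) c(stages[i], stages[i - 1]))
  )
  out <- lapply(pairs, function(p) {
    build_connectivity(
      tables[[as.character(p[1])]], tables[[as.character(p[2])]], atlas,
      sd_source = sd_source, sign_policy = sign_policy,
      mask_policy = mask_policy
    )
  })
  names(out) <- vapply(pairs, function(p) paste0(p[1], "-", p[2]),
                       character(1))
  out
}

#' Construct a connectivity object from a ready-made matrix
#'
#' Wraps an N x N symmetric matrix of R' values (e.g. read from file, or an
#' engineered fixture) as a `metconn_conn` aligned to a registry.
#'
#' @param rprime Symmetric numeric matrix with zero diagonal, entries in
#'   \[0, 1\] (NAs allowed for masked pairs).
#' @param atlas A `metconn_atlas` with `nrow(atlas) == nrow(rprime)`.
#' @param stage_pair Length-2 integer vector.
#' @return A `metconn_conn` with `sign_policy = "absolute"`,
#'   `mask_policy` inferred from the presence of NAs.
#' @export
as_connectivity <- function(rprime, atlas, stage_pair = c(2L, 1L)) {
  stopifnot(inherits(atlas, "metconn_atlas"))
  rprime <- as.matrix(rprime)
  if (nrow(rprime) != nrow(atlas) || ncol(rprime) != nrow(atlas)) {
    abort("rprime dimensions must match the registry size")
  }
  if (!isTRUE(all.equal(unname(rprime), unname(t(rprime))))) {
    abort("rprime must be symmetric")
  }
  if (any(diag(rprime) != 0, na.rm = TRUE)) abort("diagonal must be zero")
  if (any(rprime < 0 | rprime > 1, na.rm = TRUE)) {
    abort("rprime entries must lie in [0, 1]")
  }
  dimnames(rprime) <- list(atlas$name, atlas$name)
  masked <- is.na(rprime)
  structure(
    list(
      rprime = rprime, masked = masked, atlas = atlas,
      stage_pair = as.integer(stage_pair), sign_policy = "absolute",
      mask_policy = if (any(masked)) "nan_masked" else "zero_masked"
    ),
    class = "metconn_conn"
  )
}

#' @export
as.matrix.metconn_conn <- function(x, ...) x$rprime

#' @export
print.metconn_conn <- function(x, ...) {
  cat(
    "<metconn_conn> stage pair ", paste(x$stage_pair, collapse = "-"),
    "; ", nrow(x$rprime), " x ", ncol(x$rprime), " regions; policies: ",
    x$sign_policy, " / ", x$mask_policy, "\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy a connectivity matrix into a long edge table
#'
#' @param x A `metconn_conn`.
#' @param ... Unused.
#' @return Tibble over unordered region pairs (i < j in registry order) with
#'   columns `region_i`, `region_j`, `name_i`, `name_j`, `rprime`, `masked`.
#' @exportS3Method generics::tidy
tidy.metconn_conn <- function(x, ...) {
  atlas <- x$atlas
  n <- nrow(x$rprime)
  ut <- which(upper.tri(x$rprime), arr.ind = TRUE)
  tibble::tibble(
    region_i = atlas$region_id[ut[, 1]],
    region_j = atlas$region_id[ut[, 2]],
    name_i = atlas$name[ut[, 1]],
    name_j = atlas$name[ut[, 2]],
    rprime = x$rprime[ut],
    masked = x$masked[ut]
  )
}

#' Binarize a connectivity matrix at a threshold
#'
#' An edge joins regions i and j (i < j) iff R'(i, j) > tau (strictly), so
#' tau = 1 always yields the empty graph; self-edges are never produced, and
#' masked pairs (R' = 0 or NA) never survive a positive threshold.
#'
#' @param conn A `metconn_conn`.
#' @param tau Threshold in \[0, 1\].
#' @return An object of class `metconn_binary`: list with `edges` (tibble
#'   `region_i`, `region_j`, `rprime`), `edge_count`, `tau`, `stage_pair`.
#' @export
binarize <- function(conn, tau) {
  stopifnot(inherits(conn, "metconn_conn"))
  if (!is.numeric(tau) || length(tau) != 1 || is.na(tau) || tau < 0 ||
      tau > 1) {
    abort("tau must be a single value in [0, 1]")
  }
  edges <- tidy(conn)
  edges <- edges[!is.na(edges$rprime) & edges$rprime > tau,
                 c("region_i", "region_j", "name_i", "name_j", "rprime")]
  structure(
    list(
      edges = edges, edge_count = nrow(edges), tau = tau,
      stage_pair = conn$stage_pair
    ),
    class = "metconn_binary"
  )
}

#' @export
print.metconn_binary <- function(x, ...) {
  cat(
    "<metconn_binary> stage pair ", paste(x$stage_pair, collapse = "-"),
    "; tau = ", format(x$tau), "; ", x$edge_count, " edges\n",
    sep = ""
  )
  invisible(x)
}

#' Edge-count curve over the 101-point threshold grid
#'
#' Counts surviving edges at each threshold tau in 0, 0.01, ..., 1 (101
#' values). The count is non-increasing in tau.
#'
#' @param conn A `metconn_conn`.
#' @param taus Threshold grid (default `seq(0, 1, by = 0.01)`).
#' @return Tibble of class `metconn_sweep` with columns `tau`, `edge_count`.
#' @export
threshold_sweep <- function(conn, taus = seq(0, 1, by = 0.01)) {
  stopifnot(inherits(conn, "metconn_conn"))
  vals <- conn$rprime[upper.tri(conn$rprime)]
  vals <- vals[!is.na(vals)]
  counts <- vapply(taus, function(tau) sum(vals > tau), integer(1))
  out <- tibble::tibble(tau = taus, edge_count = counts)
  class(out) <- c("metconn_sweep", class(out))
  attr(out, "stage_pair") <- conn$stage_pair
  out
}

#' Display thresholds used for network figures
#'
#' Canonical display thresholds for binarized network renderings: 0.95 for
#' cerebral networks and 0.65 for cerebellar networks.
#'
#' @return Named numeric vector with elements `cerebrum` and `cerebellum`.
#' @export
display_thresholds <- function() {
  c(cerebrum = 0.95, cerebellum = 0.65)
}

#' @exportS3Method ggplot2::autoplot
autoplot.metconn_sweep <- function(object, ...) {
  pair <- paste(attr(object, "stage_pair"), collapse = "-")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$tau, y = .data$edge_count)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "threshold τ", y = "number of edges",
      title = paste0("Edge count vs threshold (stage ", pair, ")")
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.metconn_conn <- function(object, ...) {
  long <- tidy(object)
  both <- dplyr::bind_rows(
    long,
    dplyr::rename(long,
                  name_i = "name_j", name_j = "name_i",
                  region_i = "region_j", region_j = "region_i")
  )
  lv <- object$atlas$name
  both$name_i <- factor(both$name_i, levels = lv)
  both$name_j <- factor(both$name_j, levels = rev(lv))
  pair <- paste(object$stage_pair, collapse = "-")
  ggplot2::ggplot(both,
                  ggplot2::aes(x = .data$name_i, y = .data$name_j,
                               fill = .data$rprime)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "R'") +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = paste0("Connectivity matrix (stage ", pair, ")")
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}
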