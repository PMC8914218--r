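#' Seed-to-cortex connectivity for the dentato-rubro-thalamo-cortical pathway
#'
#' For one stage-pair connectivity matrix, extracts the R' values between the
#' pathway seeds (dentate nuclei, red nucleus, thalami) and every cortical
#' target region. A target counts as *connected to the thalamus* when the
#' maximum R' over the left/right thalamic seeds exceeds `tau_seed`
#' (strictly); the connected fraction is reported over the full configured
#' target list (default 76 regions). The relay links of the pathway chain
#' (dentate-red nucleus, red nucleus-thalamus, dentate-thalamus) are reported
#' as a per-link table rather than a path-existence boolean.
#'
#' @param conn A `metconn_conn`.
#' @param atlas A `metconn_atlas` (defaults to the one stored in `conn`).
#' @param tau_seed Connectivity threshold in \[0, 1\] (default 0.95, the
#'   cerebral display threshold).
#' @return Object of class `metconn_seedpath` with fields `targets` (tibble
#'   `region_id`, `name`, `lobe`, `strength`, `connected`), `seed_values`
#'   (long tibble of every seed-target R'), `chain` (relay-link tibble),
#'   `n_targets`, `connected_count`, `connected_fraction`, `tau_seed`,
#'   `stage_pair`.
#' @export
seed_connectivity <- function(conn, atlas = NULL, tau_seed = 0.95) {
  stopifnot(inherits(conn, "metconn_conn"))
  atlas <- atlas %||% conn$atlas
  if (!is.numeric(tau_seed) || length(tau_seed) != 1 || is.na(tau_seed) ||
      tau_seed < 0 || tau_seed > 1) {
    abort("tau_seed must be a single value in [0, 1]")
  }
  seeds <- seed_regions(atlas)
  targets <- cortical_targets(atlas)
  if (length(seeds) == 0 || length(targets) == 0) {
    abort("atlas must define seed regions and cortical targets")
  }
  seed_names <- region_names(atlas, seeds)
  thal <- seeds[startsWith(seed_names, "Thalamus")]
  if (length(thal) == 0) {
    abort("no thalamic seed (name starting 'Thalamus') in the seed set")
  }

  m <- conn$rprime
  si <- region_index(atlas, seeds)
  ti <- region_index(atlas, targets)
  sub <- m[si, ti, drop = FALSE]
  seed_values <- tibble::tibble(
    seed = rep(region_names(atlas, seeds), times = length(targets)),
    seed_id = rep(seeds, times = length(targets)),
    target = rep(region_names(atlas, targets), each = length(seeds)),
    target_id = rep(targets, each = length(seeds)),
    rprime = as.vector(sub)
  )

  thal_sub <- m[region_index(atlas, thal), ti, drop = FALSE]
  thal_sub[is.na(thal_sub)] <- 0
  strength <- apply(thal_sub, 2, max)
  targets_tbl <- tibble::tibble(
    region_id = targets,
    name = region_names(atlas, targets),
    lobe = atlas$lobe[ti],
    strength = unname(strength),
    connected = unname(strength) > tau_seed
  )

  dn <- seeds[startsWith(seed_names, "Dentate")]
  rn <- seeds[startsWith(seed_names, "Red_Nucleus")]
  link <- function(from, to, label) {
    if (length(from) == 0 || length(to) == 0) return(NULL)
    grid <- expand.grid(from = from, to = to)
    grid <- grid[grid$from != grid$to, , drop = FALSE]
    tibble::tibble(
      link = label,
      from = region_names(atlas, grid$from),
      to = region_names(atlas, grid$to),
      rprime = m[cbind(region_index(atlas, grid$from),
                       region_index(atlas, grid$to))]
    )
  }
  chain <- dplyr::bind_rows(
    link(dn, rn, "dentate-red_nucleus"),
    link(rn, thal, "red_nucleus-thalamus"),
    link(dn, thal, "dentate-thalamus")
  )

  structure(
    list(
      targets = targets_tbl,
      seed_values = seed_values,
      chain = chain,
      n_targets = length(targets),
      connected_count = sum(targets_tbl$connected),
      connected_fraction = sum(targets_tbl$connected) / length(targets),
      tau_seed = tau_seed,
      stage_pair = conn$stage_pair
    ),
    class = "metconn_seedpath"
  )
}

#' @export
print.metconn_seedpath <- function(x, ...) {
  cat(
    "<metconn_seedpath> stage pair ", paste(x$stage_pair, collapse = "-"),
    "; tau_seed = ", format(x$tau_seed), "; connected ",
    x$connected_count, "/", x$n_targets, " (",
    sprintf("%.1f%%", 100 * x$connected_fraction), ")\n",
    sep = ""
  )
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.metconn_seedpath <- function(x, ...) x$targets

#' @exportS3Method generics::glance
glance.metconn_seedpath <- function(x, ...) {
  tibble::tibble(
    stage_pair = paste(x$stage_pair, collapse = "-"),
    tau_seed = x$tau_seed,
    n_targets = x$n_targets,
    connected_count = x$connected_count,
    connected_fraction = x$connected_fraction
  )
}

#' Classify per-target connectivity change between two stage pairs
#'
#' Compares thalamo-cortical connection strength between an earlier and a
#' later stage-pair result. Two accountings are produced:
#'
#' * `class` partitions the union of connected targets:
#'   `stronger` / `weaker` for targets connected in both results (by strength
#'   comparison; ties count as `weaker` under the default, i.e. "not further
#'   improving"), `newly_connected` for targets connected only in the later
#'   result, `lost` for targets connected only in the earlier one.
#' * `direction` compares raw strengths for every target connected in the
#'   *later* result regardless of earlier connectivity (the accounting used
#'   when quoting "x% of the connected power were stronger/weaker").
#'
#' @param earlier,later `metconn_seedpath` results on the same atlas and
#'   threshold.
#' @param ties How to classify exactly equal strengths: `"weaker"` (default)
#'   or `"stronger"`.
#' @return Object of class `metconn_pathdelta` with fields `targets` (tibble
#'   `region_id`, `name`, `earlier_strength`, `later_strength`,
#'   `connected_earlier`, `connected_later`, `class`, `direction`), `counts`
#'   (named list), `earlier_pair`, `later_pair`.
#' @export
classify_delta <- function(earlier, later, ties = c("weaker", "stronger")) {
  ties <- match.arg(ties)
  stopifnot(inherits(earlier, "metconn_seedpath"),
            inherits(later, "metconn_seedpath"))
  if (!identical(earlier$targets$region_id, later$targets$region_id)) {
    abort("seed-pathway results have mismatched target sets")
  }
  if (earlier$tau_seed != later$tau_seed) {
    abort("seed-pathway results use different tau_seed")
  }
  e <- earlier$targets
  l <- later$targets
  up <- if (ties == "weaker") l$strength > e$strength else
    l$strength >= e$strength
  cls <- dplyr::case_when(
    e$connected & l$connected & up ~ "stronger",
    e$connected & l$connected ~ "weaker",
    !e$connected & l$connected ~ "newly_connected",
    e$connected & !l$connected ~ "lost",
    TRUE ~ "not_connected"
  )
  direction <- ifelse(l$connected, ifelse(up, "stronger", "weaker"),
                      NA_character_)
  targets <- tibble::tibble(
    region_id = e$region_id,
    name = e$name,
    earlier_strength = e$strength,
    later_strength = l$strength,
    connected_earlier = e$connected,
    connected_later = l$connected,
    class = cls,
    direction = direction
  )
  counts <- list(
    n_targets = nrow(targets),
    n_both = sum(e$connected & l$connected),
    n_stronger = sum(cls == "stronger"),
    n_weaker = sum(cls == "weaker"),
    n_newly_connected = sum(cls == "newly_connected"),
    n_lost = sum(cls == "lost"),
    n_connected_later = sum(l$connected),
    n_later_stronger = sum(direction == "stronger", na.rm = TRUE),
    n_later_weaker = sum(direction == "weaker", na.rm = TRUE)
  )
  structure(
    list(
      targets = targets, counts = counts,
      earlier_pair = earlier$stage_pair, later_pair = later$stage_pair
    ),
    class = "metconn_pathdelta"
  )
}

#' @export
print.metconn_pathdelta <- function(x, ...) {
  c_ <- x$counts
  cat(
    "<metconn_pathdelta> ", paste(x$later_pair, collapse = "-"), " vs ",
    paste(x$earlier_pair, collapse = "-"), ": connected later ",
    c_$n_connected_later, "/", c_$n_targets, "; of these stronger ",
    c_$n_later_stronger, ", weaker ", c_$n_later_weaker,
    " (classes: ", c_$n_stronger, " stronger / ", c_$n_weaker,
    " weaker / ", c_$n_newly_connected, " new / ", c_$n_lost, " lost)\n",
    sep = ""
  )
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.metconn_pathdelta <- function(x, ...) x$targets

#' @exportS3Method generics::glance
glance.metconn_pathdelta <- function(x, ...) {
  c_ <- x$counts
  tibble::tibble(
    earlier_pair = paste(x$earlier_pair, collapse = "-"),
    later_pair = paste(x$later_pair, collapse = "-"),
    n_targets = c_$n_targets,
    n_both = c_$n_both,
    n_stronger = c_$n_stronger,
    n_weaker = c_$n_weaker,
    n_newly_connected = c_$n_newly_connected,
    n_lost = c_$n_lost,
    n_connected_later = c_$n_connected_later,
    n_later_stronger = c_$n_later_stronger,
    n_later_weaker = c_$n_later_weaker,
    frac_later_stronger = c_$n_later_stronger /
      max(c_$n_connected_later, 1),
    frac_later_weaker = c_$n_later_weaker / max(c_$n_connected_later, 1)
  )
}

#' Targets whose thalamic connection strengthens across every transition
#'
#' Intersects the `direction == "stronger"` target sets of an ordered
#' sequence of pathway deltas; the fraction is reported over the full
#' cortical-target list.
#'
#' @param deltas List of `metconn_pathdelta` (chronological order).
#' @return List with `region_id`, `name`, `n`, `n_targets`, `fraction`.
#' @export
continuously_improving <- function(deltas) {
  if (length(deltas) < 1) abort("need at least one pathway delta")
  stopifnot(all(vapply(deltas, inherits, logical(1), "metconn_pathdelta")))
  ids0 <- deltas[[1]]$targets$region_id
  for (d in deltas) {
    if (!identical(d$targets$region_id, ids0)) {
      abort("pathway deltas have mismatched target sets")
    }
  }
  stronger_sets <- lapply(deltas, function(d) {
    d$targets$region_id[!is.na(d$targets$direction) &
                          d$targets$direction == "stronger"]
  })
  ids <- Reduce(intersect, stronger_sets)
  names <- deltas[[1]]$targets$name[match(ids, ids0)]
  list(
    region_id = ids,
    name = names,
    n = length(ids),
    n_targets = length(ids0),
    fraction = length(ids) / length(ids0)
  )
}
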