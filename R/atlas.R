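#' @keywords internal
.metconn_subnetworks <- c("SMN", "FPN", "CON", "OCC", "DMN", "CEREBELLUM")

#' @keywords internal
.metconn_lobes <- c(
  "frontal", "paracentral", "central_core", "parietal", "temporal",
  "occipital", "subcortical", "cerebellum", "vermis", "brainstem", "other"
)

# Cerebral lobes whose members form the default cortical-target set.
#' @keywords internal
.metconn_target_lobes <- c(
  "frontal", "paracentral", "central_core", "parietal", "temporal", "occipital"
)

# AAL-116 base structures in conventional atlas order; each expands to _L/_R
# except the vermis entries, which are midline singletons.
aal116_base_names <- function() {
  list(
    paired = c(
      "Precentral", "Frontal_Sup", "Frontal_Sup_Orb", "Frontal_Mid",
      "Frontal_Mid_Orb", "Frontal_Inf_Oper", "Frontal_Inf_Tri",
      "Frontal_Inf_Orb", "Rolandic_Oper", "Supp_Motor_Area", "Olfactory",
      "Frontal_Sup_Medial", "Frontal_Med_Orb", "Rectus", "Insula",
      "Cingulum_Ant", "Cingulum_Mid", "Cingulum_Post", "Hippocampus",
      "ParaHippocampal", "Amygdala", "Calcarine", "Cuneus", "Lingual",
      "Occipital_Sup", "Occipital_Mid", "Occipital_Inf", "Fusiform",
      "Postcentral", "Parietal_Sup", "Parietal_Inf", "SupraMarginal",
      "Angular", "Precuneus", "Paracentral_Lobule", "Caudate", "Putamen",
      "Pallidum", "Thalamus", "Heschl", "Temporal_Sup", "Temporal_Pole_Sup",
      "Temporal_Mid", "Temporal_Pole_Mid", "Temporal_Inf",
      "Cerebelum_Crus1", "Cerebelum_Crus2", "Cerebelum_3", "Cerebelum_4_5",
      "Cerebelum_6", "Cerebelum_7b", "Cerebelum_8", "Cerebelum_9",
      "Cerebelum_10"
    ),
    midline = c(
      "Vermis_1_2", "Vermis_3", "Vermis_4_5", "Vermis_6", "Vermis_7",
      "Vermis_8", "Vermis_9", "Vermis_10"
    )
  )
}

# base-name -> lobe assignment for the AAL-116 structures
aal_lobe_of <- function(base) {
  lobe_map <- c(
    Precentral = "central_core", Frontal_Sup = "frontal",
    Frontal_Sup_Orb = "frontal", Frontal_Mid = "frontal",
    Frontal_Mid_Orb = "frontal", Frontal_Inf_Oper = "frontal",
    Frontal_Inf_Tri = "frontal", Frontal_Inf_Orb = "frontal",
    Rolandic_Oper = "central_core", Supp_Motor_Area = "paracentral",
    Olfactory = "frontal", Frontal_Sup_Medial = "frontal",
    Frontal_Med_Orb = "frontal", Rectus = "frontal", Insula = "subcortical",
    Cingulum_Ant = "frontal", Cingulum_Mid = "paracentral",
    Cingulum_Post = "paracentral", Hippocampus = "subcortical",
    ParaHippocampal = "subcortical", Amygdala = "subcortical",
    Calcarine = "occipital", Cuneus = "occipital", Lingual = "occipital",
    Occipital_Sup = "occipital", Occipital_Mid = "occipital",
    Occipital_Inf = "occipital", Fusiform = "occipital",
    Postcentral = "central_core", Parietal_Sup = "parietal",
    Parietal_Inf = "parietal", SupraMarginal = "parietal",
    Angular = "parietal", Precuneus = "parietal",
    Paracentral_Lobule = "paracentral", Caudate = "subcortical",
    Putamen = "central_core", Pallidum = "subcortical",
    Thalamus = "subcortical", Heschl = "temporal", Temporal_Sup = "temporal",
    Temporal_Pole_Sup = "temporal", Temporal_Mid = "temporal",
    Temporal_Pole_Mid = "temporal", Temporal_Inf = "temporal"
  )
  out <- unname(lobe_map[base])
  out[startsWith(base, "Cerebelum")] <- "cerebellum"
  out[startsWith(base, "Vermis")] <- "vermis"
  out
}

# base-name -> functional subnetwork (NA = none). Memberships beyond the
# cerebellum (name rule) and occipital network (calcarine, cuneus, occipital,
# lingual, fusiform) are a documented reconstruction from standard AAL
# assignments; the six sets are pairwise disjoint.
aal_subnetwork_of <- function(base) {
  sub_map <- c(
    Precentral = "SMN", Postcentral = "SMN", Supp_Motor_Area = "SMN",
    Paracentral_Lobule = "SMN",
    Frontal_Inf_Oper = "FPN", Frontal_Inf_Tri = "FPN", Parietal_Inf = "FPN",
    Angular = "FPN",
    Cingulum_Mid = "CON", Hippocampus = "CON", Amygdala = "CON",
    Caudate = "CON", Putamen = "CON", Pallidum = "CON",
    Calcarine = "OCC", Cuneus = "OCC", Lingual = "OCC", Occipital_Sup = "OCC",
    Occipital_Mid = "OCC", Occipital_Inf = "OCC", Fusiform = "OCC",
    Frontal_Sup_Medial = "DMN", Frontal_Med_Orb = "DMN", Cingulum_Ant = "DMN",
    Cingulum_Post = "DMN", Precuneus = "DMN", ParaHippocampal = "DMN"
  )
  out <- unname(sub_map[base])
  out[startsWith(base, "Cerebelum") | startsWith(base, "Vermis")] <-
    "CEREBELLUM"
  out
}

#' Default 120-region brain parcellation registry
#'
#' Builds the packaged region registry: the 116 AAL structures in conventional
#' atlas order followed by four added structures (pons, left and right dentate
#' nucleus, red nucleus) carrying label ids >= 9000. The pons is the SUVR
#' reference region; the dentate nuclei, red nucleus and both thalami are the
#' seed set for the dentato-rubro-thalamo-cortical pathway analysis; the 76
#' cerebral regions in the frontal, paracentral, central-core, parietal,
#' temporal and occipital lobes form the default cortical-target set.
#'
#' The `x`, `y`, `z` columns hold a synthetic deterministic layout (left
#' regions at x = -45, right at +45, midline at 0, spread along y/z) so that
#' BrainNet Viewer `.node` export works; they are not anatomical MNI
#' centroids.
#'
#' @return A validated atlas tibble of class `metconn_atlas` with columns
#'   `region_id`, `name`, `hemisphere`, `lobe`, `source`, `subnetwork`,
#'   `is_seed`, `is_cortical_target`, `x`, `y`, `z`.
#' @examples
#' atlas <- default_atlas()
#' nrow(atlas)                       # 120
#' length(cortical_targets(atlas))   # 76
#' @export
default_atlas <- function() {
  base <- aal116_base_names()
  paired <- base$paired
  rows <- list()
  for (i in seq_along(paired)) {
    for (side in c("L", "R")) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        name = paste0(paired[i], "_", side),
        hemisphere = if (side == "L") "left" else "right",
        lobe = aal_lobe_of(paired[i]),
        subnetwork = aal_subnetwork_of(paired[i])
      )
    }
  }
  for (v in base$midline) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      name = v, hemisphere = "midline", lobe = "vermis",
      subnetwork = "CEREBELLUM"
    )
  }
  aal <- dplyr::bind_rows(rows)
  aal$region_id <- seq_len(nrow(aal))
  aal$source <- "aal116"

  added <- tibble::tibble(
    region_id = c(9001L, 9002L, 9003L, 9004L),
    name = c("Pons", "Dentate_L", "Dentate_R", "Red_Nucleus"),
    hemisphere = c("midline", "left", "right", "midline"),
    lobe = c("brainstem", "cerebellum", "cerebellum", "brainstem"),
    subnetwork = NA_character_,
    source = "added"
  )

  reg <- dplyr::bind_rows(aal, added)
  reg$is_seed <- reg$name %in%
    c("Dentate_L", "Dentate_R", "Red_Nucleus", "Thalamus_L", "Thalamus_R")
  reg$is_cortical_target <- reg$lobe %in% .metconn_target_lobes

  # synthetic layout coordinates (not MNI): deterministic, export-only
  n <- nrow(reg)
  reg$x <- unname(c(left = -45, right = 45, midline = 0)[reg$hemisphere])
  reg$y <- round(85 - 170 * (seq_len(n) - 1) / (n - 1))
  reg$z <- round(35 * sin(seq_len(n) / 5))

  reg <- reg[, c(
    "region_id", "name", "hemisphere", "lobe", "source", "subnetwork",
    "is_seed", "is_cortical_target", "x", "y", "z"
  )]
  as_metconn_atlas(reg, reference = "Pons", strict = TRUE)
}

#' Construct and validate an atlas registry
#'
#' Checks registry invariants and attaches the reference region. With
#' `strict = TRUE` (used for the packaged 120-region registry) the canonical
#' counts are enforced: 116 `aal116` + 4 `added` regions, a 26-member
#' CEREBELLUM subnetwork, and 76 cortical targets disjoint from seeds and the
#' reference. With `strict = FALSE` only structural validity is checked, so
#' reduced or custom parcellations can be used throughout the pipeline.
#'
#' @param regions Data frame with columns `region_id`, `name`, `hemisphere`,
#'   `lobe`, `source`, `subnetwork`, `is_seed`, `is_cortical_target` and
#'   optionally `x`, `y`, `z`.
#' @param reference Name (or region id) of the SUVR reference region.
#' @param strict Enforce the canonical default-registry counts?
#' @return A `metconn_atlas` tibble; the reference region id is stored in the
#'   `reference_region` attribute.
#' @export
as_metconn_atlas <- function(regions, reference = "Pons", strict = FALSE) {
  reg <- tibble::as_tibble(regions)
  required <- c(
    "region_id", "name", "hemisphere", "lobe", "source", "subnetwork",
    "is_seed", "is_cortical_target"
  )
  missing_cols <- setdiff(required, names(reg))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "registry is missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  for (col in c("x", "y", "z")) {
    if (!col %in% names(reg)) reg[[col]] <- NA_real_
  }
  reg$region_id <- as.integer(reg$region_id)
  reg$is_seed <- as.logical(reg$is_seed)
  reg$is_cortical_target <- as.logical(reg$is_cortical_target)

  dup <- reg$region_id[duplicated(reg$region_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate region_id: ", paste(unique(dup), collapse = ", ")))
  }
  bad_hemi <- setdiff(unique(reg$hemisphere), c("left", "right", "midline"))
  if (length(bad_hemi) > 0) {
    abort(paste0("unknown hemisphere value: ", paste(bad_hemi, collapse = ", ")))
  }
  bad_lobe <- setdiff(unique(reg$lobe), .metconn_lobes)
  if (length(bad_lobe) > 0) {
    abort(paste0("unknown lobe value: ", paste(bad_lobe, collapse = ", ")))
  }
  bad_src <- setdiff(unique(reg$source), c("aal116", "added"))
  if (length(bad_src) > 0) {
    abort(paste0("unknown source value: ", paste(bad_src, collapse = ", ")))
  }
  bad_sub <- setdiff(
    unique(reg$subnetwork[!is.na(reg$subnetwork)]), .metconn_subnetworks
  )
  if (length(bad_sub) > 0) {
    abort(paste0(
      "unknown subnetwork: ", paste(bad_sub, collapse = ", "),
      " (valid: ", paste(.metconn_subnetworks, collapse = ", "), ")"
    ))
  }

  if (is.character(reference)) {
    ref_row <- which(reg$name == reference)
  } else {
    ref_row <- which(reg$region_id == as.integer(reference))
  }
  if (length(ref_row) != 1) {
    abort(paste0("reference region absent from registry: ", reference))
  }
  ref_id <- reg$region_id[ref_row]

  targets <- reg$region_id[reg$is_cortical_target]
  seeds <- reg$region_id[reg$is_seed]
  if (length(intersect(targets, seeds)) > 0) {
    abort("cortical targets must be disjoint from seed regions")
  }
  if (ref_id %in% targets) {
    abort("cortical targets must not include the reference region")
  }

  if (isTRUE(strict)) {
    if (sum(reg$source == "aal116") != 116) {
      abort("strict registry requires exactly 116 aal116 regions")
    }
    if (sum(reg$source == "added") != 4) {
      abort("strict registry requires exactly 4 added regions")
    }
    need <- c("Pons", "Dentate_L", "Dentate_R", "Red_Nucleus")
    miss <- setdiff(need, reg$name[reg$source == "added"])
    if (length(miss) > 0) {
      abort(paste0(
        "required added structure(s) absent: ", paste(miss, collapse = ", ")
      ))
    }
    n_cer <- sum(!is.na(reg$subnetwork) & reg$subnetwork == "CEREBELLUM")
    if (n_cer != 26) {
      abort(paste0("CEREBELLUM subnetwork must have 26 members, found ", n_cer))
    }
    if (length(targets) != 76) {
      abort(paste0("default registry requires 76 cortical targets, found ",
                   length(targets)))
    }
  }

  class(reg) <- c("metconn_atlas", class(tibble::tibble()))
  attr(reg, "reference_region") <- ref_id
  attr(reg, "strict") <- isTRUE(strict)
  reg
}

#' Read / write an atlas registry TSV
#'
#' The registry file is a TSV with header `region_id name hemisphere lobe
#' source subnetwork is_seed is_cortical_target x y z`; an empty `subnetwork`
#' field means no subnetwork membership. Writing then reading a registry
#' yields an identical atlas.
#'
#' @param path File path.
#' @param reference,strict Passed to [as_metconn_atlas()].
#' @return `read_registry()` returns a `metconn_atlas`; `write_registry()`
#'   returns `path` invisibly.
#' @export
read_registry <- function(path, reference = "Pons", strict = TRUE) {
  if (!file.exists(path)) abort(paste0("registry file not found: ", path))
  reg <- readr::read_tsv(
    path,
    col_types = readr::cols(
      region_id = readr::col_integer(),
      name = readr::col_character(),
      hemisphere = readr::col_character(),
      lobe = readr::col_character(),
      source = readr::col_character(),
      subnetwork = readr::col_character(),
      is_seed = readr::col_logical(),
      is_cortical_target = readr::col_logical(),
      x = readr::col_double(),
      y = readr::col_double(),
      z = readr::col_double()
    ),
    progress = FALSE
  )
  as_metconn_atlas(reg, reference = reference, strict = strict)
}

#' @rdname read_registry
#' @param atlas A `metconn_atlas`.
#' @export
write_registry <- function(atlas, path) {
  stopifnot(inherits(atlas, "metconn_atlas"))
  readr::write_tsv(tibble::as_tibble(atlas), path, progress = FALSE)
  invisible(path)
}

#' Atlas accessors
#'
#' `n_regions()` gives the parcellation size (the row/column dimension of all
#' connectivity matrices); `reference_region()` the SUVR reference region id;
#' `seed_regions()` the pathway seed ids; `cortical_targets()` the ordered
#' cortical-target ids (default length 76); `subnetwork_members()` the member
#' ids of one of the six functional subnetworks, in registry order.
#'
#' @param atlas A `metconn_atlas`.
#' @return Integer vector(s) of region ids (scalar for `n_regions` /
#'   `reference_region`).
#' @export
n_regions <- function(atlas) {
  stopifnot(inherits(atlas, "metconn_atlas"))
  nrow(atlas)
}

#' @rdname n_regions
#' @export
reference_region <- function(atlas) {
  stopifnot(inherits(atlas, "metconn_atlas"))
  attr(atlas, "reference_region")
}

#' @rdname n_regions
#' @export
seed_regions <- function(atlas) {
  stopifnot(inherits(atlas, "metconn_atlas"))
  atlas$region_id[atlas$is_seed]
}

#' @rdname n_regions
#' @export
cortical_targets <- function(atlas) {
  stopifnot(inherits(atlas, "metconn_atlas"))
  atlas$region_id[atlas$is_cortical_target]
}

#' @rdname n_regions
#' @param name Subnetwork name, one of `"SMN"`, `"FPN"`, `"CON"`, `"OCC"`,
#'   `"DMN"`, `"CEREBELLUM"`.
#' @export
subnetwork_members <- function(atlas, name) {
  stopifnot(inherits(atlas, "metconn_atlas"))
  if (length(name) != 1 || !name %in% .metconn_subnetworks) {
    abort(paste0(
      "unknown subnetwork '", paste(name, collapse = ","),
      "'; valid names: ", paste(.metconn_subnetworks, collapse = ", ")
    ))
  }
  atlas$region_id[!is.na(atlas$subnetwork) & atlas$subnetwork == name]
}

#' @rdname n_regions
#' @export
subnetwork_names <- function(atlas) {
  .metconn_subnetworks
}

# region_id -> row index lookup (errors on unknown ids)
region_index <- function(atlas, ids) {
  idx <- match(ids, atlas$region_id)
  if (anyNA(idx)) {
    abort(paste0(
      "region id(s) not in registry: ",
      paste(ids[is.na(idx)], collapse = ", ")
    ))
  }
  idx
}

# region_id -> name lookup
region_names <- function(atlas, ids) {
  atlas$name[region_index(atlas, ids)]
}

#' @export
print.metconn_atlas <- function(x, ...) {
  cat(
    "<metconn_atlas> ", nrow(x), " regions (",
    sum(x$source == "aal116"), " aal116 + ", sum(x$source == "added"),
    " added); reference: ",
    region_names(x, attr(x, "reference_region")),
    "; ", length(cortical_targets(x)), " cortical targets, ",
    length(seed_regions(x)), " seeds\n",
    sep = ""
  )
  NextMethod()
}
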