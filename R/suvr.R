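#' Convert an activity volume to standardized uptake values
#'
#' SUV = tissue activity / (injected dose / body weight). Units must be
#' consistent (e.g. activity in kBq/mL with dose in kBq per gram of body
#' weight, or any jointly consistent convention): the function is a pure
#' scaling and performs no unit conversion. Downstream SUVR is a ratio, so
#' any common scale factor cancels.
#'
#' @param activity Numeric array (any shape) of tissue activity.
#' @param injected_dose Injected dose, > 0.
#' @param body_weight Body weight, > 0.
#' @return Array of SUV values, same shape as `activity`.
#' @examples
#' compute_suv(5.0, injected_dose = 185, body_weight = 37) # 1.0
#' @export
compute_suv <- function(activity, injected_dose, body_weight) {
  if (!is.numeric(injected_dose) || length(injected_dose) != 1 ||
      injected_dose <= 0) {
    abort("injected_dose must be a single positive number")
  }
  if (!is.numeric(body_weight) || length(body_weight) != 1 ||
      body_weight <= 0) {
    abort("body_weight must be a single positive number")
  }
  activity / (injected_dose / body_weight)
}

#' Parcellate a SUV volume over an integer label volume
#'
#' Computes per-region mean, SD and voxel count of `suv` over voxels whose
#' label equals each atlas `region_id`. Voxels with label 0 (background) are
#' excluded. Every atlas region must be represented by at least one voxel.
#'
#' @param suv Numeric array of SUV values.
#' @param labels Integer array of the same shape; values are atlas region ids,
#'   0 = background.
#' @param atlas A `metconn_atlas`.
#' @param sd SD convention: `"sample"` (ddof = 1, default) or `"population"`.
#'   Single-voxel regions get SD 0 under either convention.
#' @return Tibble with columns `region_id`, `name`, `mean_suv`, `sd_suv`,
#'   `n_voxels`, in registry order.
#' @export
parcellate <- function(suv, labels, atlas, sd = c("sample", "population")) {
  sd <- match.arg(sd)
  stopifnot(inherits(atlas, "metconn_atlas"))
  if (length(suv) != length(labels)) {
    abort("suv and label volumes must have the same dimensions")
  }
  lab <- as.integer(labels)
  vals <- as.numeric(suv)
  keep <- lab != 0L
  lab <- lab[keep]
  vals <- vals[keep]

  rows <- lapply(seq_len(nrow(atlas)), function(i) {
    id <- atlas$region_id[i]
    v <- vals[lab == id]
    n <- length(v)
    if (n == 0) {
      abort(paste0("region has no voxels in label volume: ", atlas$name[i]))
    }
    m <- mean(v)
    s <- if (n == 1) 0 else stats::sd(v)
    if (sd == "population") s <- s * sqrt((n - 1) / n)
    tibble::tibble(
      region_id = id, name = atlas$name[i],
      mean_suv = m, sd_suv = s, n_voxels = n
    )
  })
  dplyr::bind_rows(rows)
}

#' Convert per-region SUV statistics to a stage SUVR table
#'
#' Divides regional mean and SD SUV by the mean SUV of the atlas reference
#' region (the pons in the default registry), yielding the dimensionless SUVR
#' statistics the network analysis consumes. The reference region's SUVR is 1
#' by construction.
#'
#' @param parcels Tibble from [parcellate()] (columns `region_id`, `mean_suv`,
#'   `sd_suv`, `n_voxels`).
#' @param atlas A `metconn_atlas`.
#' @param stage_id Integer stage label (>= 1).
#' @return A stage SUVR table: tibble with columns `stage_id`, `region_id`,
#'   `mean_suvr`, `sd_suvr`, `n_voxels`, in registry order.
#' @export
to_suvr <- function(parcels, atlas, stage_id = 1L) {
  stopifnot(inherits(atlas, "metconn_atlas"))
  ref_id <- reference_region(atlas)
  ref <- parcels$mean_suv[parcels$region_id == ref_id]
  if (length(ref) != 1 || is.na(ref) || ref <= 0) {
    abort("reference region mean SUV must be present and > 0")
  }
  out <- tibble::tibble(
    stage_id = as.integer(stage_id),
    region_id = parcels$region_id,
    mean_suvr = parcels$mean_suv / ref,
    sd_suvr = parcels$sd_suv / ref,
    n_voxels = as.integer(parcels$n_voxels)
  )
  validate_suvr_table(out, atlas)
}

#' Validate a stage SUVR table against a registry
#'
#' Checks that every atlas region is present exactly once, SDs are
#' non-negative and voxel counts positive, and returns the table sorted into
#' registry order.
#'
#' @param tbl Data frame with columns `stage_id`, `region_id`, `mean_suvr`,
#'   `sd_suvr`, `n_voxels`.
#' @param atlas A `metconn_atlas`.
#' @return The validated tibble in registry order.
#' @export
validate_suvr_table <- function(tbl, atlas) {
  stopifnot(inherits(atlas, "metconn_atlas"))
  tbl <- tibble::as_tibble(tbl)
  required <- c("stage_id", "region_id", "mean_suvr", "sd_suvr", "n_voxels")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "SUVR table missing column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  if (length(unique(tbl$stage_id)) != 1) {
    abort("a stage SUVR table must contain exactly one stage_id")
  }
  missing_regions <- setdiff(atlas$region_id, tbl$region_id)
  if (length(missing_regions) > 0) {
    abort(paste0(
      "SUVR table missing region(s): ",
      paste(region_names(atlas, missing_regions), collapse = ", ")
    ))
  }
  extra <- setdiff(tbl$region_id, atlas$region_id)
  if (length(extra) > 0) {
    abort(paste0(
      "SUVR table contains unknown region id(s): ",
      paste(extra, collapse = ", ")
    ))
  }
  if (anyDuplicated(tbl$region_id)) {
    abort("SUVR table contains duplicated region ids")
  }
  if (any(tbl$sd_suvr < 0)) abort("sd_suvr must be non-negative")
  if (any(tbl$n_voxels < 1)) abort("n_voxels must be >= 1")
  tbl[match(atlas$region_id, tbl$region_id), , drop = FALSE]
}

#' Read / write stage SUVR tables
#'
#' Plain-text I/O for per-stage regional SUVR statistics with header
#' `stage_id region_id mean_suvr sd_suvr n_voxels`. Tab- or comma-separated
#' is chosen from the file extension (`.csv` vs anything else). A file may
#' hold several stages; the result is a single long tibble validated per
#' stage and ordered by stage then registry order.
#'
#' @param path File path.
#' @param atlas A `metconn_atlas`.
#' @return `read_suvr_table()` returns a long tibble over all stages in the
#'   file; `write_suvr_table()` returns `path` invisibly.
#' @export
read_suvr_table <- function(path, atlas) {
  if (!file.exists(path)) abort(paste0("SUVR table not found: ", path))
  reader <- if (grepl("\\.csv$", path)) readr::read_csv else readr::read_tsv
  tbl <- reader(
    path,
    col_types = readr::cols(
      stage_id = readr::col_integer(),
      region_id = readr::col_integer(),
      mean_suvr = readr::col_double(),
      sd_suvr = readr::col_double(),
      n_voxels = readr::col_integer()
    ),
    progress = FALSE
  )
  parts <- lapply(
    split(tbl, tbl$stage_id),
    function(one) validate_suvr_table(one, atlas)
  )
  dplyr::bind_rows(parts[order(as.integer(names(parts)))])
}

#' @rdname read_suvr_table
#' @param tbl A (possibly multi-stage) SUVR table.
#' @export
write_suvr_table <- function(tbl, path) {
  writer <- if (grepl("\\.csv$", path)) readr::write_csv else readr::write_tsv
  writer(tibble::as_tibble(tbl), path, progress = FALSE)
  invisible(path)
}

#' Image-to-SUVR convenience chain
#'
#' Runs [compute_suv()], [parcellate()] and [to_suvr()] in sequence for one
#' acquisition stage.
#'
#' @inheritParams compute_suv
#' @inheritParams parcellate
#' @inheritParams to_suvr
#' @return A stage SUVR table.
#' @export
suvr_from_image <- function(activity, labels, atlas, injected_dose,
                            body_weight, stage_id = 1L,
                            sd = c("sample", "population")) {
  suv <- compute_suv(activity, injected_dose, body_weight)
  parcels <- parcellate(suv, labels, atlas, sd = match.arg(sd))
  to_suvr(parcels, atlas, stage_id = stage_id)
}

#' Read a NIfTI volume as a plain array
#'
#' Thin wrapper over `RNifti::readNifti()` returning a bare numeric array, so
#' activity and label volumes stored as `.nii`/`.nii.gz` can feed
#' [parcellate()].
#'
#' @param path Path to a NIfTI file.
#' @return Numeric array.
#' @export
read_nifti_volume <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    abort("reading NIfTI volumes requires the RNifti package")
  }
  img <- RNifti::readNifti(path)
  array(as.numeric(img), dim = dim(img))
}

#' @rdname read_nifti_volume
#' @param volume Numeric array to write.
#' @export
write_nifti_volume <- function(volume, path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    abort("writing NIfTI volumes requires the RNifti package")
  }
  RNifti::writeNifti(RNifti::asNifti(volume), path)
  invisible(path)
}
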