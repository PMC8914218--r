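#' Dense matrix I/O for connectivity matrices
#'
#' `write_conn_csv()` writes the R' matrix as dense CSV with a region-id
#' header row and a leading region-id column; `read_conn_csv()` reads it back
#' and re-attaches a registry. The round trip is lossless up to numeric
#' printing precision (values are written with full precision).
#'
#' @param conn A `metconn_conn`.
#' @param path File path.
#' @return `read_conn_csv()` returns a `metconn_conn`; writers return `path`
#'   invisibly.
#' @export
write_conn_csv <- function(conn, path) {
  stopifnot(inherits(conn, "metconn_conn"))
  m <- conn$rprime
  df <- data.frame(region_id = conn$atlas$region_id, m,
                   check.names = FALSE)
  colnames(df) <- c("region_id", as.character(conn$atlas$region_id))
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_conn_csv
#' @param atlas A `metconn_atlas` matching the stored matrix.
#' @param stage_pair Length-2 integer vector for the restored object.
#' @export
read_conn_csv <- function(path, atlas, stage_pair = c(2L, 1L)) {
  if (!file.exists(path)) abort(paste0("matrix file not found: ", path))
  df <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  ids <- as.integer(df$region_id)
  if (!identical(ids, atlas$region_id)) {
    abort("matrix row ids do not match the registry")
  }
  m <- as.matrix(df[, -1])
  storage.mode(m) <- "double"
  as_connectivity(m, atlas, stage_pair = stage_pair)
}

#' Write a suprathreshold edge list
#'
#' TSV with columns `region_i region_j rprime`, one row per unordered pair
#' with R' strictly above `tau`.
#'
#' @inheritParams write_conn_csv
#' @param tau Threshold; 0 writes every unmasked positive-R' pair.
#' @export
write_edge_list <- function(conn, path, tau = 0) {
  bin <- binarize(conn, tau)
  readr::write_tsv(
    bin$edges[, c("region_i", "region_j", "rprime")], path, progress = FALSE
  )
  invisible(path)
}

# lobe -> BrainNet node colour code (red frontal, green temporal, deep blue
# parietal, yellow occipital, pink subcortical grey, light blue other)
brainnet_color_code <- function(lobe) {
  code <- c(
    frontal = 1, temporal = 2, parietal = 3, paracentral = 3,
    central_core = 3, occipital = 4, subcortical = 5
  )[lobe]
  code[is.na(code)] <- 6
  unname(code)
}

#' Export a network in BrainNet Viewer .node / .edge format
#'
#' The `.node` file has one whitespace-delimited row per region: `x y z
#' color size label`; colour encodes the lobe group and size the node degree
#' at threshold `tau` (or 1 everywhere when `tau` is `NULL`). The `.edge`
#' file is the N x N connectivity matrix, whitespace-delimited, with masked
#' pairs as 0 and (when `tau` is given) subthreshold entries zeroed.
#'
#' @inheritParams write_conn_csv
#' @param node_path,edge_path Output paths.
#' @param tau Optional display threshold.
#' @export
write_brainnet <- function(conn, node_path, edge_path, tau = NULL) {
  stopifnot(inherits(conn, "metconn_conn"))
  atlas <- conn$atlas
  m <- conn$rprime
  m[is.na(m)] <- 0
  if (!is.null(tau)) m[m <= tau] <- 0
  degree <- rowSums(m > 0)
  size <- if (is.null(tau)) rep(1, nrow(atlas)) else pmax(degree, 1)
  xyz <- cbind(atlas$x, atlas$y, atlas$z)
  xyz[is.na(xyz)] <- 0
  node <- data.frame(
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    color = brainnet_color_code(atlas$lobe),
    size = size,
    label = atlas$name
  )
  utils::write.table(node, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(format(m, trim = TRUE, digits = 10), edge_path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(node = node_path, edge = edge_path))
}
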