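#' Per-subnetwork regional SUVR observations across stages
#'
#' Collects, for every (subnetwork, stage), the mean SUVR of each member
#' region. The regional means are the observational units of the stage
#' comparison (a simplification the single-subject design imposes: regions
#' within a subnetwork are treated as independent observations).
#'
#' @param tables Long SUVR table over all stages (or list of single-stage
#'   tables).
#' @param atlas A `metconn_atlas`.
#' @return Long tibble with columns `subnetwork`, `stage_id`, `region_id`,
#'   `name`, `mean_suvr`.
#' @export
subnetwork_observations <- function(tables, atlas) {
  stopifnot(inherits(atlas, "metconn_atlas"))
  if (!is.data.frame(tables)) tables <- dplyr::bind_rows(tables)
  parts <- lapply(subnetwork_names(atlas), function(sn) {
    ids <- subnetwork_members(atlas, sn)
    if (length(ids) == 0) abort(paste0("subnetwork has no members: ", sn))
    obs <- tables[tables$region_id %in% ids, ]
    tibble::tibble(
      subnetwork = sn,
      stage_id = obs$stage_id,
      region_id = obs$region_id,
      name = region_names(atlas, obs$region_id),
      mean_suvr = obs$mean_suvr
    )
  })
  dplyr::bind_rows(parts)
}

#' Summary statistics per (subnetwork, stage)
#'
#' @inheritParams subnetwork_observations
#' @return Tibble with one row per (subnetwork, stage): `subnetwork`,
#'   `stage_id`, `n`, `mean`, `sd`, and `observations` (list-column of member
#'   regional mean SUVR values).
#' @export
subnetwork_stats <- function(tables, atlas) {
  obs <- subnetwork_observations(tables, atlas)
  out <- obs |>
    dplyr::group_by(.data$subnetwork, .data$stage_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$mean_suvr),
      sd = stats::sd(.data$mean_suvr),
      observations = list(.data$mean_suvr),
      .groups = "drop"
    )
  out$subnetwork <- factor(out$subnetwork, levels = subnetwork_names(atlas))
  dplyr::arrange(out, .data$subnetwork, .data$stage_id)
}

# "**" below 0.01, "*" below 0.05, else "ns"
significance_stars <- function(p) {
  dplyr::case_when(p < 0.01 ~ "**", p < 0.05 ~ "*", TRUE ~ "ns")
}

#' Compare stages within one subnetwork (one-way ANOVA + Tukey HSD)
#'
#' Omnibus one-way ANOVA of member-region mean SUVR across stages, followed
#' by all pairwise Tukey honest-significant-difference contrasts with
#' family-wise adjusted p-values. Stars mark `p_adj < 0.05` (`*`) and
#' `p_adj < 0.01` (`**`).
#'
#' If every group is constant and all group means coincide there is no
#' variation at all; by convention the result is F = 0, p = 1, with all
#' contrasts non-significant.
#'
#' @param observations Long tibble from [subnetwork_observations()], or any
#'   data frame with columns `stage_id` and `mean_suvr` (plus optionally
#'   `subnetwork`).
#' @param subnetwork If `observations` spans several subnetworks, which one
#'   to compare.
#' @return Object of class `metconn_anova` with fields `subnetwork`,
#'   `statistic` (F), `p_value`, `df`, and `pairwise` (tibble `stage_a`,
#'   `stage_b`, `mean_diff`, `lwr`, `upr`, `p_adj`, `stars`).
#' @export
compare_stages <- function(observations, subnetwork = NULL) {
  obs <- tibble::as_tibble(observations)
  if (!is.null(subnetwork)) {
    obs <- obs[obs$subnetwork == subnetwork, ]
  } else if ("subnetwork" %in% names(obs)) {
    if (length(unique(obs$subnetwork)) > 1) {
      abort("observations span several subnetworks; pass `subnetwork`")
    }
    subnetwork <- unique(obs$subnetwork)
  }
  stages <- sort(unique(obs$stage_id))
  if (length(stages) < 2) abort("need >= 2 stages to compare")
  counts <- table(obs$stage_id)
  if (any(counts < 2)) abort("need >= 2 observations per stage")

  grp <- factor(obs$stage_id, levels = stages)
  y <- obs$mean_suvr

  group_means <- tapply(y, grp, mean)
  resid_var <- sum(tapply(y, grp, function(v) sum((v - mean(v))^2))) /
    (length(y) - length(stages))
  pairs_idx <- utils::combn(length(stages), 2)

  if (resid_var < 1e-24 && max(group_means) - min(group_means) < 1e-12) {
    pairwise <- tibble::tibble(
      stage_a = stages[pairs_idx[2, ]],
      stage_b = stages[pairs_idx[1, ]],
      mean_diff = 0, lwr = 0, upr = 0, p_adj = 1, stars = "ns"
    )
    res <- list(subnetwork = subnetwork, statistic = 0, p_value = 1,
                df = c(length(stages) - 1L, length(y) - length(stages)),
                pairwise = pairwise)
    class(res) <- "metconn_anova"
    return(res)
  }

  fit <- stats::aov(y ~ grp)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$grp
  cmp_names <- rownames(tk)
  ab <- strsplit(cmp_names, "-", fixed = TRUE)
  pairwise <- tibble::tibble(
    stage_a = as.integer(vapply(ab, `[`, character(1), 1)),
    stage_b = as.integer(vapply(ab, `[`, character(1), 2)),
    mean_diff = unname(tk[, "diff"]),
    lwr = unname(tk[, "lwr"]),
    upr = unname(tk[, "upr"]),
    p_adj = unname(tk[, "p adj"])
  )
  pairwise$stars <- significance_stars(pairwise$p_adj)
  res <- list(
    subnetwork = subnetwork,
    statistic = an[["F value"]][1],
    p_value = an[["Pr(>F)"]][1],
    df = c(an[["Df"]][1], an[["Df"]][2]),
    pairwise = pairwise
  )
  class(res) <- "metconn_anova"
  res
}

#' @export
print.metconn_anova <- function(x, ...) {
  cat(
    "<metconn_anova> ", if (!is.null(x$subnetwork)) paste0(x$subnetwork, ": "),
    "F(", x$df[1], ", ", x$df[2], ") = ", signif(x$statistic, 4),
    ", p = ", signif(x$p_value, 3), "\n",
    sep = ""
  )
  print(x$pairwise)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.metconn_anova <- function(x, ...) x$pairwise

#' @exportS3Method generics::glance
glance.metconn_anova <- function(x, ...) {
  tibble::tibble(
    subnetwork = x$subnetwork %||% NA_character_,
    statistic = x$statistic,
    p_value = x$p_value,
    df = x$df[1],
    df_residual = x$df[2]
  )
}

#' Stage comparisons for every subnetwork
#'
#' @inheritParams subnetwork_observations
#' @return Tibble with one row per subnetwork: the [glance()] columns plus a
#'   `pairwise` list-column of Tukey contrast tables.
#' @export
compare_subnetworks <- function(tables, atlas) {
  obs <- subnetwork_observations(tables, atlas)
  rows <- lapply(subnetwork_names(atlas), function(sn) {
    cmp <- compare_stages(obs, subnetwork = sn)
    out <- glance(cmp)
    out$pairwise <- list(tidy(cmp))
    out
  })
  dplyr::bind_rows(rows)
}

#' Bar plot of subnetwork SUVR dynamics across stages
#'
#' @param stats Tibble from [subnetwork_stats()].
#' @param ... Unused.
#' @return A ggplot: mean regional SUVR per stage, one facet per subnetwork,
#'   error bars at +/- 1 SD.
#' @export
plot_subnetwork_dynamics <- function(stats, ...) {
  ggplot2::ggplot(
    stats,
    ggplot2::aes(x = factor(.data$stage_id), y = .data$mean)
  ) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      width = 0.25
    ) +
    ggplot2::facet_wrap(~subnetwork) +
    ggplot2::labs(x = "stage", y = "mean regional SUVR") +
    ggplot2::theme_minimal()
}
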