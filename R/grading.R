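#' Severity-grading anchors for postoperative cerebellar mutism syndrome
#'
#' The categorical 1-4 grading of symptom severity in the three pCMS
#' symptom domains. Motoric: atonia (1), limb hypotonia (2), trunk hypotonia
#' (3), able to stand and walk (4). Linguistic: mutism (1), speak words (2),
#' sentence (3), fluent speech (4). Neurobehavioral: minimal response (1),
#' emotional liability (2), liability but controllable (3), irritable mood
#' (4).
#'
#' @return Tibble with columns `domain`, `score`, `anchor`.
#' @export
cms_grading_anchors <- function() {
  tibble::tibble(
    domain = rep(c("motoric", "linguistic", "neurobehavioral"), each = 4),
    score = rep(1:4, times = 3),
    anchor = c(
      "atonia", "limb hypotonia", "trunk hypotonia", "able to stand and walk",
      "mutism", "speak words", "sentence", "fluent speech",
      "minimal response", "emotional liability", "liability but controllable",
      "irritable mood"
    )
  )
}

#' Map a symptom description to its severity score
#'
#' Exact anchor lookup (case-insensitive, surrounding whitespace ignored);
#' the grading is categorical, not free-text interpretation, so unknown
#' descriptions are an error listing the valid anchors for the domain.
#'
#' @param domain One of `"motoric"`, `"linguistic"`, `"neurobehavioral"`.
#' @param description Anchor text, e.g. `"mutism"`.
#' @return Integer score 1-4.
#' @examples
#' cms_score("linguistic", "mutism")              # 1
#' cms_score("motoric", "able to stand and walk") # 4
#' @export
cms_score <- function(domain, description) {
  anchors <- cms_grading_anchors()
  if (!domain %in% unique(anchors$domain)) {
    abort(paste0(
      "unknown domain '", domain, "'; valid: ",
      paste(unique(anchors$domain), collapse = ", ")
    ))
  }
  rows <- anchors[anchors$domain == domain, ]
  hit <- which(tolower(trimws(description)) == tolower(rows$anchor))
  if (length(hit) != 1) {
    abort(paste0(
      "unknown ", domain, " anchor '", description, "'; valid anchors: ",
      paste(rows$anchor, collapse = "; ")
    ))
  }
  rows$score[hit]
}

#' Validate a symptom-score timeline
#'
#' A timeline is a tibble with columns `pod` (postoperative day, >= 0),
#' `domain`, `score` (integer 1-4) and optional `note`; at most one score per
#' (day, domain).
#'
#' @param timeline Data frame.
#' @return Validated tibble sorted by day within domain.
#' @export
validate_timeline <- function(timeline) {
  tl <- tibble::as_tibble(timeline)
  required <- c("pod", "domain", "score")
  missing_cols <- setdiff(required, names(tl))
  if (length(missing_cols) > 0) {
    abort(paste0("timeline missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"note" %in% names(tl)) tl$note <- NA_character_
  if (any(tl$pod < 0)) abort("postoperative days must be non-negative")
  if (!all(tl$score %in% 1:4)) abort("scores must be integers in 1..4")
  bad_dom <- setdiff(unique(tl$domain),
                     c("motoric", "linguistic", "neurobehavioral"))
  if (length(bad_dom) > 0) {
    abort(paste0("unknown domain(s): ", paste(bad_dom, collapse = ", ")))
  }
  if (anyDuplicated(tl[, c("pod", "domain")])) {
    abort("at most one score per (day, domain)")
  }
  tl$pod <- as.integer(tl$pod)
  tl$score <- as.integer(tl$score)
  dplyr::arrange(tl, .data$domain, .data$pod)
}

#' Read / write a symptom timeline TSV
#'
#' Header `pod domain score note`; the round trip is lossless.
#'
#' @param path File path.
#' @return `read_timeline()` returns a validated timeline tibble;
#'   `write_timeline()` returns `path` invisibly.
#' @export
read_timeline <- function(path) {
  if (!file.exists(path)) abort(paste0("timeline file not found: ", path))
  tl <- readr::read_tsv(
    path,
    col_types = readr::cols(
      pod = readr::col_integer(),
      domain = readr::col_character(),
      score = readr::col_integer(),
      note = readr::col_character()
    ),
    progress = FALSE
  )
  validate_timeline(tl)
}

#' @rdname read_timeline
#' @param timeline Timeline tibble.
#' @export
write_timeline <- function(timeline, path) {
  readr::write_tsv(validate_timeline(timeline), path, progress = FALSE)
  invisible(path)
}

#' Per-domain score on a given postoperative day
#'
#' Stepwise carry-forward lookup: the latest score on or before `day` in each
#' domain; `NA` ("unscored") when the day precedes a domain's first entry.
#'
#' @param timeline Validated timeline tibble.
#' @param day Postoperative day.
#' @return Tibble with columns `domain`, `score`.
#' @export
timeline_at <- function(timeline, day) {
  tl <- validate_timeline(timeline)
  domains <- c("motoric", "linguistic", "neurobehavioral")
  score <- vapply(domains, function(d) {
    sub <- tl[tl$domain == d & tl$pod <= day, ]
    if (nrow(sub) == 0) NA_integer_ else sub$score[which.max(sub$pod)]
  }, integer(1))
  tibble::tibble(domain = domains, score = unname(score))
}

#' Default PET stage days
#'
#' Postoperative day of each of the four PET acquisitions: stage 1 on day 7,
#' stage 2 on day 21, stage 3 on day 36, stage 4 on day 93.
#'
#' @return Named integer vector (names are stage ids).
#' @export
default_stage_days <- function() {
  c(`1` = 7L, `2` = 21L, `3` = 36L, `4` = 93L)
}

#' Align the symptom timeline with the PET stages
#'
#' One row per PET stage with the carried-forward score of each symptom
#' domain on the acquisition day.
#'
#' @param timeline Validated timeline tibble.
#' @param stage_days Named vector mapping stage id to postoperative day
#'   (default [default_stage_days()]).
#' @return Tibble with columns `stage`, `day`, `motoric`, `linguistic`,
#'   `neurobehavioral`.
#' @export
align_stages <- function(timeline, stage_days = default_stage_days()) {
  rows <- lapply(seq_along(stage_days), function(i) {
    at <- timeline_at(timeline, stage_days[i])
    tibble::tibble(
      stage = as.integer(names(stage_days)[i]),
      day = as.integer(stage_days[i]),
      motoric = at$score[at$domain == "motoric"],
      linguistic = at$score[at$domain == "linguistic"],
      neurobehavioral = at$score[at$domain == "neurobehavioral"]
    )
  })
  dplyr::bind_rows(rows)
}

#' Demonstration symptom timeline
#'
#' A reconstructed demonstration timeline following the typical course of a
#' severe pCMS episode with near-complete recovery over three months: onset
#' of mutism, atonia and minimal responsiveness within days of surgery,
#' stepwise motoric and neurobehavioral recovery through the first month,
#' and late linguistic recovery. It ships for examples and the pipeline demo;
#' it is not patient data.
#'
#' @return A validated timeline tibble.
#' @export
demo_timeline <- function() {
  validate_timeline(tibble::tibble(
    pod = c(2L, 12L, 26L, 36L,
            2L, 28L, 60L,
            2L, 13L, 26L, 90L),
    domain = c(rep("motoric", 4), rep("linguistic", 3),
               rep("neurobehavioral", 4)),
    score = c(1L, 2L, 3L, 4L,
              1L, 2L, 3L,
              1L, 2L, 3L, 4L),
    note = c(
      "general atonia", "limb movements return", "truncal stability",
      "walks short distance",
      "mutism", "speaks single words", "speaks sentences",
      "minimal response", "emotional lability", "consolable lability",
      "irritable but interactive"
    )
  ))
}

#' Step plot of the symptom timeline
#'
#' @param timeline Validated timeline tibble.
#' @param stage_days Optional stage-day markers drawn as vertical lines.
#' @return A ggplot of carried-forward scores per domain over postoperative
#'   days.
#' @export
plot_timeline <- function(timeline, stage_days = default_stage_days()) {
  tl <- validate_timeline(timeline)
  p <- ggplot2::ggplot(
    tl, ggplot2::aes(x = .data$pod, y = .data$score, colour = .data$domain)
  ) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(breaks = 1:4, limits = c(1, 4)) +
    ggplot2::labs(x = "postoperative day", y = "severity score") +
    ggplot2::theme_minimal()
  if (!is.null(stage_days)) {
    p <- p + ggplot2::geom_vline(xintercept = as.numeric(stage_days),
                                 linetype = "dashed", colour = "grey50")
  }
  p
}
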