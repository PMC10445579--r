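#' Cranial trait names used by the scoring pipeline
#'
#' The three morphoscopic traits that are consistently observable on
#' sinus-CT derived cranial models and accepted throughout this package:
#' the mastoid process, the supra-orbital margin and the glabella. Each is
#' scored on the standard ordinal 1-5 robusticity scale (1 gracile,
#' typically female; 5 robust, typically male).
#'
#' @return A character vector of the three trait identifiers.
#' @export
#' @examples
#' trait_names()
trait_names <- function() {
  c("mastoid_process", "supraorbital_margin", "glabella")
}

sex_levels <- function() c("male", "female")
estimate_levels <- function() c("male", "female", "indeterminate", "missing")

#' Validate a long-format score table
#'
#' Checks that a data frame of ordinal trait scores has the canonical long
#' layout used across the package: columns `observer`, `cranium`, `trait`
#' and `score`, traits drawn from [trait_names()], scores in 1-5 or `NA`
#' (an explicitly missing cell), and at most one row per
#' (observer, cranium, trait) triple.
#'
#' @param scores A data frame with columns `observer`, `cranium`, `trait`,
#'   `score`.
#' @return The validated table as a tibble (invisibly usable in pipes).
#' @export
validate_scores <- function(scores) {
  if (!is.data.frame(scores)) {
    abort("`scores` must be a data frame.")
  }
  needed <- c("observer", "cranium", "trait", "score")
  missing_cols <- setdiff(needed, names(scores))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "`scores` is missing required column(s): ",
      paste(missing_cols, collapse = ", "), "."
    ))
  }
  scores <- as_tibble(scores)[needed]
  bad_trait <- setdiff(unique(scores$trait), trait_names())
  if (length(bad_trait) > 0) {
    abort(paste0(
      "Unknown trait(s): ", paste(bad_trait, collapse = ", "),
      ". Traits must be one of: ", paste(trait_names(), collapse = ", "), "."
    ))
  }
  s <- scores$score
  bad <- !is.na(s) & (!is.numeric(s) | s %% 1 != 0 | s < 1 | s > 5)
  if (any(bad)) {
    abort(paste0(
      "Scores must be integers in 1-5 or NA; found invalid value(s): ",
      paste(unique(s[bad]), collapse = ", "), "."
    ))
  }
  scores$score <- as.integer(scores$score)
  dup <- duplicated(scores[c("observer", "cranium", "trait")])
  if (any(dup)) {
    first <- scores[which(dup)[1], ]
    abort(paste0(
      "Duplicate (observer, cranium, trait) triple: (",
      first$observer, ", ", first$cranium, ", ", first$trait, ")."
    ))
  }
  scores
}

#' Tabulate score frequencies per observer and trait
#'
#' Counts how often each ordinal score 1-5 was assigned, per observer and
#' trait (the tabular equivalent of per-observer score-frequency bar
#' charts). Missing cells are not counted, so for each observer/trait the
#' five counts sum to the number of non-missing cells.
#'
#' @param scores A long score table (see [validate_scores()]).
#' @param observer,trait Optional filters. Requesting an observer or trait
#'   absent from the table is an error (likely a typo), except that a
#'   known trait with no rows yields zero counts.
#' @return A tibble with columns `observer`, `trait`, `score` (1-5) and
#'   `n`, complete over all combinations present after filtering.
#' @export
#' @examples
#' freq <- score_frequencies(study_scores("observers"), observer = "O1")
#' freq[freq$trait == "mastoid_process", ]
score_frequencies <- function(scores, observer = NULL, trait = NULL) {
  scores <- validate_scores(scores)
  if (!is.null(observer)) {
    unknown <- setdiff(observer, unique(scores$observer))
    if (length(unknown) > 0) {
      abort(paste0("Unknown observer(s): ", paste(unknown, collapse = ", "), "."))
    }
    scores <- dplyr::filter(scores, .data$observer %in% !!observer)
  }
  all_observers <- unique(scores$observer)
  if (!is.null(trait)) {
    unknown <- setdiff(trait, trait_names())
    if (length(unknown) > 0) {
      abort(paste0("Unknown trait(s): ", paste(unknown, collapse = ", "), "."))
    }
    scores <- dplyr::filter(scores, .data$trait %in% !!trait)
  }
  keep_traits <- if (is.null(trait)) trait_names() else trait
  scores |>
    dplyr::filter(!is.na(.data$score)) |>
    dplyr::count(.data$observer, .data$trait, .data$score) |>
    tidyr::complete(
      observer = all_observers,
      trait = keep_traits,
      score = 1:5,
      fill = list(n = 0L)
    ) |>
    dplyr::arrange(.data$observer, match(.data$trait, trait_names()), .data$score)
}

#' Plot score frequencies
#'
#' Bar charts of the frequency of each ordinal score (1-5), facetted by
#' trait and observer, mirroring the usual presentation of morphoscopic
#' scoring behaviour (score avoidance, mid-score pile-up, high-score bias).
#'
#' @inheritParams score_frequencies
#' @return A ggplot object.
#' @export
plot_score_frequencies <- function(scores) {
  freq <- score_frequencies(scores)
  freq$trait <- factor(freq$trait, levels = trait_names())
  ggplot2::ggplot(freq, ggplot2::aes(x = .data$score, y = .data$n)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$trait),
      cols = ggplot2::vars(.data$observer)
    ) +
    ggplot2::scale_x_continuous(breaks = 1:5) +
    ggplot2::labs(
      x = "ordinal trait score", y = "frequency",
      title = "Cranial trait score frequencies per observer"
    ) +
    ggplot2::theme_minimal()
}
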