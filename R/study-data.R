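# Embedded study tables: trait scores from four direct observers (O1-O4,
# each scoring the 3D cranial model they built) and four video observers
# (V1-V4, scoring screen recordings of Observer 1's models), twenty crania
# from clinical sinus CT scans, plus the recorded sex of each individual.
# Transcribed cell-for-cell, including the two cells Observer 3 left
# unscored on cranium 4 (mastoid process and supra-orbital margin).

# columns: mastoid O1-O4, supraorbital O1-O4, glabella O1-O4
.observer_scores_wide <- "
cranium m1 m2 m3 m4 s1 s2 s3 s4 g1 g2 g3 g4
1 1 3 4 2 1 4 3 2 1 3 3 2
2 1 5 4 4 3 5 5 4 1 5 4 3
3 1 5 5 2 2 5 4 3 2 5 3 3
4 1 5 NA 5 1 5 NA 2 1 1 1 2
5 3 5 5 5 3 5 5 5 5 5 5 4
6 2 5 5 5 2 4 3 4 3 5 4 4
7 1 2 3 1 2 3 3 3 2 2 4 3
8 1 1 2 3 1 1 4 3 1 1 1 2
9 2 5 3 3 4 5 4 5 5 5 5 4
10 1 3 2 3 2 1 2 2 3 2 1 2
11 3 5 4 5 4 5 4 4 4 4 4 4
12 4 5 5 5 5 5 5 5 5 5 5 5
13 3 5 4 4 4 5 4 5 5 5 5 5
14 2 3 3 3 3 4 3 3 4 5 4 3
15 1 1 1 1 2 3 1 2 3 1 1 3
16 2 4 4 4 4 5 5 4 5 5 5 5
17 1 3 2 2 2 2 1 2 3 1 1 2
18 2 3 3 4 3 1 2 3 3 2 1 3
19 2 2 3 3 1 1 2 1 3 1 2 2
20 2 4 4 5 3 5 4 4 5 5 4 4
"

.video_scores_wide <- "
cranium m1 m2 m3 m4 s1 s2 s3 s4 g1 g2 g3 g4
1 2 4 2 2 2 4 2 3 3 3 3 2
2 4 5 3 2 4 4 2 2 4 4 2 2
3 3 5 2 3 4 3 3 4 5 3 1 2
4 5 5 2 2 3 2 1 3 2 1 1 1
5 5 5 5 4 5 5 5 5 5 5 5 5
6 5 5 4 4 4 4 2 3 5 4 3 3
7 1 2 1 1 3 2 1 4 3 3 2 3
8 3 2 1 1 2 2 3 2 1 1 1 1
9 3 4 4 2 5 5 5 5 5 5 5 5
10 4 4 3 3 3 2 1 3 3 3 2 2
11 5 5 5 4 4 4 3 2 4 4 2 2
12 5 5 5 4 5 5 3 4 5 5 5 5
13 4 5 4 4 4 5 5 5 5 5 5 5
14 3 4 2 3 4 4 3 3 4 4 2 1
15 1 3 1 2 3 2 1 4 3 3 2 2
16 4 5 4 3 5 5 4 5 5 4 5 4
17 2 3 3 2 3 2 2 3 3 2 1 3
18 3 4 2 3 3 3 3 4 2 2 1 1
19 1 4 3 3 1 1 1 2 1 1 2 2
20 5 5 4 4 4 4 4 4 5 5 4 3
"

.wide_to_long <- function(txt, prefix_map) {
  wide <- utils::read.table(text = txt, header = TRUE)
  long <- tidyr::pivot_longer(
    as_tibble(wide), -"cranium",
    names_to = c("trait", "obs_idx"),
    names_pattern = "([msg])(\\d)",
    values_to = "score"
  )
  long$trait <- unname(c(
    m = "mastoid_process", s = "supraorbital_margin", g = "glabella"
  )[long$trait])
  long$observer <- paste0(prefix_map, long$obs_idx)
  long$cranium <- as.integer(long$cranium)
  long$score <- as.integer(long$score)
  dplyr::arrange(
    long[c("observer", "cranium", "trait", "score")],
    .data$observer, .data$cranium, match(.data$trait, trait_names())
  )
}

#' Embedded study score tables
#'
#' The complete trait-score tables of the embedded study: twenty cranial
#' models from clinical sinus CT scans of living adults, scored on the
#' ordinal 1-5 scale for mastoid process, supra-orbital margin and
#' glabella. The `"observers"` set holds the four direct observers
#' ("O1"-"O4"), each scoring the 3D model they had reconstructed
#' themselves; Observer 3 left the mastoid process and supra-orbital
#' margin of cranium 4 unscored, so that set contains exactly two missing
#' cells. The `"video"` set holds the four video observers ("V1"-"V4")
#' who scored 360-degree screen recordings of Observer 1's models; it is
#' complete.
#'
#' @param set `"observers"` for the direct-observer table or `"video"` for
#'   the video-observer table.
#' @return A long-format tibble with columns `observer`, `cranium` (1-20),
#'   `trait` and `score` (integer 1-5 or `NA` for a missing cell);
#'   240 rows per set.
#' @seealso [study_recorded_sex()] for the matching ground truth.
#' @export
#' @examples
#' study_scores("observers")
#' sum(is.na(study_scores("observers")$score))
study_scores <- function(set = c("observers", "video")) {
  set <- match.arg(set)
  if (set == "observers") {
    .wide_to_long(.observer_scores_wide, "O")
  } else {
    .wide_to_long(.video_scores_wide, "V")
  }
}

#' Recorded sex of the embedded study crania
#'
#' The documented sex of the twenty individuals whose CT scans underlie
#' the embedded score tables: crania 5, 6, 9, 11, 12, 13, 14, 16, 18 and
#' 20 are male, the remaining ten female.
#'
#' @return A tibble with columns `cranium` (1-20) and `sex`
#'   (`"male"`/`"female"`).
#' @export
study_recorded_sex <- function() {
  males <- c(5L, 6L, 9L, 11L, 12L, 13L, 14L, 16L, 18L, 20L)
  tibble(
    cranium = 1:20,
    sex = ifelse(1:20 %in% males, "male", "female")
  )
}

# Published per-cranium sex calls and whole-percent probability pairs for
# both observer sets, used by the reproduction report to compare
# recomputed estimates against the printed ones. Layout per row:
# cranium, then (sex, prob_male_pct, prob_female_pct) for each observer.
.printed_observer_estimates <- "
1 F 1 99 M 84 16 M 96 4 F 20 80
2 F 1 99 M 100 0 M 99 1 M 96 4
3 F 6 94 M 100 0 M 99 1 M 55 45
4 F 1 99 M 81 19 NA NA NA M 95 5
5 M 99 1 M 100 0 M 100 0 M 100 0
6 M 55 45 M 100 0 M 100 0 M 100 0
7 F 6 94 F 20 80 M 96 4 F 22 78
8 F 1 99 F 1 99 F 5 95 M 52 48
9 M 97 3 M 100 0 M 99 1 M 96 4
10 F 22 78 M 52 48 F 5 95 M 96 4
11 M 96 4 M 100 0 M 99 1 M 100 0
12 M 100 0 M 100 0 M 100 0 M 100 0
13 M 99 1 M 100 0 M 100 0 M 100 0
14 M 85 15 M 99 1 M 96 4 M 84 16
15 F 22 78 F 1 99 F 1 99 F 22 78
16 M 97 3 M 100 0 M 100 0 M 100 0
17 F 22 78 F 18 82 F 5 95 F 20 80
18 M 55 45 M 52 48 F 18 82 M 96 4
19 M 55 45 F 5 95 M 52 48 M 52 48
20 M 97 3 M 100 0 M 99 1 M 100 0
"

.printed_video_estimates <- "
1 M 55 45 M 96 4 M 55 45 F 20 80
2 M 99 1 M 100 0 M 52 48 F 20 80
3 M 99 1 M 99 1 F 5 95 M 52 48
4 M 95 5 M 81 19 F 5 95 F 5 95
5 M 100 0 M 100 0 M 100 0 M 100 0
6 M 100 0 M 100 0 M 96 4 M 96 4
7 F 22 78 M 55 45 F 6 94 F 22 78
8 F 18 82 F 5 95 F 1 99 F 1 99
9 M 99 1 M 100 0 M 100 0 M 100 0
10 M 96 4 M 96 4 M 52 48 M 52 48
11 M 100 0 M 100 0 M 95 5 M 82 18
12 M 100 0 M 100 0 M 100 0 M 100 0
13 M 100 0 M 100 0 M 100 0 M 100 0
14 M 96 4 M 99 1 F 20 80 F 18 82
15 F 22 78 M 84 16 F 6 9 F 20 80
16 M 100 0 M 100 0 M 100 0 M 96 4
17 M 55 45 M 52 48 F 18 82 M 55 45
18 M 52 48 M 82 18 F 5 95 F 18 82
19 F 1 99 F 49 51 M 52 48 M 52 48
20 M 100 0 M 100 0 M 99 1 M 96 4
"

#' Published sex estimates of the embedded study
#'
#' The per-cranium sex calls and whole-percent male/female probability
#' pairs as published for each observer set, transcribed verbatim
#' (including the three cells whose printed probabilities are not
#' consistent with the printed trait scores; see [reproduce_study()],
#' which flags them). Used to audit recomputed estimates against the
#' published ones.
#'
#' @inheritParams study_scores
#' @return A tibble with columns `observer`, `cranium`, `sex`
#'   (`"male"`/`"female"`, `NA` where no estimate was published),
#'   `prob_male_pct` and `prob_female_pct` (integer percentages).
#' @export
study_printed_estimates <- function(set = c("observers", "video")) {
  set <- match.arg(set)
  txt <- if (set == "observers") .printed_observer_estimates else .printed_video_estimates
  prefix <- if (set == "observers") "O" else "V"
  raw <- utils::read.table(
    text = txt, header = FALSE, na.strings = "NA",
    colClasses = c("integer", rep(c("character", "integer", "integer"), 4))
  )
  purrr::map_dfr(1:4, function(o) {
    tibble(
      observer = paste0(prefix, o),
      cranium = raw[[1]],
      sex = unname(c(M = "male", F = "female")[raw[[2 + (o - 1) * 3]]]),
      prob_male_pct = raw[[3 + (o - 1) * 3]],
      prob_female_pct = raw[[4 + (o - 1) * 3]]
    )
  }) |>
    dplyr::arrange(.data$observer, .data$cranium)
}
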