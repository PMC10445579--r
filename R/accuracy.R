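#' Per-observer classification accuracy against recorded sex
#'
#' Scores each observer's sex estimates against the recorded sex. An
#' estimate is correct iff its label equals the recorded sex; `"missing"`
#' and `"indeterminate"` estimates are never correct but stay in the
#' denominator (an unscorable cranium is a failed estimation, not an
#' excluded one). Per-sex percentages use the per-sex denominators.
#'
#' @param estimates A tibble from [estimate_sex()] (columns `observer`,
#'   `cranium`, `sex`).
#' @param recorded A recorded-sex tibble (`cranium`, `sex`); every
#'   estimated cranium must appear in it.
#' @return A tibble with one row per observer: `observer`, `n_crania`,
#'   `n_correct`, `n_incorrect`, `n_missing`, `percent_correct`
#'   (unrounded, denominator `n_crania`), `male_percent_correct`,
#'   `female_percent_correct`.
#' @export
#' @examples
#' percent_correct(estimate_sex(study_scores("observers")), study_recorded_sex())
percent_correct <- function(estimates, recorded) {
  est <- as_tibble(estimates)[c("observer", "cranium", "sex")]
  rec <- as_tibble(recorded)[c("cranium", "sex")]
  names(rec)[2] <- "recorded"
  unknown <- setdiff(est$cranium, rec$cranium)
  if (length(unknown) > 0) {
    abort(paste0(
      "No recorded sex for cranium/crania: ",
      paste(unknown, collapse = ", "), "."
    ))
  }
  est |>
    dplyr::left_join(rec, by = "cranium") |>
    dplyr::group_by(.data$observer) |>
    dplyr::summarise(
      n_crania = dplyr::n(),
      n_correct = sum(.data$sex == .data$recorded),
      n_missing = sum(.data$sex == "missing"),
      n_incorrect = n_crania - n_correct - n_missing,
      percent_correct = 100 * n_correct / n_crania,
      male_percent_correct =
        100 * sum(.data$sex == .data$recorded & .data$recorded == "male") /
          pmax(sum(.data$recorded == "male"), 1L),
      female_percent_correct =
        100 * sum(.data$sex == .data$recorded & .data$recorded == "female") /
          pmax(sum(.data$recorded == "female"), 1L),
      .groups = "drop"
    ) |>
    dplyr::relocate("n_incorrect", .after = "n_correct")
}

#' Confusion counts of recorded versus estimated sex
#'
#' @inheritParams percent_correct
#' @return A tibble with columns `observer`, `recorded`, `estimated`,
#'   `n`, complete over recorded sexes and the estimate labels that occur
#'   (including `"missing"`).
#' @export
sex_confusion <- function(estimates, recorded) {
  est <- as_tibble(estimates)[c("observer", "cranium", "sex")]
  rec <- as_tibble(recorded)[c("cranium", "sex")]
  names(rec)[2] <- "recorded"
  est |>
    dplyr::left_join(rec, by = "cranium") |>
    dplyr::count(.data$observer, .data$recorded, estimated = .data$sex) |>
    tidyr::complete(
      observer = unique(est$observer),
      recorded = sex_levels(),
      estimated = intersect(estimate_levels(), unique(est$sex)),
      fill = list(n = 0L)
    )
}

#' Full accuracy report for a score table
#'
#' Runs [estimate_sex()] then [percent_correct()] and appends a pooled
#' row aggregating the counts over all observers (observer `"pooled"`).
#' `percent_correct_pct` is the whole-percent value as reported in study
#' tables; `percent_correct` keeps the raw fraction of 100.
#'
#' @param scores A long score table.
#' @param recorded A recorded-sex tibble (`cranium`, `sex`).
#' @param spec A [discriminant_spec()]; default [walker_eq2()].
#' @return A tibble as from [percent_correct()], plus a pooled row and a
#'   `percent_correct_pct` column (rounded half away from zero).
#' @export
#' @examples
#' accuracy_report(study_scores("observers"), study_recorded_sex())
accuracy_report <- function(scores, recorded, spec = walker_eq2()) {
  est <- estimate_sex(scores, spec)
  per_obs <- percent_correct(est, recorded)
  pooled <- est |>
    dplyr::mutate(observer = "pooled") |>
    percent_correct(recorded)
  dplyr::bind_rows(per_obs, pooled) |>
    dplyr::mutate(percent_correct_pct = round_half_up(.data$percent_correct))
}
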