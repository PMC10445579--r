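#' Read and write long-format rating tables
#'
#' Rating tables are comma-delimited UTF-8 text with header
#' `observer,cranium,trait,score`; traits are spelled as in
#' [trait_names()] and a missing score is an empty field. `read_scores()`
#' validates on the way in and reports the offending line number for
#' malformed rows, duplicate (observer, cranium, trait) triples and
#' out-of-range scores.
#'
#' @param path Path to a rating-table file.
#' @return For `read_scores()`, a validated long score tibble; for
#'   `write_scores()`, `path` invisibly.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_scores(study_scores("video"), f)
#' identical(read_scores(f), study_scores("video"))
read_scores <- function(path) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      observer = readr::col_character(),
      cranium = readr::col_character(),
      trait = readr::col_character(),
      score = readr::col_character()
    )
  )
  needed <- c("observer", "cranium", "trait", "score")
  if (!all(needed %in% names(raw))) {
    abort(paste0(
      "'", path, "': expected header observer,cranium,trait,score."
    ))
  }
  line <- seq_len(nrow(raw)) + 1L # header is line 1

  fail <- function(i, msg) {
    abort(paste0("'", path, "' line ", line[i], ": ", msg))
  }
  score_num <- suppressWarnings(as.numeric(raw$score))
  bad_score <- !is.na(raw$score) & raw$score != "" &
    (is.na(score_num) | score_num %% 1 != 0 | score_num < 1 | score_num > 5)
  if (any(bad_score)) {
    i <- which(bad_score)[1]
    fail(i, paste0("score '", raw$score[i], "' is not an integer in 1-5."))
  }
  if (any(bad_trait <- !raw$trait %in% trait_names())) {
    i <- which(bad_trait)[1]
    fail(i, paste0("unknown trait '", raw$trait[i], "'."))
  }
  if (any(dup <- duplicated(raw[c("observer", "cranium", "trait")]))) {
    i <- which(dup)[1]
    fail(i, paste0(
      "duplicate (observer, cranium, trait) triple (",
      raw$observer[i], ", ", raw$cranium[i], ", ", raw$trait[i], ")."
    ))
  }
  cranium <- suppressWarnings(as.integer(raw$cranium))
  validate_scores(tibble(
    observer = raw$observer,
    cranium = if (anyNA(cranium)) raw$cranium else cranium,
    trait = raw$trait,
    score = as.integer(score_num)
  ))
}

#' @rdname read_scores
#' @param scores A long score table (see [validate_scores()]).
#' @export
write_scores <- function(scores, path) {
  scores <- validate_scores(scores)
  readr::write_csv(scores, path, na = "")
  invisible(path)
}

#' Read and write recorded-sex tables
#'
#' Comma-delimited text with header `cranium,sex` and
#' sex in `"male"`/`"female"`.
#'
#' @param path Path to a recorded-sex file.
#' @return For `read_recorded_sex()`, a tibble with columns `cranium` and
#'   `sex`; for `write_recorded_sex()`, `path` invisibly.
#' @export
read_recorded_sex <- function(path) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      cranium = readr::col_character(),
      sex = readr::col_character()
    )
  )
  if (!all(c("cranium", "sex") %in% names(raw))) {
    abort(paste0("'", path, "': expected header cranium,sex."))
  }
  bad <- !raw$sex %in% sex_levels()
  if (any(bad)) {
    abort(paste0(
      "'", path, "' line ", which(bad)[1] + 1L, ": sex must be one of ",
      paste(sex_levels(), collapse = "/"), "."
    ))
  }
  if (anyDuplicated(raw$cranium)) {
    abort(paste0("'", path, "': duplicate cranium identifier."))
  }
  cranium <- suppressWarnings(as.integer(raw$cranium))
  tibble(
    cranium = if (anyNA(cranium)) raw$cranium else cranium,
    sex = raw$sex
  )
}

#' @rdname read_recorded_sex
#' @param recorded A tibble with columns `cranium` and `sex`.
#' @export
write_recorded_sex <- function(recorded, path) {
  stopifnot(all(c("cranium", "sex") %in% names(recorded)))
  readr::write_csv(as_tibble(recorded)[c("cranium", "sex")], path, na = "")
  invisible(path)
}

#' Write a sex-estimate table
#'
#' Exports estimates from [estimate_sex()] as comma-delimited text with
#' header `observer,cranium,sex,prob_male_pct,prob_female_pct,y`. Missing
#' estimates (unscorable crania) emit `sex = "missing"` with empty numeric
#' fields.
#'
#' @param estimates A tibble from [estimate_sex()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_estimates <- function(estimates, path) {
  out <- as_tibble(estimates)[
    c("observer", "cranium", "sex", "prob_male_pct", "prob_female_pct", "y")
  ]
  readr::write_csv(out, path, na = "")
  invisible(path)
}
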