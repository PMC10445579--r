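#' Define a logistic discriminant for sex estimation
#'
#' A discriminant specification bundles per-trait coefficients (units: per
#' score point on the ordinal 1-5 scale), an intercept, and the cut-off
#' separating male from female calls. The discriminant score is
#' \deqn{Y = \sum_t \beta_t \, s_t + \beta_0,}
#' and a cranium is called male when `y < cut_off`, female when
#' `y > cut_off` (robust, high-scoring crania drive `y` negative when the
#' coefficients are negative).
#'
#' @param coefficients Named numeric vector of per-trait coefficients;
#'   names must be a subset of [trait_names()].
#' @param intercept Intercept term.
#' @param cut_off Decision boundary on the `y` scale (default 0).
#' @return An object of class `discriminant_spec`.
#' @seealso [walker_eq2()] for the built-in specification.
#' @export
discriminant_spec <- function(coefficients, intercept, cut_off = 0) {
  if (is.null(names(coefficients)) || any(names(coefficients) == "")) {
    abort("`coefficients` must be a fully named numeric vector.")
  }
  unknown <- setdiff(names(coefficients), trait_names())
  if (length(unknown) > 0) {
    abort(paste0(
      "Unknown trait(s) in coefficients: ", paste(unknown, collapse = ", "), "."
    ))
  }
  if (!is.numeric(coefficients) || anyNA(coefficients)) {
    abort("`coefficients` must be numeric and non-missing.")
  }
  stopifnot(is.numeric(intercept), length(intercept) == 1L,
            is.numeric(cut_off), length(cut_off) == 1L)
  structure(
    list(
      coefficients = coefficients,
      intercept = as.numeric(intercept),
      cut_off = as.numeric(cut_off)
    ),
    class = "discriminant_spec"
  )
}

#' @export
print.discriminant_spec <- function(x, ...) {
  cat("<discriminant_spec>\n")
  for (tr in names(x$coefficients)) {
    cat(sprintf("  %-20s %+.4g\n", tr, x$coefficients[[tr]]))
  }
  cat(sprintf("  %-20s %+.4g\n", "intercept", x$intercept))
  cat(sprintf("  %-20s %g (male if y below)\n", "cut-off", x$cut_off))
  invisible(x)
}

#' Walker equation 2
#'
#' The built-in discriminant for sex estimation from the glabella and the
#' mastoid process:
#' \deqn{Y = -1.568\,\mathrm{glabella} - 1.459\,\mathrm{mastoid} + 7.434,}
#' with cut-off 0 (male if `Y < 0`, female if `Y > 0`). This is the only
#' equation of the Walker morphoscopic family applicable when just these
#' two traits are observable; the supra-orbital margin carries no term.
#'
#' @return A `discriminant_spec`.
#' @export
#' @examples
#' discriminant_score(glabella = 5, mastoid_process = 3) # -4.783 -> male
walker_eq2 <- function() {
  discriminant_spec(
    coefficients = c(glabella = -1.568, mastoid_process = -1.459),
    intercept = 7.434,
    cut_off = 0
  )
}

.spec_scores <- function(spec, dots) {
  needed <- names(spec$coefficients)
  missing_traits <- setdiff(needed, names(dots))
  if (length(missing_traits) > 0) {
    abort(paste0(
      "Missing trait score argument(s): ",
      paste(missing_traits, collapse = ", "), "."
    ))
  }
  extra <- setdiff(names(dots), needed)
  if (length(extra) > 0) {
    abort(paste0(
      "Trait(s) not used by this discriminant: ",
      paste(extra, collapse = ", "), "."
    ))
  }
  vals <- lapply(dots[needed], as.numeric)
  for (v in vals) {
    if (any(!is.na(v) & (v < 1 | v > 5))) {
      abort("Trait scores must be in 1-5 (or NA for a missing cell).")
    }
  }
  do.call(cbind, vals)
}

#' Discriminant score of one or more crania
#'
#' Evaluates `y = sum(coef * score) + intercept` for vectors of trait
#' scores. A missing (`NA`) score in any required trait yields `NA`
#' (no estimate can be made); [classify_sex()] maps that to the
#' `"missing"` label.
#'
#' @param ... Named vectors of ordinal trait scores, one argument per
#'   trait required by `spec` (e.g. `glabella = 3, mastoid_process = 2`).
#'   Vectors are recycled by row binding rules of equal length.
#' @param spec A [discriminant_spec()]; default [walker_eq2()].
#' @return Numeric vector of discriminant scores.
#' @export
#' @examples
#' discriminant_score(glabella = c(1, 5, 3), mastoid_process = c(1, 3, 2))
discriminant_score <- function(..., spec = walker_eq2()) {
  m <- .spec_scores(spec, list(...))
  as.numeric(m %*% spec$coefficients[colnames(m)] + spec$intercept)
}

#' Male/female probabilities from a discriminant score
#'
#' Converts discriminant scores to posterior sex probabilities through the
#' logistic function: `p_female = 1 / (1 + exp(-y))`, `p_male = 1 -
#' p_female`. Negative scores (robust crania) favour male; `y = 0` gives
#' 50/50.
#'
#' @param y Numeric vector of discriminant scores.
#' @return A tibble with columns `p_male` and `p_female` (rows sum to 1).
#' @export
#' @examples
#' sex_probabilities(c(-4.783, 0, 4.407))
sex_probabilities <- function(y) {
  stopifnot(is.numeric(y))
  p_female <- stats::plogis(y)
  tibble(p_male = 1 - p_female, p_female = p_female)
}

#' Classify sex from trait scores
#'
#' Evaluates the discriminant and labels each cranium `"male"`
#' (`y < cut_off`), `"female"` (`y > cut_off`), `"indeterminate"`
#' (`y` exactly at the cut-off; the function refuses to guess a side) or
#' `"missing"` (a required trait score is `NA`, so no estimate exists).
#'
#' @inheritParams discriminant_score
#' @return A tibble with columns `sex`, `p_male`, `p_female`, `y`
#'   (probabilities and `y` are `NA` when `sex` is `"missing"`).
#' @export
#' @examples
#' classify_sex(glabella = c(1, 3, NA), mastoid_process = c(1, 2, 4))
classify_sex <- function(..., spec = walker_eq2()) {
  y <- discriminant_score(..., spec = spec)
  p <- sex_probabilities(y)
  sex <- dplyr::case_when(
    is.na(y) ~ "missing",
    y < spec$cut_off ~ "male",
    y > spec$cut_off ~ "female",
    TRUE ~ "indeterminate"
  )
  tibble(sex = sex, p_male = p$p_male, p_female = p$p_female, y = y)
}

#' Estimate sex for every observer-cranium pair of a score table
#'
#' Applies a discriminant to a long score table, producing one sex
#' estimate per (observer, cranium) pair. Pairs where any trait required
#' by the discriminant is missing get `sex = "missing"`. Probabilities are
#' also reported as whole percentages (`prob_male_pct`,
#' `prob_female_pct`), rounded half away from zero as in the study tables
#' (0.9566 -> 96).
#'
#' @param scores A long score table (see [validate_scores()]).
#' @param spec A [discriminant_spec()]; default [walker_eq2()].
#' @return A tibble with columns `observer`, `cranium`, `sex`, `p_male`,
#'   `p_female`, `y`, `prob_male_pct`, `prob_female_pct`; one row per
#'   (observer, cranium) pair in the table.
#' @export
#' @examples
#' est <- estimate_sex(study_scores("observers"))
#' est[est$observer == "O1" & est$cranium %in% 1:3, ]
estimate_sex <- function(scores, spec = walker_eq2()) {
  scores <- validate_scores(scores)
  if (nrow(scores) == 0) {
    return(tibble(
      observer = character(), cranium = integer(), sex = character(),
      p_male = double(), p_female = double(), y = double(),
      prob_male_pct = double(), prob_female_pct = double()
    ))
  }
  pairs <- dplyr::distinct(scores, .data$observer, .data$cranium)
  wide <- scores |>
    dplyr::filter(.data$trait %in% names(spec$coefficients)) |>
    tidyr::pivot_wider(
      id_cols = c("observer", "cranium"),
      names_from = "trait", values_from = "score"
    )
  wide <- dplyr::left_join(pairs, wide, by = c("observer", "cranium"))
  # pairs present in the table but lacking a required trait column entirely
  for (tr in setdiff(names(spec$coefficients), names(wide))) {
    wide[[tr]] <- NA_integer_
  }
  cls <- do.call(
    classify_sex,
    c(as.list(wide[names(spec$coefficients)]), list(spec = spec))
  )
  dplyr::bind_cols(wide[c("observer", "cranium")], cls) |>
    dplyr::mutate(
      prob_male_pct = round_half_up(100 * .data$p_male),
      prob_female_pct = round_half_up(100 * .data$p_female)
    ) |>
    dplyr::arrange(.data$observer, .data$cranium)
}
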