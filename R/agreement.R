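#' Mid-ranks of a vector
#'
#' Ranks with tied values receiving the mean of the ranks they span, so
#' the ranks always sum to `n(n+1)/2`. This is the ranking convention used
#' by the tie-corrected Kendall's W in [kendalls_w()].
#'
#' @param values A non-empty numeric vector without `NA`.
#' @return Numeric vector of (possibly fractional) ranks.
#' @export
#' @examples
#' midrank(c(5, 5, 1)) # 2.5 2.5 1
midrank <- function(values) {
  if (length(values) == 0) abort("`values` must be non-empty.")
  if (anyNA(values)) abort("`values` must not contain NA.")
  rank(values, ties.method = "average")
}

new_agreement <- function(statistic, value, m, n, components, dropped = NULL) {
  structure(
    list(
      statistic = statistic,
      value = value,
      m = m,
      n = n,
      components = components,
      dropped = dropped,
      label = landis_koch(value)
    ),
    class = "agreement"
  )
}

.check_ratings <- function(ratings) {
  if (is.data.frame(ratings)) ratings <- as.matrix(ratings)
  if (!is.matrix(ratings)) {
    abort("`ratings` must be a matrix (raters in rows, items in columns).")
  }
  if (anyNA(ratings)) {
    abort(paste0(
      "`ratings` must be complete; apply a missing-data policy first ",
      "(see complete_ratings())."
    ))
  }
  if (nrow(ratings) < 2 || ncol(ratings) < 2) {
    abort("Agreement needs at least 2 raters and 2 items.")
  }
  ratings
}

#' Tie-corrected Kendall's coefficient of concordance
#'
#' Measures agreement among `m` raters each ranking the same `n` items on
#' an ordinal scale; 0 is no concordance, 1 perfect. Each rater's `n`
#' values are converted to mid-ranks, the rank sums per item
#' \eqn{R_i} are compared with their null expectation \eqn{m(n+1)/2},
#' \eqn{S = \sum_i (R_i - m(n+1)/2)^2}, and ties are corrected per rater
#' through \eqn{T_j = \sum (t^3 - t)} over that rater's tie groups:
#' \deqn{W = \frac{12 S}{m^2 (n^3 - n) - m \sum_j T_j}.}
#'
#' @param ratings Numeric matrix of ordinal ratings, raters in rows,
#'   items in columns, no missing cells.
#' @return An object of class `agreement` holding the statistic, `m`,
#'   `n`, the [landis_koch()] band, and components (`rank_sums`,
#'   `deviation_sum`, `tie_terms`). See [tidy.agreement()] and
#'   [glance.agreement()].
#' @export
#' @examples
#' cc <- complete_ratings(study_scores("video"), "glabella")
#' kendalls_w(cc$ratings) # W = 0.84, almost perfect agreement
kendalls_w <- function(ratings) {
  ratings <- .check_ratings(ratings)
  m <- nrow(ratings)
  n <- ncol(ratings)
  rk <- t(apply(ratings, 1, midrank)) # m x n mid-ranks
  rank_sums <- colSums(rk)
  s <- sum((rank_sums - m * (n + 1) / 2)^2)
  tie_terms <- apply(ratings, 1, function(x) {
    t <- tabulate(match(x, unique(x)))
    sum(t^3 - t)
  })
  denom <- m^2 * (n^3 - n) - m * sum(tie_terms)
  if (denom <= 0) {
    abort(paste0(
      "Kendall's W is undefined: every rater assigned a single value ",
      "to all items (tie correction exhausts the denominator)."
    ))
  }
  value <- 12 * s / denom
  new_agreement(
    "kendalls_w", value, m, n,
    components = list(
      rank_sums = rank_sums,
      deviation_sum = s,
      tie_terms = tie_terms
    )
  )
}

#' Fleiss' kappa for multiple raters
#'
#' Chance-corrected agreement among `m` raters assigning `n` items to
#' nominal categories. With \eqn{n_{ij}} raters putting item `i` in
#' category `j`: per-item agreement
#' \eqn{P_i = (\sum_j n_{ij}^2 - m) / (m(m-1))}, observed agreement
#' \eqn{\bar P} (mean of \eqn{P_i}), category proportions
#' \eqn{p_j = \sum_i n_{ij} / (nm)}, expected agreement
#' \eqn{P_e = \sum_j p_j^2}, and
#' \eqn{\kappa = (\bar P - P_e) / (1 - P_e)}.
#'
#' @param ratings Matrix of nominal ratings (character or factor-like),
#'   raters in rows, items in columns, no missing cells.
#' @param categories Category set; defaults to the sorted distinct values
#'   observed. Ratings outside the set are an error.
#' @return An `agreement` object with components `item_agreement` (P_i),
#'   `observed_agreement` (P-bar), `expected_agreement` (P_e) and
#'   `category_proportions` (p_j).
#' @export
#' @examples
#' est <- estimate_sex(study_scores("video"))
#' lab <- matrix(est$sex, nrow = 4, byrow = TRUE)
#' fleiss_kappa(lab, categories = c("male", "female"))
fleiss_kappa <- function(ratings, categories = NULL) {
  ratings <- .check_ratings(ratings)
  m <- nrow(ratings)
  n <- ncol(ratings)
  if (is.null(categories)) categories <- sort(unique(as.vector(ratings)))
  if (!all(as.vector(ratings) %in% categories)) {
    abort("All ratings must belong to `categories`.")
  }
  nij <- matrix(
    vapply(
      seq_len(n),
      function(i) vapply(categories, function(ct) sum(ratings[, i] == ct), 0L),
      integer(length(categories))
    ),
    nrow = length(categories)
  ) # categories x items
  item_agreement <- (colSums(nij^2) - m) / (m * (m - 1))
  p_bar <- mean(item_agreement)
  p_j <- rowSums(nij) / (n * m)
  p_e <- sum(p_j^2)
  if (p_e >= 1) {
    abort(paste0(
      "Fleiss' kappa is undefined: all ratings fall in one category, ",
      "so expected agreement is 1 and the correction divides by zero."
    ))
  }
  value <- (p_bar - p_e) / (1 - p_e)
  new_agreement(
    "fleiss_kappa", value, m, n,
    components = list(
      item_agreement = item_agreement,
      observed_agreement = p_bar,
      expected_agreement = p_e,
      category_proportions = setNames(p_j, as.character(categories))
    )
  )
}

#' Landis-Koch interpretation band
#'
#' Maps a kappa-type agreement value to the conventional verbal band:
#' below 0 "poor", 0-0.20 "slight", 0.21-0.40 "fair", 0.41-0.60
#' "moderate", 0.61-0.80 "substantial", 0.81-1.00 "almost perfect". The
#' raw (unrounded) value is compared against the band edges; an edge
#' value such as 0.80 belongs to the lower band.
#'
#' @param value Numeric vector of agreement values, each at most 1.
#' @return Character vector of band names.
#' @export
#' @examples
#' landis_koch(c(-0.1, 0.5, 0.81))
landis_koch <- function(value) {
  stopifnot(is.numeric(value))
  if (any(value > 1, na.rm = TRUE)) {
    abort("Agreement values cannot exceed 1.")
  }
  dplyr::case_when(
    is.na(value) ~ NA_character_,
    value < 0 ~ "poor",
    value <= 0.20 ~ "slight",
    value <= 0.40 ~ "fair",
    value <= 0.60 ~ "moderate",
    value <= 0.80 ~ "substantial",
    TRUE ~ "almost perfect"
  )
}

#' Complete-case ratings matrix for one trait
#'
#' Builds the raters-by-items matrix needed by [kendalls_w()] from a long
#' score table, dropping every cranium with any missing score for the
#' trait (listwise deletion) — rank-based concordance is undefined on
#' ragged matrices.
#'
#' @param scores A long score table (see [validate_scores()]).
#' @param trait One of [trait_names()].
#' @return A list with `ratings` (numeric matrix, observers in rows,
#'   crania in columns, dimnames set) and `dropped` (crania removed by
#'   listwise deletion).
#' @export
#' @examples
#' complete_ratings(study_scores("observers"), "mastoid_process")$dropped
complete_ratings <- function(scores, trait) {
  scores <- validate_scores(scores)
  if (!trait %in% trait_names()) {
    abort(paste0("Unknown trait '", trait, "'."))
  }
  wide <- scores |>
    dplyr::filter(.data$trait == !!trait) |>
    tidyr::pivot_wider(
      id_cols = "cranium",
      names_from = "observer", values_from = "score"
    )
  if (nrow(wide) == 0 || ncol(wide) < 3) {
    abort("Need at least 2 observers and 2 crania with scores for this trait.")
  }
  m <- t(as.matrix(wide[-1]))
  colnames(m) <- as.character(wide$cranium)
  complete <- colSums(is.na(m)) == 0
  dropped <- wide$cranium[!complete]
  m <- m[, complete, drop = FALSE]
  if (ncol(m) < 2) {
    abort("Fewer than 2 crania with complete scores for this trait.")
  }
  list(ratings = m, dropped = dropped)
}

#' Per-trait observer concordance for a score table
#'
#' Data-frame front end running [complete_ratings()] then [kendalls_w()]
#' for each trait: one row per trait with the tie-corrected W, its
#' Landis-Koch band, and how many crania listwise deletion removed.
#'
#' @param scores A long score table.
#' @param traits Traits to evaluate (default all three).
#' @return A tibble with columns `trait`, `statistic`, `m`, `n`,
#'   `n_dropped`, `value`, `label`.
#' @export
#' @examples
#' score_agreement(study_scores("video"))
score_agreement <- function(scores, traits = trait_names()) {
  purrr::map_dfr(traits, function(tr) {
    cc <- complete_ratings(scores, tr)
    w <- kendalls_w(cc$ratings)
    tibble(
      trait = tr, statistic = "kendalls_w",
      m = w$m, n = w$n, n_dropped = length(cc$dropped),
      value = w$value, label = w$label
    )
  })
}

#' Observer agreement on estimated sex labels
#'
#' Fleiss' kappa across observers' sex calls for the same crania.
#' Crania where any observer's estimate is `"missing"` are excluded
#' (listwise deletion), matching the completeness requirement of the
#' statistic. Optionally the recorded sex is added as one further
#' "rater", measuring agreement of the panel with the ground truth.
#'
#' @param estimates A tibble from [estimate_sex()].
#' @param recorded Optional recorded-sex tibble (`cranium`, `sex`); when
#'   supplied it joins the panel as an extra rater.
#' @return An `agreement` object (statistic `"fleiss_kappa"`, categories
#'   male/female), with `dropped` listing excluded crania.
#' @export
#' @examples
#' sex_agreement(estimate_sex(study_scores("observers")))
sex_agreement <- function(estimates, recorded = NULL) {
  est <- as_tibble(estimates)[c("observer", "cranium", "sex")]
  wide <- tidyr::pivot_wider(
    est,
    id_cols = "cranium", names_from = "observer", values_from = "sex"
  )
  m <- t(as.matrix(wide[-1]))
  colnames(m) <- as.character(wide$cranium)
  if (!is.null(recorded)) {
    rec <- setNames(recorded$sex, as.character(recorded$cranium))
    m <- rbind(m, recorded = rec[colnames(m)])
  }
  # a cranium is unusable if any rater's call is NA or not a definite
  # male/female (missing or indeterminate estimates)
  usable <- apply(m, 2, function(col) all(!is.na(col) & col %in% sex_levels()))
  dropped <- colnames(m)[!usable]
  m <- m[, usable, drop = FALSE]
  res <- fleiss_kappa(m, categories = sex_levels())
  res$dropped <- dropped
  res
}

#' @export
print.agreement <- function(x, ...) {
  name <- c(
    kendalls_w = "Kendall's W (tie-corrected)",
    fleiss_kappa = "Fleiss' kappa"
  )[[x$statistic]]
  cat(sprintf(
    "%s = %.4f  (%d raters, %d items): %s agreement\n",
    name, x$value, x$m, x$n, x$label
  ))
  if (length(x$dropped) > 0) {
    cat("  items dropped (incomplete):", paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy an agreement object
#'
#' Per-item components as a tibble: for Kendall's W the item rank sums
#' and their deviations from the null expectation; for Fleiss' kappa the
#' per-item observed agreement.
#'
#' @param x An `agreement` object.
#' @param ... Unused.
#' @return A tibble with one row per item.
#' @export
tidy.agreement <- function(x, ...) {
  if (x$statistic == "kendalls_w") {
    rs <- x$components$rank_sums
    tibble(
      item = if (is.null(names(rs))) as.character(seq_along(rs)) else names(rs),
      rank_sum = as.numeric(rs),
      deviation = as.numeric(rs) - x$m * (x$n + 1) / 2
    )
  } else {
    pa <- x$components$item_agreement
    tibble(
      item = if (is.null(names(pa))) as.character(seq_along(pa)) else names(pa),
      item_agreement = as.numeric(pa)
    )
  }
}

#' One-row summary of an agreement object
#'
#' @param x An `agreement` object.
#' @param ... Unused.
#' @return A one-row tibble: `statistic`, `value`, `m`, `n`, `label`,
#'   `n_dropped`.
#' @export
glance.agreement <- function(x, ...) {
  tibble(
    statistic = x$statistic, value = x$value, m = x$m, n = x$n,
    label = x$label, n_dropped = length(x$dropped)
  )
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")

#' Plot per-trait agreement against the Landis-Koch bands
#'
#' @param agreement A tibble from [score_agreement()].
#' @return A ggplot object.
#' @export
plot_agreement <- function(agreement) {
  bands <- tibble(
    lo = c(0, 0.20, 0.40, 0.60, 0.80),
    hi = c(0.20, 0.40, 0.60, 0.80, 1.00),
    band = c("slight", "fair", "moderate", "substantial", "almost perfect")
  )
  ggplot2::ggplot(agreement) +
    ggplot2::geom_rect(
      data = bands,
      ggplot2::aes(xmin = -Inf, xmax = Inf, ymin = .data$lo, ymax = .data$hi,
                   fill = .data$band),
      alpha = 0.25
    ) +
    ggplot2::geom_point(
      ggplot2::aes(x = .data$trait, y = .data$value), size = 3
    ) +
    ggplot2::scale_fill_brewer(palette = "RdYlGn", breaks = bands$band) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = NULL, y = "Kendall's W", fill = "Landis-Koch band",
      title = "Observer concordance per cranial trait"
    ) +
    ggplot2::theme_minimal()
}
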