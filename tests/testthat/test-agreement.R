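test_that("midrank assigns mean ranks to ties and sums to n(n+1)/2", {
  expect_equal(midrank(c(1, 2, 3)), c(1, 2, 3))
  expect_equal(midrank(c(5, 5, 1)), c(2.5, 2.5, 1))
  expect_equal(midrank(rep(3, 4)), rep(2.5, 4))
  for (i in 1:20) {
    x <- sample.int(5, 12, replace = TRUE)
    expect_equal(sum(midrank(x)), 12 * 13 / 2)
  }
  expect_error(midrank(numeric(0)), "non-empty")
  expect_error(midrank(c(1, NA)), "NA")
})

test_that("Kendall's W is 1 under perfect concordance and errors when degenerate", {
  perfect <- rbind(1:6, 1:6, 1:6)
  expect_equal(kendalls_w(perfect)$value, 1)
  # identical raters with ties still give W = 1 under the tie correction
  tied <- rbind(c(1, 1, 2, 5), c(1, 1, 2, 5))
  expect_equal(kendalls_w(tied)$value, 1)

  expect_error(kendalls_w(matrix(1:4, nrow = 1)), "at least 2 raters")
  expect_error(kendalls_w(rbind(c(2, 2, 2), c(3, 3, 3))), "undefined")
  expect_error(kendalls_w(rbind(c(1, NA), c(2, 1))), "complete")
})

test_that("Kendall's W matches an independently coded evaluation", {
  withr::local_seed(101)
  for (i in 1:25) {
    m <- sample(2:6, 1)
    n <- sample(3:12, 1)
    r <- random_ratings(m, n)
    # skip the all-constant degenerate draw
    if (all(apply(r, 1, function(x) length(unique(x))) == 1)) next
    expect_equal(kendalls_w(r)$value, oracle_kendalls_w(r), tolerance = 1e-12)
  }
})

test_that("Kendall's W agrees with vegan's concordance analysis", {
  skip_if_not_installed("vegan")
  withr::local_seed(7)
  for (i in 1:10) {
    r <- random_ratings(4, 10)
    kg <- vegan::kendall.global(t(r))
    expect_equal(
      kendalls_w(r)$value,
      unname(kg$Concordance_analysis["W", 1]),
      tolerance = 1e-10
    )
  }
})

test_that("W is invariant to permutations and rater-wise monotone transforms", {
  withr::local_seed(33)
  r <- random_ratings(4, 10)
  w0 <- kendalls_w(r)$value
  expect_equal(kendalls_w(r[, sample(10)])$value, w0)
  expect_equal(kendalls_w(r[sample(4), ])$value, w0)
  transformed <- r
  transformed[1, ] <- exp(r[1, ])         # strictly increasing
  transformed[2, ] <- r[2, ]^3 + 5 * r[2, ]
  expect_equal(kendalls_w(transformed)$value, w0)
})

test_that("with two raters and no ties W = (spearman + 1) / 2", {
  withr::local_seed(5)
  for (i in 1:10) {
    a <- sample(1:9)
    b <- sample(1:9)
    rho <- cor(a, b, method = "spearman")
    expect_equal(kendalls_w(rbind(a, b))$value, (rho + 1) / 2)
  }
})

test_that("study concordance reproduces the published W values that recompute", {
  w_vid <- score_agreement(study_scores("video"))
  expect_equal(w_vid$n, rep(20L, 3))
  expect_equal(
    round(w_vid$value, 2)[match(
      c("mastoid_process", "supraorbital_margin", "glabella"), w_vid$trait
    )],
    c(0.79, 0.76, 0.84)
  )
  w_obs <- score_agreement(study_scores("observers"))
  expect_equal(round(w_obs$value[w_obs$trait == "glabella"], 2), 0.81)
  # direct-observer mastoid/supra-orbital published as 0.68/0.78 are NOT
  # reproduced under listwise deletion; the recomputed values are stable:
  expect_equal(round(w_obs$value[w_obs$trait == "mastoid_process"], 2), 0.74)
  expect_equal(round(w_obs$value[w_obs$trait == "supraorbital_margin"], 2), 0.81)
})

test_that("Fleiss' kappa matches hand evaluation and the independent oracle", {
  # perfect agreement over >= 2 categories
  perfect <- rbind(c("a", "b", "a"), c("a", "b", "a"), c("a", "b", "a"))
  expect_equal(fleiss_kappa(perfect)$value, 1)

  # 3 raters x 4 items with per-item counts (3,0),(2,1),(1,2),(0,3):
  # P_i = (9-3)/6, (5-3)/6, (5-3)/6, (9-3)/6 -> P_bar = 16/24
  # p = (0.5, 0.5) -> P_e = 0.5 -> kappa = (2/3 - 1/2)/(1/2) = 1/3
  m <- rbind(
    c("x", "x", "x", "y"),
    c("x", "x", "y", "y"),
    c("x", "y", "y", "y")
  )
  k <- fleiss_kappa(m)
  expect_equal(k$value, 1 / 3)
  expect_equal(k$components$observed_agreement, 2 / 3)
  expect_equal(k$components$expected_agreement, 1 / 2)

  withr::local_seed(11)
  for (i in 1:15) {
    r <- matrix(sample(letters[1:3], 5 * 8, TRUE), nrow = 5)
    cats <- letters[1:3]
    if (length(unique(as.vector(r))) < 2) next
    expect_equal(
      fleiss_kappa(r, cats)$value,
      oracle_fleiss_kappa(r, cats),
      tolerance = 1e-12
    )
  }

  expect_error(fleiss_kappa(rbind(c("a", "a"), c("a", "a"))), "one category")
})

test_that("kappa near zero for independent uniform ratings and invariant to relabeling", {
  withr::local_seed(2024)
  r <- matrix(sample(c("m", "f"), 4 * 500, TRUE), nrow = 4)
  expect_lt(abs(fleiss_kappa(r)$value), 0.05)

  relabeled <- matrix(c(m = "male", f = "female")[r], nrow = 4)
  expect_equal(fleiss_kappa(relabeled)$value, fleiss_kappa(r)$value)
})

test_that("Landis-Koch bands partition (-Inf, 1] with closed upper edges", {
  expect_equal(landis_koch(0.50), "moderate")
  expect_equal(landis_koch(-0.1), "poor")
  expect_equal(landis_koch(0.81), "almost perfect")
  expect_equal(
    landis_koch(c(0, 0.20, 0.40, 0.60, 0.80, 1)),
    c("slight", "slight", "fair", "moderate", "substantial", "almost perfect")
  )
  expect_equal(
    landis_koch(c(0.201, 0.405, 0.61, 0.805)),
    c("fair", "moderate", "substantial", "almost perfect")
  )
  expect_error(landis_koch(1.2), "exceed 1")

  # every agreement object's label is consistent with its value
  withr::local_seed(9)
  r <- random_ratings(3, 8)
  w <- kendalls_w(r)
  expect_equal(w$label, landis_koch(w$value))
})

test_that("complete_ratings applies listwise deletion per trait", {
  obs <- study_scores("observers")
  cc <- complete_ratings(obs, "mastoid_process")
  expect_equal(dim(cc$ratings), c(4, 19))
  expect_equal(cc$dropped, 4L)
  expect_equal(complete_ratings(obs, "glabella")$dropped, integer(0))
  expect_equal(dim(complete_ratings(study_scores("video"), "supraorbital_margin")$ratings),
               c(4, 20))
  expect_error(complete_ratings(obs, "nose"), "Unknown trait")

  sparse <- tibble::tibble(
    observer = rep(c("A", "B"), each = 2),
    cranium = rep(1:2, 2),
    trait = "glabella",
    score = c(1, NA, 2, 3)
  )
  expect_error(complete_ratings(sparse, "glabella"), "Fewer than 2")
})

test_that("sex-label agreement excludes crania with missing estimates", {
  est <- estimate_sex(study_scores("observers"))
  k <- sex_agreement(est)
  expect_equal(k$n, 19) # cranium 4 dropped (Observer 3 estimate missing)
  expect_equal(k$dropped, "4")
  expect_equal(k$m, 4)

  with_truth <- sex_agreement(est, study_recorded_sex())
  expect_equal(with_truth$m, 5)
  expect_gt(with_truth$value, k$value - 1) # defined, finite
})

test_that("agreement objects print, tidy and glance coherently", {
  w <- kendalls_w(complete_ratings(study_scores("video"), "glabella")$ratings)
  td <- tidy(w)
  expect_equal(nrow(td), 20)
  expect_equal(sum(td$deviation), 0)
  g <- glance(w)
  expect_equal(g$value, w$value)
  expect_output(print(w), "Kendall's W")

  p <- plot_agreement(score_agreement(study_scores("video")))
  expect_s3_class(p, "ggplot")
})
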