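test_that("configuration validation rejects malformed settings", {
  expect_s3_class(synthetic_config(), "synthetic_config")
  expect_error(synthetic_config(n_crania = 0), "positive")
  expect_error(synthetic_config(sex_ratio = 1.5), "probability")
  expect_error(synthetic_config(thresholds = c(1, 0, 2, 3)), "increasing")
  expect_error(synthetic_config(thresholds = c(0, 1, 2)), "increasing")
  expect_error(synthetic_config(observer_sd = -1), "non-negative")
  expect_error(synthetic_config(missing_rate = 2), "probability")
  expect_error(
    synthetic_config(observer_biases = c(0, 0)), "named"
  )
})

test_that("identical configurations generate identical datasets", {
  cfg <- synthetic_config(n_crania = 12, missing_rate = 0.1, seed = 99)
  a <- simulate_ratings(cfg)
  b <- simulate_ratings(cfg)
  expect_identical(a$scores, b$scores)
  expect_identical(a$recorded, b$recorded)
  expect_identical(a$latent, b$latent)
  c <- simulate_ratings(cfg, seed = 100)
  expect_false(identical(a$scores$score, c$scores$score))
})

test_that("simulated datasets have the configured shape and valid cells", {
  cfg <- synthetic_config(
    n_crania = 15,
    observer_biases = c(A = -0.5, B = 0, C = 0.8),
    missing_rate = 0.2, seed = 3
  )
  ds <- simulate_ratings(cfg)
  expect_equal(nrow(ds$scores), 15 * 3 * 3)
  expect_setequal(unique(ds$scores$observer), c("A", "B", "C"))
  expect_equal(nrow(ds$recorded), 15)
  expect_true(all(ds$recorded$sex %in% c("male", "female")))
  expect_true(all(is.na(ds$scores$score) | ds$scores$score %in% 1:5))
  expect_gt(sum(is.na(ds$scores$score)), 0)
  # scores are the thresholded latents wherever the cell is present
  expected <- 1L + vapply(
    ds$latent$latent, function(x) sum(cfg$thresholds < x), 0L
  )
  present <- !is.na(ds$scores$score)
  expect_equal(ds$scores$score[present], expected[present])
})

test_that("a noise-free dataset yields perfect agreement everywhere", {
  cfg <- synthetic_config(
    n_crania = 10, cranium_sd = 0, observer_sd = 0, seed = 21
  )
  ds <- simulate_ratings(cfg)
  per_obs <- tidyr::pivot_wider(
    ds$scores, names_from = observer, values_from = score
  )
  expect_equal(per_obs$O1, per_obs$O2)
  expect_equal(per_obs$O1, per_obs$O3)
  for (tr in trait_names()) {
    expect_equal(
      kendalls_w(complete_ratings(ds$scores, tr)$ratings)$value, 1
    )
  }
  expect_equal(sex_agreement(estimate_sex(ds$scores))$value, 1)
})

test_that("unseparated sexes drive accuracy to the majority rate", {
  cfg <- synthetic_config(
    n_crania = 500,
    sex_ratio = 0.5,
    trait_means = setNames(
      rep(list(c(female = 0, male = 0)), 3), trait_names()
    ),
    seed = 77
  )
  ds <- simulate_ratings(cfg)
  acc <- estimate_sex(ds$scores) |>
    dplyr::mutate(observer = "pooled") |>
    percent_correct(ds$recorded)
  # estimates carry no information about sex, so expected accuracy is the
  # rate of the majority class implied by sex_ratio
  majority <- 100 * max(cfg$sex_ratio, 1 - cfg$sex_ratio)
  expect_lt(abs(acc$percent_correct - majority) / 100, 0.05)
})

test_that("well-separated sexes give near-perfect discriminant accuracy", {
  cfg <- synthetic_config(
    n_crania = 60,
    trait_means = setNames(
      rep(list(c(female = -3, male = 3)), 3), trait_names()
    ),
    cranium_sd = 0.1, observer_sd = 0.1, seed = 5
  )
  ds <- simulate_ratings(cfg)
  acc <- estimate_sex(ds$scores) |>
    dplyr::mutate(observer = "pooled") |>
    percent_correct(ds$recorded)
  expect_gte(acc$percent_correct, 95)
})

test_that("mean agreement degrades monotonically with observer noise", {
  grid <- lapply(c(0, 0.5, 1, 2), function(s) {
    synthetic_config(observer_sd = s)
  })
  rec <- recovery_experiment(grid, replicates = 25, seed = 42)
  expect_equal(rec$observer_sd, c(0, 0.5, 1, 2))
  expect_equal(rec$mean_w[1], 1)
  expect_equal(rec$mean_kappa[1], 1)
  expect_true(all(diff(rec$mean_w) < 0))
  expect_true(all(diff(rec$mean_kappa) < 0))

  p <- plot_recovery(rec)
  expect_s3_class(p, "ggplot")
})

test_that("score distributions mirror under a sex swap with mirrored means", {
  mirrored <- function(ratio, seed) {
    cfg <- synthetic_config(
      n_crania = 4000, sex_ratio = ratio,
      cranium_sd = 0, observer_biases = c(O1 = 0),
      observer_sd = 1, seed = seed
    )
    simulate_ratings(cfg)
  }
  all_male <- mirrored(1, 8)$scores$score
  all_female <- mirrored(0, 8)$scores$score
  # symmetric thresholds + mirrored means (+1/-1): score of one sex is the
  # reflection 6 - score of the other, in distribution
  expect_lt(
    max(abs(prop.table(table(factor(all_male, 1:5))) -
              rev(prop.table(table(factor(all_female, 1:5)))))),
    0.03
  )
})

test_that("configurations round-trip through YAML", {
  cfg <- synthetic_config(
    n_crania = 7, sex_ratio = 0.3,
    observer_biases = c(A = -1, B = 0.25),
    observer_sd = 1.2, missing_rate = 0.05, seed = 1234
  )
  f <- withr::local_tempfile(fileext = ".yml")
  write_synthetic_config(cfg, f)
  back <- read_synthetic_config(f)
  expect_equal(back$n_crania, cfg$n_crania)
  expect_equal(back$observer_biases, cfg$observer_biases)
  expect_equal(back$trait_means, cfg$trait_means)
  expect_identical(
    simulate_ratings(back)$scores, simulate_ratings(cfg)$scores
  )
})

test_that("the default configuration lands accuracy in the study's range", {
  ds <- simulate_ratings(synthetic_config(seed = 2))
  report <- accuracy_report(ds$scores, ds$recorded)
  pooled <- report$percent_correct[report$observer == "pooled"]
  expect_gte(pooled, 65)
  expect_lte(pooled, 95)
})
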