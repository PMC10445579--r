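# Independent reference implementations used to cross-check the package's
# agreement statistics. These deliberately use a different algebraic route
# than the package code.

# Kendall's W via the sum-of-squared-rank-sums arrangement,
# 12*sum(Ri^2) - 3*m^2*n*(n+1)^2 in the numerator, and tie terms counted
# with rle() on sorted values rather than tabulate().
oracle_kendalls_w <- function(ratings) {
  m <- nrow(ratings)
  n <- ncol(ratings)
  rk <- apply(ratings, 1, function(x) rank(x, ties.method = "average"))
  ri <- rowSums(rk) # n rank sums (rk is n x m here)
  numerator <- 12 * sum(ri^2) - 3 * m^2 * n * (n + 1)^2
  ties <- sum(apply(ratings, 1, function(x) {
    t <- rle(sort(x))$lengths
    sum(t^3 - t)
  }))
  numerator / (m^2 * (n^3 - n) - m * ties)
}

# Fleiss' kappa straight from category-count tables built with table().
oracle_fleiss_kappa <- function(ratings, categories) {
  m <- nrow(ratings)
  n <- ncol(ratings)
  counts <- t(vapply(
    seq_len(n),
    function(i) as.integer(table(factor(ratings[, i], levels = categories))),
    integer(length(categories))
  ))
  p_i <- (rowSums(counts^2) - m) / (m * (m - 1))
  p_j <- colSums(counts) / sum(counts)
  p_e <- sum(p_j^2)
  (mean(p_i) - p_e) / (1 - p_e)
}

random_ratings <- function(m, n, k = 5) {
  matrix(sample.int(k, m * n, replace = TRUE), nrow = m)
}
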