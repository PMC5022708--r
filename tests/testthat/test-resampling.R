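test_that("bootstrap_stat resamples individuals reproducibly", {
  d <- data.frame(individual = 1:6, x = rep(3, 6), y = rep(1, 6))
  dist <- bootstrap_stat(d, function(t) mean(t$x), iterations = 20,
                         seed = 1)
  expect_true(all(unlist(dist$draws) == 3))
  d2 <- simulate_population(fix_spd(3, 1), n = 500, seed = 2)
  bs <- bootstrap_stat(d2, function(t) unclass(calculate_matrix(t)),
                       iterations = 50, seed = 3)
  mean_mat <- Reduce(`+`, bs$draws) / length(bs$draws)
  expect_lt(frob(mean_mat, unclass(fix_spd(3, 1))) /
            frob(unclass(fix_spd(3, 1))), 0.10)
  # bit-reproducible under the same seed
  bs2 <- bootstrap_stat(d2, function(t) unclass(calculate_matrix(t)),
                        iterations = 50, seed = 3)
  expect_identical(bs$draws, bs2$draws)
})

test_that("monte_carlo_stat converges to the generating matrix", {
  g <- fix_spd(3, 4)
  mc <- monte_carlo_stat(g, sample_size = 5000,
                         statistic = function(t) unclass(calculate_matrix(t)),
                         iterations = 5, seed = 5)
  for (d in mc$draws)
    expect_lt(frob(d, unclass(g)) / frob(unclass(g)), 0.1)
  expect_error(monte_carlo_stat(trait_matrix(diag(c(1, 0)),
                                             role = "covariance"),
                                10, identity), "positive-definite")
  expect_error(monte_carlo_stat(g, 3, identity), "sample_size")
})

test_that("matrix repeatabilities are high for well-sampled structure", {
  g <- fix_spd(4, 6)
  d_big <- simulate_population(g, n = 1000, seed = 7)
  rep_big <- bootstrap_rep(d_big, "random_skewers", iterations = 30,
                           seed = 8)
  expect_gte(rep_big$value, 0.95)
  # small n, many traits: lower but still below 1
  g10 <- fix_spd(10, 9)
  d_small <- simulate_population(g10, n = 12, seed = 10)
  rep_small <- bootstrap_rep(d_small, "random_skewers", iterations = 30,
                             seed = 11)
  expect_lt(rep_small$value, rep_big$value)
  expect_lte(rep_small$value, 1)
  # degenerate data fail at the covariance step
  flat <- data.frame(individual = 1:5, x = rep(1, 5), y = rep(2, 5))
  expect_error(bootstrap_rep(flat, iterations = 5, seed = 1), "degenerate")
})

test_that("monte carlo repeatability approaches 1 with huge samples", {
  g <- fix_spd(4, 12)
  rep_mc <- monte_carlo_rep(g, sample_size = 10000, iterations = 20,
                            seed = 13)
  expect_gte(rep_mc$value, 0.99)
  rep_mc2 <- monte_carlo_rep(g, sample_size = 10000, iterations = 20,
                             seed = 13)
  expect_identical(rep_mc$value, rep_mc2$value)
})

test_that("alpha repeatability follows the analytic expression", {
  # hand-computed oracle on a fixed 4x4 correlation matrix at n = 50
  r_low <- c(0.3, 0.5, 0.2, -0.1, 0.4, 0.25)
  m <- diag(4)
  m[lower.tri(m)] <- r_low
  m <- m + t(m) - diag(4)
  corr <- trait_matrix(m, role = "correlation")
  var_r <- var(r_low)
  eps2 <- (1 - mean(r_low^2))^2 / (50 - 2)
  expect_equal(alpha_rep(corr, 50)$value, (var_r - eps2) / var_r,
               tolerance = 1e-12)
  # permutation invariance
  perm <- c(3, 1, 4, 2)
  corr_p <- trait_matrix(m[perm, perm], role = "correlation")
  expect_equal(alpha_rep(corr_p, 50)$value, alpha_rep(corr, 50)$value,
               tolerance = 1e-12)
  # large n drives alpha to 1 from below
  expect_gt(alpha_rep(corr, 1e7)$value, 0.999)
  expect_lt(alpha_rep(corr, 1e7)$value, 1)
  # constant off-diagonals clamp to 0; tiny n is an error
  u <- modular_matrix(4, rep(1, 4), 0.5, 0.5)
  expect_equal(alpha_rep(u, 50)$value, 0)
  expect_error(alpha_rep(corr, 2), "n > 2")
})

test_that("corrected correlations divide by the geometric mean and cap", {
  expect_equal(corrected_correlation(0.8, 1, 1)$value, 0.8)
  capped <- corrected_correlation(0.5, 0.64, 0.25)
  expect_equal(capped$value, 1)
  expect_true(capped$capped)
  expect_equal(corrected_correlation(0.6, 0.9, 0.9)$value, 0.6 / 0.9,
               tolerance = 1e-12)
  expect_error(corrected_correlation(0.5, 0, 1), "positive")
})

test_that("rarefaction degrades gracefully with sample size", {
  d <- simulate_population(fix_spd(3, 14), n = 60, seed = 15)
  tab <- rarefaction(d, sizes = c(10, 30, 60), iterations = 20,
                     comparison_method = "pca_similarity", seed = 16)
  means <- tapply(tab$value, tab$size, mean)
  expect_true(all(diff(means) > -0.02))  # non-decreasing within MC error
  expect_lt(means[["60"]], 1)
  expect_gt(means[["60"]], 0.9)
  tab2 <- rarefaction(d, sizes = c(10, 30, 60), iterations = 20,
                      comparison_method = "pca_similarity", seed = 16)
  expect_identical(tab, tab2)
  expect_error(rarefaction(d, sizes = 1, iterations = 2), "sizes")
})

test_that("extend_matrix raises only the trailing eigenvalues", {
  m <- fix_diag(10, 5, 1, 0.1, 0.01)
  ext <- extend_matrix(m, retained_rank = 3)
  expect_equal(eigen_sorted(ext)$values, c(10, 5, 1, 1, 1),
               tolerance = 1e-10)
  # identity at full rank
  g <- fix_spd(5, 17)
  expect_equal(bare(extend_matrix(g, retained_rank = 5)), bare(g),
               tolerance = 1e-10)
  # eigendecomposition oracle: direct reconstruction with the original
  # eigenvectors and the raised spectrum
  ext2 <- extend_matrix(g, retained_rank = 2)
  e_old <- eigen_sorted(g)
  lam <- e_old$values; lam[3:5] <- lam[2]
  expect_equal(bare(ext2),
               e_old$vectors %*% (lam * t(e_old$vectors)),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(eigen_sorted(ext2)$values[1:2], e_old$values[1:2],
               tolerance = 1e-10)
  diff_ev <- eigen(unclass(ext2) - unclass(g), symmetric = TRUE,
                   only.values = TRUE)$values
  expect_gte(min(diff_ev), -1e-12)
  expect_error(extend_matrix(g, retained_rank = 9), "retained_rank")
})
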