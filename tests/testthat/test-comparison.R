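test_that("self-comparisons are exact for every method", {
  for (seed in 1:5) {
    p <- 2 + seed
    g <- fix_spd(p, seed = seed)
    expect_equal(random_skewers(g, g, n_vectors = 200,
                                seed = seed)$value, 1, tolerance = 1e-10)
    expect_equal(krz_cor(g, g)$value, 1, tolerance = 1e-10)
    expect_equal(pca_similarity(g, g)$value, 1, tolerance = 1e-10)
    r <- to_correlation(g)
    expect_equal(mantel_cor(r, r, permutations = 49, seed = seed)$value, 1,
                 tolerance = 1e-12)
    expect_equal(matrix_distance(g, g, method = "riemann")$value, 0,
                 tolerance = 1e-10)
  }
})

test_that("random skewers matches a brute-force oracle and is symmetric", {
  a <- fix_diag(10, 1); b <- fix_diag(1, 10)
  # brute-force oracle: independent high-replication MC with raw loops
  oracle <- withr::with_seed(99, {
    vals <- numeric(20000)
    for (i in seq_along(vals)) {
      beta <- rnorm(2); beta <- beta / sqrt(sum(beta^2))
      ra <- as.matrix(a) %*% beta; rb <- as.matrix(b) %*% beta
      vals[i] <- sum(ra * rb) / (sqrt(sum(ra^2)) * sqrt(sum(rb^2)))
    }
    mean(vals)
  })
  rs <- random_skewers(a, b, n_vectors = 20000, seed = 1)
  expect_equal(rs$value, oracle, tolerance = 0.01)
  # symmetry under shared gradients is exact
  betas <- random_unit_vectors(4, 500, seed = 2)
  x <- fix_spd(4, 3); y <- fix_spd(4, 4)
  expect_identical(random_skewers(x, y, betas = betas)$value,
                   random_skewers(y, x, betas = betas)$value)
  # invariance under positive rescaling with shared gradients
  x2 <- trait_matrix(3.7 * unclass(x), role = "covariance")
  expect_equal(random_skewers(x, y, betas = betas)$value,
               random_skewers(x2, y, betas = betas)$value,
               tolerance = 1e-12)
})

test_that("mantel correlation equals the direct element correlation", {
  a <- fix_corr(4, seed = 5)
  b <- fix_corr(4, seed = 6)
  mt <- mantel_cor(a, b, permutations = 99, seed = 7)
  low <- lower.tri(a)
  expect_equal(mt$value, cor(unclass(a)[low], unclass(b)[low]),
               tolerance = 1e-12)
  # self-comparison p-value is the add-one minimum
  self <- mantel_cor(a, a, permutations = 99, seed = 8)
  expect_equal(self$p_value, 1 / 100)
  # flipping off-diagonal signs flips the correlation
  flip <- unclass(a) * -1; diag(flip) <- 1
  expect_equal(mantel_cor(a, trait_matrix(flip, role = "correlation"),
                          permutations = 9, seed = 9)$value, -1,
               tolerance = 1e-12)
  # covariance input is refused with guidance
  g <- fix_spd(4, seed = 10)
  expect_error(mantel_cor(g, g), "correlation matrices only")
})

test_that("mantel statistic agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  a <- fix_corr(6, seed = 11); b <- fix_corr(6, seed = 12)
  ours <- mantel_cor(a, b, permutations = 49, seed = 1)$value
  ref <- vegan::mantel(as.dist(1 - unclass(a)), as.dist(1 - unclass(b)),
                       permutations = 0)$statistic
  # 1 - r transforms both matrices identically; Pearson r is invariant
  # up to the sign flip induced on both, so the statistics coincide
  expect_equal(ours, unname(ref), tolerance = 1e-10)
})

test_that("krzanowski correlation separates and respects rotations", {
  eps <- 1e-4
  a <- fix_diag(8, 4, eps, eps)
  b <- trait_matrix(diag(c(eps, eps, 8, 4)), role = "covariance")
  expect_equal(krz_cor(a, b, k = 1)$value, 0, tolerance = 1e-10)
  expect_equal(krz_cor(a, a, k = 2)$value, 1, tolerance = 1e-10)
  expect_error(krz_cor(a, b, k = 4), "k must satisfy")
  # rotation invariance
  g1 <- fix_spd(6, 13); g2 <- fix_spd(6, 14)
  q <- qr.Q(qr(withr::with_seed(15, matrix(rnorm(36), 6, 6))))
  rot <- function(m) trait_matrix(q %*% unclass(m) %*% t(q),
                                  role = "covariance")
  expect_equal(krz_cor(rot(g1), rot(g2))$value, krz_cor(g1, g2)$value,
               tolerance = 1e-10)
  # default subspace size
  expect_equal(krz_cor(fix_spd(8, 16), fix_spd(8, 17))$k, 3)
})

test_that("pca similarity equals the double-loop formula", {
  a <- fix_spd(5, 18); b <- fix_spd(5, 19)
  ea <- eigen_sorted(a); eb <- eigen_sorted(b)
  num <- 0
  for (i in 1:5) for (j in 1:5)
    num <- num + ea$values[i] * eb$values[j] *
      sum(ea$vectors[, i] * eb$vectors[, j])^2
  den <- sum(ea$values * eb$values)
  expect_equal(pca_similarity(a, b)$value, num / den, tolerance = 1e-12)
  # disjoint variation scores near zero
  expect_lt(pca_similarity(fix_diag(1, 1e-6),
                           trait_matrix(diag(c(1e-6, 1)),
                                        role = "covariance"))$value, 1e-5)
})

test_that("riemann distance has its closed form and invariances", {
  expect_equal(
    matrix_distance(fix_diag(exp(2), 1), fix_diag(1, 1))$value, 2,
    tolerance = 1e-12)
  a <- fix_diag(1, 2, 5); b <- fix_diag(3, 4, 0.5)
  expect_equal(matrix_distance(a, b)$value,
               sqrt(sum(log(c(1 / 3, 2 / 4, 5 / 0.5))^2)),
               tolerance = 1e-10)
  g1 <- fix_spd(4, 20); g2 <- fix_spd(4, 21)
  d <- matrix_distance(g1, g2)$value
  # symmetric and inversion-invariant
  expect_equal(matrix_distance(g2, g1)$value, d, tolerance = 1e-8)
  inv <- function(m) trait_matrix(solve(unclass(m)), role = "covariance")
  expect_equal(matrix_distance(inv(g1), inv(g2))$value, d,
               tolerance = 1e-8)
  # congruence invariance under a random invertible transform
  t_mat <- withr::with_seed(22, matrix(rnorm(16), 4, 4))
  cong <- function(m) trait_matrix(t_mat %*% unclass(m) %*% t(t_mat),
                                   role = "covariance")
  expect_equal(matrix_distance(cong(g1), cong(g2))$value, d,
               tolerance = 1e-8)
})

test_that("overlap distance is zero at self and symmetric by design", {
  g <- fix_spd(3, 23)
  ov <- matrix_distance(g, g, method = "overlap", mc_draws = 5000,
                        seed = 24)
  expect_lte(abs(ov$q - 0.5), 3 * ov$se)
  expect_equal(ov$value, sqrt(max(1 - 2 * ov$q, 0)))
  # triangle inequality on a sampled SPD triple (within MC error)
  a <- fix_spd(3, 25); b <- fix_spd(3, 26); c <- fix_spd(3, 27)
  dab <- matrix_distance(a, b, "overlap", 4000, seed = 1)$value
  dbc <- matrix_distance(b, c, "overlap", 4000, seed = 2)$value
  dac <- matrix_distance(a, c, "overlap", 4000, seed = 3)$value
  expect_lt(dac, dab + dbc + 0.05)
})

test_that("compare_all fills raw, corrected and repeatability cells", {
  g <- fix_spd(4, 28)
  tab <- compare_all(list(a = g, b = g), method = "krz")
  expect_equal(tab["b", "a"], 1, tolerance = 1e-10)
  expect_equal(tab["a", "b"], tab["b", "a"])
  mats <- list(a = fix_spd(4, 29), b = fix_spd(4, 30), c = fix_spd(4, 31))
  raw <- compare_all(mats, method = "pca_similarity")
  expect_equal(raw[lower.tri(raw)], t(raw)[lower.tri(raw)])
  corr <- compare_all(mats, method = "pca_similarity",
                      repeatabilities = c(0.8, 0.8, 0.9))
  expect_equal(diag(corr), c(a = 0.8, b = 0.8, c = 0.9))
  expect_equal(corr["a", "b"],
               min(raw["b", "a"] / sqrt(0.8 * 0.8), 1))
})
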