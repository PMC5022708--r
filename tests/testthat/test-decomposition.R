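test_that("srd of a matrix with itself is exactly (1, 0)", {
  g <- fix_spd(5, seed = 1)
  res <- srd(g, g, n_vectors = 50, seed = 2)
  expect_equal(res$scores$mu_srd, rep(1, 5), tolerance = 1e-12)
  expect_equal(res$scores$sigma_srd, rep(0, 5), tolerance = 1e-12)
})

test_that("srd equals the explicit-loop evaluation on shared gradients", {
  a <- fix_spd(4, seed = 3); b <- fix_spd(4, seed = 4)
  betas <- random_unit_vectors(4, 500, seed = 5)
  res <- srd(a, b, betas = betas)
  # independent oracle: raw loops over gradients, traits and terms
  am <- unclass(a); bm <- unclass(b)
  cors <- matrix(NA_real_, 500, 4)
  for (v in 1:500) for (i in 1:4) {
    ra <- numeric(4); rb <- numeric(4)
    for (j in 1:4) {
      ra[j] <- am[i, j] * betas[v, j]
      rb[j] <- bm[i, j] * betas[v, j]
    }
    cors[v, i] <- cor(ra, rb)
  }
  expect_equal(res$scores$mu_srd, colMeans(cors), tolerance = 1e-12)
  expect_equal(res$scores$sigma_srd, apply(cors, 2, sd),
               tolerance = 1e-12)
})

test_that("srd localizes a difference planted in one trait", {
  a <- fix_spd(5, seed = 6)
  bm <- unclass(a)
  bm[3, ] <- bm[3, ] * c(1, -1, 1, -1, 1)
  bm[, 3] <- bm[3, ]
  bm <- bm + diag(5) * max(0, -min(eigen(bm, symmetric = TRUE,
                                         only.values = TRUE)$values) + 0.1)
  b <- trait_matrix(bm, role = "covariance")
  res <- srd(a, b, n_vectors = 5000, seed = 7)
  expect_equal(which.min(res$scores$mu_srd), 3)
  expect_true(res$scores$flagged[3])
})

test_that("the frechet mean solves its stationarity condition", {
  # singleton: the mean is the member
  g <- fix_spd(4, seed = 8)
  expect_equal(bare(mean_matrix(list(g))), bare(g),
               tolerance = 1e-10)
  # {A, A^-1} has mean I: log(M^-1/2 A M^-1/2) cancels its inverse
  ainv <- trait_matrix(solve(unclass(g)), role = "covariance",
                       labels = rownames(g))
  m <- mean_matrix(list(g, ainv))
  expect_lt(frob(m, diag(4)), 1e-8)
  expect_lte(attr(m, "residual"), 1e-9)
  # commuting diagonals: element-wise geometric mean
  m2 <- mean_matrix(list(fix_diag(1, 4), fix_diag(4, 1)))
  expect_equal(unname(bare(m2)), diag(c(2, 2)), tolerance = 1e-8)
  # stationarity residual at convergence
  samp <- lapply(1:6, function(i) fix_spd(3, seed = 10 + i))
  mm <- mean_matrix(samp, tol = 1e-11)
  ms <- matrix_sqrt(mm); msi <- solve(ms)
  resid <- Reduce(`+`, lapply(samp, function(x)
    matrix_log(msi %*% unclass(x) %*% msi)))
  expect_lte(frob(resid) / length(samp), 10 * 1e-11)
})

test_that("eigentensor bases are orthonormal and conserve variance", {
  samp <- matrix_sample(lapply(1:8, function(i) fix_spd(4, seed = 20 + i)))
  basis <- eigentensor_decomposition(samp)
  ets <- basis$eigentensors
  for (i in seq_along(ets)) for (j in seq_len(i)) {
    ip <- sum(ets[[i]] * ets[[j]])
    expect_equal(ip, as.numeric(i == j), tolerance = 1e-8)
  }
  # score covariance is diagonal with the eigenvalues on the diagonal
  sc <- cov(basis$scores)
  expect_equal(sc, diag(basis$eigenvalues), tolerance = 1e-8,
               ignore_attr = TRUE)
  # total variance conservation
  p <- 4
  ms <- basis$m_inv_sqrt
  vecs <- t(vapply(samp, function(x) {
    f <- matrix_log(ms %*% unclass(x) %*% ms)
    c(diag(f), sqrt(2) * f[lower.tri(f)])
  }, numeric(p * (p + 1) / 2)))
  expect_equal(sum(basis$eigenvalues), sum(diag(cov(vecs))),
               tolerance = 1e-8)
  # identical members give a zero tensor
  same <- matrix_sample(list(fix_spd(3, 30), fix_spd(3, 30)))
  b0 <- eigentensor_decomposition(same)
  expect_lt(max(abs(b0$eigenvalues)), 1e-15)
  expect_lt(max(abs(b0$scores)), 1e-7)
})

test_that("project and revert are mutually inverse", {
  samp <- matrix_sample(lapply(1:6, function(i) fix_spd(4, seed = 40 + i)))
  basis <- eigentensor_decomposition(samp)
  # the mean projects to the origin
  expect_lt(max(abs(project_matrix(basis$mean, basis))), 1e-10)
  # sample members reproduce their stored score rows
  for (i in c(1, 4))
    expect_equal(project_matrix(samp[[i]], basis), basis$scores[i, ],
                 tolerance = 1e-8)
  # revert(0) is the mean exactly
  expect_equal(bare(revert_matrix(rep(0, 10), basis)),
               bare(basis$mean), tolerance = 1e-10)
  # full round trips in both directions
  for (i in c(2, 5))
    expect_lt(frob(revert_matrix(basis$scores[i, ], basis), samp[[i]]),
              1e-8)
  s <- withr::with_seed(50, rnorm(10, sd = 0.3))
  expect_equal(project_matrix(revert_matrix(s, basis), basis), s,
               tolerance = 1e-8)
  # any finite scores yield an SPD matrix
  wild <- revert_matrix(c(5, -4, 3), basis)
  expect_gt(min(eigen(unclass(wild), symmetric = TRUE,
                      only.values = TRUE)$values), 0)
})

test_that("rs projection flags directions with separated variance", {
  make_sample <- function(target, seeds) {
    matrix_sample(lapply(seeds, function(s)
      calculate_matrix(simulate_population(target, 100, seed = s))))
  }
  a <- make_sample(fix_diag(10, 1), 1:8)
  b <- make_sample(trait_matrix(diag(c(1, 10)), role = "covariance"), 11:18)
  res <- rs_projection(list(a = a, b = b), n_vectors = 1000, seed = 60)
  expect_gt(nrow(res$flags), 0)
  # the e1 direction must be among the flagged ones
  e1_like <- abs(res$directions[, 1]) > 0.95
  expect_true(any(e1_like))
  # identical samples flag nothing
  res0 <- rs_projection(list(a = a, b = a), n_vectors = 200, seed = 61)
  expect_equal(nrow(res0$flags), 0)
  # wider credibility flags a subset of narrower credibility
  res50 <- rs_projection(list(a = a, b = b), n_vectors = 300,
                         credible_level = 0.5, seed = 62)
  res95 <- rs_projection(list(a = a, b = b), n_vectors = 300,
                         credible_level = 0.95, seed = 62)
  expect_true(all(res95$flags$direction %in% res50$flags$direction))
})
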