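test_that("test_modularity recovers a planted block structure", {
  m <- modular_matrix(4, c(1, 1, 2, 2), r_within = 0.8, r_between = 0.2)
  membership <- data.frame(row.names = rownames(m),
                           first = c(1, 1, 0, 0), second = c(0, 0, 1, 1))
  res <- test_modularity(m, modularity_hypotheses(membership),
                         permutations = 99, seed = 1)
  full <- res$table[res$table$hypothesis == "full_model", ]
  expect_equal(full$avg_within, 0.8)
  expect_equal(full$avg_between, 0.2)
  expect_equal(full$avg_ratio, 4)
  expect_gt(full$mantel_cor, 0.9)
  # uniform matrix: no modular contrast
  u <- modular_matrix(4, c(1, 1, 2, 2), 0.5, 0.5)
  res_u <- test_modularity(u, modularity_hypotheses(membership),
                           permutations = 99, seed = 2)
  expect_equal(res_u$table$mhi, rep(0, nrow(res_u$table)))
  expect_equal(res_u$table$avg_ratio, rep(1, nrow(res_u$table)))
  expect_true(all(is.na(res_u$table$mantel_cor)))
  expect_match(res_u$notes, "Mantel undefined", all = FALSE)
})

test_that("a crossed hypothesis finds no support", {
  over_seeds <- vapply(1:5, function(s) {
    m <- modular_matrix(4, c(1, 1, 2, 2), 0.8, 0.2)
    wrong <- modularity_hypotheses(data.frame(
      row.names = rownames(m), crossed_a = c(1, 0, 1, 0),
      crossed_b = c(0, 1, 0, 1)))
    res <- test_modularity(m, wrong, permutations = 199, seed = s)
    full <- res$table[res$table$hypothesis == "full_model", ]
    c(full$avg_ratio, full$p_value)
  }, numeric(2))
  expect_lt(mean(over_seeds[1, ]), 1.5)
  expect_gt(min(over_seeds[2, ]), 0.05)
})

test_that("degenerate hypotheses are skipped with a note", {
  m <- modular_matrix(4, c(1, 1, 2, 2), 0.8, 0.2)
  all_ones <- matrix(1, 4, 4) - diag(4)
  dimnames(all_ones) <- dimnames(m)
  expect_error(test_modularity(m, list(flat = all_ones)), "no testable")
  res <- test_modularity(m, list(
    flat = all_ones,
    ok = modularity_hypotheses(data.frame(row.names = rownames(m),
                                          a = c(1, 1, 0, 0)))$a),
    permutations = 49, seed = 3)
  expect_match(res$notes, "no contrast", all = FALSE)
})

test_that("greedy L-modularity matches exhaustive search on planted blocks", {
  planted <- rep(1:2, each = 4)
  m <- modular_matrix(8, planted, 0.7, 0.05)
  greedy <- l_modularity(m, seed = 4)
  exact <- l_modularity(m, optimizer = "exhaustive")
  expect_equal(greedy$l_value, exact$l_value, tolerance = 1e-10)
  expect_equal(unname(greedy$partition), planted)
  expect_equal(unname(exact$partition), planted)
})

test_that("the single-module partition scores exactly zero", {
  m <- fix_corr(6, seed = 5)
  res <- l_modularity(m, seed = 6)
  w <- abs(unclass(m)); diag(w) <- 0
  ki <- rowSums(w)
  single_l <- sum(w - outer(ki, ki) / sum(ki))
  expect_lt(abs(single_l), 1e-10)
  # and the optimizer never returns less than that
  expect_gte(res$l_value, -1e-10)
})

test_that("uniform correlation favours a single module", {
  u <- modular_matrix(4, rep(1, 4), 0.5, 0.5)
  res <- l_modularity(u, optimizer = "exhaustive")
  expect_lte(res$l_value, 1e-12)
  expect_equal(length(unique(res$partition)), 1)
})

test_that("trait order only relabels the partition", {
  m <- modular_matrix(6, c(1, 1, 2, 2, 1, 2), 0.6, 0.1)
  res <- l_modularity(m, optimizer = "exhaustive")
  perm <- c(3, 6, 1, 4, 2, 5)
  mp <- trait_matrix(unclass(m)[perm, perm], role = "correlation")
  res_p <- l_modularity(mp, optimizer = "exhaustive")
  expect_equal(res_p$l_value, res$l_value, tolerance = 1e-10)
  # same grouping after permutation, up to module labels
  expect_equal(outer(res_p$partition, res_p$partition, `==`),
               outer(res$partition[perm], res$partition[perm], `==`),
               ignore_attr = TRUE)
})

test_that("zero matrices collapse to one module with a note", {
  z <- trait_matrix(diag(4), role = "correlation")
  res <- l_modularity(z)
  expect_equal(res$l_value, 0)
  expect_equal(length(unique(res$partition)), 1)
  expect_match(res$notes, "zero", all = FALSE)
})

test_that("remove_size projects out the leading component", {
  # dominant size axis: all-positive loadings
  m <- trait_matrix(0.6 + 0.4 * diag(5), role = "covariance")
  rs <- remove_size(m)
  v1 <- eigen_sorted(m)$vectors[, 1]
  expect_lt(abs(t(v1) %*% unclass(rs$residual) %*% v1), 1e-10)
  # rank drops by exactly one
  ev <- eigen_sorted(rs$residual)$values
  expect_equal(sum(ev > 1e-10 * max(ev)), 4)
  # rank-1 size component restores the original
  rebuilt <- unclass(rs$residual) + tcrossprod(rs$size_vector)
  expect_lt(frob(rebuilt, unclass(m)), 1e-10)
  # residual leading eigenvalue falls to the second original one
  d <- fix_diag(50, 5, 1)
  expect_equal(eigen_sorted(suppressWarnings(remove_size(d))$residual
               )$values[1], 5, tolerance = 1e-10)
  # mixed-sign PC1 triggers the warning
  contrast <- trait_matrix(matrix(c(2, -1, -1, 2), 2, 2),
                           role = "covariance")
  expect_warning(remove_size(contrast), "one sign")
})
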