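#' Random Skewers matrix comparison
#'
#' Applies the same set of random unit selection gradients beta to both
#' matrices through the Lande equation (dz = G beta) and averages the
#' cosine between the two response vectors:
#' RS(A, B) = E\[cos(A beta, B beta)\]. Values run from -1 (opposite
#' structures) through 0 (distinct structures) to 1 (identical response
#' structure). Significance is judged against an empirical null of
#' cosines between independent random unit vectors of the same
#' dimension: the comparison is flagged significant when the observed
#' mean exceeds the null's 95th percentile.
#'
#' @param a,b conformable trait matrices (same labels).
#' @param n_vectors number of random gradients.
#' @param seed optional integer seed.
#' @param betas optional fixed matrix of unit gradients (rows); when
#'   given, `n_vectors` and `seed` are ignored. Sharing one beta set
#'   across several comparisons makes them exactly comparable.
#' @param null_draws size of the random-cosine null sample.
#' @return `comparison_result`: list with `method`, `value`, `p_value`,
#'   `significant`, `null_quantile_95`, `n_vectors`, `seed`.
#' @export
#' @examples
#' g <- random_spd_matrix(4, seed = 1)
#' random_skewers(g, g, n_vectors = 100, seed = 2)$value  # exactly 1
random_skewers <- function(a, b, n_vectors = 1000, seed = NULL,
                           betas = NULL, null_draws = 10000) {
  a <- as_trait_matrix(a); b <- as_trait_matrix(b)
  check_pair(a, b)
  p <- nrow(a)
  if (is.null(betas)) betas <- random_unit_vectors(p, n_vectors, seed = seed)
  n_vectors <- nrow(betas)
  ra <- betas %*% unclass_tm(a)   # row i = A beta_i (A symmetric)
  rb <- betas %*% unclass_tm(b)
  cosines <- rowSums(ra * rb) /
    (sqrt(rowSums(ra^2)) * sqrt(rowSums(rb^2)))
  value <- mean(cosines)
  null_seed <- if (is.null(seed)) NULL else seed + 1L
  null_cos <- with_opt_seed(null_seed, {
    u <- matrix(stats::rnorm(null_draws * p), null_draws, p)
    v <- matrix(stats::rnorm(null_draws * p), null_draws, p)
    rowSums(u * v) / (sqrt(rowSums(u^2)) * sqrt(rowSums(v^2)))
  })
  q95 <- stats::quantile(null_cos, 0.95, names = FALSE)
  comparison_result(
    method = "random_skewers", value = value,
    p_value = mean(null_cos >= value),
    significant = value > q95,
    null_quantile_95 = q95,
    n_vectors = n_vectors, seed = seed)
}

comparison_result <- function(method, value, ...) {
  structure(c(list(method = method, value = value), list(...)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: %.6g", x$method, x$value))
  if (!is.null(x$p_value)) cat(sprintf("  (p = %.4g)", x$p_value))
  cat("\n")
  invisible(x)
}

#' Mantel correlation between two correlation matrices
#'
#' Pearson correlation of the below-diagonal elements, with significance
#' by a permutation scheme: one random relabelling of the traits is
#' applied jointly to the rows and columns of `b` and the element-wise
#' correlation recomputed; the p-value is the add-one proportion of
#' permuted statistics at least as large as the observed one,
#' p = (1 + #\{perm >= obs\}) / (permutations + 1). Covariance input is
#' refused: differing variances inflate the element-wise correlation
#' through scale alone, so the test is only meaningful on correlation
#' matrices.
#'
#' @param a,b conformable correlation matrices.
#' @param permutations number of row/column permutations.
#' @param seed optional integer seed.
#' @return `comparison_result` with `value`, `p_value`, `permutations`.
#' @export
mantel_cor <- function(a, b, permutations = 999, seed = NULL) {
  a <- as_trait_matrix(a); b <- as_trait_matrix(b)
  if (matrix_role(a) != "correlation" || matrix_role(b) != "correlation")
    stop("mantel_cor is defined for correlation matrices only: ",
         "covariances of different scale inflate element-wise correlations; ",
         "use to_correlation() first", call. = FALSE)
  check_pair(a, b)
  p <- nrow(a)
  if (p < 3)
    stop("mantel_cor needs at least 3 traits", call. = FALSE)
  low <- lower.tri(a)
  av <- as.matrix(a)[low]
  bm <- as.matrix(b)
  if (stats::sd(av) == 0 || stats::sd(bm[low]) == 0)
    stop("constant below-diagonal elements; Mantel correlation undefined",
         call. = FALSE)
  obs <- stats::cor(av, bm[low])
  perm_stats <- with_opt_seed(seed, {
    vapply(seq_len(permutations), function(i) {
      # the identity relabelling reproduces the observed statistic and
      # is excluded from the null draws (it would tie at the observed
      # value for self-comparisons)
      repeat {
        idx <- sample.int(p)
        if (!identical(idx, seq_len(p))) break
      }
      stats::cor(av, bm[idx, idx][low])
    }, numeric(1))
  })
  comparison_result(
    method = "mantel", value = obs,
    p_value = (1 + sum(perm_stats >= obs)) / (permutations + 1),
    permutations = permutations, seed = seed)
}

#' Krzanowski subspace correlation
#'
#' Measures how much the subspaces spanned by the leading k principal
#' components of two matrices overlap:
#' Krz(A, B) = (1/k) sum_\{i<=k\} sum_\{j<=k\} cos^2(PC_i^A, PC_j^B).
#' The default retained size is k = floor(p/2) - 1 (at least 1), i.e.
#' just under half the dimensions. Ranges from 0 (orthogonal subspaces)
#' to 1 (identical subspaces); suitable for covariance or correlation
#' matrices.
#'
#' @param a,b conformable trait matrices.
#' @param k retained subspace size, 1 <= k < p.
#' @return `comparison_result` with `value` and `k`.
#' @export
krz_cor <- function(a, b, k = NULL) {
  a <- as_trait_matrix(a); b <- as_trait_matrix(b)
  check_pair(a, b)
  p <- nrow(a)
  if (is.null(k)) k <- max(1, floor(p / 2) - 1)
  if (k < 1 || k >= p)
    stop(sprintf("k must satisfy 1 <= k < p (got k = %g, p = %d)", k, p),
         call. = FALSE)
  va <- eigen_sorted(a)$vectors[, seq_len(k), drop = FALSE]
  vb <- eigen_sorted(b)$vectors[, seq_len(k), drop = FALSE]
  value <- sum(crossprod(va, vb)^2) / k
  comparison_result(method = "krz", value = value, k = k)
}

#' Eigenvalue-weighted PCA similarity
#'
#' Extends the Krzanowski idea to all principal components, weighting
#' each squared cosine by the variance associated with the two
#' directions:
#' PCAsim(A, B) = sum_ij lambda_i^A lambda_j^B cos^2(PC_i^A, PC_j^B) /
#' sum_i lambda_i^A lambda_i^B, with eigenvalues sorted descending in
#' the denominator pairing. Ranges from 0 (no shared variation) to 1
#' (identical variation); self-similarity is exactly 1. Tracks the
#' random-skewers comparison closely at a fraction of the cost.
#'
#' @param a,b conformable covariance matrices.
#' @return `comparison_result` with `value`.
#' @export
pca_similarity <- function(a, b) {
  a <- as_trait_matrix(a); b <- as_trait_matrix(b)
  check_pair(a, b)
  ea <- eigen_sorted(a); eb <- eigen_sorted(b)
  cos2 <- crossprod(ea$vectors, eb$vectors)^2
  num <- sum(outer(ea$values, eb$values) * cos2)
  den <- sum(ea$values * eb$values)
  comparison_result(method = "pca_similarity", value = num / den)
}

# log-density of MVN via Cholesky (no dependency needed for this)
mvn_logdensity <- function(x, mean, chol_sigma) {
  p <- ncol(x)
  centred <- sweep(x, 2, mean)
  z <- backsolve(chol_sigma, t(centred), transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(chol_sigma))) -
    0.5 * p * log(2 * pi)
}

#' Misclassification probability between two Gaussian distributions
#'
#' Monte-Carlo estimate of q(f, g) = E_f\[ g(x) / (f(x) + g(x)) \], the
#' probability that a draw from f is misclassified as coming from g.
#' q = 1/2 for indistinguishable distributions, q -> 0 for fully
#' separated ones. The estimate is symmetrized:
#' q = (q_\{f->g\} + q_\{g->f\}) / 2.
#'
#' @param cov_f,cov_g SPD covariance matrices.
#' @param mean_f,mean_g mean vectors (default zero).
#' @param draws Monte-Carlo draws per direction.
#' @param seed optional integer seed.
#' @return list with `q`, `se` (MC standard error of q).
#' @export
overlap_probability <- function(cov_f, cov_g,
                                mean_f = NULL, mean_g = NULL,
                                draws = 10000, seed = NULL) {
  cov_f <- unclass_tm_safe(cov_f); cov_g <- unclass_tm_safe(cov_g)
  p <- nrow(cov_f)
  if (is.null(mean_f)) mean_f <- rep(0, p)
  if (is.null(mean_g)) mean_g <- rep(0, p)
  cf <- chol(cov_f); cg <- chol(cov_g)
  with_opt_seed(seed, {
    one_way <- function(mu_from, chol_from, mu_to, chol_to) {
      x <- MASS::mvrnorm(draws, mu = mu_from,
                         Sigma = crossprod(chol_from))
      if (draws == 1) x <- matrix(x, nrow = 1)
      lf <- mvn_logdensity(x, mu_from, chol_from)
      lg <- mvn_logdensity(x, mu_to, chol_to)
      1 / (1 + exp(lf - lg))   # g/(f+g) computed stably in log space
    }
    w1 <- one_way(mean_f, cf, mean_g, cg)
    w2 <- one_way(mean_g, cg, mean_f, cf)
    q <- (mean(w1) + mean(w2)) / 2
    se <- 0.5 * sqrt(stats::var(w1) / draws + stats::var(w2) / draws)
    list(q = q, se = se)
  })
}

#' Distances between covariance matrices
#'
#' Two distances in use in the comparative literature:
#' * `overlap`: d = sqrt(1 - 2 q), where q is the symmetrized
#'   probability of misclassifying a draw from the zero-mean Gaussian
#'   defined by one matrix as coming from the other (see
#'   [overlap_probability()]). d = 0 for indistinguishable
#'   distributions; the square root makes d a metric.
#' * `riemann`: d = sqrt(sum_i log^2 lambda_i) over the eigenvalues
#'   lambda_i of solve(A) %*% B — the affine-invariant Riemannian metric
#'   on SPD matrices, unchanged under any change of basis
#'   (d(TAT', TBT') = d(A, B) for invertible T).
#'
#' @param a,b SPD trait matrices.
#' @param method `"overlap"` or `"riemann"`.
#' @param mc_draws Monte-Carlo draws per direction (overlap only).
#' @param seed optional integer seed (overlap only).
#' @return `comparison_result` with `value` (the distance) and, for
#'   overlap, `q` and its `se`.
#' @export
matrix_distance <- function(a, b, method = c("riemann", "overlap"),
                            mc_draws = 10000, seed = NULL) {
  method <- match.arg(method)
  a <- as_trait_matrix(a); b <- as_trait_matrix(b)
  check_pair(a, b)
  ea <- eigen(unclass_tm(a), symmetric = TRUE, only.values = TRUE)$values
  eb <- eigen(unclass_tm(b), symmetric = TRUE, only.values = TRUE)$values
  if (min(ea) <= 0 || min(eb) <= 0)
    stop("matrix_distance requires positive-definite matrices",
         call. = FALSE)
  if (method == "riemann") {
    lam <- eigen(solve(unclass_tm(a), unclass_tm(b)),
                 only.values = TRUE)$values
    value <- sqrt(sum(log(Re(lam))^2))
    comparison_result(method = "riemann", value = value)
  } else {
    ov <- overlap_probability(a, b, draws = mc_draws, seed = seed)
    value <- sqrt(max(1 - 2 * ov$q, 0))
    comparison_result(method = "overlap", value = value,
                      q = ov$q, se = ov$se,
                      mc_draws = mc_draws, seed = seed)
  }
}

#' All-pairs matrix comparison table
#'
#' Compares every pair in a list of conformable matrices by one method.
#' The lower triangle holds raw comparison values. When per-matrix
#' repeatabilities are supplied, the upper triangle holds correlations
#' corrected by the geometric mean of the two repeatabilities (capped at
#' 1) and the diagonal holds the repeatabilities themselves; otherwise
#' the table is symmetric with self-comparisons on the diagonal.
#'
#' @param matrices named list of trait matrices (same labels).
#' @param method one of `"random_skewers"`, `"mantel"`, `"krz"`,
#'   `"pca_similarity"`.
#' @param repeatabilities optional numeric vector, one per matrix.
#' @param seed optional integer seed (stochastic methods).
#' @param ... passed to the comparison function.
#' @return square numeric matrix with matrix names on both dimensions.
#' @export
compare_all <- function(matrices,
                        method = c("random_skewers", "mantel", "krz",
                                   "pca_similarity"),
                        repeatabilities = NULL, seed = NULL, ...) {
  method <- match.arg(method)
  k <- length(matrices)
  if (k < 2) stop("need at least two matrices", call. = FALSE)
  mats <- lapply(matrices, as_trait_matrix)
  for (m in mats[-1]) check_pair(mats[[1]], m)
  if (!is.null(repeatabilities) && length(repeatabilities) != k)
    stop("one repeatability per matrix required", call. = FALSE)
  nm <- names(matrices)
  if (is.null(nm)) nm <- paste0("matrix_", seq_len(k))
  fn <- switch(method,
    random_skewers = function(x, y, s) random_skewers(x, y, seed = s, ...),
    mantel = function(x, y, s) mantel_cor(x, y, seed = s, ...),
    krz = function(x, y, s) krz_cor(x, y, ...),
    pca_similarity = function(x, y, s) pca_similarity(x, y, ...))
  out <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) for (j in seq_len(i - 1)) {
    s <- if (is.null(seed)) NULL else seed + i * k + j
    out[i, j] <- fn(mats[[i]], mats[[j]], s)$value
  }
  if (is.null(repeatabilities)) {
    out[upper.tri(out)] <- t(out)[upper.tri(out)]
    diag(out) <- 1
  } else {
    diag(out) <- repeatabilities
    for (i in seq_len(k)) for (j in seq_len(i - 1))
      out[j, i] <- corrected_correlation(
        out[i, j], repeatabilities[i], repeatabilities[j])$value
  }
  out
}
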