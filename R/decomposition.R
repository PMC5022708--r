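#' Selection Response Decomposition
#'
#' Localizes differences between two matrices at the trait level by
#' decomposing the response to selection. For a random unit gradient
#' beta, the i-th trait's response decomposes into the row vector
#' r_i = (A_ij beta_j)_j — direct selection (j = i) plus correlated
#' responses (j != i). For each trait the Pearson correlation between
#' r_i computed under A and under B is averaged over gradients
#' (mu_SRD_i) and its standard deviation recorded (sigma_SRD_i). Traits
#' whose correlated-response pattern agrees have high mu and low sigma;
#' traits driving the divergence have low mu and high sigma. Traits with
#' centered mu (mu minus the across-trait mean) below zero are flagged
#' as a reporting convenience — the raw scores are the result.
#'
#' @param a,b conformable trait matrices (p >= 2).
#' @param n_vectors number of random gradients.
#' @param seed optional integer seed.
#' @param betas optional fixed unit-gradient matrix (rows).
#' @return object of class `srd_result`: data.frame `scores` (trait,
#'   mu_srd, sigma_srd, centered_mu, flagged), `n_vectors`, `seed`.
#' @export
srd <- function(a, b, n_vectors = 1000, seed = NULL, betas = NULL) {
  a <- as_trait_matrix(a); b <- as_trait_matrix(b)
  check_pair(a, b)
  p <- nrow(a)
  if (p < 2)
    stop("srd needs at least 2 traits (correlations of length-1 vectors ",
         "are undefined)", call. = FALSE)
  if (is.null(betas)) betas <- random_unit_vectors(p, n_vectors, seed = seed)
  n_vectors <- nrow(betas)
  am <- unclass_tm(a); bm <- unclass_tm(b)
  cors <- matrix(NA_real_, n_vectors, p)
  for (v in seq_len(n_vectors)) {
    # term matrices: row i holds (A_ij beta_j)_j
    ta <- am * rep(betas[v, ], each = p)
    tb <- bm * rep(betas[v, ], each = p)
    for (i in seq_len(p)) cors[v, i] <- stats::cor(ta[i, ], tb[i, ])
  }
  mu <- colMeans(cors)
  sigma <- apply(cors, 2, stats::sd)
  centered <- mu - mean(mu)
  scores <- data.frame(trait = rownames(a), mu_srd = mu, sigma_srd = sigma,
                       centered_mu = centered, flagged = centered < 0)
  rownames(scores) <- NULL
  structure(list(scores = scores, n_vectors = n_vectors, seed = seed),
            class = "srd_result")
}

#' @export
print.srd_result <- function(x, ...) {
  cat(sprintf("SRD over %d gradients:\n", x$n_vectors))
  print(x$scores, digits = 4)
  invisible(x)
}

#' Riemannian (Frechet) mean of a matrix sample
#'
#' The geometric mean matrix M minimizing the sum of squared Riemannian
#' distances to the sample members, found by the standard fixed-point
#' iteration
#' M <- M^(1/2) exp(mean_i log(M^(-1/2) X_i M^(-1/2))) M^(1/2),
#' initialized at the arithmetic mean (always SPD). Convergence is
#' declared when the Frobenius norm of the mean log term drops to `tol`;
#' that term is the Riemannian gradient, so at convergence the
#' stationarity condition sum_i log(M^(-1/2) X_i M^(-1/2)) = 0 holds to
#' the same order.
#'
#' @param sample a `matrix_sample` (or list) of SPD matrices.
#' @param tol convergence tolerance on the mean log term.
#' @param max_iter iteration cap.
#' @return covariance `trait_matrix` with attributes `iterations` and
#'   `residual`.
#' @export
mean_matrix <- function(sample, tol = 1e-10, max_iter = 100) {
  if (!inherits(sample, "matrix_sample"))
    sample <- matrix_sample(sample)
  mats <- lapply(sample, unclass_tm)
  n <- length(mats)
  m <- Reduce(`+`, mats) / n
  for (it in seq_len(max_iter)) {
    ms <- matrix_sqrt(m)
    msi <- solve(ms)
    logs <- lapply(mats, function(x) matrix_log(msi %*% x %*% msi))
    grad <- Reduce(`+`, logs) / n
    resid <- sqrt(sum(grad^2))
    if (resid <= tol) {
      out <- trait_matrix(m, role = "covariance",
                          labels = rownames(sample[[1]]))
      attr(out, "iterations") <- it - 1L
      attr(out, "residual") <- resid
      return(out)
    }
    m <- ms %*% matrix_exp(grad) %*% ms
    m <- (m + t(m)) / 2
  }
  stop(sprintf(
    "mean_matrix did not converge in %d iterations (residual %g)",
    max_iter, resid), call. = FALSE)
}

# vectorize a symmetric matrix so the Euclidean inner product of the
# vectors equals the Frobenius inner product of the matrices:
# off-diagonal entries scaled by sqrt(2)
sym_vectorize <- function(x) {
  p <- nrow(x)
  low <- lower.tri(x)
  c(diag(x), sqrt(2) * x[low])
}

sym_unvectorize <- function(v, p) {
  x <- matrix(0, p, p)
  diag(x) <- v[seq_len(p)]
  x[lower.tri(x)] <- v[-seq_len(p)] / sqrt(2)
  x <- x + t(x) - diag(diag(x))
  x
}

#' Eigentensor decomposition of a matrix sample
#'
#' Characterizes how a set of covariance matrices varies. Each member
#' X_i is mapped to the tangent space at the sample's Riemannian mean M
#' by f(X) = log(M^(-1/2) X M^(-1/2)); the mapped (symmetric) matrices
#' are vectorized preserving the Frobenius inner product, their
#' covariance across the sample is eigendecomposed, and the eigenvectors
#' are un-vectorized into orthonormal symmetric matrices — the
#' eigentensors. Each sample member is then a combination of
#' eigentensors, scored by Frobenius inner products in the tangent
#' space, in direct analogy to principal component analysis.
#'
#' @param sample a `matrix_sample` (or list) of >= 2 SPD matrices.
#' @param tol,max_iter passed to [mean_matrix()].
#' @return object of class `tensor_basis`: list with `mean` (M),
#'   `eigentensors` (list of symmetric matrices, descending eigenvalue
#'   order), `eigenvalues`, `scores` (sample x eigentensor matrix),
#'   `m_inv_sqrt`, `m_sqrt`.
#' @export
eigentensor_decomposition <- function(sample, tol = 1e-10,
                                      max_iter = 100) {
  if (!inherits(sample, "matrix_sample"))
    sample <- matrix_sample(sample)
  if (length(sample) < 2)
    stop("eigentensor decomposition needs at least 2 matrices",
         call. = FALSE)
  p <- nrow(sample[[1]])
  m <- mean_matrix(sample, tol = tol, max_iter = max_iter)
  ms <- matrix_sqrt(m)
  msi <- solve(ms)
  mapped <- lapply(sample, function(x)
    matrix_log(msi %*% unclass_tm(x) %*% msi))
  vecs <- t(vapply(mapped, sym_vectorize, numeric(p * (p + 1) / 2)))
  cv <- stats::cov(vecs)
  e <- eigen(cv, symmetric = TRUE)
  ets <- lapply(seq_len(ncol(e$vectors)), function(j)
    sym_unvectorize(e$vectors[, j], p))
  scores <- vapply(ets, function(et)
    vapply(mapped, function(f) sum(f * et), numeric(1)),
    numeric(length(sample)))
  structure(list(mean = m, eigentensors = ets,
                 eigenvalues = e$values, scores = scores,
                 m_sqrt = ms, m_inv_sqrt = msi,
                 labels = rownames(sample[[1]])),
            class = "tensor_basis")
}

#' @export
print.tensor_basis <- function(x, ...) {
  cat(sprintf("eigentensor basis: %d traits, %d eigentensors\n",
              nrow(x$mean), length(x$eigentensors)))
  cat("eigenvalues:", format(x$eigenvalues, digits = 4), "\n")
  invisible(x)
}

#' Project a matrix onto an eigentensor basis
#'
#' Maps `x` to the tangent space at the basis's mean matrix (same
#' f(X) = log(M^(-1/2) X M^(-1/2)) used to build the basis) and returns
#' its Frobenius inner products with each eigentensor. The mean itself
#' scores zero on every eigentensor.
#'
#' @param x SPD trait matrix of the basis's dimension.
#' @param basis a `tensor_basis`.
#' @return numeric score vector, one entry per eigentensor.
#' @export
project_matrix <- function(x, basis) {
  x <- as_trait_matrix(x)
  if (nrow(x) != nrow(basis$mean))
    stop("matrix dimension does not match the basis", call. = FALSE)
  f <- matrix_log(basis$m_inv_sqrt %*% unclass_tm(x) %*% basis$m_inv_sqrt)
  vapply(basis$eigentensors, function(et) sum(f * et), numeric(1))
}

#' Rebuild a matrix from eigentensor scores
#'
#' Inverse of [project_matrix()]: X = M^(1/2) exp(sum_i s_i ET_i)
#' M^(1/2). The exponential map guarantees an SPD result for any finite
#' scores, so truncated score vectors give valid covariance matrices —
#' useful for visualizing what variation an eigentensor encodes.
#'
#' @param scores numeric vector, length at most the number of
#'   eigentensors.
#' @param basis a `tensor_basis`.
#' @return SPD covariance `trait_matrix`.
#' @export
revert_matrix <- function(scores, basis) {
  k <- length(scores)
  if (k > length(basis$eigentensors))
    stop("more scores than eigentensors", call. = FALSE)
  acc <- matrix(0, nrow(basis$mean), nrow(basis$mean))
  for (i in seq_len(k)) acc <- acc + scores[i] * basis$eigentensors[[i]]
  out <- basis$m_sqrt %*% matrix_exp(acc) %*% basis$m_sqrt
  out <- (out + t(out)) / 2
  trait_matrix(out, role = "covariance", labels = basis$labels)
}

#' Directional variance comparison across posterior matrix samples
#'
#' Random-skewers projection: for each of `n_vectors` random unit
#' directions beta, the posterior distribution of the variance
#' beta' G beta is computed for every population's matrix sample;
#' directions where the equal-tailed credible intervals of two
#' populations do not overlap are flagged as showing a credible
#' difference in the amount of variation. Most informative when the
#' compared matrices have similar overall scale.
#'
#' @param samples named list of `matrix_sample` objects (>= 2
#'   populations, common dimension, >= 2 draws each).
#' @param n_vectors number of random directions.
#' @param credible_level width of the equal-tailed intervals.
#' @param seed optional integer seed.
#' @return object of class `rs_projection`: list with `directions`
#'   (matrix of flagged unit vectors), `flags` (data.frame: direction
#'   index, population pair, interval endpoints), `intervals` (array
#'   direction x population x \[lo, hi\]), `n_vectors`, `credible_level`.
#' @export
rs_projection <- function(samples, n_vectors = 1000,
                          credible_level = 0.95, seed = NULL) {
  if (length(samples) < 2)
    stop("need at least 2 populations", call. = FALSE)
  samples <- lapply(samples, function(s)
    if (inherits(s, "matrix_sample")) s else matrix_sample(s))
  if (any(vapply(samples, length, integer(1)) < 2))
    stop("each population needs at least 2 posterior draws", call. = FALSE)
  p <- nrow(samples[[1]][[1]])
  for (s in samples) check_pair(samples[[1]][[1]], s[[1]])
  pop_names <- names(samples)
  if (is.null(pop_names)) pop_names <- paste0("pop_", seq_along(samples))
  betas <- random_unit_vectors(p, n_vectors, seed = seed)
  alpha <- (1 - credible_level) / 2
  n_pop <- length(samples)
  intervals <- array(NA_real_, c(n_vectors, n_pop, 2),
                     dimnames = list(NULL, pop_names, c("lo", "hi")))
  for (k in seq_len(n_pop)) {
    # variance along each beta for each posterior draw: draws x vectors
    vv <- vapply(samples[[k]], function(g)
      rowSums((betas %*% unclass_tm(g)) * betas), numeric(n_vectors))
    qs <- apply(vv, 1, stats::quantile, probs = c(alpha, 1 - alpha),
                names = FALSE)
    intervals[, k, "lo"] <- qs[1, ]
    intervals[, k, "hi"] <- qs[2, ]
  }
  flags <- list()
  for (i in seq_len(n_pop - 1)) for (j in (i + 1):n_pop) {
    sep <- intervals[, i, "lo"] > intervals[, j, "hi"] |
           intervals[, j, "lo"] > intervals[, i, "hi"]
    for (d in which(sep))
      flags[[length(flags) + 1]] <- data.frame(
        direction = d, pop_a = pop_names[i], pop_b = pop_names[j],
        lo_a = intervals[d, i, "lo"], hi_a = intervals[d, i, "hi"],
        lo_b = intervals[d, j, "lo"], hi_b = intervals[d, j, "hi"])
  }
  flags <- if (length(flags)) do.call(rbind, flags) else
    data.frame(direction = integer(), pop_a = character(),
               pop_b = character(), lo_a = numeric(), hi_a = numeric(),
               lo_b = numeric(), hi_b = numeric())
  structure(list(directions = betas[unique(flags$direction), ,
                                    drop = FALSE],
                 flags = flags, intervals = intervals,
                 n_vectors = n_vectors, credible_level = credible_level,
                 seed = seed),
            class = "rs_projection")
}

#' @export
print.rs_projection <- function(x, ...) {
  cat(sprintf(
    "RS projection: %d directions, %d flagged at %.0f%% credibility\n",
    x$n_vectors, nrow(x$flags), 100 * x$credible_level))
  invisible(x)
}
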