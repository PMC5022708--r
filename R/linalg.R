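#' Eigendecomposition with a fixed sign convention
#'
#' Wraps [base::eigen()] for symmetric matrices and removes the sign
#' ambiguity of eigenvectors by forcing the largest-magnitude entry of
#' each eigenvector to be positive. Eigenvalues come out in descending
#' order. A stable sign convention matters downstream: the constraints
#' statistic and subspace comparisons take cosines against these vectors.
#'
#' @param m symmetric numeric matrix.
#' @return list with `values` (descending) and `vectors` (orthonormal,
#'   columns, sign-fixed).
#' @export
eigen_sorted <- function(m) {
  m <- as.matrix(m)
  e <- eigen(unclass_tm_safe(m), symmetric = TRUE)
  v <- e$vectors
  for (j in seq_len(ncol(v))) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) v[, j] <- -v[, j]
  }
  rownames(v) <- rownames(m)
  list(values = e$values, vectors = v)
}

unclass_tm_safe <- function(x) {
  if (inherits(x, "trait_matrix")) unclass_tm(x) else as.matrix(x)
}

# apply f to the spectrum of a symmetric matrix
spectral_map <- function(m, f, require_pd = FALSE, op = "spectral_map") {
  e <- eigen_sorted(m)
  if (require_pd && min(e$values) <= 0)
    stop(sprintf("%s requires a positive-definite matrix (min eigenvalue %g)",
                 op, min(e$values)), call. = FALSE)
  out <- e$vectors %*% (f(e$values) * t(e$vectors))
  out <- (out + t(out)) / 2
  dimnames(out) <- dimnames(as.matrix(m))
  out
}

#' Matrix logarithm, exponential and square root
#'
#' Spectral versions for symmetric matrices: the scalar function is
#' applied to the eigenvalues and the matrix is rebuilt on the original
#' eigenvectors. `matrix_log()` and `matrix_sqrt()` require strictly
#' positive eigenvalues; `matrix_exp()` accepts any symmetric matrix.
#' These are the workhorses of the Riemannian geometry of SPD matrices
#' used by the mean matrix and the eigentensor decomposition.
#'
#' @param m symmetric numeric matrix.
#' @return symmetric matrix of the same dimension.
#' @export
matrix_log <- function(m) spectral_map(m, log, require_pd = TRUE,
                                       op = "matrix_log")

#' @rdname matrix_log
#' @export
matrix_exp <- function(m) spectral_map(m, exp)

#' @rdname matrix_log
#' @export
matrix_sqrt <- function(m) spectral_map(m, sqrt, require_pd = TRUE,
                                        op = "matrix_sqrt")

#' Random unit selection gradients
#'
#' Draws `n` vectors i.i.d. uniform on the unit (p-1)-sphere (standard
#' normal draws normalized to unit Euclidean norm). These are the random
#' selection gradients ("skewers") shared by the random-skewers
#' comparison, the selection-response statistics and the SRD.
#'
#' @param p dimension.
#' @param n number of vectors.
#' @param seed optional integer; when given the draw is reproducible and
#'   the caller's RNG state is untouched.
#' @return n x p matrix, one unit vector per row.
#' @export
random_unit_vectors <- function(p, n, seed = NULL) {
  stopifnot(p >= 1, n >= 1)
  draw <- function() {
    b <- matrix(stats::rnorm(n * p), nrow = n, ncol = p)
    b / sqrt(rowSums(b^2))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# run expr under an optional local seed without touching global RNG state
with_opt_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}
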