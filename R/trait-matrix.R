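#' Trait covariance / correlation matrices
#'
#' A `trait_matrix` is a plain numeric p x p matrix carrying trait labels
#' (dimnames) and a `role` attribute, either `"covariance"` or
#' `"correlation"`. It is the central object of the package: G- and
#' P-matrices, pooled within-group matrices, between-group matrices and
#' hypothesis matrices are all stored this way. All binary operations
#' require identical label sets in identical order; use
#' [reorder_traits()] to align two matrices.
#'
#' Validation enforces symmetry (maximum absolute asymmetry 1e-10 after
#' construction; asymmetry up to 1e-8 is repaired by averaging the two
#' triangles), and role-specific invariants: correlation matrices must
#' have unit diagonal and entries in \[-1, 1\]; covariance matrices must be
#' positive semi-definite within a tolerance of 1e-10 times the trace.
#'
#' @param values numeric p x p matrix.
#' @param role `"covariance"` or `"correlation"`.
#' @param labels optional character vector of p trait names; defaults to
#'   existing dimnames or `"trait_1"` ... `"trait_p"`.
#' @return a validated `trait_matrix`.
#' @export
#' @examples
#' trait_matrix(diag(2), role = "correlation")
trait_matrix <- function(values, role = c("covariance", "correlation"),
                         labels = NULL) {
  role <- match.arg(role)
  values <- as.matrix(values)
  if (!is.numeric(values) || nrow(values) != ncol(values))
    stop("trait_matrix requires a square numeric matrix", call. = FALSE)
  p <- nrow(values)
  if (is.null(labels)) {
    labels <- rownames(values)
    if (is.null(labels)) labels <- paste0("trait_", seq_len(p))
  }
  if (length(labels) != p)
    stop("labels length must match matrix dimension", call. = FALSE)
  asym <- max(abs(values - t(values)))
  scale <- max(abs(values), 1)
  if (asym > 1e-8 * scale)
    stop(sprintf("matrix is asymmetric (max |a_ij - a_ji| = %g)", asym),
         call. = FALSE)
  values <- (values + t(values)) / 2
  dimnames(values) <- list(labels, labels)
  if (role == "correlation") {
    if (any(abs(values) > 1 + 1e-12))
      stop("correlation matrix has entries outside [-1, 1]", call. = FALSE)
    diag(values) <- 1
  } else {
    ev <- eigen(values, symmetric = TRUE, only.values = TRUE)$values
    tol <- 1e-10 * max(sum(diag(values)), 1)
    if (min(ev) < -tol)
      stop(sprintf(
        "covariance matrix is not positive semi-definite (min eigenvalue %g)",
        min(ev)), call. = FALSE)
  }
  structure(values, role = role, class = c("trait_matrix", "matrix", "array"))
}

#' @rdname trait_matrix
#' @param x object to test or coerce.
#' @export
is_trait_matrix <- function(x) inherits(x, "trait_matrix")

#' @rdname trait_matrix
#' @export
matrix_role <- function(x) {
  r <- attr(x, "role")
  if (!is.null(r)) return(r)
  # heuristic for bare matrices: unit diagonal and bounded entries
  if (all(abs(diag(as.matrix(x)) - 1) < 1e-12) && all(abs(x) <= 1 + 1e-12))
    "correlation" else "covariance"
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat(sprintf("trait_matrix (%s), %d traits\n", matrix_role(x), nrow(x)))
  print(unclass_tm(x), ...)
  invisible(x)
}

# strip class/role for plain matrix arithmetic; keeps dimnames
unclass_tm <- function(x) {
  y <- as.matrix(x)
  attr(y, "role") <- NULL
  attr(y, "class") <- NULL
  y
}

# coerce to validated trait_matrix, inferring role when absent
as_trait_matrix <- function(x, role = NULL) {
  if (is_trait_matrix(x) && is.null(role)) return(x)
  if (is.null(role)) role <- matrix_role(x)
  trait_matrix(as.matrix(x), role = role)
}

#' Reorder a trait matrix to a given label order
#'
#' @param m a `trait_matrix` (or labelled matrix).
#' @param labels character vector, a permutation of `rownames(m)`.
#' @return the matrix with rows and columns in the requested order.
#' @export
reorder_traits <- function(m, labels) {
  if (!setequal(rownames(m), labels) || length(labels) != nrow(m))
    stop("labels must be a permutation of the matrix trait labels",
         call. = FALSE)
  out <- as.matrix(m)[labels, labels, drop = FALSE]
  trait_matrix(out, role = matrix_role(m))
}

# require two matrices to be conformable with matching labels
check_pair <- function(a, b) {
  if (nrow(a) != nrow(b))
    stop("matrices have different dimensions", call. = FALSE)
  la <- rownames(a); lb <- rownames(b)
  if (!is.null(la) && !is.null(lb) && !identical(la, lb)) {
    if (setequal(la, lb))
      stop("matrices have the same labels in different order; ",
           "use reorder_traits()", call. = FALSE)
    stop("matrices have different trait labels", call. = FALSE)
  }
  invisible(TRUE)
}

#' Convert a covariance matrix to a correlation matrix
#'
#' Standardizes a covariance matrix to unit diagonal,
#' r_ij = a_ij / sqrt(a_ii a_jj), via [stats::cov2cor()].
#'
#' @param m covariance `trait_matrix` with strictly positive diagonal.
#' @return correlation `trait_matrix`.
#' @export
to_correlation <- function(m) {
  if (matrix_role(m) == "correlation") return(as_trait_matrix(m))
  if (any(diag(as.matrix(m)) <= 0))
    stop("covariance matrix has non-positive diagonal entries", call. = FALSE)
  trait_matrix(stats::cov2cor(unclass_tm(as_trait_matrix(m))),
               role = "correlation", labels = rownames(m))
}
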