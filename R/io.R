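#' Read and write labelled square matrices
#'
#' The on-disk format is a plain CSV whose first row and first column
#' hold the trait labels and whose body is the square numeric matrix
#' ('.' decimal, UTF-8). On read, asymmetry up to 1e-8 (CSV round-trip
#' noise) is repaired by averaging the two triangles; anything larger is
#' an error rather than silently fixed.
#'
#' @param path file path.
#' @param role `"covariance"` or `"correlation"`.
#' @return `read_matrix()`: a validated [trait_matrix()].
#' @export
read_matrix <- function(path, role = c("covariance", "correlation")) {
  role <- match.arg(role)
  df <- utils::read.csv(path, header = TRUE, row.names = 1,
                        check.names = FALSE)
  if (nrow(df) != ncol(df))
    stop(sprintf("matrix file '%s' is not square (%d x %d body)",
                 path, nrow(df), ncol(df)), call. = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m))
    stop(sprintf("matrix file '%s' has a non-numeric body", path),
         call. = FALSE)
  trait_matrix(m, role = role, labels = rownames(df))
}

#' @rdname read_matrix
#' @param m matrix to write.
#' @export
write_matrix <- function(m, path) {
  utils::write.csv(as.data.frame(as.matrix(m)), path, row.names = TRUE)
  invisible(path)
}

#' Read an individual-level measurement table
#'
#' Expected columns: `individual` (id), optional `replicate` (id),
#' zero or more categorical columns prefixed `factor_`, and the
#' remaining numeric columns are traits. Missing trait values are an
#' error; no imputation is done.
#'
#' @param path CSV file path.
#' @return a `data.frame` with attribute `trait_names`.
#' @export
read_individual_table <- function(path) {
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                        stringsAsFactors = FALSE)
  validate_individual_table(df)
}

#' @rdname read_individual_table
#' @param df data.frame in the layout above.
#' @export
validate_individual_table <- function(df) {
  if (!"individual" %in% names(df))
    stop("individual table needs an 'individual' column", call. = FALSE)
  reserved <- c("individual", "replicate")
  factor_cols <- grep("^factor_", names(df), value = TRUE)
  trait_cols <- setdiff(names(df), c(reserved, factor_cols))
  if (length(trait_cols) == 0)
    stop("individual table has no trait columns", call. = FALSE)
  for (tc in trait_cols) {
    if (!is.numeric(df[[tc]]))
      stop(sprintf("trait column '%s' is not numeric", tc), call. = FALSE)
    if (anyNA(df[[tc]]))
      stop(sprintf("trait column '%s' has missing values", tc), call. = FALSE)
  }
  if (length(unique(df$individual)) < 2)
    stop("need at least 2 individuals", call. = FALSE)
  attr(df, "trait_names") <- trait_cols
  attr(df, "factor_names") <- factor_cols
  df
}

trait_names <- function(df) {
  tn <- attr(df, "trait_names")
  if (is.null(tn)) tn <- attr(validate_individual_table(df), "trait_names")
  tn
}

#' Read a sample (set) of same-sized matrices
#'
#' Accepts either a directory of square-matrix CSVs (read in lexical
#' order) or a single stacked CSV with a `sample` index column, a
#' `trait` row-label column, and one column per trait. All members must
#' share dimension and labels.
#'
#' @param path directory or stacked CSV.
#' @param role matrix role for every member.
#' @return a `matrix_sample`: list of [trait_matrix()] with attribute
#'   `origin = "user"`.
#' @export
read_matrix_sample <- function(path, role = c("covariance", "correlation")) {
  role <- match.arg(role)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.csv$", full.names = TRUE))
    if (length(files) == 0)
      stop(sprintf("no CSV files in '%s'", path), call. = FALSE)
    mats <- lapply(files, read_matrix, role = role)
  } else {
    df <- utils::read.csv(path, header = TRUE, check.names = FALSE)
    if (!all(c("sample", "trait") %in% names(df)))
      stop("stacked sample CSV needs 'sample' and 'trait' columns",
           call. = FALSE)
    mats <- lapply(split(df, df$sample), function(d) {
      m <- as.matrix(d[, setdiff(names(d), c("sample", "trait")),
                       drop = FALSE])
      rownames(m) <- d$trait
      trait_matrix(m[, rownames(m), drop = FALSE], role = role)
    })
    names(mats) <- NULL
  }
  matrix_sample(mats, origin = "user")
}

#' Construct a validated matrix sample
#'
#' @param matrices list of matrices (coerced to [trait_matrix()]).
#' @param origin provenance tag: bootstrap, montecarlo, posterior or user.
#' @export
matrix_sample <- function(matrices,
                          origin = c("user", "bootstrap", "montecarlo",
                                     "posterior")) {
  origin <- match.arg(origin)
  if (length(matrices) == 0) stop("empty matrix sample", call. = FALSE)
  mats <- lapply(matrices, as_trait_matrix)
  p <- nrow(mats[[1]]); labs <- rownames(mats[[1]])
  role <- matrix_role(mats[[1]])
  for (m in mats) {
    if (nrow(m) != p)
      stop("matrix sample mixes dimensions", call. = FALSE)
    if (!identical(rownames(m), labs))
      stop("matrix sample mixes trait labels", call. = FALSE)
    if (matrix_role(m) != role)
      stop("matrix sample mixes covariance and correlation roles",
           call. = FALSE)
  }
  structure(mats, origin = origin, class = "matrix_sample")
}

#' @export
print.matrix_sample <- function(x, ...) {
  cat(sprintf("matrix_sample: %d matrices of %d traits (%s, origin %s)\n",
              length(x), nrow(x[[1]]), matrix_role(x[[1]]),
              attr(x, "origin")))
  invisible(x)
}

#' Read a rooted tree with named tips
#'
#' Thin wrapper over [ape::read.tree()] that enforces unique tip labels.
#'
#' @param path Newick file.
#' @return an `ape::phylo` tree.
#' @export
read_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop(sprintf("could not parse tree '%s'", path),
                          call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("tree has duplicate tip labels", call. = FALSE)
  tree
}

#' Serialize an analysis result to JSON
#'
#' Results are written as a JSON object carrying the method name, the
#' parameters and seed used, and the numeric results, so that every run
#' is self-describing and diffable (no timestamps in the payload).
#'
#' @param obj named list (method, params, seed, values, ...).
#' @param path output file.
#' @export
write_result <- function(obj, path) {
  obj$package_version <- as.character(utils::packageVersion("quantmat"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
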