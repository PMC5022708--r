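# shared fixtures: everything is generated in code, no data files

# labelled SPD covariance fixture
fix_spd <- function(p, seed) random_spd_matrix(p, seed = seed)

# correlation fixture derived from an SPD draw
fix_corr <- function(p, seed) to_correlation(random_spd_matrix(p, seed = seed))

# a diagonal covariance trait_matrix with given eigenvalues
fix_diag <- function(...) trait_matrix(diag(c(...)), role = "covariance")

# strip role/df/... attributes, keep dim and dimnames
bare <- function(x) {
  m <- as.matrix(x)
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  m
}

frob <- function(a, b = NULL) {
  am <- as.matrix(a)
  if (is.null(b)) return(sqrt(sum(am^2)))
  sqrt(sum((am - as.matrix(b))^2))
}

# write a trait matrix to a temp CSV, returning the path
tmp_matrix_csv <- function(m) {
  path <- tempfile(fileext = ".csv")
  write_matrix(m, path)
  path
}
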