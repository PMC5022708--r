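#' Random SPD and correlation matrices
#'
#' `random_spd_matrix()` draws a generic SPD covariance matrix: a random
#' orthogonal basis (QR of a Gaussian matrix) with eigenvalues drawn
#' log-uniformly between `lambda_range[1]` and `lambda_range[2]`.
#'
#' `random_matrix()` draws a random correlation matrix with a requested
#' level of integration, measured as the mean squared below-diagonal
#' correlation r2. Construction: random orthogonal basis, exponentially
#' decaying eigenvalue spectrum whose decay rate is tuned to the target,
#' rescaled to unit diagonal. The spectrum profile is a pragmatic
#' generator covering a usable range of integration values; outputs are
#' meant for informal tests needing an arbitrary correlation matrix, not
#' as a calibrated null model of biological covariance structure (the
#' attribute `purpose` says so).
#'
#' @param p number of traits (>= 2).
#' @param integration_range admissible \[lo, hi\] for the r2 integration
#'   of the output.
#' @param max_attempts attempts before giving up on the range.
#' @param seed optional integer seed.
#' @return a correlation (or covariance) [trait_matrix()].
#' @export
random_matrix <- function(p, integration_range = c(0, 1),
                          max_attempts = 100, seed = NULL) {
  stopifnot(p >= 2)
  lo <- integration_range[1]; hi <- integration_range[2]
  with_opt_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      # decay rate spread over a wide log range to cover weak to strong
      # integration; rejection keeps only matrices inside the target
      rate <- stats::runif(1, 0.01, 2.5)
      q <- qr.Q(qr(matrix(stats::rnorm(p * p), p, p)))
      lam <- exp(-rate * (seq_len(p) - 1))
      lam <- lam / sum(lam) * p
      m <- q %*% (lam * t(q))
      m <- (m + t(m)) / 2
      d <- diag(m)
      if (any(d <= 0)) next
      r <- stats::cov2cor(m)
      r2 <- mean(r[lower.tri(r)]^2)
      if (r2 >= lo && r2 <= hi) {
        out <- trait_matrix(r, role = "correlation",
                            labels = paste0("trait_", seq_len(p)))
        attr(out, "integration_r2") <- r2
        attr(out, "purpose") <- "for informal tests"
        return(out)
      }
    }
    stop(sprintf(
      "no matrix with integration in [%g, %g] found in %d attempts",
      lo, hi, max_attempts), call. = FALSE)
  })
}

#' @rdname random_matrix
#' @param lambda_range eigenvalue range for `random_spd_matrix()`
#'   (log-uniform draws).
#' @param eigenvalues optional explicit spectrum (length p, positive)
#'   overriding `lambda_range` — e.g. a size-dominated spectrum with a
#'   large leading eigenvalue, as in morphological covariance matrices.
#' @export
random_spd_matrix <- function(p, lambda_range = c(0.5, 4),
                              eigenvalues = NULL, seed = NULL) {
  stopifnot(p >= 1)
  with_opt_seed(seed, {
    q <- qr.Q(qr(matrix(stats::rnorm(p * p), p, p)))
    lam <- if (is.null(eigenvalues)) {
      sort(exp(stats::runif(p, log(lambda_range[1]),
                            log(lambda_range[2]))),
           decreasing = TRUE)
    } else {
      stopifnot(length(eigenvalues) == p, all(eigenvalues > 0))
      sort(eigenvalues, decreasing = TRUE)
    }
    m <- q %*% (lam * t(q))
    trait_matrix((m + t(m)) / 2, role = "covariance",
                 labels = paste0("trait_", seq_len(p)))
  })
}

#' Size-dominated eigenvalue spectrum
#'
#' The spectrum typical of morphological covariance matrices: a
#' dominant leading eigenvalue (the size axis, around half the total
#' variance) followed by a geometrically decaying tail. Used as the
#' default within-group spectrum of the drift fixtures.
#'
#' @param p number of traits.
#' @param lambda1 leading eigenvalue.
#' @param tail_range range of the remaining eigenvalues (geometric
#'   interpolation).
#' @return length-p vector of positive eigenvalues, descending.
#' @export
size_spectrum <- function(p, lambda1 = 50, tail_range = c(4, 0.25)) {
  c(lambda1, exp(seq(log(tail_range[1]), log(tail_range[2]),
                     length.out = p - 1)))
}

#' Block-structured (modular) correlation matrix
#'
#' Builds the canonical modular toy: correlation `r_within` between
#' traits of the same module, `r_between` otherwise. The result must be
#' a valid (PSD) correlation matrix; infeasible combinations fail with
#' the offending eigenvalue.
#'
#' @param p number of traits.
#' @param modules integer vector of length p assigning traits to
#'   modules.
#' @param r_within,r_between correlations inside / between modules,
#'   with 0 <= r_between < r_within < 1 (equal values give a uniform
#'   matrix).
#' @return correlation [trait_matrix()].
#' @export
modular_matrix <- function(p, modules, r_within, r_between) {
  if (length(modules) != p)
    stop("modules must assign every trait", call. = FALSE)
  if (r_within < 0 || r_within >= 1 || r_between < -1 ||
      r_between > r_within)
    stop("need r_between <= r_within, r_within in [0, 1)", call. = FALSE)
  same <- outer(modules, modules, `==`)
  m <- ifelse(same, r_within, r_between)
  diag(m) <- 1
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * p)
    stop(sprintf(
      "(r_within = %g, r_between = %g) is not PSD (min eigenvalue %g)",
      r_within, r_between, min(ev)), call. = FALSE)
  trait_matrix(m, role = "correlation",
               labels = paste0("trait_", seq_len(p)))
}

#' Simulate an individual-level population sample
#'
#' Draws `n` individuals from MVN(`mean`, `m`) into the individual-table
#' layout used across the package. With `replicates > 1`, each
#' individual's true values are repeated with i.i.d. Gaussian
#' measurement noise of standard deviation `error_sd` added per
#' replicate — the input expected by [calc_repeatability()].
#'
#' @param m SPD covariance trait matrix.
#' @param n number of individuals.
#' @param mean trait mean vector (default zero).
#' @param replicates measurements per individual.
#' @param error_sd measurement-error standard deviation (scalar or per
#'   trait).
#' @param seed optional integer seed.
#' @return individual table (`data.frame` with `individual`, optional
#'   `replicate`, trait columns).
#' @export
simulate_population <- function(m, n, mean = NULL, replicates = 1,
                                error_sd = 0, seed = NULL) {
  m <- as_trait_matrix(m)
  p <- nrow(m)
  if (is.null(mean)) mean <- rep(0, p)
  stopifnot(length(mean) == p, replicates >= 1)
  if (length(error_sd) == 1) error_sd <- rep(error_sd, p)
  with_opt_seed(seed, {
    x <- MASS::mvrnorm(n, mu = mean, Sigma = unclass_tm(m))
    if (n == 1) x <- matrix(x, nrow = 1)
    if (replicates == 1) {
      out <- data.frame(individual = seq_len(n))
      out[rownames(m)] <- as.data.frame(x)
    } else {
      idx <- rep(seq_len(n), each = replicates)
      noise <- matrix(stats::rnorm(length(idx) * p), ncol = p) *
        rep(error_sd, each = length(idx))
      obs <- x[idx, , drop = FALSE] + noise
      out <- data.frame(individual = idx,
                        replicate = rep(seq_len(replicates), times = n))
      out[rownames(m)] <- as.data.frame(obs)
    }
    validate_individual_table(out)
  })
}

#' Simulate taxon means diverging under drift
#'
#' Under drift, taxon means scatter around the ancestral mean with
#' covariance (t/Ne) W. Draws `n_taxa` such means; an optional
#' deterministic displacement along `selection_vector` (scaled per
#' taxon by its index) models correlated directional selection and
#' gives the drift tests something to reject. `t_over_ne = 0` returns
#' identical (zero) means.
#'
#' @param w SPD covariance trait matrix.
#' @param n_taxa number of taxa.
#' @param t_over_ne drift scale (>= 0).
#' @param selection_vector optional length-p direction; taxon i is
#'   displaced by `selection_strength * i / n_taxa` along its unit
#'   vector.
#' @param selection_strength total displacement magnitude.
#' @param seed optional integer seed.
#' @return taxon x trait matrix of means with taxa `taxon_1`, ...
#' @export
simulate_radiation <- function(w, n_taxa, t_over_ne,
                               selection_vector = NULL,
                               selection_strength = 1, seed = NULL) {
  w <- as_trait_matrix(w)
  p <- nrow(w)
  stopifnot(t_over_ne >= 0, n_taxa >= 1)
  means <- if (t_over_ne == 0) {
    matrix(0, n_taxa, p)
  } else {
    with_opt_seed(seed, {
      x <- MASS::mvrnorm(n_taxa, mu = rep(0, p),
                         Sigma = t_over_ne * unclass_tm(w))
      if (n_taxa == 1) matrix(x, nrow = 1) else x
    })
  }
  if (!is.null(selection_vector)) {
    v <- selection_vector / sqrt(sum(selection_vector^2))
    means <- means + outer(selection_strength * seq_len(n_taxa) / n_taxa,
                           v)
  }
  dimnames(means) <- list(paste0("taxon_", seq_len(n_taxa)), rownames(w))
  means
}
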