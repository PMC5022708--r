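#' Bootstrap distribution of a statistic over individuals
#'
#' Resamples the n individuals of an individual table with replacement
#' `iterations` times and applies `statistic` (a function of the
#' resampled table returning a scalar, vector or matrix) to each
#' resample. If the statistic fails on a resample (e.g. a degenerate
#' covariance), that resample is redrawn, at most 10 times, before
#' giving up with an error.
#'
#' @param data individual table.
#' @param statistic function(table) -> numeric scalar/vector/matrix.
#' @param iterations number of bootstrap resamples.
#' @param seed optional integer seed.
#' @return object of class `stat_distribution`: list with `draws`
#'   (list of statistic values), `method`, `iterations`, `seed`.
#' @export
bootstrap_stat <- function(data, statistic, iterations = 1000,
                           seed = NULL) {
  data <- validate_individual_table(data)
  ids <- unique(data$individual)
  rows_by_id <- split(seq_len(nrow(data)), data$individual)[as.character(ids)]
  stopifnot(iterations >= 1)
  draws <- with_opt_seed(seed, {
    lapply(seq_len(iterations), function(i) {
      for (attempt in 1:10) {
        pick <- sample(length(ids), replace = TRUE)
        resample <- data[unlist(rows_by_id[pick], use.names = FALSE), ,
                         drop = FALSE]
        attr(resample, "trait_names") <- attr(data, "trait_names")
        val <- tryCatch(statistic(resample), error = function(e) e)
        if (!inherits(val, "error")) return(val)
      }
      stop("statistic failed on 10 consecutive bootstrap resamples: ",
           conditionMessage(val), call. = FALSE)
    })
  })
  structure(list(draws = draws, method = "bootstrap",
                 iterations = iterations, seed = seed),
            class = "stat_distribution")
}

#' Monte-Carlo distribution of a statistic under a Gaussian model
#'
#' Uses the observed covariance matrix as the Sigma parameter of a
#' multivariate normal, draws `iterations` datasets of `sample_size`
#' individuals from it, and applies `statistic` to each dataset (an
#' individual table with traits named as in `m`). This parametric
#' counterpart of [bootstrap_stat()] needs no original data, only the
#' matrix, so it applies directly to matrices from linear models.
#'
#' @param m SPD covariance trait matrix.
#' @param sample_size individuals per simulated dataset (>= p + 1).
#' @param statistic function(table) -> numeric value.
#' @param iterations number of simulated datasets.
#' @param seed optional integer seed.
#' @return `stat_distribution` as in [bootstrap_stat()].
#' @export
monte_carlo_stat <- function(m, sample_size, statistic,
                             iterations = 1000, seed = NULL) {
  m <- as_trait_matrix(m)
  p <- nrow(m)
  ev <- eigen(unclass_tm(m), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("monte_carlo_stat requires a positive-definite matrix",
         call. = FALSE)
  if (sample_size < p + 1)
    stop(sprintf("sample_size must be at least p + 1 = %d", p + 1),
         call. = FALSE)
  draws <- with_opt_seed(seed, {
    lapply(seq_len(iterations), function(i) {
      x <- MASS::mvrnorm(sample_size, mu = rep(0, p),
                         Sigma = unclass_tm(m))
      tab <- as.data.frame(x)
      names(tab) <- rownames(m)
      tab <- cbind(individual = seq_len(sample_size), tab)
      attr(tab, "trait_names") <- rownames(m)
      statistic(tab)
    })
  })
  structure(list(draws = draws, method = "montecarlo",
                 iterations = iterations, seed = seed),
            class = "stat_distribution")
}

#' @export
print.stat_distribution <- function(x, ...) {
  cat(sprintf("%s distribution: %d draws\n", x$method, x$iterations))
  invisible(x)
}

#' Quantiles of a statistic distribution
#'
#' @param dist a `stat_distribution` of scalar draws.
#' @param probs quantile probabilities.
#' @export
stat_quantiles <- function(dist, probs = c(0.025, 0.5, 0.975)) {
  stats::quantile(unlist(dist$draws), probs = probs, names = TRUE)
}

compare_by_method <- function(a, b, comparison_method, seed = NULL) {
  switch(comparison_method,
    random_skewers = random_skewers(a, b, seed = seed)$value,
    mantel = mantel_cor(a, b, seed = seed)$value,
    krz = krz_cor(a, b)$value,
    pca_similarity = pca_similarity(a, b)$value,
    stop(sprintf("unknown comparison method '%s'", comparison_method),
         call. = FALSE))
}

repeatability_estimate <- function(value, method, iterations,
                                   comparison_method, seed = NULL) {
  structure(list(value = min(max(value, 0), 1), method = method,
                 iterations = iterations,
                 comparison_method = comparison_method, seed = seed),
            class = "repeatability_estimate")
}

#' @export
print.repeatability_estimate <- function(x, ...) {
  cat(sprintf("matrix repeatability (%s%s): %.4f\n", x$method,
              if (is.null(x$comparison_method)) "" else
                paste0(", ", x$comparison_method), x$value))
  invisible(x)
}

#' Matrix repeatability by bootstrap
#'
#' Repeated sampling from the same population never reproduces a matrix
#' exactly, so even matrices estimated from the same population
#' correlate below 1. This function estimates that ceiling: it
#' bootstraps the individuals, computes a covariance (or correlation)
#' matrix per resample, compares each with the full-data matrix by the
#' chosen method, and averages. Estimates are inflated upwards for small
#' samples (conservative when used to correct matrix correlations, but
#' a high value from few individuals is not evidence of a well-estimated
#' matrix).
#'
#' @param data individual table.
#' @param comparison_method `"random_skewers"`, `"mantel"`, `"krz"` or
#'   `"pca_similarity"`.
#' @param iterations bootstrap resamples.
#' @param correlation compare correlation (TRUE) or covariance matrices;
#'   Mantel always compares correlation matrices.
#' @param seed optional integer seed.
#' @return `repeatability_estimate` with `value` in \[0, 1\].
#' @export
bootstrap_rep <- function(data, comparison_method = "random_skewers",
                          iterations = 1000, correlation = FALSE,
                          seed = NULL) {
  data <- validate_individual_table(data)
  correlation <- correlation || comparison_method == "mantel"
  stat <- function(tab) {
    m <- calculate_matrix(tab)
    if (correlation) to_correlation(m) else m
  }
  cov_full <- calculate_matrix(data)
  traits <- as.matrix(data[, trait_names(data), drop = FALSE])
  if (max(abs(unclass_tm(cov_full))) <= 1e-20 * max(abs(traits), 1)^2)
    stop("degenerate data: effectively zero covariance matrix",
         call. = FALSE)
  full <- if (correlation) to_correlation(cov_full) else cov_full
  dist <- bootstrap_stat(data, stat, iterations = iterations, seed = seed)
  cmp_seed <- if (is.null(seed)) NULL else seed + 1L
  vals <- vapply(dist$draws, function(m)
    compare_by_method(m, full, comparison_method, seed = cmp_seed),
    numeric(1))
  repeatability_estimate(mean(vals), "bootstrap", iterations,
                         comparison_method, seed)
}

#' Matrix repeatability by Monte Carlo
#'
#' Parametric analogue of [bootstrap_rep()]: datasets of `sample_size`
#' individuals are simulated from MVN(0, m), a matrix is estimated from
#' each, compared with `m` by the chosen method, and the comparisons
#' averaged.
#'
#' @inheritParams bootstrap_rep
#' @param m SPD covariance trait matrix.
#' @param sample_size simulated individuals per iteration.
#' @export
monte_carlo_rep <- function(m, sample_size,
                            comparison_method = "random_skewers",
                            iterations = 1000, correlation = FALSE,
                            seed = NULL) {
  m <- as_trait_matrix(m)
  correlation <- correlation || comparison_method == "mantel"
  stat <- function(tab) {
    est <- calculate_matrix(tab)
    if (correlation) to_correlation(est) else est
  }
  target <- if (correlation) to_correlation(m) else m
  dist <- monte_carlo_stat(m, sample_size, stat,
                           iterations = iterations, seed = seed)
  cmp_seed <- if (is.null(seed)) NULL else seed + 1L
  vals <- vapply(dist$draws, function(x)
    compare_by_method(x, target, comparison_method, seed = cmp_seed),
    numeric(1))
  repeatability_estimate(mean(vals), "montecarlo", iterations,
                         comparison_method, seed)
}

#' Analytic repeatability of a correlation matrix
#'
#' Closed-form repeatability: with sigma2_r the variance of the
#' p(p-1)/2 below-diagonal correlations and
#' eps2 = (1 - rbar2)^2 / (n - 2) the expected sampling variance of a
#' single correlation (rbar2 = mean squared below-diagonal element),
#' alpha = (sigma2_r - eps2) / sigma2_r, clamped to \[0, 1\]. The
#' expression is asymptotic, so it should only be trusted for sample
#' sizes comfortably above the number of traits.
#'
#' @param corr correlation trait matrix.
#' @param n sample size behind the matrix (> 2).
#' @return `repeatability_estimate` with method `"alpha"`.
#' @export
alpha_rep <- function(corr, n) {
  corr <- as_trait_matrix(corr)
  if (matrix_role(corr) != "correlation")
    stop("alpha_rep is defined for correlation matrices", call. = FALSE)
  if (n <= 2) stop("alpha_rep needs n > 2", call. = FALSE)
  if (n <= nrow(corr))
    warning("alpha_rep is asymptotic; n <= p is unreliable", call. = FALSE)
  r <- unclass_tm(corr)[lower.tri(corr)]
  var_r <- stats::var(r)
  eps2 <- (1 - mean(r^2))^2 / (n - 2)
  value <- if (isTRUE(var_r > 0)) (var_r - eps2) / var_r else 0
  repeatability_estimate(value, "alpha", NA_integer_, NULL)
}

#' Correct a matrix correlation for estimation error
#'
#' Divides an observed between-matrix correlation by the geometric mean
#' of the two matrix repeatabilities — the maximum correlation
#' achievable given the error in each matrix. Ratios above 1 (possible
#' with noisy repeatabilities) are capped at 1 and the cap is flagged.
#'
#' @param raw observed correlation.
#' @param rep_a,rep_b repeatabilities in (0, 1\].
#' @return list with `value`, `raw`, `capped`.
#' @export
corrected_correlation <- function(raw, rep_a, rep_b) {
  if (rep_a <= 0 || rep_b <= 0)
    stop("repeatabilities must be positive", call. = FALSE)
  if (rep_a > 1 || rep_b > 1)
    stop("repeatabilities cannot exceed 1", call. = FALSE)
  value <- raw / sqrt(rep_a * rep_b)
  capped <- value > 1
  list(value = min(value, 1), raw = raw, capped = capped)
}

#' Rarefaction of a matrix (or any) statistic
#'
#' Takes progressively smaller samples with replacement from the data,
#' recomputes the statistic on each subsample and compares it with the
#' full-data statistic — a picture of how robust the inference is to
#' sample size. The default statistic is the covariance matrix and the
#' default comparison a matrix correlation method.
#'
#' @param data individual table.
#' @param sizes vector of subsample sizes (each in \[2, n\]).
#' @param comparison_method matrix comparison method (see
#'   [bootstrap_rep()]) used to compare subsample and full-data
#'   statistics.
#' @param iterations subsamples per size.
#' @param correlation compare correlation rather than covariance
#'   matrices.
#' @param seed optional integer seed.
#' @return data.frame: size, iteration, comparison value.
#' @export
rarefaction <- function(data, sizes,
                        comparison_method = "random_skewers",
                        iterations = 100, correlation = FALSE,
                        seed = NULL) {
  data <- validate_individual_table(data)
  ids <- unique(data$individual)
  n <- length(ids)
  if (any(sizes < 2) || any(sizes > n))
    stop(sprintf("sizes must lie in [2, %d]", n), call. = FALSE)
  correlation <- correlation || comparison_method == "mantel"
  stat <- function(tab) {
    m <- calculate_matrix(tab)
    if (correlation) to_correlation(m) else m
  }
  full <- stat(data)
  rows_by_id <- split(seq_len(nrow(data)), data$individual)
  res <- with_opt_seed(seed, {
    do.call(rbind, lapply(sizes, function(sz) {
      vals <- vapply(seq_len(iterations), function(i) {
        pick <- sample(n, size = sz, replace = TRUE)
        sub <- data[unlist(rows_by_id[as.character(ids[pick])],
                           use.names = FALSE), , drop = FALSE]
        attr(sub, "trait_names") <- attr(data, "trait_names")
        compare_by_method(stat(sub), full, comparison_method)
      }, numeric(1))
      data.frame(size = sz, iteration = seq_len(iterations), value = vals)
    }))
  })
  rownames(res) <- NULL
  res
}

#' Extend the trailing eigenvalues of a covariance matrix
#'
#' Sampling error mangles the smallest eigenvalues of an estimated
#' covariance matrix, which wrecks anything involving its inverse (net
#' selection-gradient reconstruction in particular). Extension replaces
#' the eigenvalues below the retained rank k* with the k*-th eigenvalue
#' and rebuilds the matrix on the original eigenvectors — a minimal
#' change to the distribution of phenotypes that stabilizes the inverse.
#'
#' When `retained_rank` is `NULL` a documented heuristic picks the
#' smallest k at which the relative spectral drop
#' (lambda_k - lambda_\{k+1\}) / lambda_1 falls below `drop_tol`; passing
#' an explicit rank is canonical.
#'
#' @param m covariance trait matrix.
#' @param retained_rank k*, in \[1, p\]; `NULL` for the heuristic.
#' @param drop_tol relative-drop threshold for the heuristic.
#' @return covariance `trait_matrix` with attribute `retained_rank`.
#' @export
extend_matrix <- function(m, retained_rank = NULL, drop_tol = 1e-4) {
  m <- as_trait_matrix(m)
  if (matrix_role(m) != "covariance")
    stop("extend_matrix is defined for covariance matrices", call. = FALSE)
  p <- nrow(m)
  e <- eigen_sorted(m)
  if (is.null(retained_rank)) {
    drops <- (e$values[-p] - e$values[-1]) / e$values[1]
    below <- which(drops < drop_tol)
    retained_rank <- if (length(below) == 0) p else min(below)
  }
  k <- retained_rank
  if (k < 1 || k > p)
    stop(sprintf("retained_rank must lie in [1, %d]", p), call. = FALSE)
  lam <- e$values
  if (k < p) lam[(k + 1):p] <- lam[k]
  out <- e$vectors %*% (lam * t(e$vectors))
  out <- (out + t(out)) / 2
  dimnames(out) <- dimnames(as.matrix(m))
  out <- trait_matrix(out, role = "covariance")
  attr(out, "retained_rank") <- k
  out
}
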