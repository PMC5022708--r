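#' Drift test by regression of between-group on within-group variance
#'
#' Under pure drift the between-taxon covariance matrix is proportional
#' to the ancestral (pooled within-group) matrix, B ~ (t/Ne) W. In the
#' eigenbasis of W this becomes per-principal-component:
#' log(B_i) = log(t/Ne) + beta * log(lambda_i^W), with slope beta = 1.
#' The taxon means are projected on the eigenvectors of W, B_i is the
#' variance of the i-th scores across taxa, and the slope of the
#' log-log ordinary least-squares regression is tested against 1 via
#' its 95% t-based confidence interval. A CI excluding 1 rejects drift
#' as a sufficient explanation of the divergence; a CI covering 1 means
#' the pattern is compatible with drift, not that selection was absent.
#'
#' Principal components with lambda_i^W / lambda_1^W below
#' `min_eigenvalue_ratio` are dropped (their log-variances are numerical
#' noise); at least 3 must remain. Reliability grows with the number of
#' traits and taxa; below roughly 20 traits and 8 taxa a warning is
#' emitted.
#'
#' @param means taxon x trait matrix or data.frame of trait means (taxa
#'   in rows), columns matching the traits of `w`.
#' @param w SPD within-group covariance trait matrix.
#' @param min_eigenvalue_ratio relative eigenvalue cutoff.
#' @return object of class `drift_regression`: list with `slope`,
#'   `intercept`, `ci` (2-vector), `points` (data.frame log_lambda,
#'   log_b), `retained`, `rejected`, `verdict`.
#' @export
drift_test <- function(means, w, min_eigenvalue_ratio = 1e-8) {
  w <- as_trait_matrix(w)
  means <- as.matrix(means)
  if (!is.null(colnames(means)) && !is.null(rownames(w))) {
    if (!setequal(colnames(means), rownames(w)))
      stop("means and w cover different traits", call. = FALSE)
    means <- means[, rownames(w), drop = FALSE]
  }
  n_taxa <- nrow(means)
  if (n_taxa < 4) stop("drift_test needs at least 4 taxa", call. = FALSE)
  p <- ncol(means)
  if (p < 20 || n_taxa < 8)
    warning("drift regression is advisory below ~20 traits and ~8 taxa",
            call. = FALSE)
  e <- eigen_sorted(w)
  if (min(e$values) <= 0)
    stop("w must be positive-definite", call. = FALSE)
  keep <- e$values / e$values[1] >= min_eigenvalue_ratio
  if (sum(keep) < 3)
    stop("fewer than 3 principal components retained", call. = FALSE)
  scores <- means %*% e$vectors[, keep, drop = FALSE]
  b <- apply(scores, 2, stats::var)
  pts <- data.frame(pc = which(keep),
                    log_lambda = log(e$values[keep]), log_b = log(b))
  fit <- stats::lm(log_b ~ log_lambda, data = pts)
  ci <- stats::confint(fit, "log_lambda", level = 0.95)
  slope <- stats::coef(fit)[["log_lambda"]]
  rejected <- ci[1] > 1 || ci[2] < 1
  verdict <- if (rejected)
    paste("drift rejected: the slope's 95% CI excludes 1, so the",
          "observed divergence pattern is not proportional to the",
          "within-group variation")
  else
    paste("drift not rejected: the divergence pattern is compatible",
          "with drift; this is not evidence that selection was absent")
  structure(list(slope = slope,
                 intercept = stats::coef(fit)[["(Intercept)"]],
                 ci = as.numeric(ci), points = pts,
                 retained = sum(keep), rejected = rejected,
                 verdict = verdict, fit = fit),
            class = "drift_regression")
}

#' @export
print.drift_regression <- function(x, ...) {
  cat(sprintf("drift regression: slope %.4f, 95%% CI [%.4f, %.4f], %d PCs\n",
              x$slope, x$ci[1], x$ci[2], x$retained))
  cat(strwrap(x$verdict, indent = 2, exdent = 2), sep = "\n")
  invisible(x)
}

#' Multivariate drift test for an ancestral/derived population pair
#'
#' With one reference (ancestral) population and one derived population,
#' drift predicts derived means scattered around the ancestral mean z0
#' with covariance B = (t/Ne) W. The test simulates `n_sim` derived
#' means from MVN(z0, (t/Ne) W + diag(se1^2)) — the diagonal term
#' carries the standard error of the observed derived means — computes
#' the null distribution of divergence norms ||sim - z0||, and compares
#' the observed divergence ||z1 - z0||. The add-one p-value is the
#' fraction of null norms at least as large as the observed one; small p
#' means drift at the stated scale cannot account for the divergence.
#' The drift scale t/Ne is not identified by the data and must be
#' supplied.
#'
#' @param z0 ancestral/reference mean vector.
#' @param z1 derived mean vector.
#' @param se1 standard errors of the derived means (scalar or vector).
#' @param w SPD covariance trait matrix of the ancestral population.
#' @param t_over_ne drift scale t/Ne (> 0).
#' @param n_sim simulated populations (>= 100).
#' @param seed optional integer seed.
#' @return object of class `multiv_drift`: list with `observed`,
#'   `null_norms`, `p_value`, `n_sim`, `t_over_ne`.
#' @export
multiv_drift_test <- function(z0, z1, se1, w, t_over_ne, n_sim = 1000,
                              seed = NULL) {
  w <- as_trait_matrix(w)
  p <- nrow(w)
  if (length(z0) != p || length(z1) != p)
    stop("mean vectors must match the matrix dimension", call. = FALSE)
  if (length(se1) == 1) se1 <- rep(se1, p)
  if (length(se1) != p)
    stop("se1 must be scalar or length p", call. = FALSE)
  if (t_over_ne <= 0) stop("t_over_ne must be positive", call. = FALSE)
  if (n_sim < 100) stop("n_sim must be at least 100", call. = FALSE)
  sigma <- t_over_ne * unclass_tm(w) + diag(se1^2, p)
  sims <- with_opt_seed(seed,
    MASS::mvrnorm(n_sim, mu = as.numeric(z0), Sigma = sigma))
  null_norms <- sqrt(rowSums(sweep(sims, 2, as.numeric(z0))^2))
  observed <- sqrt(sum((as.numeric(z1) - as.numeric(z0))^2))
  p_value <- (1 + sum(null_norms >= observed)) / (n_sim + 1)
  structure(list(observed = observed, null_norms = null_norms,
                 p_value = p_value, n_sim = n_sim,
                 t_over_ne = t_over_ne, seed = seed),
            class = "multiv_drift")
}

#' @export
print.multiv_drift <- function(x, ...) {
  cat(sprintf(
    "multivariate drift test: observed divergence %.4f, p = %.4g (t/Ne = %g)\n",
    x$observed, x$p_value, x$t_over_ne))
  if (x$p_value <= 0.05)
    cat("  divergence exceeds drift expectations at this scale\n")
  else
    cat("  divergence compatible with drift at this scale;",
        "not evidence against selection\n")
  invisible(x)
}

#' Correlation of taxon scores across principal components
#'
#' Under drift, taxon means projected on the principal components of
#' the within-group matrix should be uncorrelated between components.
#' Significant correlation between the scores of two components is a
#' signature of correlated directional selection. All p(p-1)/2 pairs
#' are tested with Pearson correlation; significance is Bonferroni
#' adjusted at level `alpha` over the pairs actually tested. Pairs with
#' constant scores on either component are skipped with a note.
#'
#' @param means taxon x trait matrix (>= 5 taxa).
#' @param w SPD within-group covariance trait matrix.
#' @param alpha family-wise significance level.
#' @return object of class `pc_score_cor`: data.frame `table` (pc_a,
#'   pc_b, correlation, p_value, p_adjusted, flagged), `notes`.
#' @export
pc_score_correlation <- function(means, w, alpha = 0.05) {
  w <- as_trait_matrix(w)
  means <- as.matrix(means)
  if (!is.null(colnames(means)) && !is.null(rownames(w))) {
    if (!setequal(colnames(means), rownames(w)))
      stop("means and w cover different traits", call. = FALSE)
    means <- means[, rownames(w), drop = FALSE]
  }
  if (nrow(means) < 5)
    stop("pc_score_correlation needs at least 5 taxa", call. = FALSE)
  e <- eigen_sorted(w)
  scores <- means %*% e$vectors
  p <- ncol(scores)
  notes <- character()
  rows <- list()
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    si <- scores[, i]; sj <- scores[, j]
    if (stats::sd(si) == 0 || stats::sd(sj) == 0) {
      notes <- c(notes, sprintf("pair (%d, %d) skipped: constant scores",
                                i, j))
      next
    }
    ct <- stats::cor.test(si, sj)
    rows[[length(rows) + 1]] <- data.frame(
      pc_a = i, pc_b = j, correlation = unname(ct$estimate),
      p_value = ct$p.value)
  }
  tab <- do.call(rbind, rows)
  tab$p_adjusted <- stats::p.adjust(tab$p_value, method = "bonferroni")
  tab$flagged <- tab$p_adjusted < alpha
  rownames(tab) <- NULL
  structure(list(table = tab, alpha = alpha, notes = notes),
            class = "pc_score_cor")
}

#' @export
print.pc_score_cor <- function(x, ...) {
  flagged <- x$table[x$table$flagged, , drop = FALSE]
  cat(sprintf("PC-score correlations: %d pairs tested, %d flagged at %.2g\n",
              nrow(x$table), nrow(flagged), x$alpha))
  if (nrow(flagged) > 0) {
    cat("flagged pairs point to correlated directional selection:\n")
    print(flagged, digits = 4)
  }
  for (note in x$notes) cat("note:", note, "\n")
  invisible(x)
}
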