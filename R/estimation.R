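#' Residual covariance matrix from a fixed-effects model
#'
#' Fits every trait on the same fixed-effects design by least squares
#' and estimates the covariance matrix from the residual cross-products,
#' dividing by the residual degrees of freedom n - rank(design) rather
#' than n - 1. With no factors this is exactly the ordinary sample
#' covariance; with factors it is the pooled within-group (MANCOVA
#' residual) covariance matrix, which removes differences in trait means
#' across groups (sex, locality, ...) that are not of interest.
#'
#' @param data individual table (see [read_individual_table()]): column
#'   `individual`, optional `factor_*` columns, numeric trait columns.
#' @param fixed_factors character vector of factor column names to
#'   adjust for (default: none).
#' @return covariance [trait_matrix()] with attribute `df` (residual
#'   degrees of freedom).
#' @export
#' @examples
#' d <- simulate_population(trait_matrix(diag(3)), n = 50, seed = 1)
#' calculate_matrix(d)
calculate_matrix <- function(data, fixed_factors = character()) {
  data <- validate_individual_table(data)
  traits <- as.matrix(data[, trait_names(data), drop = FALSE])
  n <- nrow(traits)
  if (length(fixed_factors) == 0) {
    design <- matrix(1, n, 1)
  } else {
    missing <- setdiff(fixed_factors, names(data))
    if (length(missing) > 0)
      stop(sprintf("unknown factor columns: %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    fmla <- stats::as.formula(
      paste("~", paste(sprintf("factor(`%s`)", fixed_factors),
                       collapse = " + ")))
    design <- stats::model.matrix(fmla, data = data)
  }
  fit <- stats::lm.fit(design, traits)
  df <- n - fit$rank
  if (df < 1)
    stop(sprintf(
      "design rank (%d) leaves no residual degrees of freedom (n = %d)",
      fit$rank, n), call. = FALSE)
  res <- as.matrix(fit$residuals)
  v <- crossprod(res) / df
  out <- trait_matrix(v, role = "covariance", labels = trait_names(data))
  attr(out, "df") <- df
  out
}

#' Bayesian covariance estimation with a conjugate inverse-Wishart prior
#'
#' Shrinkage estimate of a phenotypic covariance matrix. The prior scale
#' is diagonal, built from the observed per-trait variances:
#' Lambda_0 = nu_0 * diag(sample variances), so off-diagonal elements are
#' shrunk towards zero while the variance scale is respected. With
#' centred cross-product S and sample size n, the posterior is
#' inverse-Wishart(nu_n = nu_0 + n, Lambda_n = Lambda_0 + S); the
#' maximum a posteriori estimate is the posterior mode
#' Lambda_n / (nu_n + p + 1). Optionally draws posterior samples (via
#' Wishart draws on the inverse scale) and their element-wise median.
#'
#' `prior_df = "auto"` uses nu_0 = p + 2, the weakest proper prior with a
#' finite mean. A numeric nu_0 <= p - 1 is allowed but noted as an
#' improper-prior regime in the result.
#'
#' @param data individual table with numeric trait columns.
#' @param prior_df prior degrees of freedom nu_0, or `"auto"`.
#' @param n_samples number of posterior draws (0 for none).
#' @param seed optional integer seed for the draws.
#' @return object of class `bayes_posterior`: list with `map_estimate`,
#'   `samples` (a `matrix_sample` or NULL), `sample_median`,
#'   `prior_scale`, `prior_df`, `posterior_df`, `notes`.
#' @export
bayesian_calculate_matrix <- function(data, prior_df = "auto",
                                      n_samples = 0, seed = NULL) {
  data <- validate_individual_table(data)
  traits <- as.matrix(data[, trait_names(data), drop = FALSE])
  n <- nrow(traits); p <- ncol(traits)
  if (n < 2) stop("need at least 2 individuals", call. = FALSE)
  notes <- character()
  if (identical(prior_df, "auto")) {
    nu0 <- p + 2
  } else {
    nu0 <- as.numeric(prior_df)
    if (nu0 <= p - 1)
      notes <- c(notes, sprintf(
        "prior_df = %g <= p - 1 = %d: improper-prior regime", nu0, p - 1))
  }
  vars <- apply(traits, 2, stats::var)
  lambda0 <- nu0 * diag(vars, p)
  centred <- sweep(traits, 2, colMeans(traits))
  s <- crossprod(centred)
  lambda_n <- lambda0 + s
  nu_n <- nu0 + n
  map <- lambda_n / (nu_n + p + 1)
  dimnames(map) <- list(trait_names(data), trait_names(data))
  samples <- NULL
  sample_median <- NULL
  if (n_samples > 0) {
    draws <- with_opt_seed(seed, {
      w <- stats::rWishart(n_samples, df = nu_n, Sigma = solve(lambda_n))
      lapply(seq_len(n_samples), function(i) {
        inv <- solve(w[, , i])
        inv <- (inv + t(inv)) / 2
        dimnames(inv) <- dimnames(map)
        trait_matrix(inv, role = "covariance")
      })
    })
    samples <- matrix_sample(draws, origin = "posterior")
    med <- apply(simplify2array(lapply(samples, unclass_tm)), c(1, 2),
                 stats::median)
    med <- (med + t(med)) / 2
    dimnames(med) <- dimnames(map)
    sample_median <- trait_matrix(med, role = "covariance")
  }
  structure(list(
    map_estimate = trait_matrix(map, role = "covariance"),
    samples = samples,
    sample_median = sample_median,
    prior_scale = trait_matrix(lambda0, role = "covariance",
                               labels = trait_names(data)),
    prior_df = nu0,
    posterior_df = nu_n,
    n = n,
    notes = notes
  ), class = "bayes_posterior")
}

#' @export
print.bayes_posterior <- function(x, ...) {
  cat(sprintf(
    "Bayesian covariance estimate: %d traits, n = %d, prior df = %g\n",
    nrow(x$map_estimate), x$n, x$prior_df))
  if (!is.null(x$samples))
    cat(sprintf("  %d posterior draws attached\n", length(x$samples)))
  for (note in x$notes) cat("  note:", note, "\n")
  invisible(x)
}

#' Per-trait repeatability of repeated measurements
#'
#' Quantifies measurement error from individuals measured at least
#' twice. For each trait a one-way ANOVA with individual as the factor
#' gives mean squares among (MS_A) and within (MS_W) individuals; the
#' variance components are s2_W = MS_W and
#' s2_A = (MS_A - MS_W) / n0, where n0 = (N - sum(n_i^2)/N) / (a - 1)
#' is the effective replicate number (equal to the replicate count in a
#' balanced design). Repeatability is r = s2_A / (s2_A + s2_W), the
#' proportion of variance among individuals rather than among repeated
#' measurements of the same individual; r = 1 means no measurement
#' error. Negative s2_A (MS_A < MS_W) is clamped to zero, giving r = 0.
#'
#' @param data individual table with an `individual` column, at least 2
#'   rows (replicates) per individual, and numeric trait columns.
#' @return data.frame: trait, s2_among, s2_within, repeatability.
#' @export
calc_repeatability <- function(data) {
  data <- validate_individual_table(data)
  id <- factor(data$individual)
  counts <- table(id)
  if (any(counts < 2))
    stop("every individual needs at least 2 replicates", call. = FALSE)
  a <- nlevels(id)
  n_tot <- nrow(data)
  n0 <- (n_tot - sum(counts^2) / n_tot) / (a - 1)
  traits <- trait_names(data)
  res <- lapply(traits, function(tr) {
    fit <- stats::aov(data[[tr]] ~ id)
    ms <- summary(fit)[[1]][["Mean Sq"]]
    ms_a <- ms[1]; ms_w <- ms[2]
    s2_a <- max((ms_a - ms_w) / n0, 0)
    r <- if (s2_a + ms_w > 0) s2_a / (s2_a + ms_w) else 0
    data.frame(trait = tr, s2_among = s2_a, s2_within = ms_w,
               repeatability = min(max(r, 0), 1))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
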