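#' Closed-form integration statistics of a trait matrix
#'
#' Three scalar descriptors with closed forms:
#' * mean squared correlation r2 — the below-diagonal elements of the
#'   correlation matrix squared and averaged; an overall-association
#'   (integration) measure. Covariance input is converted with a note.
#' * ICV — coefficient of variation of the eigenvalues of a covariance
#'   matrix, sd(lambda)/mean(lambda) (sample sd, n - 1 divisor); an
#'   integration measure that keeps the scale of variation.
#' * PC1% — fraction of total variance on the first principal
#'   component, lambda_1 / tr.
#'
#' @param m trait matrix (p >= 2).
#' @return list: `r_squared`, `icv`, `pc1_percent`, `notes`.
#' @export
#' @examples
#' closed_form_stats(trait_matrix(diag(c(3, 1))))
closed_form_stats <- function(m) {
  m <- as_trait_matrix(m)
  if (nrow(m) < 2) stop("need at least 2 traits", call. = FALSE)
  notes <- character()
  if (matrix_role(m) == "covariance") {
    corr <- to_correlation(m)
    covm <- m
    notes <- c(notes, "r_squared computed on the derived correlation matrix")
  } else {
    corr <- m
    covm <- m
    notes <- c(notes,
      "icv and pc1_percent computed on a correlation matrix's eigenvalues")
  }
  r <- unclass_tm(corr)[lower.tri(corr)]
  lam <- eigen(unclass_tm(covm), symmetric = TRUE, only.values = TRUE)$values
  list(r_squared = mean(r^2),
       icv = stats::sd(lam) / mean(lam),
       pc1_percent = lam[1] / sum(lam),
       notes = notes)
}

#' Selection-response statistics over random selection gradients
#'
#' Monte-Carlo means over unit-norm random selection gradients beta of
#' the Hansen–Houle statistics of a covariance matrix G:
#' * evolvability e = E\[beta' G beta\] — variance available along the
#'   gradient;
#' * respondability r = E\[||G beta||\] — speed of response;
#' * flexibility f = E\[cos(G beta, beta)\] — alignment of response with
#'   the gradient;
#' * conditional evolvability c = E\[(beta' G^-1 beta)^-1\] — response
#'   along beta when all other directions are under stabilizing
#'   selection;
#' * autonomy a = E\[c(beta)/e(beta)\] on paired draws — fraction of
#'   variance along beta independent of other directions;
#' * constraints = E\[|cos(G beta, PC1)|\] — alignment of responses with
#'   the matrix's first principal component (absolute value, since the
#'   sign of an eigenvector is arbitrary).
#'
#' Per-statistic Monte-Carlo standard errors are attached. Conditional
#' evolvability and autonomy require an invertible matrix.
#'
#' @param m SPD covariance trait matrix.
#' @param n_vectors number of random gradients.
#' @param seed optional integer seed.
#' @param betas optional fixed gradient set (rows unit norm), overriding
#'   `n_vectors`/`seed`.
#' @param keep_draws keep the per-gradient draws (for distributions).
#' @return object of class `evol_stats`: list with `stats` (named
#'   vector), `se` (named vector of MC standard errors), `n_vectors`,
#'   `seed`, optionally `draws` (data.frame).
#' @export
skewer_stats <- function(m, n_vectors = 1000, seed = NULL, betas = NULL,
                         keep_draws = FALSE) {
  m <- as_trait_matrix(m)
  p <- nrow(m)
  e <- eigen_sorted(m)
  if (min(e$values) <= 0)
    stop("conditional evolvability and autonomy require a ",
         "positive-definite matrix", call. = FALSE)
  if (is.null(betas)) betas <- random_unit_vectors(p, n_vectors, seed = seed)
  n_vectors <- nrow(betas)
  g <- unclass_tm(m)
  ginv <- e$vectors %*% ((1 / e$values) * t(e$vectors))
  resp <- betas %*% g                     # row i = G beta_i
  evolvability <- rowSums(betas * resp)   # beta' G beta
  norm_resp <- sqrt(rowSums(resp^2))
  respondability <- norm_resp
  flexibility <- evolvability / norm_resp # cos(G beta, beta), ||beta|| = 1
  cond_evol <- 1 / rowSums((betas %*% ginv) * betas)
  autonomy <- cond_evol / evolvability
  pc1 <- e$vectors[, 1]
  constraints <- abs(as.vector(resp %*% pc1)) / norm_resp
  draws <- data.frame(evolvability = evolvability,
                      respondability = respondability,
                      flexibility = flexibility,
                      conditional_evolvability = cond_evol,
                      autonomy = autonomy,
                      constraints = constraints)
  stats_v <- vapply(draws, mean, numeric(1))
  se_v <- vapply(draws, function(x) stats::sd(x) / sqrt(length(x)),
                 numeric(1))
  structure(list(stats = stats_v, se = se_v, n_vectors = n_vectors,
                 seed = seed,
                 draws = if (keep_draws) draws else NULL),
            class = "evol_stats")
}

#' @export
print.evol_stats <- function(x, ...) {
  cat(sprintf("selection-response statistics (%d gradients):\n",
              x$n_vectors))
  for (nm in names(x$stats))
    cat(sprintf("  %-26s %.5f", nm, x$stats[[nm]]),
        if (!is.na(x$se[[nm]])) sprintf(" (MC se %.2g)", x$se[[nm]]) else "",
        "\n", sep = "")
  invisible(x)
}

#' All matrix statistics in one record
#'
#' Merges the closed-form integration statistics and the
#' gradient-dependent selection-response statistics of a covariance
#' matrix into one record, keeping the per-gradient draws for
#' distribution summaries.
#'
#' @inheritParams skewer_stats
#' @return `evol_stats` whose `stats` vector additionally carries
#'   `r_squared`, `icv`, `pc1_percent` (with `NA` standard errors — they
#'   are not Monte-Carlo quantities), plus `draws`.
#' @export
mean_matrix_statistics <- function(m, n_vectors = 1000, seed = NULL,
                                   betas = NULL) {
  cf <- closed_form_stats(m)
  sk <- skewer_stats(m, n_vectors = n_vectors, seed = seed, betas = betas,
                     keep_draws = TRUE)
  sk$stats <- c(r_squared = cf$r_squared, icv = cf$icv,
                pc1_percent = cf$pc1_percent, sk$stats)
  sk$se <- c(r_squared = NA_real_, icv = NA_real_, pc1_percent = NA_real_,
             sk$se)
  sk$notes <- cf$notes
  sk
}
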