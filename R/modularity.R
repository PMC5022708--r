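#' Build modularity-hypothesis matrices from a trait-module table
#'
#' A hypothesis is a binary p x p matrix with 1 where two traits belong
#' to the same module (diagonal ignored). This helper builds one
#' hypothesis per named module from a 0/1 membership table (one row per
#' trait, one column per module).
#'
#' @param membership data.frame or matrix of 0/1, traits x modules, with
#'   trait labels as rownames.
#' @return named list of binary matrices.
#' @export
modularity_hypotheses <- function(membership) {
  mm <- as.matrix(membership)
  if (!all(mm %in% c(0, 1)))
    stop("membership entries must be 0 or 1", call. = FALSE)
  traits <- rownames(mm)
  out <- lapply(seq_len(ncol(mm)), function(j) {
    h <- outer(mm[, j], mm[, j])
    diag(h) <- 0
    dimnames(h) <- list(traits, traits)
    h
  })
  names(out) <- colnames(mm)
  out
}

#' Test a priori modularity hypotheses against a correlation matrix
#'
#' Variational modularity predicts higher correlation between traits of
#' the same module. Each hypothesis (binary matrix, 1 = same module) is
#' compared with the observed correlation matrix by a Mantel test
#' (below-diagonal elements, joint row/column permutations), and
#' summarized by:
#' * AVG+ — mean correlation over within-module pairs;
#' * AVG- — mean over between-module pairs;
#' * AVG ratio = AVG+/AVG-, interpretable only when correlations share
#'   a sign;
#' * MHI = (AVG+ - AVG-) / ICV, the Modularity Hypothesis Index, usable
#'   on matrices with mixed-sign correlations (e.g. after
#'   [remove_size()]).
#'
#' A combined "full model" hypothesis (union of all supplied ones) is
#' appended. Hypotheses that mark all pairs, or none, carry no contrast
#' and are skipped with a note.
#'
#' @param corr correlation trait matrix.
#' @param hypotheses named list of binary matrices (see
#'   [modularity_hypotheses()]), or a single matrix.
#' @param permutations Mantel permutations.
#' @param seed optional integer seed.
#' @return object of class `modularity_result`: data.frame `table`
#'   (hypothesis, mantel_cor, p_value, avg_within, avg_between,
#'   avg_ratio, mhi), `icv`, `notes`.
#' @export
test_modularity <- function(corr, hypotheses, permutations = 999,
                            seed = NULL) {
  corr <- as_trait_matrix(corr)
  if (matrix_role(corr) != "correlation")
    stop("test_modularity expects a correlation matrix", call. = FALSE)
  if (is.matrix(hypotheses)) hypotheses <- list(hypothesis = hypotheses)
  if (length(hypotheses) == 0)
    stop("need at least one hypothesis", call. = FALSE)
  if (is.null(names(hypotheses)))
    names(hypotheses) <- paste0("hypothesis_", seq_along(hypotheses))
  if (length(hypotheses) > 1) {
    full <- Reduce(function(x, y) pmax(x, y), hypotheses)
    hypotheses$full_model <- full
  }
  lam <- eigen(unclass_tm(corr), symmetric = TRUE, only.values = TRUE)$values
  icv <- stats::sd(lam) / mean(lam)
  low <- lower.tri(corr)
  rvals <- unclass_tm(corr)[low]
  notes <- character()
  rows <- list()
  for (nm in names(hypotheses)) {
    h <- as.matrix(hypotheses[[nm]])
    if (nrow(h) != nrow(corr) || ncol(h) != nrow(corr))
      stop(sprintf("hypothesis '%s' does not match the matrix dimension",
                   nm), call. = FALSE)
    if (!is.null(rownames(h)) && !identical(rownames(h), rownames(corr)))
      stop(sprintf("hypothesis '%s' has mismatched trait labels", nm),
           call. = FALSE)
    if (max(abs(h - t(h))) > 0)
      stop(sprintf("hypothesis '%s' is not symmetric", nm), call. = FALSE)
    hv <- h[low]
    if (all(hv == 1) || all(hv == 0)) {
      notes <- c(notes, sprintf(
        "hypothesis '%s' has no contrast below the diagonal; skipped", nm))
      next
    }
    if (stats::sd(rvals) > 0) {
      mt <- mantel_cor(corr, trait_matrix(ifelse(h == 1, 1, 0), # 0/1 matrix
                                          role = "correlation",
                                          labels = rownames(corr)),
                       permutations = permutations, seed = seed)
      mt_value <- mt$value; mt_p <- mt$p_value
    } else {
      # constant observed correlations: no structure for the Mantel
      # statistic to align with
      mt_value <- NA_real_; mt_p <- NA_real_
      notes <- c(notes, sprintf(
        "hypothesis '%s': constant observed correlations, Mantel undefined",
        nm))
    }
    avg_in <- mean(rvals[hv == 1])
    avg_out <- mean(rvals[hv == 0])
    rows[[nm]] <- data.frame(
      hypothesis = nm, mantel_cor = mt_value, p_value = mt_p,
      avg_within = avg_in, avg_between = avg_out,
      avg_ratio = avg_in / avg_out,
      mhi = (avg_in - avg_out) / icv)
  }
  if (length(rows) == 0)
    stop("no testable hypotheses (all skipped)", call. = FALSE)
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, icv = icv, notes = notes,
                 permutations = permutations, seed = seed),
            class = "modularity_result")
}

#' @export
print.modularity_result <- function(x, ...) {
  if (!is.null(x$table)) print(x$table, digits = 4)
  if (!is.null(x$partition)) {
    cat(sprintf("L-modularity: L = %.5f, %d modules\n", x$l_value,
                length(unique(x$partition))))
    print(x$partition)
  }
  for (note in x$notes) cat("note:", note, "\n")
  invisible(x)
}

# L-modularity of a partition on absolute-correlation edge weights.
# Standard Newman numerator: null term k_i k_j / (2m) with m = sum(k)/2
# (half-edge bookkeeping), and self-pairs kept in the null sum (their
# weight is zero since diag(w) = 0). This is the convention under which
# the single-module partition scores exactly 0.
l_value_of <- function(w, ki, sumk, g) {
  same <- outer(g, g, `==`)
  null <- outer(ki, ki) / sumk
  sum((w - null)[same])
}

# enumerate set partitions of n items via restricted growth strings
set_partitions <- function(n) {
  out <- list()
  recurse <- function(prefix, maxv) {
    k <- length(prefix)
    if (k == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible(NULL))
    }
    for (v in seq_len(maxv + 1))
      recurse(c(prefix, v), max(maxv, v))
  }
  recurse(1L, 1L)
  out
}

#' Data-driven modularity search on a correlation matrix
#'
#' Treats the correlation matrix as a fully connected weighted graph
#' (edge weight |r_ij|; negative correlations enter by absolute value,
#' since a weighted graph needs nonnegative weights — refuse-and-guide
#' behaviour is available via `allow_negative = FALSE`) and maximizes a
#' Newman-type modularity over trait partitions g:
#' L(g) = sum_ij \[ w_ij - k_i k_j / (2m) \] delta(g_i, g_j),
#' with trait strength k_i = sum_\{j != i\} w_ij and total edge weight
#' m = sum_i k_i / 2 (half-edge bookkeeping). Self-pairs stay in the
#' null sum — their weight is zero — which pins the single-module
#' partition at exactly L = 0, so positive L always signals structure
#' beyond the strength-product null. Traits in the same module with
#' correlation above the null expectation raise L.
#'
#' Optimizers: `greedy` — agglomerative merging from singletons followed
#' by single-trait relocation passes, repeated over `restarts` random
#' merge orders; `exhaustive` — full enumeration of set partitions
#' (p <= 12).
#'
#' @param corr correlation trait matrix.
#' @param optimizer `"greedy"` or `"exhaustive"`.
#' @param restarts random restarts for the greedy optimizer.
#' @param seed optional integer seed (greedy restarts).
#' @param allow_negative if `FALSE`, mixed-sign matrices are refused
#'   with guidance to [remove_size()] first.
#' @return `modularity_result` with `partition` (named integer vector),
#'   `l_value`, `k` (trait strengths), `m` (total), `notes`.
#' @export
l_modularity <- function(corr, optimizer = c("greedy", "exhaustive"),
                         restarts = 20, seed = NULL,
                         allow_negative = TRUE) {
  optimizer <- match.arg(optimizer)
  corr <- as_trait_matrix(corr)
  if (matrix_role(corr) != "correlation")
    stop("l_modularity expects a correlation matrix", call. = FALSE)
  p <- nrow(corr)
  notes <- character()
  cm <- unclass_tm(corr)
  if (any(cm < 0)) {
    if (!allow_negative)
      stop("correlation matrix has negative entries; remove the size ",
           "factor first (remove_size()) or set allow_negative = TRUE ",
           "to use absolute values", call. = FALSE)
    notes <- c(notes, "negative correlations entered by absolute value")
  }
  w <- abs(cm)
  diag(w) <- 0
  ki <- rowSums(w)
  m_tot <- sum(ki)
  if (m_tot == 0) {
    part <- stats::setNames(rep(1L, p), rownames(corr))
    return(structure(list(partition = part, l_value = 0,
                          k = ki, m = m_tot / 2,
                          notes = c(notes,
                            "all off-diagonal correlations are zero; ",
                            "single-module partition returned"),
                          optimizer = optimizer, seed = seed),
                     class = "modularity_result"))
  }
  lv <- function(g) l_value_of(w, ki, m_tot, g)
  if (optimizer == "exhaustive") {
    if (p > 12)
      stop("exhaustive search is limited to p <= 12", call. = FALSE)
    parts <- set_partitions(p)
    vals <- vapply(parts, lv, numeric(1))
    best <- parts[[which.max(vals)]]
    best_l <- max(vals)
  } else {
    one_run <- function() {
      g <- seq_len(p)           # singletons
      repeat {                  # agglomerative: best merge while it helps
        cur <- lv(g)
        mods <- unique(g)
        best_gain <- 0; best_pair <- NULL
        if (length(mods) > 1) {
          pairs <- utils::combn(mods, 2)
          ord <- sample(ncol(pairs))
          for (ci in ord) {
            gg <- g
            gg[gg == pairs[2, ci]] <- pairs[1, ci]
            gain <- lv(gg) - cur
            if (gain > best_gain + 1e-12) {
              best_gain <- gain; best_pair <- pairs[, ci]
            }
          }
        }
        if (is.null(best_pair)) break
        g[g == best_pair[2]] <- best_pair[1]
      }
      repeat {                  # relocation: move single traits
        improved <- FALSE
        cur <- lv(g)
        for (i in sample(p)) {
          cands <- setdiff(unique(g), g[i])
          cands <- c(cands, max(g) + 1L)   # allow splitting out
          for (cand in cands) {
            gg <- g; gg[i] <- cand
            if (lv(gg) > cur + 1e-12) {
              g <- gg; cur <- lv(g); improved <- TRUE
            }
          }
        }
        if (!improved) break
      }
      list(g = g, l = lv(g))
    }
    runs <- with_opt_seed(seed, lapply(seq_len(restarts),
                                       function(i) one_run()))
    ls <- vapply(runs, `[[`, numeric(1), "l")
    best <- runs[[which.max(ls)]]$g
    best_l <- max(ls)
    # never worse than the single-module partition
    single <- rep(1L, p)
    if (lv(single) > best_l) {
      best <- single; best_l <- lv(single)
    }
  }
  best <- as.integer(factor(best, levels = unique(best)))
  structure(list(partition = stats::setNames(best, rownames(corr)),
                 l_value = best_l, k = ki, m = m_tot / 2, notes = notes,
                 optimizer = optimizer, seed = seed),
            class = "modularity_result")
}

#' Remove the size factor from a trait matrix
#'
#' When the first principal component absorbs a large share of variation
#' and its entries share a sign, it usually reflects overall size — a
#' dominant integrating factor that masks modular structure. This
#' removes it by projecting out the direction of the first principal
#' component v: residual = m - (m v)(m v)' / (v' m v), leaving a PSD
#' matrix with zero variance along v (rank p - 1); the normalized size
#' vector m v / sqrt(v' m v) is returned alongside so the rank-1 size
#' component reconstructs the input exactly. A warning is emitted when
#' PC1 entries are not predominantly one sign, since then the removed
#' direction is not naturally read as size.
#'
#' @param m covariance or correlation trait matrix.
#' @return list with `residual` (covariance `trait_matrix`) and
#'   `size_vector`.
#' @export
remove_size <- function(m) {
  m <- as_trait_matrix(m)
  e <- eigen_sorted(m)
  v <- e$vectors[, 1]
  signs <- sign(v[v != 0])
  if (length(unique(signs)) > 1 &&
      min(mean(signs == 1), mean(signs == -1)) > 0.2)
    warning("first principal component entries are not predominantly of ",
            "one sign; the removed factor may not represent size",
            call. = FALSE)
  mm <- unclass_tm(m)
  mv <- as.vector(mm %*% v)
  denom <- sum(v * mv)
  residual <- mm - tcrossprod(mv) / denom
  residual <- (residual + t(residual)) / 2
  dimnames(residual) <- dimnames(mm)
  list(residual = trait_matrix(residual, role = "covariance"),
       size_vector = mv / sqrt(denom))
}
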