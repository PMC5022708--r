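#' Phylogenetically structured pooling of trait matrices
#'
#' Estimates a matrix for every internal node of a rooted tree as the
#' sample-size-weighted mean of its children's matrices, by post-order
#' traversal; the root matrix equals the global weighted mean of the tip
#' matrices (the pooled within-group matrix of a MANCOVA with the
#' terminal clades as fixed effects). Branch lengths are ignored — a
#' warning is emitted when the tree carries them, since the pooling is
#' then blind to how divergence scales with time. For G-matrices the
#' appropriate weight (sample size, number of families, ...) is not
#' obvious; weights are therefore always user-supplied.
#'
#' @param tree rooted `ape::phylo` tree.
#' @param tip_matrices named list of conformable trait matrices, one per
#'   tip label.
#' @param tip_weights named numeric vector of positive weights (sample
#'   sizes), one per tip label.
#' @return object of class `phylo_matrices`: list with `tree`,
#'   `matrices` (list indexed by node id: tips then internal nodes,
#'   `ape` numbering), `weights`, `node_tips` (descendant tip sets).
#' @export
phylo_w <- function(tree, tip_matrices, tip_weights) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape::phylo object",
                                     call. = FALSE)
  tips <- tree$tip.label
  missing <- setdiff(tips, names(tip_matrices))
  if (length(missing) > 0)
    stop(sprintf("missing matrices for tips: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  missing_w <- setdiff(tips, names(tip_weights))
  if (length(missing_w) > 0)
    stop(sprintf("missing weights for tips: %s",
                 paste(missing_w, collapse = ", ")), call. = FALSE)
  if (any(tip_weights[tips] <= 0))
    stop("tip weights must be positive", call. = FALSE)
  if (!is.null(tree$edge.length))
    warning("branch lengths are ignored by the weighted pooling; ",
            "use with care when divergence tracks phylogenetic distance",
            call. = FALSE)
  mats <- lapply(tip_matrices[tips], as_trait_matrix)
  for (m in mats[-1]) check_pair(mats[[1]], m)
  n_tip <- length(tips)
  n_node <- tree$Nnode
  all_mats <- vector("list", n_tip + n_node)
  all_w <- numeric(n_tip + n_node)
  all_mats[seq_len(n_tip)] <- mats
  all_w[seq_len(n_tip)] <- tip_weights[tips]
  # post-order edge traversal: children are resolved before parents
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  for (parent in unique(edges[, 1])) {
    children <- edges[edges[, 1] == parent, 2]
    acc <- 0; wsum <- 0
    for (ch in children) {
      acc <- acc + all_w[ch] * unclass_tm(all_mats[[ch]])
      wsum <- wsum + all_w[ch]
    }
    all_mats[[parent]] <- trait_matrix(acc / wsum,
                                       role = matrix_role(mats[[1]]),
                                       labels = rownames(mats[[1]]))
    all_w[parent] <- wsum
  }
  node_tips <- lapply(seq_along(all_mats), function(node) {
    if (node <= n_tip) tips[node]
    else tips[intersect(seq_len(n_tip),
                        phangorn_free_descendants(tree, node))]
  })
  structure(list(tree = tree, matrices = all_mats, weights = all_w,
                 node_tips = node_tips),
            class = "phylo_matrices")
}

# descendant node ids of an internal node (tips included), iterative
phangorn_free_descendants <- function(tree, node) {
  out <- integer(0)
  stack <- node
  while (length(stack) > 0) {
    cur <- stack[[1]]; stack <- stack[-1]
    kids <- tree$edge[tree$edge[, 1] == cur, 2]
    out <- c(out, kids)
    stack <- c(stack, kids[kids > length(tree$tip.label)])
  }
  out
}

#' @export
print.phylo_matrices <- function(x, ...) {
  cat(sprintf("phylo_matrices: %d tips, %d internal nodes, root weight %g\n",
              length(x$tree$tip.label), x$tree$Nnode,
              x$weights[length(x$tree$tip.label) + 1]))
  invisible(x)
}

#' Compare sister groups at every internal node
#'
#' For trees with many tips, all-pairs matrix comparison tables are hard
#' to read; comparing sister lineages node by node localizes where in
#' the phylogeny covariance structure changed. Each internal node's
#' children (as pooled by [phylo_w()]) are compared by the chosen
#' method; at a multifurcation all child pairs are compared and attached
#' to the node with a note.
#'
#' @param pooled a `phylo_matrices` from [phylo_w()].
#' @param method `"random_skewers"`, `"mantel"`, `"krz"` or
#'   `"pca_similarity"`.
#' @param seed optional integer seed for stochastic methods.
#' @param ... passed to the comparison function.
#' @return data.frame: node (ape id), child_a, child_b, value, plus a
#'   `tip_sets` attribute naming each node by its descendant tips.
#' @export
phylo_compare <- function(pooled,
                          method = c("random_skewers", "mantel", "krz",
                                     "pca_similarity"),
                          seed = NULL, ...) {
  method <- match.arg(method)
  if (!inherits(pooled, "phylo_matrices"))
    stop("run phylo_w() first", call. = FALSE)
  tree <- pooled$tree
  n_tip <- length(tree$tip.label)
  fn <- switch(method,
    random_skewers = function(x, y, s) random_skewers(x, y, seed = s,
                                                      ...)$value,
    mantel = function(x, y, s) mantel_cor(x, y, seed = s, ...)$value,
    krz = function(x, y, s) krz_cor(x, y, ...)$value,
    pca_similarity = function(x, y, s) pca_similarity(x, y)$value)
  rows <- list()
  notes <- character()
  for (node in (n_tip + 1):(n_tip + tree$Nnode)) {
    children <- tree$edge[tree$edge[, 1] == node, 2]
    if (length(children) > 2)
      notes <- c(notes, sprintf(
        "node %d is a multifurcation of %d; all pairwise comparisons attached",
        node, length(children)))
    for (i in seq_along(children)) for (j in seq_len(i - 1)) {
      s <- if (is.null(seed)) NULL else seed + node
      rows[[length(rows) + 1]] <- data.frame(
        node = node, child_a = children[j], child_b = children[i],
        value = fn(pooled$matrices[[children[j]]],
                   pooled$matrices[[children[i]]], s))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "tip_sets") <- pooled$node_tips
  attr(out, "method") <- method
  attr(out, "notes") <- notes
  out
}
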