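# internal recursive node representation of a dendro tree
.dendro_nodes <- function(tree) {
  build <- function(id) {
    if (id < 0) return(list(leaf = tree$labels[-id], height = 0))
    list(left = build(tree$merge[id, 1]), right = build(tree$merge[id, 2]),
         height = tree$height[id])
  }
  if (length(tree$labels) == 1L) return(list(leaf = tree$labels, height = 0))
  build(nrow(tree$merge))
}

# rebuild a dendro from a (possibly contracted) node tree
.nodes_to_dendro <- function(node, linkage = "average") {
  labels <- character(); merges <- list()
  walk <- function(nd) {
    if (!is.null(nd$leaf)) {
      labels[[length(labels) + 1L]] <<- nd$leaf
      return(list(type = "leaf", id = length(labels)))
    }
    l <- walk(nd$left); r <- walk(nd$right)
    merges[[length(merges) + 1L]] <<- list(left = l, right = r,
                                           height = nd$height)
    list(type = "merge", id = length(merges))
  }
  walk(node)
  labels <- unlist(labels)
  n <- length(labels)
  if (n == 1L)
    return(structure(list(merge = matrix(integer(), 0, 2), height = numeric(),
                          size = integer(), order = 1L, labels = labels,
                          linkage = linkage), class = "dendro"))
  # re-sort merges by height (stable), remap child references
  hts <- vapply(merges, function(m) m$height, numeric(1))
  ord <- order(hts)
  rank_of <- integer(length(merges)); rank_of[ord] <- seq_along(ord)
  ref <- function(x) if (x$type == "leaf") -x$id else rank_of[x$id]
  merge <- matrix(0L, length(merges), 2L)
  height <- numeric(length(merges)); size <- integer(length(merges))
  leafcount <- function(k) {
    if (k < 0) 1L else size[k]
  }
  for (new_k in seq_along(ord)) {
    m <- merges[[ord[new_k]]]
    a <- ref(m$left); b <- ref(m$right)
    merge[new_k, ] <- if (a < 0 && b < 0) sort(c(a, b)) else
      if (a < 0) c(a, b) else if (b < 0) c(b, a) else sort(c(a, b))
    height[new_k] <- m$height
    size[new_k] <- leafcount(merge[new_k, 1]) + leafcount(merge[new_k, 2])
  }
  structure(list(merge = merge, height = height, size = size,
                 order = .dendro_order(merge, n), labels = labels,
                 linkage = linkage), class = "dendro")
}

#' Restrict two dendrograms to their common leaves
#'
#' Prunes each tree to the leaf set shared by both, contracting internal
#' nodes left with a single child; merge heights of surviving nodes are
#' preserved.
#'
#' @param tree_a,tree_b \code{dendro} objects.
#' @return List \code{tree_a}, \code{tree_b} (pruned), \code{common_leaves}.
#' @export
restrict_to_common_leaves <- function(tree_a, tree_b) {
  common <- intersect(tree_a$labels, tree_b$labels)
  if (length(common) < 4L) stop("fewer than 4 common leaves")
  prune <- function(tree) {
    keep <- common
    rec <- function(nd) {
      if (!is.null(nd$leaf))
        return(if (nd$leaf %in% keep) nd else NULL)
      l <- rec(nd$left); r <- rec(nd$right)
      if (is.null(l)) return(r)
      if (is.null(r)) return(l)
      list(left = l, right = r, height = nd$height)
    }
    .nodes_to_dendro(rec(.dendro_nodes(tree)), tree$linkage)
  }
  list(tree_a = prune(tree_a), tree_b = prune(tree_b),
       common_leaves = sort(common))
}

# clade label-set keys of a tree, excluding root and (trivially) singletons
.clade_keys <- function(tree, include_root = FALSE) {
  cl <- dendro_clades(tree, include_root = include_root)
  vapply(cl, function(ix) paste(sort(tree$labels[ix]), collapse = ","),
         character(1))
}

#' Shared-clade ("common node") statistics of two trees
#'
#' Clades are the leaf-label sets of internal nodes, excluding the root;
#' after restriction to the common leaves, the count of identical clades and
#' the fraction each tree shares of its own clades are reported.
#'
#' @param tree_a,tree_b \code{dendro} objects over the same leaf set (use
#'   [restrict_to_common_leaves()] first if they differ).
#' @return List \code{shared_clades}, \code{clades_a}, \code{clades_b},
#'   \code{fraction_shared_a}, \code{fraction_shared_b}.
#' @export
common_nodes <- function(tree_a, tree_b) {
  if (!setequal(tree_a$labels, tree_b$labels))
    stop("trees must share one leaf set; restrict_to_common_leaves() first")
  ka <- unique(.clade_keys(tree_a))
  kb <- unique(.clade_keys(tree_b))
  shared <- length(intersect(ka, kb))
  list(shared_clades = shared, clades_a = length(ka), clades_b = length(kb),
       fraction_shared_a = if (length(ka)) shared / length(ka) else NA_real_,
       fraction_shared_b = if (length(kb)) shared / length(kb) else NA_real_)
}

#' Fowlkes-Mallows index of two trees at k clusters
#'
#' Both trees are cut into \code{k} clusters by height order and the index
#' \eqn{B_k = T / \sqrt{P Q}} is computed, where \eqn{T} is the number of
#' leaf pairs co-clustered in both trees and \eqn{P}, \eqn{Q} the within-tree
#' co-clustered pair counts.
#'
#' @param tree_a,tree_b \code{dendro} objects over the same leaf set.
#' @param k Number of clusters, \code{2 <= k <= n - 1}.
#' @return Numeric in \eqn{[0,1]}; 0 with attribute \code{degenerate = TRUE}
#'   when either cut has no co-clustered pair.
#' @export
fowlkes_mallows <- function(tree_a, tree_b, k) {
  if (!setequal(tree_a$labels, tree_b$labels))
    stop("trees must share one leaf set")
  n <- length(tree_a$labels)
  if (k < 2L || k > n - 1L) stop("k must be in [2, n-1]")
  ca <- cut_k(tree_a, k)
  cb <- cut_k(tree_b, k)[names(ca)]
  tab <- table(ca, cb)
  T_ <- sum(tab^2) - n
  P <- sum(rowSums(tab)^2) - n
  Q <- sum(colSums(tab)^2) - n
  if (P == 0 || Q == 0) return(structure(0, degenerate = TRUE))
  T_ / sqrt(P * Q)
}

#' Cophenetic correlation between two trees
#'
#' Pearson correlation of the two cophenetic (merge-height) distance vectors
#' over all common leaf pairs.
#'
#' @param tree_a,tree_b \code{dendro} objects over the same leaf set.
#' @return Numeric in \eqn{[-1, 1]}; \code{NA} with attribute
#'   \code{degenerate} if either vector has zero variance.
#' @export
cophenetic_correlation <- function(tree_a, tree_b) {
  if (!setequal(tree_a$labels, tree_b$labels))
    stop("trees must share one leaf set")
  labs <- sort(tree_a$labels)
  da <- dendro_cophenetic(tree_a)[labs, labs]
  db <- dendro_cophenetic(tree_b)[labs, labs]
  va <- da[upper.tri(da)]; vb <- db[upper.tri(db)]
  if (stats::var(va) == 0 || stats::var(vb) == 0)
    return(structure(NA_real_, degenerate = TRUE))
  stats::cor(va, vb)
}

#' Full pairwise comparison of two dendrograms
#'
#' Restricts to common leaves, then reports shared-clade statistics,
#' Fowlkes-Mallows indices at the requested \code{k} values and the
#' cophenetic correlation.
#'
#' @param tree_a,tree_b \code{dendro} objects (leaf sets may differ).
#' @param name_a,name_b Names for the report.
#' @param k_values Integer vector of cut sizes for Fowlkes-Mallows; values
#'   outside \code{[2, n-1]} are dropped.
#' @return Object of class \code{tree_comparison} (a list).
#' @export
compare_trees <- function(tree_a, tree_b, name_a = "tree_a",
                          name_b = "tree_b",
                          k_values = c(5L, 10L, 15L)) {
  r <- restrict_to_common_leaves(tree_a, tree_b)
  n <- length(r$common_leaves)
  cn <- common_nodes(r$tree_a, r$tree_b)
  ks <- k_values[k_values >= 2L & k_values <= n - 1L]
  fm <- vapply(ks, function(k)
    as.numeric(fowlkes_mallows(r$tree_a, r$tree_b, k)), numeric(1))
  names(fm) <- ks
  structure(c(list(tree_a = name_a, tree_b = name_b, common_leaves = n),
              cn,
              list(fm_at_k = fm,
                   cophenetic_r = as.numeric(
                     cophenetic_correlation(r$tree_a, r$tree_b)))),
            class = "tree_comparison")
}

#' @export
print.tree_comparison <- function(x, ...) {
  cat("tree_comparison:", x$tree_a, "vs", x$tree_b, "over", x$common_leaves,
      "common leaves\n")
  cat("  shared clades:", x$shared_clades, "of", x$clades_a, "/", x$clades_b,
      sprintf("(%.2f / %.2f)", x$fraction_shared_a, x$fraction_shared_b), "\n")
  cat("  cophenetic r:", format(x$cophenetic_r, digits = 3), "\n")
  invisible(x)
}
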