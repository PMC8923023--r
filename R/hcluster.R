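#' Pearson-correlation distance between two (possibly masked) profiles
#'
#' Distance \eqn{d = 1 - r} where \eqn{r} is the Pearson correlation over
#' jointly usable (unmasked, non-\code{NA}) features, so \eqn{d \in [0,2]}.
#' The correlation is undefined when fewer than \code{min_support} features
#' are jointly usable or when either profile has zero variance over that
#' support; undefined distances are returned as \code{d_max} (maximally
#' dissimilar) with attribute \code{undefined = TRUE}.
#'
#' @param x,y Numeric vectors; masked positions as \code{NA}.
#' @param min_support Minimum jointly usable features (default 3).
#' @param d_max Substitute for undefined distances (default 2).
#' @return Numeric scalar in \eqn{[0, 2]}.
#' @examples
#' pearson_distance(c(1, 2, 3), c(3, 2, 1))  # 2: perfectly anti-correlated
#' @export
pearson_distance <- function(x, y, min_support = 3L, d_max = 2) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < min_support) return(structure(d_max, undefined = TRUE))
  xs <- x[ok]; ys <- y[ok]
  vx <- stats::var(xs); vy <- stats::var(ys)
  if (vx == 0 || vy == 0) return(structure(d_max, undefined = TRUE))
  r <- stats::cor(xs, ys)
  max(0, min(2, 1 - r))
}

#' Pairwise Pearson-distance matrix for a profile matrix
#'
#' Vectorized pairwise-complete computation of \eqn{1 - r} over all row
#' pairs, honouring the mask. Pairs with insufficient joint support or zero
#' variance get \code{d_max} and are recorded.
#'
#' @param pm A \code{profile_matrix}, or a plain numeric matrix (optionally
#'   containing \code{NA} for masked entries).
#' @param min_support,d_max See [pearson_distance()].
#' @return Object of class \code{pearson_dist}: list with symmetric numeric
#'   matrix \code{d} (zero diagonal), integer matrix \code{support} of
#'   jointly used feature counts, and two-column matrix \code{undefined} of
#'   row pairs that were substituted with \code{d_max}.
#' @export
pearson_dist_matrix <- function(pm, min_support = 3L, d_max = 2) {
  X <- if (inherits(pm, "profile_matrix")) pm$values else as.matrix(pm)
  M <- !is.na(X)
  X0 <- X; X0[!M] <- 0
  Mn <- M * 1
  n_ij <- tcrossprod(Mn)                    # joint support
  Sx  <- tcrossprod(X0, Mn)                 # sum of x over joint support
  Sxx <- tcrossprod(X0^2, Mn)
  Sxy <- tcrossprod(X0)
  cov_ <- Sxy - Sx * t(Sx) / n_ij
  varx <- pmax(Sxx - Sx^2 / n_ij, 0)
  vary <- t(varx)
  denom <- sqrt(varx * vary)
  r <- ifelse(denom > 0, cov_ / denom, NA_real_)
  r <- pmin(pmax(r, -1), 1)
  d <- 1 - r
  bad <- (n_ij < min_support) | !is.finite(d)
  diag(bad) <- FALSE
  und <- which(bad & upper.tri(bad), arr.ind = TRUE)
  d[bad] <- d_max
  diag(d) <- 0
  d <- (d + t(d)) / 2                        # enforce exact symmetry
  dimnames(d) <- list(rownames(X), rownames(X))
  structure(list(d = d, support = n_ij, undefined = und),
            class = "pearson_dist")
}

#' Agglomerative hierarchical clustering (Lance-Williams)
#'
#' From-scratch agglomerative clustering over a full distance matrix:
#' repeatedly merge the pair of clusters at minimum inter-cluster distance,
#' updating distances by the Lance-Williams rule for the chosen linkage
#' (average: size-weighted mean; complete: maximum; single: minimum).
#' Distance ties are broken by the lexicographically lowest pair of cluster
#' indices, where a cluster is indexed by the smallest original row it
#' contains; results are therefore stable under input row permutation.
#'
#' @param d Symmetric numeric distance matrix (or \code{pearson_dist}).
#' @param linkage One of \code{"average"}, \code{"complete"},
#'   \code{"single"}.
#' @param labels Optional leaf labels; defaults to rownames of \code{d}.
#' @return Object of class \code{dendro}: list with \code{merge} (hclust
#'   convention: negative entries are leaves, positive entries earlier
#'   merges), \code{height}, \code{size} (leaves per merge), \code{order}
#'   (leaf ordering for display), \code{labels}, \code{linkage}. Convertible
#'   with [as.hclust.dendro()].
#' @examples
#' d <- matrix(c(0, 1, 4, 1, 0, 5, 4, 5, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' agglomerate(d, "average")$height  # 1.0, 4.5
#' @export
agglomerate <- function(d, linkage = c("average", "complete", "single"),
                        labels = NULL) {
  linkage <- match.arg(linkage)
  if (inherits(d, "pearson_dist")) d <- d$d
  d <- as.matrix(d)
  n <- nrow(d)
  if (is.null(labels)) labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (n != ncol(d)) stop("distance matrix must be square")
  if (any(!is.finite(d))) stop("non-finite distances")
  if (n == 1L)
    return(structure(list(merge = matrix(integer(), 0, 2),
                          height = numeric(), size = integer(),
                          order = 1L, labels = labels, linkage = linkage),
                     class = "dendro"))

  D <- d
  diag(D) <- Inf
  active <- rep(TRUE, n)
  sizes <- rep(1L, n)
  min_leaf <- seq_len(n)        # tie-break index of each live cluster slot
  node_of <- -seq_len(n)        # hclust id of the cluster in each slot
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  msize <- integer(n - 1L)

  # cached per-row minimum over active columns (with an attaining column),
  # so each step scans O(n) rows instead of the full matrix; ties are still
  # resolved globally and exactly
  rmin <- apply(D, 1L, min)
  amin <- apply(D, 1L, which.min)

  for (step in seq_len(n - 1L)) {
    act <- which(active)
    mn <- min(rmin[act])
    rows <- act[rmin[act] == mn]
    # enumerate every pair attaining the minimum, then tie-break
    # lexicographically on the (min-leaf, min-leaf) pair
    best <- NULL
    for (r in rows) {
      cols <- act[D[r, act] == mn]
      cols <- cols[cols != r]
      for (cc in cols) {
        key <- c(min(min_leaf[r], min_leaf[cc]), max(min_leaf[r], min_leaf[cc]))
        if (is.null(best) || key[1] < best$key[1] ||
            (key[1] == best$key[1] && key[2] < best$key[2]))
          best <- list(i = r, j = cc, key = key)
      }
    }
    i <- best$i; j <- best$j
    if (min_leaf[j] < min_leaf[i]) { tmp <- i; i <- j; j <- tmp }

    # merge row: the child containing the lowest original row comes first,
    # so the display order (and hence cluster numbering) starts from it
    mi <- node_of[i]; mj <- node_of[j]
    merge[step, ] <- c(mi, mj)
    height[step] <- mn
    msize[step] <- sizes[i] + sizes[j]

    # Lance-Williams update into slot i
    others <- which(active & seq_len(n) != i & seq_len(n) != j)
    if (length(others)) {
      dnew <- switch(linkage,
        average = (sizes[i] * D[i, others] + sizes[j] * D[j, others]) /
                  (sizes[i] + sizes[j]),
        complete = pmax(D[i, others], D[j, others]),
        single = pmin(D[i, others], D[j, others]))
      D[i, others] <- dnew
      D[others, i] <- dnew
    }
    D[i, j] <- D[j, i] <- Inf
    D[j, others] <- D[others, j] <- Inf
    sizes[i] <- sizes[i] + sizes[j]
    min_leaf[i] <- min(min_leaf[i], min_leaf[j])
    node_of[i] <- step
    active[j] <- FALSE

    # refresh the row-minimum cache
    if (length(others)) {
      rmin[i] <- min(D[i, others])
      amin[i] <- others[which.min(D[i, others])]
      stale <- others[amin[others] %in% c(i, j)]
      for (k in stale) {
        ok <- which(active & seq_len(n) != k)
        rmin[k] <- min(D[k, ok])
        amin[k] <- ok[which.min(D[k, ok])]
      }
      fresh <- setdiff(others, stale)
      upd <- fresh[D[fresh, i] < rmin[fresh]]
      rmin[upd] <- D[upd, i]
      amin[upd] <- i
    }
    rmin[j] <- Inf
  }

  if (linkage %in% c("average", "complete") &&
      any(diff(height) < -1e-9 * max(abs(height), 1)))
    stop("internal error: non-monotone merge heights for ", linkage,
         " linkage")

  tree <- structure(list(merge = merge, height = height, size = msize,
                         order = .dendro_order(merge, n), labels = labels,
                         linkage = linkage),
                    class = "dendro")
  tree
}

# leaf display order by depth-first traversal of the merge list
.dendro_order <- function(merge, n) {
  if (n == 1L) return(1L)
  leaves <- function(k) {
    if (k < 0) return(-k)
    c(leaves(merge[k, 1]), leaves(merge[k, 2]))
  }
  leaves(nrow(merge))
}

#' @export
print.dendro <- function(x, ...) {
  cat("dendro:", length(x$labels), "leaves,", x$linkage, "linkage, root height",
      format(max(c(0, x$height))), "\n")
  invisible(x)
}

#' Convert a dendro object to a stats::hclust object
#'
#' @param x A \code{dendro}.
#' @param ... Ignored.
#' @return An object of class \code{hclust}.
#' @export
as.hclust.dendro <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = x$linkage,
                 call = match.call(), dist.method = "pearson"),
            class = "hclust")
}

#' Clades (internal-node leaf sets) of a dendrogram
#'
#' @param tree A \code{dendro}.
#' @param include_root Keep the root clade (all leaves)?
#' @return List of integer vectors (sorted leaf indices), one per merge.
#' @export
dendro_clades <- function(tree, include_root = FALSE) {
  nm <- nrow(tree$merge)
  if (nm == 0L) return(list())
  clades <- vector("list", nm)
  for (k in seq_len(nm)) {
    l <- tree$merge[k, 1]; r <- tree$merge[k, 2]
    clades[[k]] <- sort(c(if (l < 0) -l else clades[[l]],
                          if (r < 0) -r else clades[[r]]))
  }
  if (!include_root) clades <- clades[-nm]
  clades
}

#' Cut a dendrogram at a relative branch height
#'
#' The cut height is \code{fraction} times the root (maximum) merge height;
#' all merges with height less than or equal to the cut height are applied
#' and the resulting connected components are the clusters. Clusters are
#' numbered 1..k by the position of their leftmost leaf in the dendrogram's
#' display order.
#'
#' @param tree A \code{dendro}.
#' @param fraction Relative height in \eqn{(0, 1]} (default 0.75).
#' @return Object of class \code{cluster_assignment}: list with named
#'   integer vector \code{cluster} (per leaf label), \code{k},
#'   \code{cut_height} and \code{fraction}.
#' @export
cut_relative <- function(tree, fraction = 0.75) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]")
  n <- length(tree$labels)
  if (n == 0L) stop("empty tree")
  cut_height <- if (length(tree$height)) fraction * max(tree$height) else 0
  comp <- seq_len(n)
  if (length(tree$height)) {
    # union-find over merges at or below the cut
    node_members <- vector("list", nrow(tree$merge))
    for (k in seq_len(nrow(tree$merge))) {
      l <- tree$merge[k, 1]; r <- tree$merge[k, 2]
      members <- c(if (l < 0) -l else node_members[[l]],
                   if (r < 0) -r else node_members[[r]])
      node_members[[k]] <- members
      if (tree$height[k] <= cut_height)
        comp[members] <- min(comp[members])
    }
  }
  # renumber by leftmost leaf in display order
  ord <- tree$order
  ids <- unique(comp[ord])
  cluster <- match(comp, ids)
  names(cluster) <- tree$labels
  structure(list(cluster = cluster, k = length(ids),
                 cut_height = cut_height, fraction = fraction),
            class = "cluster_assignment")
}

#' Cut a dendrogram into exactly k clusters
#'
#' Applies the first \code{n - k} merges in height order; equivalent to a
#' height cut between the (n-k)-th and (n-k+1)-th merge heights.
#'
#' @param tree A \code{dendro}.
#' @param k Number of clusters, \code{1 <= k <= n}.
#' @return Named integer vector of cluster ids (1..k), numbered by leftmost
#'   leaf in display order.
#' @export
cut_k <- function(tree, k) {
  n <- length(tree$labels)
  stopifnot(k >= 1L, k <= n)
  comp <- seq_len(n)
  n_apply <- n - k
  if (n_apply > 0L) {
    node_members <- vector("list", nrow(tree$merge))
    for (s in seq_len(n_apply)) {
      l <- tree$merge[s, 1]; r <- tree$merge[s, 2]
      members <- c(if (l < 0) -l else node_members[[l]],
                   if (r < 0) -r else node_members[[r]])
      node_members[[s]] <- members
      comp[members] <- min(comp[members])
    }
  }
  ids <- unique(comp[tree$order])
  cluster <- match(comp, ids)
  names(cluster) <- tree$labels
  cluster
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("cluster_assignment: k =", x$k, "at cut height",
      format(x$cut_height), "(fraction", x$fraction, ")\n")
  invisible(x)
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths are derived from merge heights: a leaf's branch is its
#' parent's height, an internal branch is the difference between parent and
#' child heights. A parse-serialize round trip through any standard Newick
#' parser preserves topology and heights.
#'
#' @param tree A \code{dendro}.
#' @param labels Optional labels overriding \code{tree$labels}; must be
#'   unique.
#' @param digits Significant digits for branch lengths.
#' @return A single Newick string, semicolon-terminated.
#' @export
to_newick <- function(tree, labels = NULL, digits = 10) {
  if (is.null(labels)) labels <- tree$labels
  if (anyDuplicated(labels)) stop("duplicate leaf labels")
  n <- length(labels)
  if (n == 1L) return(paste0(labels, ";"))
  fmt <- function(x) formatC(x, digits = digits, format = "g")
  node_h <- tree$height
  render <- function(id, parent_h) {
    if (id < 0)
      return(paste0(labels[-id], ":", fmt(parent_h)))
    h <- node_h[id]
    paste0("(", render(tree$merge[id, 1], h), ",",
           render(tree$merge[id, 2], h), "):", fmt(parent_h - h))
  }
  root <- nrow(tree$merge)
  h <- node_h[root]
  paste0("(", render(tree$merge[root, 1], h), ",",
         render(tree$merge[root, 2], h), ");")
}

#' Cophenetic distance matrix of a dendrogram
#'
#' The cophenetic distance between two leaves is the merge height at which
#' they first join.
#'
#' @param tree A \code{dendro}.
#' @return Symmetric numeric matrix with leaf labels as dimnames.
#' @export
dendro_cophenetic <- function(tree) {
  n <- length(tree$labels)
  out <- matrix(0, n, n, dimnames = list(tree$labels, tree$labels))
  if (n == 1L) return(out)
  node_members <- vector("list", nrow(tree$merge))
  for (k in seq_len(nrow(tree$merge))) {
    l <- tree$merge[k, 1]; r <- tree$merge[k, 2]
    lm <- if (l < 0) -l else node_members[[l]]
    rm_ <- if (r < 0) -r else node_members[[r]]
    out[lm, rm_] <- tree$height[k]
    out[rm_, lm] <- tree$height[k]
    node_members[[k]] <- c(lm, rm_)
  }
  out
}
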