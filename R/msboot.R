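#' Multiscale bootstrap configuration
#'
#' @param scales Positive reals: relative resample sizes (default ten values
#'   0.5 to 1.4 in steps of 0.1; scale 1.0 gives the ordinary bootstrap).
#' @param B Replicates per scale (default 1000; at least 100 for a stable AU
#'   fit).
#' @param seed Integer seed.
#' @param linkage Linkage passed to [agglomerate()].
#' @param min_support,d_max Passed to [pearson_dist_matrix()].
#' @return Object of class \code{boot_config}.
#' @export
boot_config <- function(scales = seq(0.5, 1.4, by = 0.1), B = 1000L,
                        seed = 1L, linkage = "average",
                        min_support = 3L, d_max = 2) {
  if (any(scales <= 0)) stop("scales must be positive")
  B <- as.integer(B)
  if (B < 100L) stop("B must be at least 100 for AU fitting")
  structure(list(scales = as.numeric(scales), B = B, seed = as.integer(seed),
                 linkage = linkage, min_support = as.integer(min_support),
                 d_max = d_max),
            class = "boot_config")
}

#' Resample feature columns with replacement
#'
#' Draws \code{round(scale * m)} of the \code{m} feature columns with
#' replacement; masks travel with their columns. The resampling unit is the
#' feature column (one stage or cell-type measurement), the convention for
#' multiscale bootstrapping of profile clusterings.
#'
#' @param values Numeric matrix (masked entries \code{NA}).
#' @param scale Positive real.
#' @return Matrix of the resampled columns.
#' @export
resample_columns <- function(values, scale) {
  m <- ncol(values)
  if (m < 4L) stop("matrix must have at least 4 feature columns")
  m2 <- round(scale * m)
  if (m2 < 3L) stop("scale too small: fewer than 3 resampled columns")
  values[, sample.int(m, m2, replace = TRUE), drop = FALSE]
}

#' Fit the multiscale-bootstrap AU model to per-scale recovery counts
#'
#' Given per-scale counts of how often a clade was recovered among \code{B}
#' replicates, fits \eqn{z_r = v\sqrt{r} + c/\sqrt{r}} to the normal
#' quantiles \eqn{z_r = \Phi^{-1}(1 - bp_r)} of the continuity-corrected
#' proportions \eqn{(count + 0.5)/(B + 1)}, by weighted least squares with
#' weights \eqn{B\,\phi(z_r)^2 / (bp_r (1 - bp_r))} when all raw proportions
#' are strictly inside (0,1), unweighted otherwise. Then
#' \eqn{AU = 1 - \Phi(v - c)} and \eqn{BP = 1 - \Phi(v + c)}. When fewer
#' than 3 scales have raw proportions strictly inside (0,1) the fit is
#' flagged (\code{fit_ok = FALSE}) and AU falls back to the plain bootstrap
#' proportion at scale 1.0 (or the scale closest to 1.0).
#'
#' @param counts Integer vector of recovery counts, one per scale.
#' @param B Number of replicates per scale.
#' @param scales Numeric vector of scales (same length as \code{counts}).
#' @return List \code{v}, \code{c}, \code{au}, \code{bp}, \code{fit_ok},
#'   \code{bp_at_scale} (raw proportions, named by scale).
#' @export
fit_multiscale <- function(counts, B, scales) {
  stopifnot(length(counts) == length(scales))
  raw <- counts / B
  names(raw) <- format(scales)
  inside <- raw > 0 & raw < 1
  ref <- which.min(abs(scales - 1))
  if (sum(inside) < 3L) {
    return(list(v = NA_real_, c = NA_real_, au = raw[[ref]], bp = raw[[ref]],
                fit_ok = FALSE, bp_at_scale = raw))
  }
  bp_c <- (counts + 0.5) / (B + 1)
  z <- stats::qnorm(1 - bp_c)
  sq <- sqrt(scales)
  X <- cbind(v = sq, c = 1 / sq)
  w <- if (all(inside)) B * stats::dnorm(z)^2 / (bp_c * (1 - bp_c)) else
    rep(1, length(z))
  fit <- stats::lm.wfit(X, z, w)
  v <- unname(fit$coefficients["v"]); cc <- unname(fit$coefficients["c"])
  list(v = v, c = cc,
       au = 1 - stats::pnorm(v - cc), bp = 1 - stats::pnorm(v + cc),
       fit_ok = TRUE, bp_at_scale = raw)
}

#' Multiscale bootstrap support (AU and BP) for dendrogram clades
#'
#' For every internal clade of the reference tree, counts over the scales of
#' a multiscale column bootstrap how often a tree rebuilt on resampled
#' feature columns contains the identical leaf set, then fits the AU model
#' ([fit_multiscale()]) per clade. Clades are compared as leaf-label sets,
#' so support is invariant to leaf relabelling and sibling order.
#'
#' @param pm A \code{profile_matrix} or plain matrix (masked entries
#'   \code{NA}).
#' @param tree The reference \code{dendro} built from \code{pm} with the
#'   same metric and linkage.
#' @param config A [boot_config()].
#' @return data.frame with one row per internal clade (root included, its
#'   support is 1 by construction): columns \code{clade} (comma-joined
#'   sorted leaf labels), \code{size}, per-scale \code{bp_<scale>} raw
#'   proportions, \code{v}, \code{c}, \code{au}, \code{bp}, \code{fit_ok}.
#' @export
node_support <- function(pm, tree, config = boot_config()) {
  X <- if (inherits(pm, "profile_matrix")) pm$values else as.matrix(pm)
  stopifnot(inherits(config, "boot_config"))
  n <- nrow(X)
  if (n != length(tree$labels)) stop("tree does not match the matrix")
  clades <- dendro_clades(tree, include_root = TRUE)
  clade_keys <- vapply(clades, function(ix) paste(sort(tree$labels[ix]),
                                                  collapse = ","),
                       character(1))
  counts <- matrix(0L, length(clades), length(config$scales),
                   dimnames = list(clade_keys, format(config$scales)))
  for (si in seq_along(config$scales)) {
    scale <- config$scales[si]
    set.seed(.sub_seed(config$seed, paste0("scale", format(scale))))
    for (b in seq_len(config$B)) {
      Xb <- resample_columns(X, scale)
      db <- pearson_dist_matrix(Xb, min_support = config$min_support,
                                d_max = config$d_max)
      tb <- agglomerate(db, config$linkage)
      keys_b <- vapply(dendro_clades(tb, include_root = TRUE),
                       function(ix) paste(sort(tb$labels[ix]), collapse = ","),
                       character(1))
      hit <- clade_keys %in% keys_b
      counts[hit, si] <- counts[hit, si] + 1L
    }
  }
  fits <- lapply(seq_along(clades), function(i)
    fit_multiscale(counts[i, ], config$B, config$scales))
  bp_raw <- t(vapply(fits, function(f) unname(f$bp_at_scale),
                     numeric(length(config$scales))))
  colnames(bp_raw) <- paste0("bp_", format(config$scales))
  out <- data.frame(clade = clade_keys,
                    size = vapply(clades, length, integer(1)),
                    bp_raw,
                    v = vapply(fits, function(f) f$v, numeric(1)),
                    c = vapply(fits, function(f) f$c, numeric(1)),
                    au = vapply(fits, function(f) unname(f$au), numeric(1)),
                    bp = vapply(fits, function(f) unname(f$bp), numeric(1)),
                    fit_ok = vapply(fits, function(f) f$fit_ok, logical(1)),
                    check.names = FALSE)
  rownames(out) <- NULL
  out
}
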