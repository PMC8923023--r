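#' Standardize a block as fraction of its maximum
#'
#' Developmental time-course blocks are expressed as the fraction of the
#' maximum transcript read count of the set, so that every block ranges over
#' \eqn{[0,1]} with maximum 1. An all-zero block stays all zero and is
#' flagged.
#'
#' @param values Non-negative numeric vector of read counts.
#' @return List with \code{values} (rescaled), and logical \code{all_zero}.
#' @examples
#' fraction_of_max(c(5, 10, 20, 10))
#' @export
fraction_of_max <- function(values) {
  if (length(values) == 0L) stop("empty value vector")
  if (any(values < 0)) stop("values must be non-negative")
  mx <- max(values)
  if (mx == 0) return(list(values = values * 0, all_zero = TRUE))
  list(values = values / mx, all_zero = FALSE)
}

#' Standardize a block as fraction of its sum
#'
#' Two-part cell-fraction blocks (e.g. prestalk/prespore read counts) are
#' expressed as the fraction of the summed reads, so the block sums to 1.
#'
#' @inheritParams fraction_of_max
#' @return List with \code{values} and logical \code{all_zero}.
#' @examples
#' fraction_of_sum(c(4, 6))
#' @export
fraction_of_sum <- function(values) {
  if (length(values) == 0L) stop("empty value vector")
  if (any(values < 0)) stop("values must be non-negative")
  s <- sum(values)
  if (s == 0) return(list(values = values * 0, all_zero = TRUE))
  list(values = values / s, all_zero = FALSE)
}

#' Flag a low-coverage block
#'
#' A block whose summed raw reads are at most \code{threshold} (default 10)
#' carries little information; such blocks are flagged and later masked out
#' of the profile array rather than contributing spurious flat profiles.
#'
#' @param values Raw (unstandardized) counts of one block; may be empty.
#' @param threshold Maximum total reads to call low coverage.
#' @return Logical.
#' @export
mask_low_coverage <- function(values, threshold = 10) {
  sum(values) <= threshold
}

#' Standardize one profile block
#'
#' Applies the study's standardization rule: blocks of exactly two values
#' (cell fractions) are scaled to fractions of the sum, all other blocks to
#' fractions of the maximum. Low-coverage status is determined from the raw
#' counts before scaling.
#'
#' @param values Non-negative counts of one block.
#' @param method \code{"auto"} (the rule above), \code{"max"} or \code{"sum"}.
#' @param low_threshold Passed to [mask_low_coverage()].
#' @return List \code{values}, \code{all_zero}, \code{low_coverage}.
#' @export
standardize_block <- function(values, method = c("auto", "max", "sum"),
                              low_threshold = 10) {
  method <- match.arg(method)
  if (method == "auto") method <- if (length(values) == 2L) "sum" else "max"
  low <- mask_low_coverage(values, low_threshold)
  out <- if (method == "sum") fraction_of_sum(values) else fraction_of_max(values)
  out$low_coverage <- low
  out
}

#' Assemble the per-family profile matrix across a species subset
#'
#' Builds the concatenated "linear array" of standardized expression values,
#' one row per ortholog family, by joining each family's blocks across the
#' chosen species in a fixed (species, block, label) feature order. Positions
#' belonging to species where the family has no member, or to low-coverage /
#' all-zero blocks, are masked (excluded from distances, not zeroed). When a
#' family has several paralogs in one species, the member with the highest
#' summed reads represents it. Families with fewer than \code{min_features}
#' usable features are dropped and reported.
#'
#' @param counts Named list (per species) of data.frames with columns
#'   \code{gene_id}, \code{block_id}, \code{label}, \code{count}, as produced
#'   by [simulate_dataset()] or read from TSV.
#' @param ortholog_map data.frame \code{family_id}, \code{species},
#'   \code{gene_id}.
#' @param species_subset Ordered character vector of species to include.
#' @param min_features Minimum unmasked features to keep a row (default 4).
#' @param low_threshold Low-coverage read total, see [mask_low_coverage()].
#' @return Object of class \code{profile_matrix}: list with numeric matrix
#'   \code{values} (families x features, masked entries \code{NA}), logical
#'   \code{mask} (\code{TRUE} = usable), data.frame \code{features}
#'   (\code{species}, \code{block_id}, \code{label}), and character vector
#'   \code{dropped} of family ids removed for lack of usable features.
#' @export
assemble_matrix <- function(counts, ortholog_map, species_subset,
                            min_features = 4L, low_threshold = 10) {
  stopifnot(all(species_subset %in% names(counts)))
  omap <- ortholog_map[ortholog_map$species %in% species_subset, , drop = FALSE]
  families <- sort(unique(omap$family_id))
  if (length(families) == 0L) stop("no families present in species subset")

  # fixed feature layout from the first species' tables
  feat <- NULL
  for (sp in species_subset) {
    tab <- counts[[sp]]
    # feature layout: the (block, label) order of the first gene in the file
    first_gene <- tab$gene_id[1]
    layout <- tab[tab$gene_id == first_gene, c("block_id", "label")]
    feat <- rbind(feat, data.frame(species = sp, block_id = layout$block_id,
                                   label = layout$label))
  }
  m <- nrow(feat)
  key <- paste(feat$species, feat$block_id, feat$label, sep = "\r")

  vals <- matrix(NA_real_, length(families), m,
                 dimnames = list(families, NULL))
  mask <- matrix(FALSE, length(families), m, dimnames = list(families, NULL))

  for (sp in species_subset) {
    tab <- counts[[sp]]
    sp_cols <- which(feat$species == sp)
    sp_map <- omap[omap$species == sp, , drop = FALSE]
    # per-gene summed reads, to pick the dominant paralog per family
    totals <- tapply(tab$count, tab$gene_id, sum)
    for (f in unique(sp_map$family_id)) {
      genes <- sp_map$gene_id[sp_map$family_id == f]
      gene <- genes[which.max(totals[genes])]
      gtab <- tab[tab$gene_id == gene, , drop = FALSE]
      for (b in unique(gtab$block_id)) {
        btab <- gtab[gtab$block_id == b, , drop = FALSE]
        std <- standardize_block(btab$count, low_threshold = low_threshold)
        cols <- match(paste(sp, b, btab$label, sep = "\r"), key)
        if (anyNA(cols)) stop("block labels of gene ", gene,
                              " do not match the species feature layout")
        vals[f, cols] <- std$values
        mask[f, cols] <- !(std$all_zero || std$low_coverage)
      }
    }
  }

  usable <- rowSums(mask)
  dropped <- families[usable < min_features]
  keep <- setdiff(families, dropped)
  vals[!mask] <- NA_real_
  structure(list(values = vals[keep, , drop = FALSE],
                 mask = mask[keep, , drop = FALSE],
                 features = feat, dropped = dropped,
                 species_subset = species_subset),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat("profile_matrix:", nrow(x$values), "families x", ncol(x$values),
      "features (", paste(x$species_subset, collapse = ", "), ")\n")
  cat("  usable entries:", sum(x$mask), "/", length(x$mask),
      "; dropped families:", length(x$dropped), "\n")
  invisible(x)
}

#' Write an assembled profile matrix as TSV with a JSON sidecar
#'
#' @param pm A \code{profile_matrix}.
#' @param path Output TSV path; the sidecar is written as
#'   \code{<path>.meta.json}.
#' @return Invisibly the TSV path.
#' @export
write_profile_matrix <- function(pm, path) {
  df <- as.data.frame(pm$values)
  names(df) <- paste(pm$features$species, pm$features$block_id,
                     pm$features$label, sep = ".")
  df <- cbind(family_id = rownames(pm$values), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(
    species_subset = pm$species_subset,
    features = pm$features,
    dropped = pm$dropped,
    n_masked = sum(!pm$mask)
  ), paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}
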