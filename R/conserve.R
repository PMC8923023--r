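#' Classify a standardized developmental profile into an expression class
#'
#' Deterministic rules applied in order to a standardized series (values in
#' \eqn{[0,1]}, maximum 1 unless all zero):
#' \enumerate{
#'   \item \code{constitutive} if \code{max - min <= constitutive_range};
#'   \item \code{decrease_after_growth} if the maximum is at the first point
#'     and the mean of the remaining points is below 0.5;
#'   \item \code{mid_dip} if the minimum falls strictly inside the middle
#'     third and both end values are at least \code{dip_ends};
#'   \item \code{mid_peak} if the maximum falls strictly inside the middle
#'     third and both end values are at most \code{peak_ends};
#'   \item \code{early_up} if the (first-attained) maximum lies in the first
#'     half, excluding the first point; otherwise
#'   \item \code{late_up}.
#' }
#' The extremum position convention uses the first index attaining the
#' extremum; "middle third" of \code{n} points is the 0-based index range
#' \code{[ceiling(n/3), floor(2*(n-1)/3)]}.
#'
#' @param s Numeric vector, length at least 4, values in \eqn{[0,1]}.
#' @param constitutive_range Maximum range still called constitutive (0.5).
#' @param dip_ends Minimum end values for \code{mid_dip} (0.75).
#' @param peak_ends Maximum end values for \code{mid_peak} (0.5).
#' @return One of [ARCHETYPES], or \code{"none"} for an all-zero series.
#' @examples
#' classify_profile(c(1, 0.9, 0.8, 1))       # constitutive
#' classify_profile(c(1, 0.2, 0.1, 0.1))     # decrease_after_growth
#' classify_profile(c(0.1, 0.2, 1, 0.3))     # mid_peak
#' @export
classify_profile <- function(s, constitutive_range = 0.5, dip_ends = 0.75,
                             peak_ends = 0.5) {
  n <- length(s)
  if (n < 4L) stop("profile must have at least 4 points")
  if (any(s < 0 | s > 1)) stop("profile values must be in [0,1]")
  if (max(s) == 0) return("none")
  imax <- which.max(s) - 1L   # 0-based
  imin <- which.min(s) - 1L
  mid_lo <- ceiling(n / 3); mid_hi <- floor(2 * (n - 1) / 3)
  in_mid <- function(i) i >= mid_lo && i <= mid_hi
  if (max(s) - min(s) <= constitutive_range) return("constitutive")
  if (imax == 0L && mean(s[-1L]) < 0.5) return("decrease_after_growth")
  if (in_mid(imin) && s[1L] >= dip_ends && s[n] >= dip_ends) return("mid_dip")
  if (in_mid(imax) && s[1L] <= peak_ends && s[n] <= peak_ends) return("mid_peak")
  if (imax > 0L && imax < n / 2) return("early_up")
  "late_up"
}

#' Phylogenetic pattern of a cross-species difference vector
#'
#' Interprets which species differ from the majority state of a conserved
#' feature, against the dictyostelid phylogeny: group 4 is (Ddis, Dpur),
#' branch II is (Ddis, Dpur, Dlac) and branch I is (Ppal, Dfas). The call is
#' symmetric under complementing the vector (it does not matter which state
#' is labelled "majority").
#'
#' @param diff Logical vector of length 5 in the fixed order [SPECIES5];
#'   \code{TRUE} = species differs from the majority.
#' @return One of \code{"all_five"}, \code{"group4_specific_change"},
#'   \code{"branchI_vs_branchII"}, \code{"single_species"},
#'   \code{"scattered"}.
#' @export
phylo_pattern <- function(diff) {
  stopifnot(is.logical(diff), length(diff) == 5L)
  v <- diff
  if (sum(v) >= 3L) v <- !v   # canonicalize to the minority side
  k <- sum(v)
  if (k == 0L) return("all_five")
  if (k == 1L) return("single_species")
  if (k == 2L && v[1] && v[2]) return("group4_specific_change")
  if (k == 2L && v[4] && v[5]) return("branchI_vs_branchII")
  "scattered"
}

#' Prestalk/prespore specificity call from replicate fraction pairs
#'
#' A gene is called specific for a slug cell type when that type's fraction
#' of summed reads reaches \code{threshold} (default 2/3) in every replicate
#' experiment; replicates pointing at different types give
#' \code{"conflict"}; anything else is \code{"none"}.
#'
#' @param fractions Matrix or data.frame with columns \code{prestalk},
#'   \code{prespore} (each row one replicate experiment, rows summing to 1).
#' @param threshold Specificity threshold (default 2/3).
#' @return One of \code{"prestalk"}, \code{"prespore"}, \code{"none"},
#'   \code{"conflict"}.
#' @export
slug_specificity <- function(fractions, threshold = 2 / 3) {
  fractions <- as.matrix(fractions)
  calls <- apply(fractions, 1L, function(p) {
    if (p[1] >= threshold) "prestalk" else if (p[2] >= threshold) "prespore"
    else "none"
  })
  specific <- setdiff(unique(calls), "none")
  if (length(specific) > 1L) return("conflict")
  if (length(specific) == 1L && all(calls == specific)) return(specific)
  if (length(specific) == 1L) return("conflict")
  "none"
}

#' Tabulate percentage distributions of conservation features
#'
#' For grouped conservation records, computes the percentage distribution of
#' each requested feature (expression class, cell-type call, number of
#' species with an ortholog, phylogenetic pattern, ...). Every percentage
#' row sums to 100 up to rounding.
#'
#' @param records data.frame with one row per ortholog family; must contain
#'   the columns named in \code{features}, plus the grouping column.
#' @param features Character vector of column names to tabulate.
#' @param group_by Optional column name to split rows by; \code{NULL}
#'   tabulates all records as one group.
#' @param digits Rounding digits for the percentages.
#' @return Named list (one element per feature) of data.frames: one row per
#'   group, one column per observed state, values in percent.
#' @export
tabulate_conservation <- function(records, features, group_by = NULL,
                                  digits = 1) {
  stopifnot(all(features %in% names(records)))
  groups <- if (is.null(group_by)) list(all = records) else
    split(records, records[[group_by]])
  groups <- Filter(function(g) nrow(g) > 0L, groups)
  # largest-remainder rounding: percentages keep `digits` decimals and the
  # row still sums to exactly 100
  round_quota <- function(p, digits) {
    scaled <- p * 10^digits
    fl <- floor(scaled)
    need <- max(0L, min(length(p), round(100 * 10^digits - sum(fl))))
    if (need > 0L) {
      idx <- order(scaled - fl, decreasing = TRUE)[seq_len(need)]
      fl[idx] <- fl[idx] + 1
    }
    fl / 10^digits
  }
  out <- list()
  for (f in features) {
    states <- sort(unique(as.character(records[[f]])))
    tab <- do.call(rbind, lapply(groups, function(g) {
      x <- table(factor(as.character(g[[f]]), levels = states))
      round_quota(100 * as.numeric(x) / sum(x), digits)
    }))
    colnames(tab) <- states
    out[[f]] <- data.frame(group = names(groups), tab, check.names = FALSE,
                           row.names = NULL)
  }
  out
}

#' Expression-class table in the conventional reporting order
#'
#' Convenience wrapper around [tabulate_conservation()] producing the
#' six-class expression-profile table with columns in the standard order
#' (constitutive, decrease after growth, mid peak, mid dip, early up,
#' late up).
#'
#' @param records data.frame with a \code{profile} column of [ARCHETYPES]
#'   values and a grouping column.
#' @param group_by Grouping column name (e.g. conserved vs unique).
#' @param digits Rounding digits.
#' @return data.frame, one row per group, six percentage columns.
#' @export
expression_class_table <- function(records, group_by, digits = 1) {
  tab <- tabulate_conservation(records, "profile", group_by, digits)$profile
  present <- intersect(ARCHETYPES, names(tab))
  tab[, c("group", present), drop = FALSE]
}
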