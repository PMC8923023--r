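# unordered pair keys; families sorted within pair
.pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Build an interaction catalog with derived secondary edges
#'
#' Primary edges are experimentally established direct interactions between
#' ortholog families. Secondary edges connect two families that share a
#' primary partner (the other interactors of the primary partner) but are
#' not themselves primary partners; self pairs are excluded.
#'
#' @param primary data.frame with columns \code{family_a}, \code{family_b}
#'   and optionally \code{source}.
#' @return Object of class \code{interaction_catalog}: list of data.frames
#'   \code{primary} and \code{secondary} (columns \code{family_a},
#'   \code{family_b}, \code{level}, \code{source}).
#' @examples
#' expand_secondary(data.frame(family_a = c("A", "B"),
#'                             family_b = c("B", "C")))
#' @export
expand_secondary <- function(primary) {
  stopifnot(all(c("family_a", "family_b") %in% names(primary)))
  a <- as.character(primary$family_a); b <- as.character(primary$family_b)
  if (any(a == b)) stop("self-edges are not allowed in the primary catalog")
  src <- if ("source" %in% names(primary)) as.character(primary$source) else
    rep(NA_character_, length(a))
  keys <- .pair_key(a, b)
  dup <- duplicated(keys)
  a <- a[!dup]; b <- b[!dup]; src <- src[!dup]; keys <- keys[!dup]

  # adjacency: all length-2 paths a-b-c yield candidate secondary pair (a,c)
  nodes <- unique(c(a, b))
  adj <- split(c(b, a), c(a, b))
  sec_a <- character(); sec_b <- character()
  for (mid in nodes) {
    nb <- unique(adj[[mid]])
    if (length(nb) >= 2L) {
      prs <- utils::combn(sort(nb), 2L)
      sec_a <- c(sec_a, prs[1, ]); sec_b <- c(sec_b, prs[2, ])
    }
  }
  if (length(sec_a)) {
    sk <- .pair_key(sec_a, sec_b)
    keep <- !duplicated(sk) & !(sk %in% keys)
    sec_a <- sec_a[keep]; sec_b <- sec_b[keep]
  }
  structure(list(
    primary = data.frame(family_a = pmin(a, b), family_b = pmax(a, b),
                         level = rep("primary", length(a)), source = src),
    secondary = data.frame(family_a = sec_a, family_b = sec_b,
                           level = rep("secondary", length(sec_a)),
                           source = rep("derived", length(sec_a)))
  ), class = "interaction_catalog")
}

#' @export
print.interaction_catalog <- function(x, ...) {
  cat("interaction_catalog:", nrow(x$primary), "primary,",
      nrow(x$secondary), "derived secondary edges\n")
  invisible(x)
}

catalog_edges <- function(catalog, level = c("primary", "primary_and_secondary")) {
  level <- match.arg(level)
  if (level == "primary") catalog$primary else
    rbind(catalog$primary, catalog$secondary)
}

#' Count known interactions recovered within clusters
#'
#' An edge of the catalog is recovered when both endpoint families are
#' assigned and share a cluster. Edges with an endpoint absent from the
#' assignment (e.g. partners outside the clustered matrix) are excluded from
#' the denominator and reported separately. Each catalog edge is counted at
#' most once.
#'
#' @param assignment A \code{cluster_assignment} (or named integer vector of
#'   cluster ids per family).
#' @param catalog An \code{interaction_catalog} from [expand_secondary()].
#' @param level \code{"primary"} or \code{"primary_and_secondary"}.
#' @param name Label for this clustering in reports.
#' @return Object of class \code{recovery_report}: list with \code{name},
#'   \code{k}, \code{level}, \code{recovered}, \code{total} (edges with both
#'   endpoints assigned), \code{absent} (edges excluded), and data.frame
#'   \code{edges} of recovered edges with their cluster id.
#' @export
count_recovered <- function(assignment, catalog,
                            level = c("primary", "primary_and_secondary"),
                            name = "clustering") {
  level <- match.arg(level)
  cl <- if (inherits(assignment, "cluster_assignment")) assignment$cluster
        else assignment
  ed <- catalog_edges(catalog, level)
  if (nrow(ed) == 0L)
    return(structure(list(name = name, k = length(unique(cl)), level = level,
                          recovered = 0L, total = 0L, absent = 0L,
                          edges = cbind(ed, cluster = integer(0))),
                     class = "recovery_report"))
  ca <- cl[ed$family_a]; cb <- cl[ed$family_b]
  present <- !is.na(ca) & !is.na(cb)
  rec <- present & ca == cb
  structure(list(name = name, k = length(unique(cl)), level = level,
                 recovered = sum(rec), total = sum(present),
                 absent = sum(!present),
                 edges = cbind(ed[which(rec), , drop = FALSE],
                               cluster = ca[which(rec)])),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("recovery_report [", x$name, "]: ", x$recovered, "/", x$total,
      " ", x$level, " edges recovered in k = ", x$k, " clusters (",
      x$absent, " edges out of matrix)\n", sep = "")
  invisible(x)
}

#' Compare clusterings by recovered interactions
#'
#' Ranks clustering analyses by the number of recovered known interactions
#' (descending), ties broken by name.
#'
#' @param reports List of \code{recovery_report} objects.
#' @return data.frame with columns \code{name}, \code{k}, \code{level},
#'   \code{recovered}, \code{total}, \code{absent}, sorted.
#' @export
compare_clusterings <- function(reports) {
  if (length(reports) < 2L) stop("need at least two reports to compare")
  df <- do.call(rbind, lapply(reports, function(r)
    data.frame(name = r$name, k = r$k, level = r$level,
               recovered = r$recovered, total = r$total, absent = r$absent)))
  df <- df[order(-df$recovered, df$name), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Per-cluster network edge lists
#'
#' Splits the recovered edges of a report into one edge-list data.frame per
#' cluster, suitable for import into graph viewers.
#'
#' @param report A \code{recovery_report}.
#' @return Named list of data.frames keyed by cluster id.
#' @export
cluster_networks <- function(report) {
  if (nrow(report$edges) == 0L) return(list())
  split(report$edges, report$edges$cluster)
}
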