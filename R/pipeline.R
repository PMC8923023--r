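#' Pipeline configuration for the multi-subset clustering study
#'
#' Defines the named species subsets to cluster, the linkage per run, the
#' relative cut height and optional bootstrap settings. Defaults reproduce
#' the study design: average-linkage trees from the Group4 (Ddis, Dpur),
#' BranchII (Ddis, Dpur, Dlac), Ddisonly and Fullprofile (all five species)
#' subsets, plus a complete-linkage Group4 run, all cut at 75% relative
#' branch height.
#'
#' @param species All species present in the inputs.
#' @param subsets Named list of character vectors (subset name -> species).
#' @param linkages Named character vector of linkage per subset run.
#' @param cut_fraction Relative cut height (default 0.75).
#' @param bootstrap \code{NULL} or a [boot_config()]; when set, node support
#'   is computed for every subset tree.
#' @param min_features Passed to [assemble_matrix()].
#' @param seed Integer seed recorded in the manifest.
#' @return Object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(species = SPECIES5,
                            subsets = NULL,
                            linkages = NULL,
                            cut_fraction = 0.75,
                            bootstrap = NULL,
                            min_features = 4L,
                            seed = 1L) {
  if (is.null(subsets)) {
    subsets <- list(
      Group4 = intersect(c("Ddis", "Dpur"), species),
      BranchII = intersect(c("Ddis", "Dpur", "Dlac"), species),
      Ddisonly = intersect("Ddis", species),
      Fullprofile = species,
      Group4Complete = intersect(c("Ddis", "Dpur"), species))
    subsets <- Filter(length, subsets)
  }
  for (nm in names(subsets))
    if (!all(subsets[[nm]] %in% species))
      stop("subset ", nm, " names species outside the declared set")
  if (is.null(linkages)) {
    linkages <- stats::setNames(rep("average", length(subsets)),
                                names(subsets))
    if ("Group4Complete" %in% names(subsets))
      linkages[["Group4Complete"]] <- "complete"
  }
  stopifnot(setequal(names(linkages), names(subsets)))
  structure(list(species = species, subsets = subsets,
                 linkages = linkages, cut_fraction = cut_fraction,
                 bootstrap = bootstrap, min_features = as.integer(min_features),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Validate pipeline inputs
#'
#' Checks count tables for non-negative integer counts and consistent block
#' labels per species, the ortholog map for referential integrity against
#' the count tables, and the interaction catalog for resolvable families.
#' Problems are split into errors (data unusable) and warnings (e.g. catalog
#' partners absent from the matrix, reported but tolerated).
#'
#' @param counts Named list of per-species count data.frames.
#' @param ortholog_map data.frame \code{family_id}, \code{species},
#'   \code{gene_id}.
#' @param catalog Optional data.frame with \code{family_a}, \code{family_b}.
#' @return List \code{errors}, \code{warnings} (character vectors) and
#'   logical \code{ok}.
#' @export
validate_inputs <- function(counts, ortholog_map, catalog = NULL) {
  errors <- character(); warnings_ <- character()
  for (sp in names(counts)) {
    tab <- counts[[sp]]
    need <- c("gene_id", "block_id", "label", "count")
    if (!all(need %in% names(tab))) {
      errors <- c(errors, paste0(sp, ": missing columns ",
                                 paste(setdiff(need, names(tab)),
                                       collapse = ", ")))
      next
    }
    bad <- which(!is.finite(tab$count) | tab$count < 0)
    if (length(bad))
      errors <- c(errors, sprintf(
        "%s: negative or non-finite count for gene %s block %s (value %s)",
        sp, tab$gene_id[bad[1]], tab$block_id[bad[1]], tab$count[bad[1]]))
    # every gene must carry the same (block, label) layout
    layouts <- tapply(paste(tab$block_id, tab$label, sep = "\r"),
                      tab$gene_id, paste, collapse = ";")
    if (length(unique(layouts)) > 1L)
      errors <- c(errors, paste0(sp, ": inconsistent block labels across genes"))
  }
  known_genes <- unlist(lapply(counts, function(t) unique(t$gene_id)),
                        use.names = FALSE)
  missing_genes <- setdiff(ortholog_map$gene_id, known_genes)
  if (length(missing_genes))
    errors <- c(errors, paste0("ortholog map references unknown genes: ",
                               paste(utils::head(missing_genes, 5),
                                     collapse = ", ")))
  if (!is.null(catalog) && nrow(catalog)) {
    fams <- unique(ortholog_map$family_id)
    out_of_map <- setdiff(unique(c(catalog$family_a, catalog$family_b)), fams)
    if (length(out_of_map))
      warnings_ <- c(warnings_, paste0(
        "catalog families absent from ortholog map (out-of-matrix partners): ",
        paste(utils::head(out_of_map, 10), collapse = ", ")))
  }
  list(errors = errors, warnings = warnings_, ok = length(errors) == 0L)
}

#' Run the full multi-subset clustering and recovery pipeline
#'
#' For every named species subset: assembles the standardized profile
#' matrix, computes Pearson distances, builds the dendrogram with the
#' configured linkage, cuts it at the relative height, and scores the
#' clustering against the interaction catalog at both levels. Afterwards all
#' subset trees are compared pairwise and the clusterings ranked by
#' recovered interactions. A manifest records the configuration, seed and
#' input checksums so identical inputs give identical bundles.
#'
#' @param counts Named list of per-species count data.frames.
#' @param ortholog_map data.frame \code{family_id}, \code{species},
#'   \code{gene_id}.
#' @param catalog Primary-interaction data.frame (\code{family_a},
#'   \code{family_b}, optional \code{source}); secondary edges are derived.
#' @param config A [pipeline_config()].
#' @return Object of class \code{pipeline_result}: per-subset list
#'   \code{runs} (matrix, dist, tree, newick, assignment, recovery at both
#'   levels, optional \code{support}), \code{comparison} (ranked recovery
#'   table at primary+secondary level), \code{tree_comparisons} (pairwise
#'   \code{tree_comparison} list), \code{validation}, \code{manifest}.
#' @export
run_pipeline <- function(counts, ortholog_map, catalog, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  val <- validate_inputs(counts, ortholog_map, catalog)
  if (!val$ok)
    stop("input validation failed:\n  ",
         paste(val$errors, collapse = "\n  "))
  cat_full <- expand_secondary(catalog)
  runs <- list()
  for (nm in names(config$subsets)) {
    sp <- config$subsets[[nm]]
    linkage <- config$linkages[[nm]]
    pm <- assemble_matrix(counts, ortholog_map, sp,
                          min_features = config$min_features)
    pd <- pearson_dist_matrix(pm)
    tree <- agglomerate(pd, linkage)
    asg <- cut_relative(tree, config$cut_fraction)
    rec_p <- count_recovered(asg, cat_full, "primary", name = nm)
    rec_ps <- count_recovered(asg, cat_full, "primary_and_secondary",
                              name = nm)
    support <- if (!is.null(config$bootstrap))
      node_support(pm, tree, config$bootstrap) else NULL
    runs[[nm]] <- list(name = nm, species = sp, linkage = linkage,
                       matrix = pm, dist = pd, tree = tree,
                       newick = to_newick(tree),
                       assignment = asg,
                       recovery_primary = rec_p,
                       recovery_primary_and_secondary = rec_ps,
                       support = support)
  }
  comparison <- compare_clusterings(
    lapply(runs, function(r) r$recovery_primary_and_secondary))
  tree_cmp <- list()
  nms <- names(runs)
  if (length(nms) >= 2L) {
    for (i in seq_len(length(nms) - 1L)) for (j in (i + 1L):length(nms)) {
      key <- paste(nms[i], nms[j], sep = "_vs_")
      tree_cmp[[key]] <- compare_trees(runs[[nms[i]]]$tree,
                                       runs[[nms[j]]]$tree,
                                       nms[i], nms[j])
    }
  }
  manifest <- list(
    seed = config$seed,
    cut_fraction = config$cut_fraction,
    subsets = lapply(config$subsets, identity),
    linkages = as.list(config$linkages),
    n_families_per_subset = lapply(runs, function(r) nrow(r$matrix$values)),
    n_features_per_subset = lapply(runs, function(r) ncol(r$matrix$values)),
    input_checksums = .input_checksums(counts, ortholog_map, catalog),
    package_version = as.character(utils::packageVersion("dictynet")))
  structure(list(runs = runs, comparison = comparison,
                 tree_comparisons = tree_cmp, validation = val,
                 manifest = manifest),
            class = "pipeline_result")
}

.input_checksums <- function(counts, ortholog_map, catalog) {
  ser <- function(x) {
    f <- tempfile()
    on.exit(unlink(f), add = TRUE)
    utils::write.table(x, f, sep = "\t", quote = FALSE, row.names = FALSE)
    unname(tools::md5sum(f))
  }
  c(lapply(counts, ser),
    list(ortholog_map = ser(ortholog_map), catalog = ser(catalog)))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result with", length(x$runs), "clustering runs\n")
  for (r in x$runs)
    cat(sprintf("  %-15s %s linkage, %d families, k = %d, recovered %d/%d\n",
                r$name, r$linkage, nrow(r$matrix$values), r$assignment$k,
                r$recovery_primary_and_secondary$recovered,
                r$recovery_primary_and_secondary$total))
  invisible(x)
}

#' Write a pipeline result bundle to disk
#'
#' Emits, per subset run: the assembled matrix TSV (+ JSON sidecar), the
#' dendrogram as Newick, the cluster assignment TSV, per-cluster network
#' edge lists, and optional bootstrap-support TSV. Plus the ranked recovery
#' comparison (TSV), pairwise tree comparisons (JSON) and the manifest
#' (JSON).
#'
#' @param result A \code{pipeline_result}.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_pipeline_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (r in result$runs) {
    base <- file.path(dir, r$name)
    write_profile_matrix(r$matrix, paste0(base, "_matrix.tsv"))
    writeLines(r$newick, paste0(base, ".nwk"))
    asg <- data.frame(family_id = names(r$assignment$cluster),
                      cluster_id = unname(r$assignment$cluster))
    utils::write.table(asg, paste0(base, "_clusters.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (nrow(r$recovery_primary_and_secondary$edges))
      utils::write.table(r$recovery_primary_and_secondary$edges,
                         paste0(base, "_network_edges.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    if (!is.null(r$support))
      utils::write.table(r$support, paste0(base, "_support.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }
  utils::write.table(result$comparison, file.path(dir, "recovery_comparison.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    lapply(result$tree_comparisons, function(tc) unclass(tc)),
    file.path(dir, "tree_comparisons.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read per-species expression tables, ortholog map and catalog from TSV
#'
#' Counterpart of [write_dataset()]: reads the plain-text input layout.
#'
#' @param dir Directory containing \code{expression_<species>.tsv},
#'   \code{ortholog_map.tsv} and optionally \code{interaction_catalog.tsv}.
#' @return List \code{counts}, \code{ortholog_map}, \code{catalog}.
#' @export
read_dataset <- function(dir) {
  files <- list.files(dir, pattern = "^expression_.*\\.tsv$",
                      full.names = TRUE)
  if (!length(files)) stop("no expression_<species>.tsv files in ", dir)
  counts <- list()
  for (f in files) {
    sp <- sub("^expression_(.*)\\.tsv$", "\\1", basename(f))
    counts[[sp]] <- utils::read.delim(f, stringsAsFactors = FALSE)
  }
  omap <- utils::read.delim(file.path(dir, "ortholog_map.tsv"),
                            stringsAsFactors = FALSE)
  cat_path <- file.path(dir, "interaction_catalog.tsv")
  catalog <- if (file.exists(cat_path))
    utils::read.delim(cat_path, stringsAsFactors = FALSE) else NULL
  list(counts = counts, ortholog_map = omap, catalog = catalog)
}

#' Read a supplementary-style profile workbook
#'
#' Reads an XLSX workbook whose sheets each hold one assembled profile
#' matrix (one row per ortholog family, first column the family identifier,
#' remaining columns labelled standardized feature values; empty cells are
#' masked positions). Requires the \pkg{readxl} package.
#'
#' @param path Path to the workbook.
#' @param sheet Sheet name or index.
#' @param species_subset Optional species identifiers recorded in the
#'   returned object.
#' @return A \code{profile_matrix} (features carry the column headers;
#'   species/block descriptors are parsed from headers of the form
#'   \code{species.block.label} when present).
#' @export
read_profile_workbook <- function(path, sheet = 1, species_subset = NULL) {
  if (!requireNamespace("readxl", quietly = TRUE))
    stop("reading XLSX workbooks requires the 'readxl' package")
  df <- as.data.frame(readxl::read_excel(path, sheet = sheet))
  fam <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- fam
  hdr <- colnames(vals)
  parts <- strsplit(hdr, ".", fixed = TRUE)
  feat <- data.frame(
    species = vapply(parts, function(p) if (length(p) >= 3) p[1] else NA_character_,
                     character(1)),
    block_id = vapply(parts, function(p) if (length(p) >= 3) p[2] else "block",
                      character(1)),
    label = hdr)
  structure(list(values = vals, mask = !is.na(vals), features = feat,
                 dropped = character(),
                 species_subset = species_subset %||% unique(feat$species)),
            class = "profile_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
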