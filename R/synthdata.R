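#' Archetypal developmental expression classes
#'
#' The six canonical developmental expression profiles used throughout the
#' package: constitutive expression, decrease after the growth stage, a peak
#' or a dip in mid-development, and upregulation in early or late development.
#'
#' @format Character vector of the six class names, in the conventional
#'   reporting order.
#' @export
ARCHETYPES <- c("constitutive", "decrease_after_growth", "mid_peak",
                "mid_dip", "early_up", "late_up")

#' The five dictyostelid species, in fixed phylogenetic order
#'
#' Group 4: Ddis, Dpur; group 3: Dlac; group 2: Ppal; group 1: Dfas.
#' Branch II comprises groups 3 and 4 (Ddis, Dpur, Dlac); branch I groups 1
#' and 2 (Ppal, Dfas).
#'
#' @format Character vector of length 5.
#' @export
SPECIES5 <- c("Ddis", "Dpur", "Dlac", "Ppal", "Dfas")

#' Template curve for a developmental expression archetype
#'
#' Returns a fixed piecewise-defined template on a unit time axis, scaled so
#' the maximum is 1. Templates are chosen so that each class satisfies the
#' shape predicate its name implies: \code{constitutive} is flat at 1;
#' \code{decrease_after_growth} is maximal at the first time point with all
#' later values at most 0.25; \code{early_up}/\code{late_up} are monotone
#' non-decreasing with the (first-attained) maximum in the first/last third;
#' \code{mid_peak}/\code{mid_dip} place their extremum strictly inside the
#' middle third of the time axis.
#'
#' @param name One of [ARCHETYPES].
#' @param n_timepoints Number of time points (at least 4).
#' @return Numeric vector of length \code{n_timepoints} with values in
#'   \eqn{[0,1]} and maximum 1.
#' @examples
#' archetype_curve("constitutive", 4)
#' archetype_curve("mid_peak", 9)
#' @export
archetype_curve <- function(name, n_timepoints) {
  name <- match.arg(name, ARCHETYPES)
  n <- as.integer(n_timepoints)
  if (is.na(n) || n < 4L)
    stop("n_timepoints must be at least 4")
  t <- seq(0, 1, length.out = n)
  s <- switch(name,
    constitutive = rep(1, n),
    # sharp drop after the first (growth) point, slow decay thereafter
    decrease_after_growth = c(1, seq(0.25, 0.05, length.out = n - 1L)),
    # triangular peak centred slightly right of mid so the argmax is unique
    # on both odd and even grids
    mid_peak = pmax(0, 1 - 2.2 * abs(t - 0.55)),
    mid_dip = 1 - 0.95 * pmax(0, 1 - 2.2 * abs(t - 0.55)),
    early_up = pmin(1, t / 0.25),
    late_up = pmax(0, (t - 0.6) / 0.4)
  )
  s / max(s)
}

# individualized class curve: same shape predicates as archetype_curve, with
# per-program timing/shape parameters so distinct programs of one class are
# distinguishable; params drawn once per program by .draw_program()
.program_curve <- function(cl, par, n) {
  t <- seq(0, 1, length.out = n)
  s <- switch(cl,
    constitutive = {                     # gentle ripple, range <= 0.3
      x <- 1 - par$u * (0.5 + 0.5 * sin(2 * pi * t + par$phase))
      x
    },
    decrease_after_growth =
      c(1, seq(par$a, par$b, length.out = n - 1L)),
    mid_peak = pmax(0, 1 - abs(t - par$p) / par$w),
    mid_dip = 1 - (1 - par$floor) * pmax(0, 1 - abs(t - par$p) / par$w),
    early_up = pmin(1, t / par$tau)^par$g,
    late_up = pmax(0, (t - par$s0) / (1 - par$s0))^par$g)
  s / max(s)
}

# signature/timing parameters for one expression program; sig_cell indexes
# the 2 x 10 grid of (slug-dominant cell, mature-cell pattern: 4 single
# types + 6 type pairs)
.draw_program <- function(cl, sig_cell = NULL) {
  if (is.null(sig_cell)) sig_cell <- sample.int(20L, 1L)
  th <- stats::runif(1)
  par <- switch(cl,
    constitutive = list(u = stats::runif(1, 0.05, 0.3), phase = 2 * pi * th),
    decrease_after_growth = {
      a <- 0.1 + 0.15 * th
      list(a = a, b = stats::runif(1, 0.02, 0.8 * a))
    },
    mid_peak = list(p = 0.42 + 0.2 * th, w = stats::runif(1, 0.12, 0.2)),
    mid_dip = list(p = 0.42 + 0.2 * th, w = stats::runif(1, 0.12, 0.2),
                   floor = stats::runif(1, 0, 0.1)),
    early_up = list(tau = 0.15 + 0.25 * th, g = stats::runif(1, 0.7, 1.5)),
    late_up = list(s0 = 0.5 + 0.22 * th, g = stats::runif(1, 0.7, 1.5)))
  slug_dom <- (sig_cell - 1L) %% 2L + 1L
  mat_cell <- (sig_cell - 1L) %/% 2L + 1L
  p <- stats::runif(1, 0.75, 0.95)
  slug <- if (slug_dom == 1L) c(p, 1 - p) else c(1 - p, p)
  mat <- stats::runif(4, 0, 0.2)
  if (mat_cell <= 4L) mat[mat_cell] <- 1 else {
    pair <- utils::combn(4L, 2L)[, mat_cell - 4L]
    mat[pair] <- c(1, stats::runif(1, 0.7, 0.9))
  }
  list(class = cl, par = par, slug = slug, mature = mat)
}

# expected (noise-free) standardized values of one program for one block
.program_block <- function(prog, block_size, block_index, n_timepoints) {
  if (block_index == 0L)
    return(.program_curve(prog$class, prog$par, n_timepoints))
  if (block_size == 2L) prog$slug else
    rep_len(prog$mature, block_size)
}

#' Simulation configuration for synthetic multi-species expression data
#'
#' Bundles the knobs of [simulate_dataset()] with validation. Defaults
#' emulate the shape of the real study inputs: five species, a 12-point
#' developmental time course each, two replicate prestalk/prespore fraction
#' experiments and two mature-cell-type experiments per species, read depths
#' of a few thousand, moderate lognormal replicate noise, and occasional
#' missing orthologs and low-coverage blocks.
#'
#' @param n_families Number of ortholog families (matrix rows).
#' @param n_modules Number of planted co-expressed modules.
#' @param module_size_range Length-2 integer vector, min/max module size.
#' @param species_list Character vector of species identifiers (max 5).
#' @param n_timepoints Integer (recycled per species): developmental time
#'   points.
#' @param celltype_blocks List (per species) of integer block sizes; size-2
#'   blocks are slug-cell fractions standardized to the sum, larger blocks
#'   mature-cell sets standardized to the maximum.
#' @param noise_sd Standard deviation (log scale) of multiplicative
#'   lognormal noise applied to expected counts.
#' @param base_depth Expected maximum read count of a profile.
#' @param missing_family_rate Probability that a family lacks its member in
#'   a given non-reference species.
#' @param low_coverage_rate Probability that a block is downscaled to a
#'   total of at most 10 reads (emulating poorly covered genes).
#' @param seed Integer seed; all randomness derives from it.
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(n_families = 300L,
                       n_modules = 40L,
                       module_size_range = c(3L, 6L),
                       species_list = SPECIES5,
                       n_timepoints = 12L,
                       celltype_blocks = NULL,
                       noise_sd = 0.05,
                       base_depth = 2000,
                       missing_family_rate = 0.1,
                       low_coverage_rate = 0.02,
                       seed = 1L) {
  n_families <- as.integer(n_families)
  n_modules <- as.integer(n_modules)
  module_size_range <- as.integer(module_size_range)
  stopifnot(length(module_size_range) == 2L,
            module_size_range[1] >= 2L,
            module_size_range[1] <= module_size_range[2])
  if (length(species_list) < 1L || length(species_list) > 5L)
    stop("species_list must contain between 1 and 5 species")
  if (anyDuplicated(species_list))
    stop("species_list must be unique")
  n_timepoints <- rep_len(as.integer(n_timepoints), length(species_list))
  names(n_timepoints) <- species_list
  if (any(n_timepoints < 4L)) stop("each species needs >= 4 time points")
  if (is.null(celltype_blocks))
    celltype_blocks <- rep(list(c(2L, 2L, 4L, 4L)), length(species_list))
  celltype_blocks <- rep_len(celltype_blocks, length(species_list))
  names(celltype_blocks) <- species_list
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  for (p in c(missing_family_rate, low_coverage_rate))
    if (p < 0 || p > 1) stop("rates must be probabilities in [0,1]")
  if (n_modules > 0L && n_modules * module_size_range[2] > n_families)
    stop("impossible config: n_modules x max module size exceeds n_families")
  structure(list(
    n_families = n_families, n_modules = n_modules,
    module_size_range = module_size_range, species_list = species_list,
    n_timepoints = n_timepoints, celltype_blocks = celltype_blocks,
    noise_sd = noise_sd, base_depth = base_depth,
    missing_family_rate = missing_family_rate,
    low_coverage_rate = low_coverage_rate, seed = as.integer(seed)
  ), class = "sim_config")
}

# deterministic sub-seed per (dataset seed, label); keeps species streams
# independent of each other and of config order
.sub_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 131L)
  (as.integer(seed) * 48271L + h) %% 2147483562L
}

#' Simulate a multi-species expression study with planted modules
#'
#' Generates per-species read-count tables, an ortholog map, a ground-truth
#' interaction catalog of planted within-module edges, and module labels.
#' Each planted module carries one expression program — a developmental
#' archetype curve with module-specific timing parameters plus a
#' module-specific cell-type signature — shared by all its member families
#' across all species where they are present, so module members co-cluster
#' on the concatenated profile array. Programs of distinct modules are made
#' mutually distinguishable by stratifying classes round-robin over the six
#' archetypes and sampling cell-type signature cells without replacement
#' within a class; background families draw independent random programs.
#' Expected counts are \code{base_depth} times the program value,
#' multiplied by lognormal noise and rounded to non-negative integers.
#'
#' @param config A [sim_config()] object.
#' @return List with elements:
#'   \describe{
#'     \item{counts}{named list per species; each a data.frame with columns
#'       \code{gene_id}, \code{block_id}, \code{label}, \code{count}.}
#'     \item{ortholog_map}{data.frame \code{family_id}, \code{species},
#'       \code{gene_id}.}
#'     \item{catalog}{data.frame \code{family_a}, \code{family_b},
#'       \code{level}, \code{source}: the planted primary edges.}
#'     \item{truth}{list \code{module_of_family} (named integer, NA for
#'       background families), \code{archetype_of_family} (named character)
#'       and \code{planted_edges} (two-column matrix).}
#'     \item{config}{the config used.}
#'   }
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  set.seed(cf$seed)
  fam_ids <- sprintf("fam%04d", seq_len(cf$n_families))

  # module membership: blocks of a shuffled family pool
  module_of <- rep(NA_integer_, cf$n_families)
  names(module_of) <- fam_ids
  if (cf$n_modules > 0L) {
    sizes <- sample(seq(cf$module_size_range[1], cf$module_size_range[2]),
                    cf$n_modules, replace = TRUE)
    pool <- sample(fam_ids)
    idx <- 1L
    for (m in seq_len(cf$n_modules)) {
      module_of[pool[idx:(idx + sizes[m] - 1L)]] <- m
      idx <- idx + sizes[m]
    }
  }

  # module programs: classes round-robin over the six archetypes; signature
  # cells allocated most-distinguishable-first (the 8 mutually
  # anti-correlated corner cells before the 12 edge cells), globally without
  # replacement while cells last, then without replacement within class
  programs <- vector("list", max(cf$n_modules, 0L))
  if (cf$n_modules > 0L) {
    corner_cells <- which((seq_len(20L) - 1L) %/% 2L + 1L <= 4L)
    edge_cells <- setdiff(seq_len(20L), corner_cells)
    priority <- c(sample(corner_cells), sample(edge_cells))
    cls_idx <- (seq_len(cf$n_modules) - 1L) %% 6L + 1L
    cells <- integer(cf$n_modules)
    if (cf$n_modules <= 20L) {
      cells <- priority[seq_len(cf$n_modules)]
    } else {
      for (ci in 1:6) {
        mods <- which(cls_idx == ci)
        cells[mods] <- if (length(mods) <= 20L)
          priority[seq_len(length(mods))] else
          sample.int(20L, length(mods), replace = TRUE)
      }
    }
    for (m in seq_len(cf$n_modules))
      programs[[m]] <- .draw_program(ARCHETYPES[cls_idx[m]], cells[m])
  }
  fam_program <- vector("list", cf$n_families)
  names(fam_program) <- fam_ids
  for (f in seq_len(cf$n_families)) {
    fam_program[[f]] <- if (!is.na(module_of[f])) programs[[module_of[f]]]
      else .draw_program(sample(ARCHETYPES, 1L))
  }
  archetype_of <- vapply(fam_program, function(p) p$class, character(1))

  # species membership: reference (first) species always present
  present <- matrix(TRUE, cf$n_families, length(cf$species_list),
                    dimnames = list(fam_ids, cf$species_list))
  if (length(cf$species_list) > 1L && cf$missing_family_rate > 0) {
    miss <- matrix(stats::runif(cf$n_families * (length(cf$species_list) - 1L)) <
                     cf$missing_family_rate,
                   cf$n_families, length(cf$species_list) - 1L)
    present[, -1L] <- !miss
  }

  # per-species count tables, one RNG sub-stream per species
  counts <- list()
  omap_rows <- list()
  for (sp in cf$species_list) {
    set.seed(.sub_seed(cf$seed, sp))
    ntp <- cf$n_timepoints[[sp]]
    blocks <- cf$celltype_blocks[[sp]]
    gene_ids <- character(); block_ids <- character()
    labels <- character(); cvals <- numeric()
    noisy <- function(mu) {
      x <- mu * stats::rlnorm(length(mu), meanlog = -cf$noise_sd^2 / 2,
                              sdlog = cf$noise_sd)
      pmax(0, round(x))
    }
    emit <- function(gene, bid, labs, counts_) {
      gene_ids <<- c(gene_ids, rep(gene, length(labs)))
      block_ids <<- c(block_ids, rep(bid, length(labs)))
      labels <<- c(labels, labs)
      cvals <<- c(cvals, counts_)
    }
    for (f in fam_ids) {
      if (!present[f, sp]) next
      gene <- paste0(sp, "_", f)
      omap_rows[[length(omap_rows) + 1L]] <- c(f, sp, gene)
      prog <- fam_program[[f]]
      downscale <- function(x) {
        if (cf$low_coverage_rate > 0 && stats::runif(1) < cf$low_coverage_rate) {
          tot <- sum(x)
          if (tot > 10) x <- floor(x * (10 / tot))
        }
        x
      }
      dev <- downscale(noisy(cf$base_depth *
                               .program_block(prog, ntp, 0L, ntp)))
      emit(gene, "dev", sprintf("t%02d", seq_len(ntp) - 1L), dev)
      for (b in seq_along(blocks)) {
        k <- blocks[b]
        mu <- cf$base_depth * .program_block(prog, k, b, ntp)
        ct <- downscale(noisy(mu))
        emit(gene, paste0("ct", b), paste0("ct", b, "_", seq_len(k)), ct)
      }
    }
    counts[[sp]] <- data.frame(gene_id = gene_ids, block_id = block_ids,
                               label = labels, count = cvals)
  }
  om <- do.call(rbind, omap_rows)
  omap <- data.frame(family_id = om[, 1], species = om[, 2], gene_id = om[, 3])

  # planted edges: all within-module pairs
  planted <- NULL
  if (cf$n_modules > 0L) {
    for (m in seq_len(cf$n_modules)) {
      members <- sort(fam_ids[which(module_of == m)])
      if (length(members) >= 2L)
        planted <- rbind(planted, t(utils::combn(members, 2L)))
    }
  }
  catalog <- if (is.null(planted)) {
    data.frame(family_a = character(), family_b = character(),
               level = character(), source = character())
  } else {
    data.frame(family_a = planted[, 1], family_b = planted[, 2],
               level = "primary", source = "planted")
  }
  list(counts = counts, ortholog_map = omap, catalog = catalog,
       truth = list(module_of_family = module_of,
                    archetype_of_family = archetype_of,
                    planted_edges = planted),
       config = cf)
}

#' Write a simulated dataset to plain-text files
#'
#' Emits one expression TSV per species, an ortholog-map TSV, the planted
#' interaction catalog TSV and the ground truth as JSON.
#'
#' @param dataset Result of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of paths written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (sp in names(dataset$counts)) {
    p <- file.path(dir, paste0("expression_", sp, ".tsv"))
    utils::write.table(dataset$counts[[sp]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "ortholog_map.tsv")
  utils::write.table(dataset$ortholog_map, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "interaction_catalog.tsv")
  utils::write.table(dataset$catalog, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(list(
    module_of_family = as.list(dataset$truth$module_of_family),
    archetype_of_family = as.list(dataset$truth$archetype_of_family),
    planted_edges = if (is.null(dataset$truth$planted_edges)) list() else
      apply(dataset$truth$planted_edges, 1L, as.list)
  ), p, auto_unbox = TRUE, null = "null")
  paths <- c(paths, p)
  invisible(paths)
}
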