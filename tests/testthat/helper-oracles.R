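# Independent oracles and small fixture builders used across the suite.

# Naive O(n^3) agglomerative clustering: at every step recompute ALL
# inter-cluster distances from the original matrix by direct enumeration
# over member pairs, then merge the minimum (ties: lexicographically lowest
# min-leaf pair). Deliberately independent of the package's Lance-Williams
# implementation.
naive_agglomerate <- function(d, linkage) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  sets <- list()
  while (length(clusters) > 1L) {
    best <- NULL
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        dv <- d[clusters[[i]], clusters[[j]], drop = FALSE]
        dij <- switch(linkage, average = mean(dv), complete = max(dv),
                      single = min(dv))
        key <- c(min(clusters[[i]]), min(clusters[[j]]))
        key <- c(min(key), max(key))
        if (is.null(best) || dij < best$d - 1e-15 ||
            (abs(dij - best$d) <= 1e-15 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(i = i, j = j, d = dij, key = key)
        }
      }
    }
    heights <- c(heights, best$d)
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    sets[[length(sets) + 1L]] <- merged
    clusters[[best$i]] <- merged
    clusters[[best$j]] <- NULL
  }
  list(heights = heights, sets = sets)
}

# clade sets of a dendro as canonical strings
clade_strings <- function(tree, include_root = TRUE) {
  cl <- dendro_clades(tree, include_root = include_root)
  sort(vapply(cl, function(ix) paste(sort(ix), collapse = ","), character(1)))
}

# random symmetric distance matrix with continuous entries (no ties)
random_dist <- function(n, seed) {
  set.seed(seed)
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.1, 2)
  d <- d + t(d)
  rownames(d) <- colnames(d) <- paste0("g", seq_len(n))
  d
}

# random full (unmasked) profile-like matrix
random_matrix <- function(n, m, seed) {
  set.seed(seed)
  matrix(runif(n * m), n, m, dimnames = list(paste0("g", seq_len(n)), NULL))
}

# small standard synthetic study used by several test files
small_study <- function(seed = 5, noise_sd = 0.02) {
  simulate_dataset(sim_config(
    n_families = 60, n_modules = 8, module_size_range = c(3, 5),
    species_list = c("Ddis", "Dpur"), noise_sd = noise_sd,
    missing_family_rate = 0.05, low_coverage_rate = 0, seed = seed))
}
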