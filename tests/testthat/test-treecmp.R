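make_tree <- function(d, linkage = "average") agglomerate(d, linkage)

# fixed 4-leaf trees: ((A,B),(C,D)) and ((A,C),(B,D))
tree_ab_cd <- function() {
  d <- matrix(2, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  diag(d) <- 0
  d["A", "B"] <- d["B", "A"] <- 0.2
  d["C", "D"] <- d["D", "C"] <- 0.3
  make_tree(d)
}
tree_ac_bd <- function() {
  d <- matrix(2, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  diag(d) <- 0
  d["A", "C"] <- d["C", "A"] <- 0.2
  d["B", "D"] <- d["D", "B"] <- 0.3
  make_tree(d)
}

test_that("identical trees share all clades, Bk = 1 and cophenetic r = 1", {
  tr <- make_tree(random_dist(8, seed = 71))
  cn <- common_nodes(tr, tr)
  expect_equal(cn$fraction_shared_a, 1.0)
  expect_equal(cn$fraction_shared_b, 1.0)
  expect_equal(cn$shared_clades, cn$clades_a)
  for (k in c(2, 4, 7)) expect_equal(fowlkes_mallows(tr, tr, k), 1.0)
  expect_equal(cophenetic_correlation(tr, tr), 1.0)
  # scale invariance: doubling all heights leaves cophenetic r at 1
  tr2 <- tr
  tr2$height <- tr$height * 2
  expect_equal(cophenetic_correlation(tr, tr2), 1.0)
})

test_that("the disjoint 4-leaf topologies share no clades", {
  cn <- common_nodes(tree_ab_cd(), tree_ac_bd())
  expect_equal(cn$shared_clades, 0L)
  expect_equal(cn$clades_a, 2L)   # {A,B} and {C,D}; root excluded
  expect_equal(cn$clades_b, 2L)
})

test_that("restriction to common leaves prunes and preserves heights", {
  d <- random_dist(9, seed = 81)
  tr_a <- make_tree(d)
  # tree_b lacks two leaves of tree_a
  keep <- rownames(d)[1:7]
  tr_b <- make_tree(d[keep, keep])
  r <- restrict_to_common_leaves(tr_a, tr_b)
  expect_setequal(r$tree_a$labels, keep)
  expect_setequal(r$tree_b$labels, keep)
  # pruned-tree cophenetic distances equal the originals on surviving pairs
  ca <- dendro_cophenetic(tr_a)[keep, keep]
  cp <- dendro_cophenetic(r$tree_a)[keep, keep]
  expect_equal(cp, ca, tolerance = 1e-12)
  # idempotence: comparing pre-pruned trees gives the identical comparison
  c1 <- compare_trees(tr_a, tr_b)
  c2 <- compare_trees(r$tree_a, r$tree_b)
  expect_equal(c1$shared_clades, c2$shared_clades)
  expect_equal(c1$fm_at_k, c2$fm_at_k)
  expect_equal(c1$cophenetic_r, c2$cophenetic_r)
  expect_error(restrict_to_common_leaves(tree_ab_cd(), make_tree(random_dist(5, 1))),
               "common leaves")
})

test_that("comparison statistics are symmetric and rotation-invariant", {
  d <- random_dist(10, seed = 91)
  tr_a <- make_tree(d)
  tr_b <- make_tree(d, linkage = "complete")
  ab <- common_nodes(tr_a, tr_b)
  ba <- common_nodes(tr_b, tr_a)
  expect_equal(ab$shared_clades, ba$shared_clades)
  expect_equal(ab$fraction_shared_a, ba$fraction_shared_b)
  expect_equal(fowlkes_mallows(tr_a, tr_b, 4), fowlkes_mallows(tr_b, tr_a, 4))
  expect_equal(cophenetic_correlation(tr_a, tr_b),
               cophenetic_correlation(tr_b, tr_a))
  # sibling order (rotation) does not change clade sets
  rot <- tr_a
  rot$merge <- rot$merge[, 2:1]
  expect_equal(common_nodes(rot, tr_b)$shared_clades, ab$shared_clades)
})

test_that("Fowlkes-Mallows matches its contingency formula and the permutation null", {
  # hand-checkable small case via direct pair counting
  tr_a <- tree_ab_cd(); tr_b <- tree_ac_bd()
  # at k = 2: partitions {AB|CD} vs {AC|BD}; T = 0 agreements
  expect_equal(fowlkes_mallows(tr_a, tr_b, 2), 0)
  # permutation null: for fixed partitions of size n with k clusters,
  # E[Bk] under random relabelling ~ sqrt(P*Q)/ (n(n-1)/ ...) - use the
  # empirical permutation mean as the oracle
  set.seed(7)
  n <- 60
  d1 <- random_dist(n, seed = 101)
  d2 <- random_dist(n, seed = 102)
  t1 <- make_tree(d1); t2 <- make_tree(d2)
  k <- 6
  obs <- fowlkes_mallows(t1, t2, k)
  c1 <- cut_k(t1, k)
  c2 <- cut_k(t2, k)
  perm_bk <- replicate(200, {
    cp <- c2[sample(length(c2))]
    names(cp) <- names(c2)
    tab <- table(c1, cp[names(c1)])
    T_ <- sum(tab^2) - n
    P <- sum(rowSums(tab)^2) - n
    Q <- sum(colSums(tab)^2) - n
    T_ / sqrt(P * Q)
  })
  # two independent random trees should look like the permutation null
  se <- sd(perm_bk) / sqrt(length(perm_bk))
  expect_lt(abs(obs - mean(perm_bk)), 3 * sd(perm_bk) + 3 * se)
  expect_error(fowlkes_mallows(t1, t2, 1), "k must be")
})

test_that("cophenetic correlation matches a direct hand computation", {
  d <- matrix(c(0, 1, 6, 6,
                1, 0, 6, 6,
                6, 6, 0, 2,
                6, 6, 2, 0), 4, byrow = TRUE,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  t1 <- make_tree(d)            # heights 1, 2, 6
  d2 <- d
  d2["A", "B"] <- d2["B", "A"] <- 3    # same topology, different heights
  t2 <- make_tree(d2)
  v1 <- c(1, 6, 6, 6, 6, 2)      # pairs AB, AC, AD, BC, BD, CD
  v2 <- c(3, 6, 6, 6, 6, 2)
  expect_equal(cophenetic_correlation(t1, t2), cor(v1, v2), tolerance = 1e-12)
  # zero variance flagged
  star <- make_tree(matrix(1, 4, 4, dimnames = dimnames(d)) - diag(4))
  out <- cophenetic_correlation(star, star)
  expect_true(is.na(out))
  expect_true(attr(out, "degenerate"))
})

test_that("half-split trees of one dataset agree more than trees of unrelated data", {
  set.seed(3)
  wins <- 0L
  for (s in 1:12) {
    ds <- simulate_dataset(sim_config(
      n_families = 40, n_modules = 6, module_size_range = c(3, 4),
      species_list = c("Ddis", "Dpur"), noise_sd = 0.1,
      missing_family_rate = 0, low_coverage_rate = 0, seed = s))
    pm <- assemble_matrix(ds$counts, ds$ortholog_map, c("Ddis", "Dpur"))
    m <- ncol(pm$values)
    odd <- seq(1, m, by = 2); even <- seq(2, m, by = 2)
    t_odd <- make_tree(pearson_dist_matrix(pm$values[, odd])$d)
    t_even <- make_tree(pearson_dist_matrix(pm$values[, even])$d)
    split_frac <- common_nodes(t_odd, t_even)$fraction_shared_a
    rnd <- random_matrix(nrow(pm$values), m, seed = 1000 + s)
    rownames(rnd) <- rownames(pm$values)
    t_rnd <- make_tree(pearson_dist_matrix(rnd)$d)
    rnd_frac <- common_nodes(t_odd, t_rnd)$fraction_shared_a
    if (split_frac >= rnd_frac) wins <- wins + 1L
  }
  expect_gte(wins, 10L)
})
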