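test_that("pearson_distance matches hand-computed values and handles masks", {
  expect_equal(pearson_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(pearson_distance(c(1, 2, 3), c(3, 2, 1)), 2)
  # hand evaluation of the Pearson formula: r = 0.5
  expect_equal(pearson_distance(c(1, 2, 3), c(1, 3, 2)), 0.5)
  # pairwise-complete support: NA positions excluded on either side
  x <- c(1, 2, 3, NA, 5)
  y <- c(2, 4, 6, 100, NA)
  expect_equal(pearson_distance(x, y), 0)   # joint support is (1,2,3)~(2,4,6)
  # insufficient support and zero variance give d_max with a flag
  u <- pearson_distance(c(1, 2, NA, NA), c(1, 2, NA, NA))
  expect_equal(as.numeric(u), 2)
  expect_true(attr(u, "undefined"))
  v <- pearson_distance(c(1, 1, 1, 1), c(1, 2, 3, 4))
  expect_equal(as.numeric(v), 2)
  expect_true(attr(v, "undefined"))
})

test_that("vectorized distance matrix agrees with the scalar function", {
  set.seed(21)
  X <- random_matrix(15, 20, seed = 21)
  X[sample(length(X), 60)] <- NA   # random mask
  pd <- pearson_dist_matrix(X)
  for (i in 1:14) for (j in (i + 1):15) {
    expect_equal(pd$d[i, j],
                 as.numeric(pearson_distance(X[i, ], X[j, ])),
                 tolerance = 1e-12)
  }
  expect_equal(pd$d, t(pd$d))
  expect_true(all(diag(pd$d) == 0))
  expect_true(all(pd$d >= 0 & pd$d <= 2))
})

test_that("agglomerate reproduces hand-worked Lance-Williams merges", {
  d <- matrix(c(0, 1, 4,
                1, 0, 5,
                4, 5, 0), 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  avg <- agglomerate(d, "average")
  expect_equal(avg$height, c(1.0, 4.5))   # (4+5)/2
  cmp <- agglomerate(d, "complete")
  expect_equal(cmp$height, c(1.0, 5.0))   # max(4,5)
  sgl <- agglomerate(d, "single")
  expect_equal(sgl$height, c(1.0, 4.0))   # min(4,5)
  # n = 1: empty merge list
  one <- agglomerate(matrix(0, 1, 1, dimnames = list("A", "A")))
  expect_equal(nrow(one$merge), 0L)
  expect_error(agglomerate(matrix(c(0, NA, NA, 0), 2)), "non-finite")
})

test_that("agglomerate agrees with stats::hclust on random matrices", {
  for (seed in 1:20) {
    n <- sample(5:14, 1)
    d <- random_dist(n, seed)
    for (lk in c("average", "complete", "single")) {
      mine <- agglomerate(d, lk)
      ref <- stats::hclust(stats::as.dist(d), method = lk)
      expect_equal(mine$height, ref$height, tolerance = 1e-12)
      expect_equal(dendro_cophenetic(mine)[ref$labels, ref$labels],
                   as.matrix(stats::cophenetic(ref)), tolerance = 1e-12)
    }
  }
})

test_that("merge heights are monotone for average and complete linkage", {
  for (seed in 1:10) {
    d <- random_dist(10, seed + 100)
    for (lk in c("average", "complete")) {
      tr <- agglomerate(d, lk)
      expect_true(all(diff(tr$height) >= -1e-12))
    }
  }
})

test_that("row permutation leaves the partition invariant", {
  for (seed in 1:5) {
    X <- random_matrix(12, 15, seed + 300)
    d <- pearson_dist_matrix(X)$d
    for (lk in c("average", "complete", "single")) {
      base <- cut_relative(agglomerate(d, lk), 0.6)
      perm <- sample(12)
      dp <- d[perm, perm]
      permuted <- cut_relative(agglomerate(dp, lk), 0.6)
      part <- function(a) {
        unname(lapply(split(names(a$cluster), a$cluster), sort))
      }
      expect_setequal(part(base), part(permuted))
    }
  }
})

test_that("cut_relative applies merges at or below the cut height", {
  d <- matrix(c(0, 1, 4,
                1, 0, 5,
                4, 5, 0), 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- agglomerate(d, "average")           # heights 1.0, 4.5
  a <- cut_relative(tr, 0.75)               # cut at 3.375
  expect_equal(a$k, 2L)
  expect_equal(unname(a$cluster[c("A", "B")]), c(1L, 1L))
  expect_equal(unname(a$cluster["C"]), 2L)
  expect_equal(cut_relative(tr, 1.0)$k, 1L)
  expect_equal(cut_relative(tr, 1e-6)$k, 3L)
  expect_error(cut_relative(tr, 0), "fraction")
  expect_error(cut_relative(tr, 1.2), "fraction")
  # boundary: a merge exactly at the cut height is applied
  d2 <- matrix(c(0, 3, 8,
                 3, 0, 8,
                 8, 8, 0), 3, byrow = TRUE,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr2 <- agglomerate(d2, "average")         # heights 3, 8
  expect_equal(cut_relative(tr2, 3 / 8)$k, 2L)
})

test_that("cluster count is non-increasing in the cut fraction", {
  X <- random_matrix(20, 12, seed = 77)
  tr <- agglomerate(pearson_dist_matrix(X), "average")
  ks <- vapply(seq(0.05, 1, by = 0.05),
               function(f) cut_relative(tr, f)$k, integer(1))
  expect_true(all(diff(ks) <= 0))
})

test_that("cut_k matches stats::cutree partitions", {
  X <- random_matrix(18, 14, seed = 55)
  tr <- agglomerate(pearson_dist_matrix(X), "average")
  hc <- as.hclust(tr)
  for (k in c(2, 5, 9, 17)) {
    mine <- cut_k(tr, k)
    ref <- stats::cutree(hc, k = k)
    expect_equal(length(unique(mine)), k)
    # same partition up to label renaming
    expect_equal(unname(table(mine, ref) > 0) |> rowSums() |> max(), 1)
  }
})

test_that("newick export round-trips through an independent parser", {
  skip_if_not_installed("ape")
  expect_equal(to_newick(structure(list(
    merge = matrix(integer(), 0, 2), height = numeric(), size = integer(),
    order = 1L, labels = "A", linkage = "average"), class = "dendro")), "A;")

  d <- matrix(c(0, 1, 4,
                1, 0, 5,
                4, 5, 0), 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- agglomerate(d, "average")
  nw <- to_newick(tr)
  ph <- ape::read.tree(text = nw)
  cc <- ape::cophenetic.phylo(ph) / 2    # path length = 2 x merge height
  expect_equal(cc[c("A", "B", "C"), c("A", "B", "C")],
               dendro_cophenetic(tr), tolerance = 1e-9)

  # property: 30 random trees round-trip with topology and heights intact
  for (seed in 1:30) {
    n <- sample(4:12, 1)
    tr <- agglomerate(random_dist(n, seed + 500), "average")
    ph <- ape::read.tree(text = to_newick(tr))
    cc <- ape::cophenetic.phylo(ph) / 2
    labs <- tr$labels
    expect_equal(cc[labs, labs], dendro_cophenetic(tr), tolerance = 1e-8)
  }
  expect_error(to_newick(tr, labels = c("A", "A", "B")), "duplicate")
})
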