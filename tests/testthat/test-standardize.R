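test_that("fraction_of_max and fraction_of_sum match their definitions", {
  expect_equal(fraction_of_max(c(5, 10, 20, 10))$values,
               c(0.25, 0.5, 1.0, 0.5))
  expect_equal(fraction_of_max(7)$values, 1.0)
  z <- fraction_of_max(c(0, 0, 0))
  expect_equal(z$values, c(0, 0, 0))
  expect_true(z$all_zero)

  expect_equal(fraction_of_sum(c(4, 6))$values, c(0.4, 0.6))
  expect_equal(fraction_of_sum(c(10, 0))$values, c(1, 0))
  z2 <- fraction_of_sum(c(0, 0))
  expect_equal(z2$values, c(0, 0))
  expect_true(z2$all_zero)

  expect_error(fraction_of_max(numeric(0)), "empty")
  expect_error(fraction_of_sum(numeric(0)), "empty")
  expect_error(fraction_of_max(c(-1, 2)), "non-negative")
})

test_that("standardization is idempotent and scale-invariant on random blocks", {
  set.seed(42)
  for (i in 1:1000) {
    n <- sample(2:12, 1)
    v <- rpois(n, lambda = sample(c(1, 50, 2000), 1))
    fm <- fraction_of_max(v)
    fs <- fraction_of_sum(v)
    if (!fm$all_zero) {
      expect_equal(max(fm$values), 1)
      # idempotence
      expect_equal(fraction_of_max(fm$values)$values, fm$values,
                   tolerance = 1e-12)
      # scale invariance
      c_ <- runif(1, 0.1, 100)
      expect_equal(fraction_of_max(c_ * v)$values, fm$values,
                   tolerance = 1e-12)
    }
    if (!fs$all_zero) {
      expect_equal(sum(fs$values), 1, tolerance = 1e-9)
      expect_equal(fraction_of_sum(fs$values)$values, fs$values,
                   tolerance = 1e-12)
    }
    expect_true(all(fm$values >= 0 & fm$values <= 1))
    expect_true(all(fs$values >= 0 & fs$values <= 1))
  }
})

test_that("low-coverage rule follows the sum-at-most-10 convention", {
  expect_true(mask_low_coverage(c(3, 4, 2)))    # sum 9
  expect_false(mask_low_coverage(c(5, 6)))      # sum 11
  expect_true(mask_low_coverage(numeric(0)))    # empty = 0 reads
  expect_true(mask_low_coverage(c(5, 5)))       # boundary: sum exactly 10
})

test_that("standardize_block dispatches sum for 2-value blocks, max otherwise", {
  two <- standardize_block(c(30, 10))
  expect_equal(two$values, c(0.75, 0.25))
  four <- standardize_block(c(30, 10, 60, 0))
  expect_equal(four$values, c(0.5, 1 / 6, 1, 0))
  expect_equal(standardize_block(c(30, 10), method = "max")$values, c(1, 1 / 3))
  expect_true(standardize_block(c(2, 3))$low_coverage)
})

test_that("assemble_matrix masks missing species and low-coverage blocks", {
  ds <- simulate_dataset(sim_config(
    n_families = 25, n_modules = 3, module_size_range = c(3, 4),
    species_list = c("Ddis", "Dpur"), noise_sd = 0.05,
    missing_family_rate = 0.3, low_coverage_rate = 0, seed = 8))
  pm <- assemble_matrix(ds$counts, ds$ortholog_map, c("Ddis", "Dpur"))
  # all unmasked values in [0,1]
  expect_true(all(pm$values[pm$mask] >= 0 & pm$values[pm$mask] <= 1))
  expect_true(all(is.na(pm$values[!pm$mask])))
  # families absent from Dpur have that species' span fully masked
  dpur_fams <- unique(ds$ortholog_map$family_id[
    ds$ortholog_map$species == "Dpur"])
  absent <- setdiff(rownames(pm$values), dpur_fams)
  dpur_cols <- which(pm$features$species == "Dpur")
  for (f in absent) expect_false(any(pm$mask[f, dpur_cols]))
  # present-in-both families with full coverage are fully unmasked
  both <- intersect(rownames(pm$values), dpur_fams)
  expect_true(any(rowSums(pm$mask[both, , drop = FALSE]) ==
                    ncol(pm$values)))
})

test_that("assemble_matrix output is deterministic and drops sparse rows", {
  ds <- small_study(seed = 4)
  pm1 <- assemble_matrix(ds$counts, ds$ortholog_map, c("Ddis", "Dpur"))
  pm2 <- assemble_matrix(ds$counts, ds$ortholog_map, c("Ddis", "Dpur"))
  expect_identical(pm1, pm2)

  # force low coverage on every block of one gene -> its family drops when
  # it has no other usable features
  counts <- ds$counts
  fam <- rownames(pm1$values)[1]
  for (sp in names(counts)) {
    g <- paste0(sp, "_", fam)
    counts[[sp]]$count[counts[[sp]]$gene_id == g] <- 0
  }
  pm3 <- assemble_matrix(counts, ds$ortholog_map, c("Ddis", "Dpur"))
  expect_true(fam %in% pm3$dropped)
  expect_false(fam %in% rownames(pm3$values))
})

test_that("highest-expressed paralog represents a family", {
  counts <- list(Ddis = rbind(
    data.frame(gene_id = "Ddis_g1", block_id = "dev",
               label = paste0("t", 0:4), count = c(1, 2, 3, 4, 5)),
    data.frame(gene_id = "Ddis_g2", block_id = "dev",
               label = paste0("t", 0:4), count = c(100, 80, 60, 40, 20))))
  omap <- data.frame(family_id = c("famA", "famA"),
                     species = c("Ddis", "Ddis"),
                     gene_id = c("Ddis_g1", "Ddis_g2"))
  pm <- assemble_matrix(counts, omap, "Ddis")
  expect_equal(unname(pm$values["famA", ]), c(1, 0.8, 0.6, 0.4, 0.2))
})

test_that("profile matrix TSV round trip preserves values and masks", {
  ds <- small_study(seed = 10)
  pm <- assemble_matrix(ds$counts, ds$ortholog_map, c("Ddis", "Dpur"))
  path <- file.path(withr::local_tempdir(), "m.tsv")
  write_profile_matrix(pm, path)
  back <- utils::read.delim(path, check.names = FALSE)
  expect_equal(nrow(back), nrow(pm$values))
  vals <- as.matrix(back[, -1])
  expect_equal(unname(vals), unname(pm$values), tolerance = 1e-9)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"))
  expect_equal(meta$n_masked, sum(!pm$mask))
})
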