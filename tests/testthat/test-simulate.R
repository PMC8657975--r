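test_that("simulated counts are reproducible and match design moments", {
  design <- simulation_design(
    cells_per_type = c(A = 600L, B = 600L), n_genes = 60,
    targets_per_module = 10, baseline_mean = 4, nb_dispersion = 1e6,
    dropout_rate = 0, library_size_spread = 0.2, active_multiplier = 1,
    seed = 5)
  sim1 <- simulate_counts(design)
  sim2 <- simulate_counts(design)
  expect_identical(sim1$counts, sim2$counts)

  # multipliers all 1, no dropout, near-Poisson: per-gene mean across
  # cells should sit within 3 standard errors of baseline * mean(libsize)
  expected <- design$baseline_mean * mean(sim1$truth$libsize)
  means <- rowMeans(sim1$counts)
  se <- apply(sim1$counts, 1, sd) / sqrt(ncol(sim1$counts))
  expect_gt(mean(abs(means - expected) <= 3 * se), 0.95)
})

test_that("dropout only adds zeros, holding the count stream fixed", {
  base_design <- function(rate) simulation_design(
    cells_per_type = c(A = 100L), n_genes = 100, targets_per_module = 20,
    dropout_rate = rate, seed = 9)
  none <- simulate_counts(base_design(0))$counts
  half <- simulate_counts(base_design(0.5))$counts
  expect_gte(mean(half == 0), mean(none == 0))
  # dropout can only zero entries of the identically-seeded count draw
  expect_true(all(half == none | half == 0))
})

test_that("planted modules shape the true mean profiles and the GMT table", {
  sim <- small_sim()
  mu <- sim$truth$mean_profiles
  rel <- sim$relationships
  expect_identical(colnames(mu), paste0("T", 1:3))
  # module TF_T2's targets are 6x baseline in T2, baseline elsewhere
  t2 <- rel$TF_T2
  expect_true(all(mu[t2, "T2"] == 6 * mu[t2, "T1"]))
  expect_true(all(mu[rel$TF_null, ] == mu[rel$TF_null[1], 1]))
  # the emitted table round-trips through GMT
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(rel, path)
  expect_identical(read_relationships(path), rel)
})

test_that("the planted partition is recoverable from noiseless true means", {
  sim <- small_sim()
  truth <- sim$truth$assignment
  noiseless <- t(sim$truth$mean_profiles[, truth[colnames(sim$counts)]])
  rownames(noiseless) <- colnames(sim$counts)
  km <- kmeans_convenience(log1p(noiseless), k = 3, seed = 3)
  expect_equal(mclust::adjustedRandIndex(km[names(truth)], truth), 1)
})

test_that("paired experiments share types with identical expected profiles", {
  pair <- simulate_paired_experiments(simulation_design(seed = 13))
  expect_equal(nrow(pair$correspondence), 3)
  expect_identical(pair$correspondence$cluster_a, c("X1", "X2", "X5"))
  expect_identical(pair$correspondence$cluster_b, c("Y1", "Y2", "Y3"))
  expect_setequal(unique(pair$a$truth$assignment), paste0("X", 1:5))
  expect_setequal(unique(pair$b$truth$assignment), paste0("Y", 1:3))
  # matrices are independent draws
  expect_false(isTRUE(all.equal(dim(pair$a$counts), dim(pair$b$counts))) &&
                 isTRUE(all.equal(pair$a$counts, pair$b$counts)))

  # disjoint designs yield an empty correspondence
  da <- simulation_design(cells_per_type = c(P = 30L, Q = 30L), n_genes = 200,
                          targets_per_module = 20, seed = 1)
  db <- simulation_design(cells_per_type = c(R = 30L), n_genes = 200,
                          targets_per_module = 20, seed = 2)
  disjoint <- simulate_paired_experiments(da, db)
  expect_equal(nrow(disjoint$correspondence), 0)

  # inconsistent shared-type profiles are rejected
  db2 <- simulation_design(cells_per_type = c(P = 30L), n_genes = 200,
                           targets_per_module = 20, active_multiplier = 3,
                           seed = 2)
  expect_error(simulate_paired_experiments(da, db2), "inconsistent")
})

test_that("ATAC fixtures place regions with the promised structure", {
  fx <- simulate_atac_fixture(n_genes = 4, n_regions = 13, n_cells = 5,
                              seed = 2)
  expect_identical(simulate_atac_fixture(4, 13, 5, seed = 2)$peaks, fx$peaks)
  n_assigned <- lengths(fx$truth$assignments)
  expect_true(any(n_assigned == 0))   # intergenic regions exist
  expect_true(any(n_assigned == 2))   # the locus-spanning region exists
  # GTF text parses back to the generating loci
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(fx$gtf, path)
  expect_equal(read_gtf_gene_loci(path), fx$loci)
  # a fixture whose regions all sit inside loci conserves counts
  fx_in <- simulate_atac_fixture(n_genes = 8, n_regions = 8, n_cells = 4,
                                 seed = 3, span_pair = FALSE)
  map <- assign_regions_to_genes(fx_in$regions, fx_in$loci)
  expect_equal(sum(gene_activity_matrix(fx_in$peaks, map)), sum(fx_in$peaks))
})
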