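toy_loci <- function() {
  data.frame(gene_id = c("G1", "G2"), chrom = c("chr1", "chr1"),
             start = c(150L, 301L), end = c(300L, 500L),
             strand = c("+", "-"), stringsAsFactors = FALSE)
}

region_df <- function(starts, ends, chrom = "chr1") {
  data.frame(region_id = paste0("r", seq_along(starts)), chrom = chrom,
             start = starts, end = ends, stringsAsFactors = FALSE)
}

test_that("region-gene assignment follows 1-bp overlap on harmonized intervals", {
  loci <- toy_loci()
  # BED [99,200) overlaps 1-based locus 150-300
  hit <- assign_regions_to_genes(region_df(99L, 200L), loci)
  expect_identical(hit$r1, "G1")
  # BED [99,149) is exactly upstream of the half-open locus [149,300): no hit
  miss <- assign_regions_to_genes(region_df(99L, 149L), loci)
  expect_identical(miss$r1, character(0))
  # one extra base crosses the boundary
  edge <- assign_regions_to_genes(region_df(99L, 150L), loci)
  expect_identical(edge$r1, "G1")
  # a region spanning two adjacent loci maps to both
  both <- assign_regions_to_genes(region_df(250L, 350L), loci)
  expect_setequal(both$r1, c("G1", "G2"))
})

test_that("assignment ignores region order and chromosome prefix style", {
  loci <- toy_loci()
  fwd <- assign_regions_to_genes(region_df(c(99L, 320L), c(200L, 400L)), loci)
  rev_in <- region_df(c(320L, 99L), c(400L, 200L))
  rev_in$region_id <- c("r2", "r1")
  rev <- assign_regions_to_genes(rev_in, loci)
  expect_identical(fwd[sort(names(fwd))], rev[sort(names(rev))])

  bare <- assign_regions_to_genes(region_df(99L, 200L, chrom = "1"), loci)
  expect_identical(bare$r1, "G1")
})

test_that("upstream extension captures promoter-proximal regions when asked", {
  loci <- toy_loci()
  promoter <- region_df(100L, 140L)  # 9 bp upstream of G1's TSS at 150
  expect_identical(assign_regions_to_genes(promoter, loci)$r1, character(0))
  expect_identical(assign_regions_to_genes(promoter, loci,
                                           extend_upstream = 20)$r1, "G1")
})

test_that("gene activity sums region counts with full multi-gene duplication", {
  peaks <- count_matrix(matrix(c(5, 3, 4, 2, 1, 7), 3,
                               dimnames = list(c("r1", "r2", "r3"),
                                               c("c1", "c2"))))
  map <- list(r1 = "G1", r2 = "G1", r3 = c("G1", "G2"))
  act <- gene_activity_matrix(peaks, map)
  expect_equal(act["G1", "c1"], 5 + 3 + 4)
  expect_equal(act["G2", "c1"], 4)
  expect_equal(act["G2", "c2"], 7)
  expect_error(gene_activity_matrix(peaks, map[1:2]), "missing from")

  # unmapped regions vanish; single-assignment totals are conserved
  map1 <- list(r1 = "G1", r2 = "G2", r3 = character(0))
  act1 <- gene_activity_matrix(peaks, map1)
  expect_equal(sum(act1), sum(peaks[c("r1", "r2"), ]))
  expect_lte(sum(act1), sum(peaks))
})

test_that("random toy instances equal a brute-force accumulation oracle", {
  set.seed(21)
  fx <- simulate_atac_fixture(n_genes = 6, n_regions = 25, n_cells = 8,
                              seed = 33)
  got <- assign_regions_to_genes(fx$regions, fx$loci)
  expect_identical(got[names(fx$truth$assignments)],
                   lapply(fx$truth$assignments, as.character))

  act <- gene_activity_matrix(fx$peaks, got)
  # independent double loop over (region, gene) pairs
  genes <- sort(unique(unlist(got)))
  oracle <- matrix(0, length(genes), ncol(fx$peaks),
                   dimnames = list(genes, colnames(fx$peaks)))
  for (r in names(got)) for (g in got[[r]])
    oracle[g, ] <- oracle[g, ] + fx$peaks[r, ]
  expect_equal(act[genes, ], oracle)
})

test_that("the ATAC cell filter applies the inclusive present-gene bar", {
  m <- matrix(0, 450, 3,
              dimnames = list(sprintf("G%03d", 1:450), c("pass", "edge", "fail")))
  m[1:420, "pass"] <- 5
  m[1:400, "edge"] <- 3
  m[1:399, "fail"] <- 9
  m <- count_matrix(m)
  expect_message(kept <- filter_atac_cells(m), "2 cell\\(s\\) passed")
  expect_identical(colnames(kept), c("pass", "edge"))
  expect_identical(filter_atac_cells(m, min_genes = 0), m)

  # brute-force survivor set on a toy 5-cell instance
  set.seed(8)
  toy <- count_matrix(matrix(rpois(5 * 500, 0.9), 500, 5,
                             dimnames = list(sprintf("G%03d", 1:500),
                                             paste0("c", 1:5))))
  survivors <- colnames(toy)[colSums(toy >= 3) >= 30]
  expect_identical(colnames(suppressMessages(filter_atac_cells(toy, 30))),
                   survivors)
})
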