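# Shared fixtures. Heavy simulation + training products are computed once
# per test run and reused across test files.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_env, inherits = FALSE))
    assign(name, force(expr), envir = .fixture_env)
  get(name, envir = .fixture_env, inherits = FALSE)
}

toy_counts <- function() {
  count_matrix(matrix(c(1, 0, 4, 2, 3, 0, 0, 5, 6, 1, 0, 2), nrow = 3,
                      dimnames = list(paste0("g", 1:3), paste0("c", 1:4))))
}

# small 3-type planted-module simulation used by several unit tests
small_sim <- function() cached("small_sim", {
  simulate_counts(simulation_design(
    cells_per_type = stats::setNames(rep(50L, 3), paste0("T", 1:3)),
    n_genes = 200, targets_per_module = 20, seed = 101))
})

# reference 5-cluster benchmark: 150 cells/cluster, 800 genes, 20 runs of
# 200 epochs (the package's standing validation conditions)
recovery_fixture <- function() cached("recovery", {
  sim <- simulate_counts(simulation_design(seed = 7))
  cfg <- sca_config(n_epochs = 200, base_seed = 42)
  pb <- pseudobulk_replicates(sim$counts, sim$truth$assignment, cfg,
                              n_runs = 20)
  list(sim = sim, pb = pb)
})

# brute-force UPGMA: O(n^3) agglomeration straight from the definition,
# kept independent of the package's hclust-backed implementation
brute_upgma <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  active <- seq_len(n)
  members <- as.list(seq_len(n))
  id <- -seq_len(n)  # hclust convention: leaves negative
  merges <- NULL
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); best_h <- Inf
    for (a in seq_along(active)) for (b in seq_along(active)) {
      if (a >= b) next
      h <- mean(d[members[[active[a]]], members[[active[b]]], drop = FALSE])
      if (h < best_h - 1e-12) { best_h <- h; best <- c(a, b) }
    }
    ia <- active[best[1]]; ib <- active[best[2]]
    merges <- rbind(merges, c(sort(c(id[ia], id[ib])), best_h))
    members[[ia]] <- c(members[[ia]], members[[ib]])
    id[ia] <- step
    active <- active[-best[2]]
  }
  merges
}
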