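test_that("connectivity masks encode target sets and drop empty rows/columns", {
  rel <- list(TF1 = c("g1", "g2"), TF2 = c("g2", "g3"))
  mask <- build_mask(rel, c("g1", "g2", "g3"), drop_unconnected = FALSE)
  expect_equal(unname(mask), rbind(c(1, 1, 0), c(0, 1, 1)))
  expect_identical(dimnames(mask), list(c("TF1", "TF2"), c("g1", "g2", "g3")))

  expect_error(build_mask(list(TF1 = "g9"), c("g1", "g2")),
               "no metafeature")
  dropped <- build_mask(list(TF1 = "g1"), c("g1", "g2"))
  expect_identical(colnames(dropped), "g1")
  kept <- build_mask(list(TF1 = "g1"), c("g1", "g2"),
                     drop_unconnected = FALSE)
  expect_identical(colnames(kept), c("g1", "g2"))
  expect_equal(sum(kept[, "g2"]), 0)
})

sim_training_problem <- function(n = 60, p = 30, k = 6, seed = 5) {
  set.seed(seed)
  rel <- lapply(seq_len(k), function(i)
    sample(sprintf("f%02d", 1:p), 8))
  names(rel) <- paste0("M", seq_len(k))
  mask <- build_mask(rel, sprintf("f%02d", 1:p), drop_unconnected = FALSE)
  data <- matrix(rnbinom(n * p, mu = 4, size = 2), n, p,
                 dimnames = list(paste0("s", 1:n), sprintf("f%02d", 1:p)))
  list(data = data, mask = mask)
}

test_that("training is bitwise reproducible and reduces the loss", {
  prob <- sim_training_problem()
  cfg <- sca_config(n_epochs = 50, base_seed = 9)
  fit1 <- train_sca(prob$data, prob$mask, cfg)
  fit2 <- train_sca(prob$data, prob$mask, cfg)
  expect_identical(fit1$hidden, fit2$hidden)
  expect_identical(fit1$decoder_weights, fit2$decoder_weights)
  expect_lte(fit1$loss_trace[length(fit1$loss_trace)], fit1$loss_trace[1])
})

test_that("reconstruction error falls over training across many seeds", {
  # 200x100 data, 50-metafeature random mask, 200 epochs; the loss at the
  # end must sit below the loss at the start for the median of >= 10 seeds
  set.seed(11)
  p <- 100
  rel <- lapply(1:50, function(i) sample(sprintf("f%03d", 1:p), 10))
  names(rel) <- paste0("M", 1:50)
  mask <- build_mask(rel, sprintf("f%03d", 1:p), drop_unconnected = FALSE)
  data <- matrix(rnbinom(200 * p, mu = 3, size = 1), 200, p,
                 dimnames = list(paste0("s", 1:200), sprintf("f%03d", 1:p)))
  deltas <- vapply(1:10, function(s) {
    fit <- train_sca(data, mask, sca_config(n_epochs = 200), seed = s)
    fit$loss_trace[length(fit$loss_trace)] - fit$loss_trace[1]
  }, numeric(1))
  expect_lt(median(deltas), 0)
  expect_true(all(deltas <= 0))
})

test_that("masked weights stay exactly zero and block input influence", {
  prob <- sim_training_problem()
  cfg <- sca_config(n_epochs = 80, base_seed = 3, scale_input = FALSE)
  x <- scSCA:::scale_for_sca(prob$data)
  fit <- train_sca(x, prob$mask, cfg)
  expect_true(all(fit$encoder_weights[prob$mask == 0] == 0))
  expect_true(all(fit$decoder_weights[t(prob$mask) == 0] == 0))

  # finite perturbation of a feature outside node k's target set leaves
  # node k's activation untouched, exactly
  zero_pos <- which(prob$mask == 0, arr.ind = TRUE)
  for (r in sample(nrow(zero_pos), 10)) {
    k <- zero_pos[r, 1]; j <- zero_pos[r, 2]
    x2 <- x
    x2[, j] <- x2[, j] + 0.37
    h2 <- predict(fit, x2)
    expect_identical(h2[, k], fit$hidden[, k])
  }
})

test_that("an unconnected feature contributes nothing to any hidden node", {
  mask <- build_mask(list(TF1 = "g1"), c("g1", "g2"),
                     drop_unconnected = FALSE)
  set.seed(2)
  data <- matrix(runif(40), 20, 2, dimnames = list(NULL, c("g1", "g2")))
  fit <- train_sca(data, mask, sca_config(n_epochs = 30, scale_input = FALSE))
  data2 <- data
  data2[, "g2"] <- data2[, "g2"] * 5 + 1
  expect_identical(predict(fit, data2), fit$hidden)
})

test_that("hidden activations are nonnegative under relu and sigmoid", {
  prob <- sim_training_problem()
  for (act in c("relu", "sigmoid")) {
    fit <- train_sca(prob$data, prob$mask,
                     sca_config(n_epochs = 40, hidden_activation = act))
    expect_true(all(fit$hidden >= 0))
  }
})

test_that("permutation runs are seeded independently and reproducibly", {
  prob <- sim_training_problem(n = 40, p = 20, k = 4)
  cfg <- sca_config(n_epochs = 30, base_seed = 17)
  one <- run_permutations(prob$data, prob$mask, cfg, n_runs = 1)
  expect_identical(one[[1]], structure(train_sca(prob$data, prob$mask, cfg,
                                                 seed = 17)$hidden,
                                       run_index = 0L))
  tri1 <- run_permutations(prob$data, prob$mask, cfg, n_runs = 3)
  tri2 <- run_permutations(prob$data, prob$mask, cfg, n_runs = 3)
  expect_identical(tri1, tri2)
  expect_identical(attr(tri1[[3]], "run_index"), 2L)
  # run r depends only on base_seed + r: run 2 of base 17 = run 0 of base 19
  base19 <- run_permutations(prob$data, prob$mask,
                             sca_config(n_epochs = 30, base_seed = 19), 1)
  expect_equal(unclass(tri1[[3]]), unclass(base19[[1]]), ignore_attr = TRUE)
  # different base seeds give different activations
  expect_false(isTRUE(all.equal(unclass(tri1[[1]]), unclass(base19[[1]]),
                                check.attributes = FALSE)))
})

test_that("minibatch mode engages past the full-batch limit and still learns", {
  prob <- sim_training_problem(n = 300, p = 20, k = 4)
  cfg <- sca_config(n_epochs = 30, full_batch_limit = 100, base_seed = 4)
  fit <- train_sca(prob$data, prob$mask, cfg)
  expect_lt(fit$loss_trace[length(fit$loss_trace)], fit$loss_trace[1])
  expect_identical(train_sca(prob$data, prob$mask, cfg)$hidden, fit$hidden)
})
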