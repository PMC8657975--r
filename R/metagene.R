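#' Cumulative-sum metagene matrix from repeated SCA runs
#'
#' Runs the metafeature autoencoder — samples are cells, input features are
#' the target genes, each hidden node is one TF or miRNA connected only to
#' its targets — and accumulates the hidden layer over independent runs by
#' entrywise summation. Because each run partially discards noise while
#' retaining informative structure, summing many runs progressively
#' amplifies metafeatures that drive cell subpopulations relative to
#' nonspecifically modulated ones. Reference setting: 100 runs of 1000
#' epochs.
#'
#' @param m feature x cell count matrix (the same preprocessed matrix used
#'   for full-gene clustering).
#' @param rel a [relationship_table()] of metafeature target sets.
#' @param config an [sca_config()].
#' @param n_runs number of runs to accumulate.
#' @param mean divide the sum by \code{n_runs} for scale-sensitive
#'   downstream use (default FALSE: plain cumulative sum).
#' @param keep_runs retain the per-run hidden matrices in attribute
#'   \code{runs}.
#' @return cells x metafeatures matrix of class \code{metagene_matrix}
#'   with attribute \code{n_runs_summed}. Entries are nonnegative and,
#'   as sums of nonnegative activations, entrywise nondecreasing in the
#'   number of runs.
#' @export
metagene_matrix <- function(m, rel, config = sca_config(), n_runs = 100,
                            mean = FALSE, keep_runs = FALSE) {
  mask <- build_mask(rel, rownames(m), drop_unconnected = TRUE)
  data <- t(m[colnames(mask), , drop = FALSE])  # cells x target genes
  runs <- run_permutations(data, mask, config, n_runs)
  out <- Reduce(`+`, runs)
  if (mean) out <- out / n_runs
  dimnames(out) <- list(colnames(m), rownames(mask))
  out <- structure(out, n_runs_summed = n_runs,
                   class = c("metagene_matrix", "matrix", "array"))
  if (keep_runs) attr(out, "runs") <- runs
  out
}

#' Seeded k-means on a metagene matrix
#'
#' A self-contained clustering convenience so end-to-end analyses need no
#' external graph-clustering tool: k-means++ seeding followed by standard
#' k-means (Lloyd iterations via \code{stats::kmeans}). Cluster labels are
#' \code{m1..mk} in decreasing size order.
#'
#' @param mm cells x metafeatures matrix (any numeric matrix with row
#'   names works).
#' @param k number of clusters, \code{2 <= k <= n_cells}.
#' @param seed RNG seed for the k-means++ draw.
#' @return a [cluster_assignment()] over the matrix's rows.
#' @export
kmeans_convenience <- function(mm, k, seed = 1) {
  x <- unclass(mm)
  stopifnot(k >= 2, k <= nrow(x))
  if (k > nrow(unique(x))) stop("k exceeds the number of distinct rows")
  set.seed(seed)
  if (k == nrow(x))  # every cell its own cluster; kmeans rejects k = n
    return(cluster_assignment(stats::setNames(paste0("m", seq_len(k)),
                                              rownames(x))))
  centers <- kmeanspp_centers(x, k)
  fit <- stats::kmeans(x, centers = centers, iter.max = 100)
  sizes <- table(fit$cluster)
  rank <- rank(-as.numeric(sizes), ties.method = "first")
  relabel <- paste0("m", rank)[as.integer(names(sizes))]
  cluster_assignment(stats::setNames(relabel[fit$cluster], rownames(x)))
}

# k-means++ seeding: iteratively draw centers with probability
# proportional to squared distance from the nearest chosen center.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- rowSums(sweep(x, 2, x[idx[1], ], `-`)^2)
  for (j in seq_len(k - 1)) {
    if (all(d2 == 0)) {
      idx[j + 1] <- sample.int(n, 1)
    } else {
      idx[j + 1] <- sample.int(n, 1, prob = d2)
    }
    d2 <- pmin(d2, rowSums(sweep(x, 2, x[idx[j + 1], ], `-`)^2))
  }
  x[idx, , drop = FALSE]
}
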