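#' Cluster-membership connectivity mask
#'
#' The pseudo-bulk autoencoder reuses the metafeature machinery with cells
#' as input features and clusters as hidden nodes: the mask rows are the
#' clusters and \code{mask[c, i] = 1} iff cell i belongs to cluster c.
#' Because a clustering is a partition, mask rows are mutually disjoint and
#' every retained cell column has exactly one 1.
#'
#' @param assignment a [cluster_assignment()].
#' @param cell_ids cells of the expression matrix, in matrix order. Cells
#'   with no cluster label are dropped with a warning.
#' @return binary clusters x cells matrix (cluster rows in first-appearance
#'   order of the assignment).
#' @export
cluster_membership_mask <- function(assignment, cell_ids) {
  assignment <- cluster_assignment(assignment)
  cell_ids <- as.character(cell_ids)
  unassigned <- setdiff(cell_ids, names(assignment))
  if (length(unassigned)) {
    warning(length(unassigned), " cell(s) without cluster label dropped")
    cell_ids <- setdiff(cell_ids, unassigned)
  }
  if (!length(cell_ids)) stop("no assigned cells left")
  labels <- assignment[cell_ids]
  lev <- cluster_levels(assignment)
  mask <- vapply(lev, function(cl) as.numeric(labels == cl),
                 numeric(length(cell_ids)))
  mask <- t(matrix(mask, nrow = length(cell_ids),
                   dimnames = list(cell_ids, lev)))
  empty <- rowSums(mask) == 0
  if (any(empty))
    stop("cluster(s) with zero cells after intersection: ",
         paste(utils::head(lev[empty], 3), collapse = ", "))
  mask
}

#' SCA pseudo-bulk pseudo-replicates
#'
#' Runs the cluster-conditioned sparsely connected autoencoder: training
#' samples are the genes, input features are the cells, and each hidden
#' node is one cluster, connected only to its member cells. The hidden
#' activation of gene g at cluster node c is a denoised aggregate of g's
#' expression over the cluster's cells — a pseudo-bulk value. Repeating
#' the run from independent initializations yields pseudo-replicates that
#' scatter around each cluster's centroid, giving the replication structure
#' bulk-style downstream analyses need. Reference setting: 20 runs of 1000
#' epochs.
#'
#' @param m post-preprocessing feature x cell count matrix.
#' @param assignment a [cluster_assignment()] covering \code{m}'s cells.
#' @param config an [sca_config()]; \code{scale_input} applies log1p +
#'   per-cell min-max scaling to the transposed matrix.
#' @param n_runs number of independent runs (pseudo-replicates per
#'   cluster).
#' @return genes x (clusters * runs) matrix with columns named
#'   \code{<cluster>.<run>} and attributes \code{cluster} and \code{run}
#'   (per-column labels), class \code{pseudobulk_set}. Entries are
#'   nonnegative under the relu/sigmoid activations.
#' @export
pseudobulk_replicates <- function(m, assignment, config = sca_config(),
                                  n_runs = 20) {
  mask <- cluster_membership_mask(assignment, colnames(m))
  small <- rowSums(mask) < 2
  if (any(small))
    warning("cluster(s) with fewer than 2 cells: ",
            paste(rownames(mask)[small], collapse = ", "))
  # training samples = genes (rows), input features = cells (columns)
  data <- m[, colnames(mask), drop = FALSE]
  runs <- run_permutations(data, mask, config, n_runs)
  out <- do.call(cbind, runs)
  cluster_lab <- rep(rownames(mask), times = n_runs)
  run_lab <- rep(seq_len(n_runs) - 1L, each = nrow(mask))
  colnames(out) <- paste(cluster_lab, run_lab, sep = ".")
  rownames(out) <- rownames(m)
  structure(out, cluster = cluster_lab, run = run_lab,
            class = c("pseudobulk_set", "matrix", "array"))
}

#' Normalize pseudo-bulk replicates for comparison
#'
#' Applies the standard pseudo-bulk transform — log2CPM followed by
#' row-mean centering — either to every replicate column
#' (\code{per_run}) or to the per-cluster mean over runs
#' (\code{mean_over_runs}).
#'
#' @param pb a \code{pseudobulk_set} from [pseudobulk_replicates()].
#' @param mode "per_run" or "mean_over_runs".
#' @param pseudocount passed to [log2cpm()].
#' @return genes x profiles centered log2CPM matrix.
#' @export
summarize_pseudobulk <- function(pb, mode = c("per_run", "mean_over_runs"),
                                 pseudocount = 1) {
  mode <- match.arg(mode)
  values <- unclass(pb)
  if (mode == "mean_over_runs") {
    cluster <- attr(pb, "cluster")
    if (is.null(cluster)) stop("'pb' lacks per-column cluster labels")
    lev <- unique(cluster)
    values <- vapply(lev, function(cl)
      rowMeans(values[, cluster == cl, drop = FALSE]),
      numeric(nrow(values)))
    colnames(values) <- lev
  }
  attr(values, "cluster") <- NULL
  attr(values, "run") <- NULL
  row_mean_center(log2cpm(values, pseudocount))
}

#' Summing pseudo-bulk baseline
#'
#' The classical pseudo-bulk: per-cluster sums of raw counts across member
#' cells. This is the single-vector representation the SCA replicates are
#' contrasted against; it conserves counts exactly (cluster sums add up to
#' the per-gene totals) but offers no replication.
#'
#' @param m feature x cell count matrix.
#' @param assignment a [cluster_assignment()] covering \code{m}'s cells.
#' @return genes x clusters matrix of summed counts.
#' @export
naive_pseudobulk <- function(m, assignment) {
  mask <- cluster_membership_mask(assignment, colnames(m))
  out <- m[, colnames(mask), drop = FALSE] %*% t(mask)
  dimnames(out) <- list(rownames(m), rownames(mask))
  out
}
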