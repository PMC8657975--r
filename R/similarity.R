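#' Pearson similarity matrix between expression profiles
#'
#' Correlates every column of \code{a} with every column of \code{b} over
#' their shared features (row names), taken in a fixed sorted order so the
#' result does not depend on input row order. Ensembl version suffixes
#' (\code{ENSG...\.12}) are stripped before intersecting, since
#' GTF-derived gene-activity matrices carry versions while expression
#' tables often do not. Zero-variance profiles yield \code{NA} entries
#' with a warning — never a silent 0.
#'
#' @param a,b feature x profile matrices (e.g. centered log2CPM
#'   pseudo-bulks, bulk reference TPM). \code{b} defaults to \code{a}.
#' @param min_shared minimum number of shared features (default 3).
#' @return profiles(a) x profiles(b) correlation matrix with attribute
#'   \code{n_shared}.
#' @export
pearson_matrix <- function(a, b = a, min_shared = 3) {
  ra <- strip_ensembl_version(rownames(a))
  rb <- strip_ensembl_version(rownames(b))
  if (anyDuplicated(ra) || anyDuplicated(rb))
    stop("duplicate feature IDs after stripping Ensembl versions")
  shared <- sort(intersect(ra, rb))
  if (length(shared) < min_shared)
    stop("only ", length(shared), " shared feature(s); need >= ", min_shared)
  av <- unclass(a)[match(shared, ra), , drop = FALSE]
  bv <- unclass(b)[match(shared, rb), , drop = FALSE]
  zero_a <- apply(av, 2, stats::sd) == 0
  zero_b <- apply(bv, 2, stats::sd) == 0
  if (any(zero_a) || any(zero_b))
    warning("zero-variance profile(s) yield NA correlations: ",
            paste(c(colnames(a)[zero_a], colnames(b)[zero_b]), collapse = ", "))
  out <- suppressWarnings(stats::cor(av, bv))
  out[zero_a, ] <- NA_real_
  out[, zero_b] <- NA_real_
  attr(out, "n_shared") <- length(shared)
  out
}

strip_ensembl_version <- function(ids) sub("^(ENS[A-Z]*[GT]\\d+)\\.\\d+$", "\\1", ids)

#' Best-match cluster pairing from a similarity matrix
#'
#' For each row (query cluster) reports the column with the highest
#' similarity — the "arrow" drawn between matching clusters of two
#' experiments — together with the runner-up and the margin between them.
#' Rows whose top two values tie within 1e-12 are flagged ambiguous rather
#' than broken arbitrarily.
#'
#' @param s similarity matrix from [pearson_matrix()].
#' @param mutual when TRUE, also flag whether each pair is a mutual best
#'   match (the column's best row is the same row).
#' @return data.frame with columns query, match, r, runner_up, margin,
#'   ambiguous (and mutual when requested).
#' @export
best_match <- function(s, mutual = FALSE) {
  stopifnot(is.matrix(s), !is.null(rownames(s)), !is.null(colnames(s)))
  out <- do.call(rbind, lapply(seq_len(nrow(s)), function(i) {
    v <- s[i, ]
    if (all(is.na(v)))
      return(data.frame(query = rownames(s)[i], match = NA_character_,
                        r = NA_real_, runner_up = NA_real_,
                        margin = NA_real_, ambiguous = NA))
    j <- which.max(v)
    runner <- if (ncol(s) > 1) max(v[-j], na.rm = TRUE) else NA_real_
    margin <- if (is.na(runner)) NA_real_ else v[j] - runner
    data.frame(query = rownames(s)[i], match = colnames(s)[j],
               r = unname(v[j]), runner_up = runner, margin = margin,
               ambiguous = !is.na(margin) && margin <= 1e-12)
  }))
  if (mutual) {
    col_best <- rownames(s)[apply(s, 2, function(v)
      if (all(is.na(v))) NA_integer_ else which.max(v))]
    names(col_best) <- colnames(s)
    out$mutual <- !is.na(out$match) & col_best[out$match] == out$query
  }
  rownames(out) <- NULL
  out
}

#' UPGMA hierarchical clustering of expression profiles
#'
#' Euclidean distance between profile columns, unweighted average linkage
#' (UPGMA) — the standard recipe for assigning cell-line identity to
#' clusters by co-clustering pseudo-bulks with bulk references. Ties break
#' deterministically by index order.
#'
#' @param profiles feature x profile matrix.
#' @return list of class \code{sca_dendrogram}: \code{merges} (data.frame
#'   node_a, node_b, height, new_node_id; leaves are negative indexes as
#'   in \code{hclust}, internal nodes positive), \code{labels}, and the
#'   underlying \code{hclust} object.
#' @export
upgma <- function(profiles) {
  x <- unclass(profiles)
  if (ncol(x) < 2) stop("need at least 2 profiles")
  if (any(!is.finite(x))) stop("non-finite values in profiles")
  hc <- stats::hclust(stats::dist(t(x), method = "euclidean"),
                      method = "average")
  merges <- data.frame(node_a = hc$merge[, 1], node_b = hc$merge[, 2],
                       height = hc$height,
                       new_node_id = seq_len(nrow(hc$merge)))
  structure(list(merges = merges, labels = hc$labels, hclust = hc),
            class = "sca_dendrogram")
}

#' @method print sca_dendrogram
#' @export
print.sca_dendrogram <- function(x, ...) {
  cat("UPGMA dendrogram, ", length(x$labels), " leaves\n", sep = "")
  print(x$merges)
  invisible(x)
}
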