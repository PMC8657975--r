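#' Present-gene calls
#'
#' A gene is called present in a cell when its count reaches \code{min_umi}
#' UMIs. The default of 3 moderates the effect of sequencing errors in UMI
#' counting, which can fabricate one or two spurious UMIs per gene.
#'
#' @param m feature x cell count matrix.
#' @param min_umi integer threshold, >= 1.
#' @return logical matrix of the same shape.
#' @export
call_present <- function(m, min_umi = 3) {
  stopifnot(min_umi >= 1)
  m >= min_umi
}

#' Remove low-quality cells by present-gene count
#'
#' Retains exactly the cells whose number of present genes (>=
#' \code{min_umi} UMIs) reaches \code{min_present_genes}. The feature axis
#' and the surviving cell order are unchanged. Typical thresholds: 250
#' present genes for scRNA-seq, 400 for ATAC-derived gene activity (see
#' [filter_atac_cells()]).
#'
#' @param m feature x cell count matrix.
#' @param min_present_genes integer >= 0.
#' @param min_umi present-call threshold passed to [call_present()].
#' @return the filtered matrix, with attribute \code{n_removed}.
#' @export
filter_cells <- function(m, min_present_genes, min_umi = 3) {
  stopifnot(min_present_genes >= 0)
  if (min_present_genes == 0) return(m)
  present_per_cell <- colSums(call_present(m, min_umi))
  keep <- present_per_cell >= min_present_genes
  if (!any(keep))
    stop("all ", ncol(m), " cells removed: max present-gene count is ",
         max(present_per_cell), ", threshold ", min_present_genes)
  out <- m[, keep, drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Two-stage informative-gene selection
#'
#' Step 1 ranks genes by total raw count across cells and keeps the
#' \code{top_expressed}; step 2 ranks the survivors by sample variance of
#' raw counts and keeps the \code{top_variant}. Ties break by input row
#' order, and the original row order is preserved among survivors. The
#' canonical setting keeps the 2500 most variant of the 5000 most
#' expressed genes.
#'
#' @param m feature x cell count matrix.
#' @param top_expressed number of genes kept by total expression.
#' @param top_variant number of genes kept by variance among those.
#' @return the row-subset matrix.
#' @export
select_genes <- function(m, top_expressed = 5000, top_variant = 2500) {
  if (!(top_variant <= top_expressed && top_expressed <= nrow(m)))
    stop("need top_variant <= top_expressed <= n_features (",
         top_variant, " / ", top_expressed, " / ", nrow(m), ")")
  totals <- rowSums(m)
  step1 <- sort(order(totals, decreasing = TRUE)[seq_len(top_expressed)])
  vars <- apply(m[step1, , drop = FALSE], 1, stats::var)
  step2 <- step1[sort(order(vars, decreasing = TRUE)[seq_len(top_variant)])]
  m[step2, , drop = FALSE]
}

#' Restrict a matrix to a given gene panel
#'
#' Reorders rows to \code{gene_ids} order, e.g. to impose on a second
#' experiment the gene panel selected from a first one.
#'
#' @param m feature x cell matrix.
#' @param gene_ids genes to keep, in the desired order.
#' @param allow_missing when TRUE, IDs absent from \code{m} are dropped
#'   (with a warning) instead of raising an error.
#' @return the reordered row-subset matrix.
#' @export
restrict_to_genes <- function(m, gene_ids, allow_missing = FALSE) {
  gene_ids <- as.character(gene_ids)
  missing <- setdiff(gene_ids, rownames(m))
  if (length(missing)) {
    if (!allow_missing)
      stop(length(missing), " requested gene(s) absent from matrix: ",
           paste(utils::head(missing, 3), collapse = ", "))
    warning(length(missing), " requested gene(s) absent, dropped")
    gene_ids <- setdiff(gene_ids, missing)
  }
  if (!length(gene_ids)) stop("empty intersection with requested genes")
  m[gene_ids, , drop = FALSE]
}

#' Counts-per-million normalization
#'
#' Scales each cell (column) to one million total counts. Columns whose
#' raw sum is zero are mapped to all-zero columns with a warning.
#'
#' @param m nonnegative feature x cell matrix.
#' @return CPM matrix with attribute \code{transform = "cpm"}.
#' @export
cpm <- function(m) {
  if (any(m < 0)) stop("cpm requires nonnegative input")
  cs <- colSums(m)
  zero <- cs == 0
  if (any(zero)) {
    warning(sum(zero), " column(s) with zero sum mapped to all-zero")
    cs[zero] <- 1
  }
  out <- sweep(m, 2, 1e6 / cs, `*`)
  attr(out, "transform") <- "cpm"
  out
}

#' log2 counts-per-million
#'
#' \code{log2(CPM + pseudocount)}; the default pseudocount of 1 keeps
#' zeros at zero.
#'
#' @param m nonnegative feature x cell matrix.
#' @param pseudocount added inside the log.
#' @return log2CPM matrix with attribute \code{transform = "log2cpm"}.
#' @export
log2cpm <- function(m, pseudocount = 1) {
  out <- log2(cpm(m) + pseudocount)
  attr(out, "transform") <- "log2cpm"
  out
}

#' Row-mean centering
#'
#' Subtracts each gene's mean across profiles, the standard step before
#' Pearson-similarity heatmaps and hierarchical clustering of expression
#' profiles.
#'
#' @param m feature x profile matrix.
#' @return centered matrix with attribute \code{transform = "centered"}.
#' @export
row_mean_center <- function(m) {
  out <- m - rowMeans(m)
  attr(out, "transform") <- "centered"
  out
}
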