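#' Construct a validated count matrix
#'
#' The universal expression container of the package: a base numeric matrix
#' with features (genes, peak regions, ...) as rows and cells as columns.
#' Feature IDs live in \code{rownames}, cell barcodes in \code{colnames}.
#'
#' @param values numeric matrix of nonnegative values (integers for raw UMI
#'   counts; reals are accepted so normalized matrices reuse the container).
#' @param feature_ids character vector of unique feature identifiers; taken
#'   from \code{rownames(values)} when missing.
#' @param cell_ids character vector of unique cell identifiers; taken from
#'   \code{colnames(values)} when missing.
#' @return the matrix with validated dimnames.
#' @export
count_matrix <- function(values, feature_ids = rownames(values),
                         cell_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(feature_ids) || is.null(cell_ids))
    stop("feature and cell identifiers are required")
  feature_ids <- as.character(feature_ids)
  cell_ids <- as.character(cell_ids)
  if (length(feature_ids) != nrow(values))
    stop("length(feature_ids) != nrow(values)")
  if (length(cell_ids) != ncol(values))
    stop("length(cell_ids) != ncol(values)")
  if (anyDuplicated(feature_ids))
    stop("duplicate feature IDs: ",
         paste(utils::head(feature_ids[duplicated(feature_ids)], 3), collapse = ", "))
  if (anyDuplicated(cell_ids))
    stop("duplicate cell IDs: ",
         paste(utils::head(cell_ids[duplicated(cell_ids)], 3), collapse = ", "))
  if (anyNA(values) || any(values < 0))
    stop("count matrix entries must be nonnegative and non-missing")
  dimnames(values) <- list(feature_ids, cell_ids)
  values
}

#' Construct a relationship table
#'
#' A relationship table maps each metafeature (a transcription factor, a
#' miRNA, or any other regulator) to the set of feature IDs it governs.
#' Represented as a named list of character vectors, the same shape
#' \code{fgsea} and other gene-set tools use.
#'
#' @param entries named list; names are metafeature IDs, elements are
#'   character vectors of target feature IDs. Duplicate targets within a set
#'   are removed.
#' @return validated named list of character vectors.
#' @export
relationship_table <- function(entries) {
  if (!is.list(entries) || is.null(names(entries)) || any(names(entries) == ""))
    stop("'entries' must be a named list of target ID vectors")
  if (anyDuplicated(names(entries)))
    stop("duplicate metafeature IDs")
  entries <- lapply(entries, function(x) unique(as.character(x)))
  empty <- lengths(entries) == 0L
  if (any(empty))
    stop("metafeature(s) with empty target set: ",
         paste(utils::head(names(entries)[empty], 3), collapse = ", "))
  entries
}

#' Construct a cluster assignment
#'
#' @param labels character vector of cluster labels named by cell ID, or a
#'   two-column data.frame (cell_id, cluster_label). Labels are opaque
#'   strings; they are never parsed as numbers, and cluster order is
#'   first-appearance order.
#' @return named character vector (names = cell IDs).
#' @export
cluster_assignment <- function(labels) {
  if (is.data.frame(labels)) {
    stopifnot(ncol(labels) >= 2)
    labels <- stats::setNames(as.character(labels[[2]]), as.character(labels[[1]]))
  }
  if (is.null(names(labels)) || any(names(labels) == ""))
    stop("cluster labels must be named by cell ID")
  labels <- stats::setNames(as.character(labels), names(labels))
  dup <- duplicated(names(labels))
  if (any(dup)) {
    conflict <- tapply(labels, names(labels), function(x) length(unique(x)) > 1L)
    if (any(conflict))
      stop("cell(s) assigned to conflicting clusters: ",
           paste(utils::head(names(conflict)[conflict], 3), collapse = ", "))
    labels <- labels[!dup]
  }
  if (length(labels) == 0L) stop("empty cluster assignment")
  labels
}

#' Cluster labels in first-appearance order
#' @param assignment named character vector from [cluster_assignment()].
#' @return character vector of distinct labels.
#' @export
cluster_levels <- function(assignment) unique(unname(assignment))

# internal: validate a gene locus index (1-based inclusive GTF coordinates)
validate_loci <- function(loci) {
  stopifnot(is.data.frame(loci),
            all(c("gene_id", "chrom", "start", "end", "strand") %in% names(loci)))
  if (anyDuplicated(loci$gene_id)) stop("duplicate gene IDs in locus index")
  if (any(loci$start > loci$end)) stop("gene locus with start > end")
  loci
}

# internal: validate a region set (0-based half-open BED coordinates)
validate_regions <- function(regions) {
  stopifnot(is.data.frame(regions),
            all(c("region_id", "chrom", "start", "end") %in% names(regions)))
  if (anyDuplicated(regions$region_id)) stop("duplicate region IDs")
  if (any(regions$start >= regions$end))
    stop("region with start >= end under 0-based half-open coordinates")
  regions
}
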