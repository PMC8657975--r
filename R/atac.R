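#' Assign open-chromatin regions to overlapping gene loci
#'
#' A region is assigned to every gene whose locus it overlaps by at least
#' one base pair; regions overlapping no locus map to an empty set, and
#' strand is ignored (accessibility is unstranded). BED regions are
#' 0-based half-open and gene loci 1-based inclusive; both are put on a
#' common footing before the interval query, and chromosome naming styles
#' ("1" vs "chr1") are harmonized first. Optionally the locus can be
#' extended upstream of the TSS to capture promoter accessibility
#' (default 0: the literal gene body only).
#'
#' @param regions data.frame from [read_bed_regions()] (region_id, chrom,
#'   start, end; 0-based half-open).
#' @param loci data.frame from [read_gtf_gene_loci()] (gene_id, chrom,
#'   start, end, strand; 1-based inclusive).
#' @param extend_upstream base pairs added upstream of each locus
#'   (strand-aware), default 0.
#' @return named list region_id -> character vector of gene_ids (possibly
#'   empty).
#' @export
assign_regions_to_genes <- function(regions, loci, extend_upstream = 0) {
  regions <- validate_regions(regions)
  loci <- validate_loci(loci)
  harmonize <- function(chrom) sub("^chr", "", chrom)
  gr_regions <- GenomicRanges::GRanges(
    harmonize(regions$chrom),
    IRanges::IRanges(start = regions$start + 1L, end = regions$end))
  gstart <- loci$start
  gend <- loci$end
  if (extend_upstream > 0) {
    plus <- loci$strand != "-"
    gstart[plus] <- pmax(1L, gstart[plus] - extend_upstream)
    gend[!plus] <- gend[!plus] + extend_upstream
  }
  gr_genes <- GenomicRanges::GRanges(
    harmonize(loci$chrom), IRanges::IRanges(start = gstart, end = gend))
  hits <- GenomicRanges::findOverlaps(gr_regions, gr_genes)
  out <- rep(list(character(0)), nrow(regions))
  names(out) <- regions$region_id
  if (length(hits)) {
    by_region <- split(loci$gene_id[S4Vectors::subjectHits(hits)],
                       S4Vectors::queryHits(hits))
    out[as.integer(names(by_region))] <- lapply(by_region, unique)
  }
  out
}

#' Gene-activity matrix from peak counts
#'
#' Collapses a peak x cell scATAC count matrix to genes: the activity of
#' gene g in cell i is the sum of counts of all regions assigned to g, so
#' it counts the reads falling within the gene's genomic locus. A region
#' overlapping several gene loci contributes its full count to each of
#' them (no splitting); genes with no assigned region are absent from the
#' output.
#'
#' @param peaks region x cell count matrix (rownames = region IDs).
#' @param map region -> genes list from [assign_regions_to_genes()].
#' @return gene x cell count matrix.
#' @export
gene_activity_matrix <- function(peaks, map) {
  unknown <- setdiff(rownames(peaks), names(map))
  if (length(unknown))
    stop("region(s) missing from the region-gene map: ",
         paste(utils::head(unknown, 3), collapse = ", "))
  map <- map[rownames(peaks)]
  n_genes_per_region <- lengths(map)
  if (all(n_genes_per_region == 0)) stop("no region maps to any gene")
  region_idx <- rep(seq_along(map), n_genes_per_region)
  gene_of_pair <- unlist(map, use.names = FALSE)
  genes <- unique(gene_of_pair)
  ind <- Matrix::sparseMatrix(
    i = match(gene_of_pair, genes), j = region_idx,
    x = 1, dims = c(length(genes), nrow(peaks)))
  out <- as.matrix(ind %*% peaks)
  dimnames(out) <- list(genes, colnames(peaks))
  count_matrix(out)
}

#' Cell filter for ATAC gene-activity matrices
#'
#' Keeps cells with at least \code{min_genes} gene loci called present,
#' a gene locus being present when supported by at least \code{min_umi}
#' counts. The defaults (400 genes, 3 UMIs) are the reference thresholds
#' for gene-activity matrices, where most barcodes carry too little
#' gene-associated signal to be usable.
#'
#' @param m gene x cell activity matrix.
#' @param min_genes present-gene threshold (inclusive), default 400.
#' @param min_umi present-call threshold, default 3.
#' @return the filtered matrix; a message reports pass/fail counts.
#' @export
filter_atac_cells <- function(m, min_genes = 400, min_umi = 3) {
  out <- filter_cells(m, min_present_genes = min_genes, min_umi = min_umi)
  n_removed <- attr(out, "n_removed")
  message(ncol(out), " cell(s) passed the >=", min_genes, "-present-genes ",
          "filter, ", if (is.null(n_removed)) 0L else n_removed, " removed")
  out
}
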