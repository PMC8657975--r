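#' Read a count matrix from CSV/TSV or MatrixMarket files
#'
#' Dense CSV/TSV files carry cell IDs in the header row and feature IDs in
#' the first column. MatrixMarket input follows the 10x Genomics layout:
#' features are MTX rows, and \code{features.tsv} (or \code{genes.tsv}) and
#' \code{barcodes.tsv} companions sit next to the \code{.mtx} file
#' (gzipped variants accepted).
#'
#' @param path path to the matrix file, or to the directory holding an MTX
#'   triplet.
#' @param format "csv", "tsv", "mtx", or "auto" (from the file extension).
#' @param transpose logical; set TRUE for MTX dialects that store cells as
#'   rows.
#' @return a feature x cell matrix (see [count_matrix()]).
#' @export
read_count_matrix <- function(path, format = c("auto", "csv", "tsv", "mtx"),
                              transpose = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    if (dir.exists(path)) format <- "mtx"
    else {
      ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))
      format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv", mtx = "mtx",
                       stop("cannot infer format from '", path, "'"))
    }
  }
  if (format %in% c("csv", "tsv")) {
    if (!file.exists(path)) stop("file not found: ", path)
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                            check.names = FALSE, comment.char = "")
    m <- as.matrix(df)
    storage.mode(m) <- "double"
    return(count_matrix(if (transpose) t(m) else m))
  }
  read_mtx_triplet(path, transpose)
}

read_mtx_triplet <- function(path, transpose = FALSE) {
  if (dir.exists(path)) {
    dir <- path
    mtx <- first_existing(file.path(dir, c("matrix.mtx", "matrix.mtx.gz")))
    if (is.na(mtx)) stop("no matrix.mtx[.gz] in ", dir)
  } else {
    if (!file.exists(path)) stop("file not found: ", path)
    mtx <- path
    dir <- dirname(path)
  }
  feat <- first_existing(file.path(dir, c("features.tsv", "features.tsv.gz",
                                          "genes.tsv", "genes.tsv.gz")))
  bc <- first_existing(file.path(dir, c("barcodes.tsv", "barcodes.tsv.gz")))
  if (is.na(feat) || is.na(bc))
    stop("MTX companions features.tsv/barcodes.tsv not found alongside ", mtx)
  m <- as.matrix(Matrix::readMM(mtx))
  feature_ids <- utils::read.table(feat, sep = "\t", colClasses = "character")[[1]]
  cell_ids <- utils::read.table(bc, sep = "\t", colClasses = "character")[[1]]
  if (transpose) m <- t(m)
  if (nrow(m) != length(feature_ids))
    stop("MTX declares ", nrow(m), " rows but features file lists ",
         length(feature_ids))
  if (ncol(m) != length(cell_ids))
    stop("MTX declares ", ncol(m), " columns but barcodes file lists ",
         length(cell_ids))
  count_matrix(m, feature_ids, cell_ids)
}

first_existing <- function(paths) {
  hit <- paths[file.exists(paths)]
  if (length(hit)) hit[[1]] else NA_character_
}

#' Write a count matrix to CSV/TSV or an MTX triplet
#'
#' @param m feature x cell matrix.
#' @param path output file (csv/tsv) or output directory (mtx; the triplet
#'   matrix.mtx + features.tsv + barcodes.tsv is written inside it).
#' @param format "csv", "tsv" or "mtx".
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(m, path, format = c("tsv", "csv", "mtx")) {
  format <- match.arg(format)
  m <- count_matrix(m)
  if (format == "mtx") {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    Matrix::writeMM(methods::as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"),
                    file.path(path, "matrix.mtx"))
    writeLines(rownames(m), file.path(path, "features.tsv"))
    writeLines(colnames(m), file.path(path, "barcodes.tsv"))
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- data.frame(feature_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read metafeature-target relationships (GMT or two-column TSV)
#'
#' GMT lines are \code{metafeature<TAB>description<TAB>target1<TAB>...};
#' the description field is ignored. The two-column dialect has one
#' \code{metafeature<TAB>target} pair per line. Duplicate targets are
#' removed; an empty target set is an error.
#'
#' @param path input file.
#' @param format "gmt", "tsv2col" or "auto" (gmt for .gmt extensions).
#' @return a [relationship_table()].
#' @export
read_relationships <- function(path, format = c("auto", "gmt", "tsv2col")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "tsv2col"
  if (format == "gmt") {
    nfield <- lengths(strsplit(readLines(path), "\t", fixed = TRUE))
    if (any(nfield < 3L))
      stop("GMT line(s) with fewer than 3 fields (no targets): line ",
           paste(utils::head(which(nfield < 3L), 3), collapse = ", "))
    return(relationship_table(fgsea::gmtPathways(path)))
  }
  df <- utils::read.table(path, sep = "\t", colClasses = "character",
                          col.names = c("metafeature", "target"))
  relationship_table(split(df$target, factor(df$metafeature,
                                             levels = unique(df$metafeature))))
}

#' Write a relationship table as GMT
#' @param rel a [relationship_table()].
#' @param path output file.
#' @param descriptions optional character vector of per-set descriptions
#'   (defaults to "na").
#' @return `path`, invisibly.
#' @export
write_gmt <- function(rel, path, descriptions = NULL) {
  rel <- relationship_table(rel)
  if (is.null(descriptions)) descriptions <- rep("na", length(rel))
  lines <- mapply(function(id, desc, targets)
    paste(c(id, desc, targets), collapse = "\t"),
    names(rel), descriptions, rel)
  writeLines(lines, path)
  invisible(path)
}

#' Read gene loci from a GTF file
#'
#' Uses rows with feature type \code{gene} when present; genes that appear
#' only as transcript/exon rows get the span \code{min(start)..max(end)}
#' over all their rows. Coordinates are kept 1-based inclusive as in GTF.
#' Gzipped input and GFF3-style \code{gene_id=...} attributes are accepted.
#'
#' @param path GTF/GFF file (optionally .gz).
#' @return data.frame with columns gene_id, chrom, start, end, strand.
#' @export
read_gtf_gene_loci <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) rtracklayer::import(path, format = "gff3"))
  meta <- S4Vectors::mcols(gr)
  if (!"gene_id" %in% names(meta) || all(is.na(meta$gene_id)))
    stop("no gene_id attribute parseable in ", path)
  keep <- !is.na(meta$gene_id)
  gr <- gr[keep]
  meta <- S4Vectors::mcols(gr)
  gene_rows <- if ("type" %in% names(meta))
    !is.na(meta$type) & as.character(meta$type) == "gene"
  else rep(FALSE, length(gr))
  ids <- as.character(meta$gene_id)
  per_gene <- function(sub_gr, sub_ids) {
    idx <- split(seq_along(sub_ids), sub_ids)
    do.call(rbind, lapply(names(idx), function(g) {
      i <- idx[[g]]
      data.frame(gene_id = g,
                 chrom = as.character(GenomicRanges::seqnames(sub_gr))[i[1]],
                 start = min(GenomicRanges::start(sub_gr)[i]),
                 end = max(GenomicRanges::end(sub_gr)[i]),
                 strand = as.character(GenomicRanges::strand(sub_gr))[i[1]],
                 stringsAsFactors = FALSE)
    }))
  }
  with_gene_row <- unique(ids[gene_rows])
  out <- NULL
  if (length(with_gene_row))
    out <- per_gene(gr[gene_rows], ids[gene_rows])
  rest <- !(ids %in% with_gene_row)
  if (any(rest))
    out <- rbind(out, per_gene(gr[rest], ids[rest]))
  out <- out[order(match(out$gene_id, unique(ids))), , drop = FALSE]
  rownames(out) <- NULL
  validate_loci(out)
}

#' Read a cluster-assignment table
#'
#' Two-column TSV, \code{cell_id<TAB>cluster_label}, no header. A cell
#' listed twice with conflicting labels is an error.
#'
#' @param path input file.
#' @return a [cluster_assignment()].
#' @export
read_cluster_assignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", colClasses = "character",
                          col.names = c("cell_id", "cluster_label"))
  cluster_assignment(df)
}

#' Write a cluster assignment as two-column TSV
#' @param assignment a [cluster_assignment()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cluster_assignment <- function(assignment, path) {
  assignment <- cluster_assignment(assignment)
  utils::write.table(data.frame(names(assignment), unname(assignment)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read peak regions from a BED file
#'
#' BED coordinates are 0-based half-open and are kept that way internally
#' (all interval logic in the package uses this convention; GTF input is
#' converted at the boundary). Regions keep input order; when the name
#' column is absent, region IDs \code{r1, r2, ...} are generated per line.
#'
#' @param path BED3/BED4 file.
#' @return data.frame with columns region_id, chrom, start, end.
#' @export
read_bed_regions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          fill = TRUE)
  if (ncol(df) < 3) stop("BED requires at least 3 columns")
  ids <- if (ncol(df) >= 4) as.character(df[[4]]) else rep(NA_character_, nrow(df))
  blank <- is.na(ids) | ids == ""
  ids[blank] <- paste0("r", which(blank))
  out <- data.frame(
    region_id = ids,
    chrom = as.character(df[[1]]),
    start = as.integer(df[[2]]),
    end = as.integer(df[[3]]),
    stringsAsFactors = FALSE)
  validate_regions(out)
}

#' Write regions as BED
#' @param regions data.frame from [read_bed_regions()] or
#'   [simulate_atac_fixture()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed_regions <- function(regions, path) {
  regions <- validate_regions(regions)
  utils::write.table(regions[, c("chrom", "start", "end", "region_id")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
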