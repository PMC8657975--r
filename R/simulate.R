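#' Planted regulatory modules for simulation designs
#'
#' Builds one module per cell type: module \code{TF_<type>} targets a
#' dedicated block of genes and is active (multiplier
#' \code{active_multiplier}) in its own type, baseline (multiplier 1)
#' elsewhere. An optional null module targets a further block with
#' multiplier 1 everywhere — a nonspecifically expressed gene set against
#' which planted signal can be ranked. Target blocks are positioned by the
#' order of \code{types}, so two designs built from the same type universe
#' share identical modules for their shared types.
#'
#' @param types character vector of cell-type labels (the type universe).
#' @param n_genes total genes in the simulated matrix.
#' @param targets_per_module genes per module block.
#' @param active_multiplier fold-activation of a module in its own type.
#' @param null_module include the uniform null module (default TRUE).
#' @return list of modules, each \code{list(targets, multipliers)} with
#'   multipliers a named vector over \code{types} (absent types default
#'   to 1).
#' @export
planted_modules <- function(types, n_genes, targets_per_module = 40,
                            active_multiplier = 6, null_module = TRUE) {
  n_blocks <- length(types) + null_module
  if (n_blocks * targets_per_module > n_genes)
    stop("n_genes too small for ", n_blocks, " blocks of ",
         targets_per_module, " targets")
  gene_ids <- sim_gene_ids(n_genes)
  block <- function(b)
    gene_ids[((b - 1) * targets_per_module + 1):(b * targets_per_module)]
  modules <- lapply(seq_along(types), function(b) {
    mult <- stats::setNames(rep(1, length(types)), types)
    mult[types[b]] <- active_multiplier
    list(targets = block(b), multipliers = mult)
  })
  names(modules) <- paste0("TF_", types)
  if (null_module)
    modules$TF_null <- list(
      targets = block(length(types) + 1),
      multipliers = stats::setNames(rep(1, length(types)), types))
  modules
}

sim_gene_ids <- function(n_genes) sprintf("g%04d", seq_len(n_genes))

#' Simulation design for clustered zero-inflated count matrices
#'
#' Describes the generative model of [simulate_counts()]: cells belong to
#' types (= planted clusters); the expected count of gene g in cell i is
#' \deqn{\mu_{gi} = \mathrm{baseline} \cdot \prod_{m \ni g}
#'   \mathrm{mult}_m(\mathrm{type}(i)) \cdot \mathrm{libsize}_i,}
#' counts are negative binomial with dispersion \code{nb_dispersion}
#' (the \code{size} parameter), and observed counts are independently
#' zeroed with probability \code{dropout_rate} (technical dropout).
#' Library sizes are log-normal with spread \code{library_size_spread}
#' and mean 1. The defaults reproduce the package's reference benchmark:
#' five types of 150 cells, 800 genes, one 40-gene module per type at
#' six-fold activation, 30\% dropout.
#'
#' @param cells_per_type named integer vector: cells per type label.
#' @param n_genes number of genes.
#' @param modules module list as from [planted_modules()]; built with the
#'   defaults when NULL.
#' @param baseline_mean expected baseline count per gene per cell.
#' @param nb_dispersion negative-binomial size (smaller = noisier).
#' @param dropout_rate probability an observed count is zeroed.
#' @param library_size_spread sdlog of the log-normal cell library factor.
#' @param seed RNG seed.
#' @param ... passed to [planted_modules()] when \code{modules} is NULL.
#' @return list of class \code{simulation_design}.
#' @export
simulation_design <- function(cells_per_type = stats::setNames(rep(150L, 5),
                                                               paste0("T", 1:5)),
                              n_genes = 800, modules = NULL,
                              baseline_mean = 2, nb_dispersion = 2,
                              dropout_rate = 0.3, library_size_spread = 0.3,
                              seed = 111, ...) {
  if (is.null(names(cells_per_type)) || any(names(cells_per_type) == ""))
    stop("'cells_per_type' must be named by type label")
  stopifnot(all(cells_per_type >= 1), n_genes >= 1, baseline_mean > 0,
            nb_dispersion > 0, dropout_rate >= 0, dropout_rate < 1,
            library_size_spread > 0)
  if (is.null(modules))
    modules <- planted_modules(names(cells_per_type), n_genes, ...)
  gene_ids <- sim_gene_ids(n_genes)
  for (m in names(modules)) {
    if (!all(modules[[m]]$targets %in% gene_ids))
      stop("module ", m, " targets genes outside the simulated gene set")
    if (any(!is.finite(modules[[m]]$multipliers)) ||
        any(modules[[m]]$multipliers < 0))
      stop("module ", m, " has invalid multipliers")
  }
  structure(list(cells_per_type = cells_per_type, n_genes = n_genes,
                 modules = modules, baseline_mean = baseline_mean,
                 nb_dispersion = nb_dispersion, dropout_rate = dropout_rate,
                 library_size_spread = library_size_spread,
                 seed = as.integer(seed)),
            class = "simulation_design")
}

# expected expression per gene and type, before library-size scaling
design_mean_profiles <- function(design) {
  gene_ids <- sim_gene_ids(design$n_genes)
  types <- names(design$cells_per_type)
  mu <- matrix(design$baseline_mean, design$n_genes, length(types),
               dimnames = list(gene_ids, types))
  for (mod in design$modules) {
    rows <- match(mod$targets, gene_ids)
    mult <- mod$multipliers[types]
    mult[is.na(mult)] <- 1
    mu[rows, ] <- mu[rows, ] * rep(mult, each = length(rows))
  }
  mu
}

#' Simulate a clustered zero-inflated count matrix
#'
#' Draws the matrix described by a [simulation_design()]: negative
#' binomial counts around type- and module-dependent means, then
#' independent dropout. Fully reproducible from the design seed.
#'
#' @param design a [simulation_design()].
#' @return list with \code{counts} (gene x cell [count_matrix()]),
#'   \code{truth} (list: \code{assignment} cell->type,
#'   \code{mean_profiles} gene x type expected expression,
#'   \code{activity} metafeature x type multipliers, \code{libsize}
#'   per-cell library factors), and \code{relationships} (the module
#'   target sets as a [relationship_table()]).
#' @export
simulate_counts <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  types <- names(design$cells_per_type)
  n_cells <- sum(design$cells_per_type)
  type_of_cell <- rep(types, design$cells_per_type)
  cell_ids <- paste0(type_of_cell, "_c", seq_len(n_cells))
  gene_ids <- sim_gene_ids(design$n_genes)

  mu_type <- design_mean_profiles(design)
  set.seed(design$seed)
  libsize <- stats::rlnorm(n_cells,
                           meanlog = -design$library_size_spread^2 / 2,
                           sdlog = design$library_size_spread)
  mu <- mu_type[, type_of_cell, drop = FALSE] *
    rep(libsize, each = design$n_genes)
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = design$nb_dispersion),
                   design$n_genes, n_cells)
  if (design$dropout_rate > 0) {
    keep <- stats::runif(length(counts)) >= design$dropout_rate
    counts <- counts * keep
  }
  dimnames(counts) <- list(gene_ids, cell_ids)

  activity <- do.call(rbind, lapply(design$modules, function(mod) {
    mult <- mod$multipliers[types]
    mult[is.na(mult)] <- 1
    stats::setNames(mult, types)
  }))
  truth <- list(
    assignment = cluster_assignment(stats::setNames(type_of_cell, cell_ids)),
    mean_profiles = mu_type,
    activity = activity,
    libsize = stats::setNames(libsize, cell_ids))
  list(counts = count_matrix(counts),
       truth = truth,
       relationships = relationship_table(
         lapply(design$modules, `[[`, "targets")))
}

#' Simulate a pair of independent experiments with shared cell types
#'
#' Emulates two independently processed single-cell experiments that share
#' a subset of cell types (e.g. a five-line and a three-line mixture of
#' the same cell lines): both matrices are drawn with their own seeds and
#' library sizes, but shared types use identical module multipliers, so a
#' true cross-experiment cluster correspondence exists and is returned.
#' Clusters are relabeled X1..Xk in experiment A and Y1..Ym in B, as two
#' labs would name clusters independently.
#'
#' @param design_a,design_b [simulation_design()]s. Shared types must
#'   have identical expected profiles in both designs (same modules
#'   restricted to those types); defaults: A = five types T1..T5,
#'   B = three types T1, T2, T5 sharing A's modules, seed offset by 1.
#' @param shared_types type labels present in both designs; defaults to
#'   the intersection.
#' @return list with \code{a}, \code{b} (each a [simulate_counts()]
#'   result) and \code{correspondence} (data.frame type, cluster_a,
#'   cluster_b over the shared types).
#' @export
simulate_paired_experiments <- function(design_a = NULL, design_b = NULL,
                                        shared_types = NULL) {
  if (is.null(design_a)) design_a <- simulation_design()
  if (is.null(design_b)) {
    keep <- names(design_a$cells_per_type)[c(1, 2, length(design_a$cells_per_type))]
    design_b <- simulation_design(
      cells_per_type = design_a$cells_per_type[keep],
      n_genes = design_a$n_genes, modules = design_a$modules,
      baseline_mean = design_a$baseline_mean,
      nb_dispersion = design_a$nb_dispersion,
      dropout_rate = design_a$dropout_rate,
      library_size_spread = design_a$library_size_spread,
      seed = design_a$seed + 1L)
  }
  types_a <- names(design_a$cells_per_type)
  types_b <- names(design_b$cells_per_type)
  if (is.null(shared_types)) shared_types <- intersect(types_a, types_b)
  if (!all(shared_types %in% types_a) || !all(shared_types %in% types_b))
    stop("shared_types must be present in both designs")
  mu_a <- design_mean_profiles(design_a)
  mu_b <- design_mean_profiles(design_b)
  if (length(shared_types) &&
      !isTRUE(all.equal(mu_a[, shared_types, drop = FALSE],
                        mu_b[, shared_types, drop = FALSE])))
    stop("shared types have inconsistent expected profiles in the two designs")

  sim_a <- simulate_counts(design_a)
  sim_b <- simulate_counts(design_b)
  relabel <- function(sim, prefix, types) {
    new <- stats::setNames(paste0(prefix, seq_along(types)), types)
    sim$truth$assignment <- cluster_assignment(
      stats::setNames(unname(new[sim$truth$assignment]),
                      names(sim$truth$assignment)))
    colnames(sim$truth$mean_profiles) <- unname(new[colnames(sim$truth$mean_profiles)])
    colnames(sim$truth$activity) <- unname(new[colnames(sim$truth$activity)])
    sim
  }
  map_a <- stats::setNames(paste0("X", seq_along(types_a)), types_a)
  map_b <- stats::setNames(paste0("Y", seq_along(types_b)), types_b)
  list(a = relabel(sim_a, "X", types_a),
       b = relabel(sim_b, "Y", types_b),
       correspondence = data.frame(
         type = shared_types,
         cluster_a = unname(map_a[shared_types]),
         cluster_b = unname(map_b[shared_types]),
         stringsAsFactors = FALSE))
}

#' Simulate a toy scATAC fixture (peaks, BED, GTF, ground truth)
#'
#' Builds a toy genome of non-overlapping gene loci on one chromosome and
#' places peak regions inside loci, in intergenic gaps, across a locus
#' boundary, and (when at least two genes exist) one region spanning two
#' adjacent loci — every placement with a known intended gene assignment.
#' Peak counts are negative binomial.
#'
#' @param n_genes,n_regions,n_cells fixture sizes.
#' @param seed RNG seed for the counts.
#' @param span_pair when TRUE (default) the last region is placed across
#'   loci 1 and 2 to exercise multi-gene assignment; set FALSE to keep
#'   every mapped region within a single locus.
#' @return list with \code{peaks} (region x cell [count_matrix()]),
#'   \code{regions} (BED-convention data.frame), \code{gtf} (character
#'   vector of GTF lines), \code{loci} (the parsed-equivalent locus
#'   table) and \code{truth} (list \code{assignments}: region ->
#'   intended gene IDs).
#' @export
simulate_atac_fixture <- function(n_genes = 10, n_regions = 30,
                                  n_cells = 20, seed = 111,
                                  span_pair = TRUE) {
  stopifnot(n_genes >= 1, n_regions >= 1, n_cells >= 1)
  gene_ids <- sprintf("G%03d", seq_len(n_genes))
  gene_start <- 1001L + (seq_len(n_genes) - 1L) * 5000L  # 1-based
  gene_end <- gene_start + 1999L
  loci <- data.frame(gene_id = gene_ids, chrom = "chr1",
                     start = gene_start, end = gene_end,
                     strand = rep(c("+", "-"), length.out = n_genes),
                     stringsAsFactors = FALSE)
  gtf <- sprintf(
    'chr1\tsim\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_name "%s";',
    gene_start, gene_end, loci$strand, gene_ids, gene_ids)

  region_id <- paste0("r", seq_len(n_regions))
  start <- integer(n_regions); end <- integer(n_regions)
  assignments <- rep(list(character(0)), n_regions)
  names(assignments) <- region_id
  for (i in seq_len(n_regions)) {
    g <- (i - 1L) %% n_genes + 1L
    kind <- (i - 1L) %/% n_genes %% 3L
    if (kind == 0L) {          # fully inside locus g
      start[i] <- gene_start[g] - 1L + 500L
      end[i] <- start[i] + 200L
      assignments[[i]] <- gene_ids[g]
    } else if (kind == 1L) {   # intergenic gap after locus g: unmapped
      start[i] <- gene_end[g] + 500L
      end[i] <- start[i] + 200L
    } else {                   # spanning the 5' boundary of locus g
      start[i] <- gene_start[g] - 1L - 100L
      end[i] <- start[i] + 200L
      assignments[[i]] <- gene_ids[g]
    }
  }
  if (span_pair && n_genes >= 2) {  # last region spans loci 1 and 2
    start[n_regions] <- gene_end[1] - 50L
    end[n_regions] <- gene_start[2] - 1L + 50L
    assignments[[n_regions]] <- gene_ids[1:2]
  }
  regions <- validate_regions(data.frame(
    region_id = region_id, chrom = "chr1", start = start, end = end,
    stringsAsFactors = FALSE))

  set.seed(seed)
  counts <- matrix(stats::rnbinom(n_regions * n_cells, mu = 5, size = 2),
                   n_regions, n_cells,
                   dimnames = list(region_id,
                                   paste0("cell", seq_len(n_cells))))
  list(peaks = count_matrix(counts), regions = regions, gtf = gtf,
       loci = validate_loci(loci), truth = list(assignments = assignments))
}
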