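#' Specification of a synthetic reference atlas
#'
#' Defines planted transcriptomic types: per-type centroids in log2
#' expression space, negative-binomial count noise, per-cell library-size
#' scaling, an exon/intron split per gene, and family/group annotations
#' per type. Centroids can be supplied directly or are generated from a
#' common baseline plus type-specific differential-expression shifts
#' whose magnitude is controlled by `type_separation`.
#'
#' @param n_types Number of neural t-types (>= 2).
#' @param n_genes Number of genes.
#' @param n_cells_per_type Reference cells simulated per type.
#' @param centroid_log_expression Optional types x genes matrix of log2
#'   mean expression; generated when `NULL`.
#' @param dispersion Negative-binomial dispersion (> 0; variance =
#'   mu + dispersion * mu^2).
#' @param library_size Mean per-cell library-size scaling factor
#'   (log-normal, sd 0.3 on the log scale).
#' @param exon_fraction Per-gene probability that a count is exonic
#'   (recycled; in [0, 1]).
#' @param type_separation Scale of the planted between-type
#'   log-expression shifts.
#' @param prop_de Fraction of genes shifted per type.
#' @param family_of_type Family label per type (default: consecutive
#'   pairs of types share a family).
#' @param group_of_type Transcriptomic group per type, each one of
#'   "CGE", "MGE", "excitatory" (default: round-robin).
#' @param n_nonneural Number of additional non-neural types appended
#'   (for first-round quality control).
#' @param seed Integer seed.
#' @return An object of class `atlas_spec` with the realized centroid
#'   matrix and annotations.
#' @export
atlas_spec <- function(n_types = 12, n_genes = 2000,
                       n_cells_per_type = 40,
                       centroid_log_expression = NULL,
                       dispersion = 0.3, library_size = 1,
                       exon_fraction = 0.7,
                       type_separation = 2, prop_de = 0.1,
                       family_of_type = NULL, group_of_type = NULL,
                       n_nonneural = 0, seed = 1L) {
  if (n_types < 2) stop("n_types must be >= 2", call. = FALSE)
  stopifnot_scalar(dispersion, "dispersion", positive = TRUE)
  exon_fraction <- rep_len(exon_fraction, n_genes)
  if (any(exon_fraction < 0 | exon_fraction > 1))
    stop("exon_fraction must be in [0, 1]", call. = FALSE)
  total <- n_types + n_nonneural
  set.seed(derive_seed(seed, 0L))
  genes <- sprintf("g%04d", seq_len(n_genes))
  if (is.null(centroid_log_expression)) {
    base <- pmax(0, stats::rnorm(n_genes, 1.5, 1.5))
    L <- matrix(rep(base, each = total), nrow = total,
                dimnames = list(NULL, genes))
    n_de <- max(1L, round(prop_de * n_genes))
    for (ty in seq_len(total)) {
      idx <- sample.int(n_genes, n_de)
      shift <- stats::runif(n_de, 0.5, 1.5) * type_separation *
        sample(c(-1, 1), n_de, replace = TRUE)
      L[ty, idx] <- pmax(0, L[ty, idx] + shift)
    }
  } else {
    L <- centroid_log_expression
    if (nrow(L) != total || ncol(L) != n_genes)
      stop("centroid_log_expression must be (n_types + n_nonneural) x n_genes",
           call. = FALSE)
    if (is.null(colnames(L))) colnames(L) <- genes
    genes <- colnames(L)
  }
  if (any(duplicated(L))) stop("centroids must be distinct", call. = FALSE)
  t_types <- c(sprintf("t%02d", seq_len(n_types)),
               if (n_nonneural) sprintf("nn%02d", seq_len(n_nonneural)))
  rownames(L) <- t_types
  groups <- c("CGE", "MGE", "excitatory")
  if (is.null(group_of_type))
    group_of_type <- groups[(seq_len(n_types) - 1L) %% 3L + 1L]
  if (!all(group_of_type %in% groups))
    stop("group_of_type entries must be CGE, MGE or excitatory",
         call. = FALSE)
  if (is.null(family_of_type))
    family_of_type <- paste0(group_of_type, "_f",
                             ((seq_len(n_types) - 1L) %/% 3L) %% 2L + 1L)
  structure(list(
    n_types = n_types, n_genes = n_genes,
    n_cells_per_type = n_cells_per_type,
    centroid_log_expression = L, dispersion = dispersion,
    library_size = library_size, exon_fraction = exon_fraction,
    type_separation = type_separation,
    t_types = t_types,
    family_of_type = stats::setNames(family_of_type, t_types[seq_len(n_types)]),
    group_of_type = stats::setNames(group_of_type, t_types[seq_len(n_types)]),
    neural_of_type = stats::setNames(
      c(rep(TRUE, n_types), rep(FALSE, n_nonneural)), t_types),
    genes = genes, seed = as.integer(seed)
  ), class = "atlas_spec")
}

nb_counts <- function(mu, dispersion) {
  matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
         nrow = nrow(mu), dimnames = dimnames(mu))
}

# simulate one genes x cells UMI atlas from the spec centroids
simulate_atlas <- function(spec, seed) {
  set.seed(seed)
  L <- spec$centroid_log_expression
  total <- nrow(L)
  n_per <- spec$n_cells_per_type
  cells_type <- rep(rownames(L), each = n_per)
  lib <- spec$library_size * exp(stats::rnorm(length(cells_type), 0, 0.3))
  mu <- t(2^L[cells_type, , drop = FALSE] - 1) * rep(lib, each = ncol(L))
  counts <- nb_counts(mu, spec$dispersion)
  rownames(counts) <- spec$genes
  colnames(counts) <- sprintf("c%05d", seq_along(cells_type))
  structure(list(counts = counts, type_of_cell = cells_type,
                 t_types = spec$t_types,
                 family_of_type = spec$family_of_type,
                 group_of_type = spec$group_of_type,
                 neural_of_type = spec$neural_of_type,
                 platform = "UMI-based"),
            class = "reference_atlas")
}

#' Generate reference atlases and Patch-seq-like query cells
#'
#' Simulates one or more UMI reference atlases from the planted
#' centroids, plus read-based query cells drawn from chosen type
#' centroids with log-normal expression noise, whose counts are split
#' into exonic and intronic parts per gene; exonic/intronic gene lengths
#' are attached. The true type of every query cell is returned.
#'
#' @param spec An [atlas_spec()].
#' @param n_query_cells Number of query cells.
#' @param query_noise SD of Gaussian noise added to the centroid log2
#'   expression of each query cell (0 = exact centroid expression).
#' @param n_atlases Number of independently simulated reference atlases.
#' @param query_library_size Mean library-size scaling of query cells.
#' @return List with `atlases` (list of `reference_atlas`), `query` (an
#'   `expression_bundle`), and `true_type` (character vector).
#' @export
generate_expression_bundle <- function(spec, n_query_cells = 50,
                                       query_noise = 0.3,
                                       n_atlases = 1,
                                       query_library_size = 20) {
  stopifnot(inherits(spec, "atlas_spec"))
  atlases <- lapply(seq_len(n_atlases), function(a)
    simulate_atlas(spec, derive_seed(spec$seed, a)))

  set.seed(derive_seed(spec$seed, 1000L))
  neural <- spec$t_types[spec$neural_of_type[spec$t_types]]
  true_type <- sample(neural, n_query_cells, replace = TRUE)
  L <- spec$centroid_log_expression[true_type, , drop = FALSE]
  if (query_noise > 0)
    L <- pmax(L + matrix(stats::rnorm(length(L), 0, query_noise),
                         nrow = nrow(L)), 0)
  lib <- query_library_size * exp(stats::rnorm(n_query_cells, 0, 0.3))
  mu <- t(2^L - 1) * rep(lib, each = ncol(L))
  total <- nb_counts(mu, spec$dispersion)
  rownames(total) <- spec$genes
  colnames(total) <- sprintf("q%04d", seq_len(n_query_cells))
  exon <- matrix(stats::rbinom(length(total), size = as.vector(total),
                               prob = rep(spec$exon_fraction,
                                          times = ncol(total))),
                 nrow = nrow(total), dimnames = dimnames(total))
  intron <- total - exon
  len_e <- exp(stats::rnorm(spec$n_genes, log(2), 0.5))
  len_i <- exp(stats::rnorm(spec$n_genes, log(10), 0.8))
  len_i[stats::runif(spec$n_genes) < 0.05] <- 0  # intronless genes
  query <- expression_bundle(exon, intron,
                             exonic_length_kb = stats::setNames(len_e, spec$genes),
                             intronic_length_kb = stats::setNames(len_i, spec$genes),
                             platform = "read-based")
  list(atlases = atlases, query = query, true_type = true_type)
}

#' Expression bundle for query cells
#'
#' Exon and intron count matrices (genes x cells) with per-gene exonic
#' and intronic lengths in kilobases and a platform tag.
#'
#' @param exon_counts,intron_counts Non-negative integer matrices,
#'   genes x cells, identical dimnames.
#' @param exonic_length_kb,intronic_length_kb Per-gene lengths (kb);
#'   intronic length may be 0 (guarded downstream).
#' @param platform `"read-based"` or `"UMI-based"`.
#' @return Object of class `expression_bundle`.
#' @export
expression_bundle <- function(exon_counts, intron_counts = NULL,
                              exonic_length_kb = NULL,
                              intronic_length_kb = NULL,
                              platform = c("read-based", "UMI-based")) {
  platform <- match.arg(platform)
  if (any(exon_counts < 0))
    stop("counts must be non-negative", call. = FALSE)
  if (is.null(intron_counts))
    intron_counts <- matrix(0, nrow(exon_counts), ncol(exon_counts),
                            dimnames = dimnames(exon_counts))
  if (any(intron_counts < 0))
    stop("counts must be non-negative", call. = FALSE)
  if (platform == "read-based") {
    if (is.null(exonic_length_kb) || any(exonic_length_kb <= 0))
      stop("exonic lengths (> 0) required for read-based data",
           call. = FALSE)
    if (is.null(intronic_length_kb) || any(intronic_length_kb < 0))
      stop("intronic lengths (>= 0) required for read-based data",
           call. = FALSE)
  }
  structure(list(exon_counts = exon_counts, intron_counts = intron_counts,
                 exonic_length_kb = exonic_length_kb,
                 intronic_length_kb = intronic_length_kb,
                 platform = platform),
            class = "expression_bundle")
}
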