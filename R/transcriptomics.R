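#' Normalize expression to log2 scale
#'
#' Read-based data: exon counts are normalized by exonic gene length in
#' kb, intron counts by intronic length in kb plus 1e-6 (guarding
#' intronless genes), the two are summed and log2(x + 1)-transformed.
#' UMI data passes through length-unnormalized: log2(UMI + 1).
#'
#' @param x An [expression_bundle()] or, for UMI data, a genes x cells
#'   count matrix.
#' @return Genes x cells matrix of log2 expression.
#' @export
normalize_expression <- function(x) {
  if (is.matrix(x)) {
    if (any(x < 0)) stop("counts must be non-negative", call. = FALSE)
    return(log2(x + 1))
  }
  stopifnot(inherits(x, "expression_bundle"))
  if (x$platform == "UMI-based")
    return(log2(x$exon_counts + x$intron_counts + 1))
  e <- x$exon_counts / x$exonic_length_kb
  i <- x$intron_counts / (x$intronic_length_kb + 1e-6)
  log2(e + i + 1)
}

#' Select the most variable genes by the dropout-rate criterion
#'
#' Genes with counts of at least `c_min` in fewer than `min_cells` cells
#' are excluded. For each remaining gene, `mu` is the mean log2 count
#' over counts larger than `c_min` and `tau` the fraction of counts
#' less than or equal to `c_min` (near-zero fraction). A binary search
#' over the offset `b` finds the value for which exactly `target_n`
#' genes satisfy `tau > exp(slope * mu + b) + margin`.
#'
#' @param counts Genes x cells count matrix (exonic counts for
#'   read-based data).
#' @param target_n Requested number of genes.
#' @param c_min Near-zero count threshold: 32 for read-based platforms,
#'   0 for UMI.
#' @param min_cells Minimum number of cells with counts >= `c_min`.
#' @param slope Slope of the exponential mean-dropout law.
#' @param margin Additive offset of the selection boundary.
#' @return Character vector of selected gene names with attributes `b`
#'   (offset found), `mu` and `tau` (named vectors over eligible genes).
#'   Warns when `target_n` is not exactly achievable and returns the
#'   nearest achievable set.
#' @export
select_variable_genes <- function(counts, target_n, c_min = 32,
                                  min_cells = 10, slope = -1.5,
                                  margin = 0.002) {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%05d", seq_len(nrow(counts)))
  eligible <- rowSums(counts >= c_min) >= min_cells
  cm <- counts[eligible, , drop = FALSE]
  if (!nrow(cm)) stop("no eligible genes", call. = FALSE)
  above <- cm > c_min
  mu <- rowSums(log2(pmax(cm, 1)) * above) / pmax(rowSums(above), 1)
  mu[rowSums(above) == 0] <- NA
  tau <- rowMeans(cm <= c_min)
  ok <- !is.na(mu)
  mu <- mu[ok]; tau <- tau[ok]
  n_sel <- function(b) sum(tau > exp(slope * mu + b) + margin)
  if (n_sel(-Inf) < target_n) {
    warning(sprintf("only %d selectable genes (target %d); returning all",
                    n_sel(-Inf), target_n))
    sel <- tau > margin
    out <- names(mu)[sel]
    attr(out, "b") <- -Inf
  } else {
    lo <- -60; hi <- 60   # n_sel(lo) = max, n_sel(hi) = 0
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      if (n_sel(mid) >= target_n) lo <- mid else hi <- mid
    }
    b <- lo
    got <- n_sel(b)
    if (got != target_n)
      warning(sprintf("selection of exactly %d genes not achievable; returning %d",
                      target_n, got))
    sel <- tau > exp(slope * mu + b) + margin
    out <- names(mu)[sel]
    attr(out, "b") <- b
  }
  attr(out, "mu") <- mu
  attr(out, "tau") <- tau
  out
}

#' Average log expression per type
#'
#' Means of log-transformed expression across the cells of each type,
#' restricted to a gene set (genes absent from the matrix are dropped and
#' recorded).
#'
#' @param log_expr Genes x cells log-expression matrix.
#' @param types Character vector of type labels per cell.
#' @param gene_set Genes to use (default: all).
#' @return Types x genes centroid matrix with attribute `missing_genes`.
#' @export
build_centroids <- function(log_expr, types, gene_set = rownames(log_expr)) {
  present <- intersect(gene_set, rownames(log_expr))
  missing <- setdiff(gene_set, present)
  if (!length(present)) stop("no genes in common", call. = FALSE)
  m <- log_expr[present, , drop = FALSE]
  tl <- unique(types)
  cen <- matrix(NA_real_, length(tl), nrow(m),
                dimnames = list(tl, rownames(m)))
  for (ty in tl)
    cen[ty, ] <- rowMeans(m[, types == ty, drop = FALSE])
  attr(cen, "missing_genes") <- missing
  cen
}

#' Map cells to types by highest Pearson correlation
#'
#' Each cell is assigned to the type whose centroid its log expression
#' correlates with most strongly (Pearson, across the shared genes).
#' Ties are broken by atlas type order.
#'
#' @param cells Genes x cells log-expression matrix (or a single named
#'   vector).
#' @param centroids Types x genes centroid matrix.
#' @return List with `best_type` (character per cell), `best_cor`, and
#'   the full `correlations` matrix (cells x types). Cells with zero
#'   variance across the shared genes get `NA` (unmappable).
#' @export
map_cells <- function(cells, centroids) {
  if (is.null(dim(cells))) cells <- matrix(cells, ncol = 1,
                                           dimnames = list(names(cells), "cell"))
  shared <- intersect(rownames(cells), colnames(centroids))
  if (length(shared) < 3) stop("need >= 3 shared genes", call. = FALSE)
  x <- cells[shared, , drop = FALSE]
  cc <- suppressWarnings(stats::cor(x, t(centroids[, shared, drop = FALSE])))
  sdx <- apply(x, 2, stats::sd)
  cc[sdx == 0, ] <- NA
  best <- apply(cc, 1, function(r) if (all(is.na(r))) NA_integer_
                else which.max(r))
  list(best_type = rownames(centroids)[best],
       best_cor = cc[cbind(seq_len(nrow(cc)),
                           ifelse(is.na(best), 1L, best))] *
         ifelse(is.na(best), NA, 1),
       correlations = cc)
}

#' First-round quality control
#'
#' A cell fails when its highest correlation is below `min_cor`, when its
#' best-correlated type is non-neural, or when its best correlation
#' exceeds the best correlation in each of the other two transcriptomic
#' groups by less than `group_margin`.
#'
#' @param correlations Named correlation vector over types for one cell
#'   (one row of [map_cells()] output).
#' @param group_of_type Named group label per neural type.
#' @param neural_of_type Named logical per type.
#' @param min_cor Minimum acceptable best correlation (default 0.4).
#' @param group_margin Required margin over the other groups (default
#'   0.02).
#' @return List with `pass`, `group` (when passing), `best_type`, and
#'   `reason` (when failing: one of "low_correlation", "non_neural",
#'   "ambiguous_group").
#' @export
round1_qc <- function(correlations, group_of_type, neural_of_type,
                      min_cor = 0.4, group_margin = 0.02) {
  best_i <- which.max(correlations)
  best_type <- names(correlations)[best_i]
  best <- correlations[[best_i]]
  if (is.na(best) || best < min_cor)
    return(list(pass = FALSE, reason = "low_correlation",
                best_type = best_type))
  if (!isTRUE(neural_of_type[[best_type]]))
    return(list(pass = FALSE, reason = "non_neural",
                best_type = best_type))
  grp <- group_of_type[[best_type]]
  other <- correlations[names(correlations) %in%
                          names(group_of_type)[group_of_type != grp]]
  if (length(other) && best - max(other, na.rm = TRUE) < group_margin)
    return(list(pass = FALSE, reason = "ambiguous_group",
                best_type = best_type))
  list(pass = TRUE, group = grp, best_type = best_type, best_cor = best)
}

#' Gene-bootstrap assignment confidence
#'
#' Resamples the gene set with replacement (at full size) `n_boot` times,
#' remaps the cell each time, and returns the fraction of draws in which
#' the cell mapped to each type.
#'
#' @param cell Named log-expression vector for one cell.
#' @param centroids Types x genes centroid matrix (already restricted to
#'   the cell's transcriptomic group and the atlas's variable genes).
#' @param n_boot Number of bootstrap draws (default 100).
#' @param seed Integer seed (per-cell independent streams recommended).
#' @return Named confidence vector over types summing to 1.
#' @export
bootstrap_confidence <- function(cell, centroids, n_boot = 100, seed = 1L) {
  shared <- intersect(names(cell), colnames(centroids))
  x <- cell[shared]
  cen <- centroids[, shared, drop = FALSE]
  set.seed(seed)
  wins <- integer(nrow(cen))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(length(shared), replace = TRUE)
    r <- suppressWarnings(stats::cor(x[idx], t(cen[, idx, drop = FALSE])))
    w <- which.max(r)
    if (length(w)) wins[w] <- wins[w] + 1L
  }
  stats::setNames(wins / sum(wins), rownames(cen))
}

#' Consensus assignment over reference atlases
#'
#' Averages per-atlas bootstrap confidence vectors (unweighted) and
#' assigns the type with the highest consensus confidence; ties go to
#' the first type in atlas order.
#'
#' @param confidences List of named confidence vectors (identical type
#'   sets).
#' @return List with `final_type` and `consensus` (named vector).
#' @export
consensus_assignment <- function(confidences) {
  stopifnot(length(confidences) >= 1)
  m <- do.call(rbind, confidences)
  cons <- colMeans(m)
  list(final_type = names(cons)[which.max(cons)], consensus = cons)
}

#' Two-round t-type assignment with bootstrap confidence
#'
#' Runs the full mapping workflow: round 1 maps every query cell to a
#' combined annotated atlas over its most variable genes for group
#' assignment and quality control; round 2 maps each passing cell to
#' each reference atlas, restricted to the t-types of the cell's group
#' and that atlas's per-group most variable genes, with gene-bootstrap
#' confidence; per-atlas confidences are averaged into a consensus and
#' the cell is assigned to the type with the highest consensus
#' confidence.
#'
#' @param query An [expression_bundle()] of query cells.
#' @param round1_atlas A `reference_atlas` with group and neural
#'   annotations (used for round 1).
#' @param atlases List of `reference_atlas` objects for round 2.
#' @param n_round1_genes,n_round2_genes Variable-gene set sizes
#'   (defaults 3000 and 500).
#' @param n_boot Bootstrap draws per cell and atlas.
#' @param seed Master seed; per-cell streams are derived from it.
#' @param exclude Optional character vector of query cell names to drop
#'   (user-supplied curation list).
#' @return List with `assignments` (data frame: cell, qc_pass,
#'   qc_reason, group, round1_best_type, round1_best_cor, final_type,
#'   final_confidence) and `consensus` (cells x types matrix of
#'   consensus confidences for passing cells).
#' @export
assign_ttypes <- function(query, round1_atlas, atlases = list(round1_atlas),
                          n_round1_genes = 3000, n_round2_genes = 500,
                          n_boot = 100, seed = 1L, exclude = NULL) {
  stopifnot(inherits(query, "expression_bundle"))
  qlog <- normalize_expression(query)
  if (!is.null(exclude))
    qlog <- qlog[, !colnames(qlog) %in% exclude, drop = FALSE]

  # round 1: combined atlas, full variable-gene set
  a1 <- round1_atlas
  c_min1 <- if (a1$platform == "UMI-based") 0 else 32
  n1 <- min(n_round1_genes, nrow(a1$counts))
  vg1 <- suppressWarnings(
    select_variable_genes(a1$counts, n1, c_min = c_min1))
  alog1 <- normalize_expression(a1$counts)
  cen1 <- build_centroids(alog1, a1$type_of_cell, vg1)
  r1 <- map_cells(qlog, cen1)

  group_of_type <- a1$group_of_type
  neural_of_type <- a1$neural_of_type

  # round 2 centroids: per atlas, per group, over that atlas's per-group
  # variable genes
  groups <- unique(group_of_type)
  prep <- lapply(atlases, function(a) {
    alog <- normalize_expression(a$counts)
    c_min <- if (a$platform == "UMI-based") 0 else 32
    per_group <- list()
    for (g in groups) {
      tys <- names(a$group_of_type)[a$group_of_type == g]
      cells_g <- a$type_of_cell %in% tys
      if (!any(cells_g)) next
      vg <- suppressWarnings(select_variable_genes(
        a$counts[, cells_g, drop = FALSE],
        min(n_round2_genes, nrow(a$counts)), c_min = c_min))
      per_group[[g]] <- build_centroids(
        alog[, cells_g, drop = FALSE],
        a$type_of_cell[cells_g], vg)
    }
    per_group
  })

  all_types <- names(group_of_type)
  n_cells <- ncol(qlog)
  res <- data.frame(cell = colnames(qlog), qc_pass = FALSE,
                    qc_reason = NA_character_, group = NA_character_,
                    round1_best_type = NA_character_,
                    round1_best_cor = NA_real_,
                    final_type = NA_character_,
                    final_confidence = NA_real_,
                    stringsAsFactors = FALSE)
  cons_mat <- matrix(NA_real_, n_cells, length(all_types),
                     dimnames = list(colnames(qlog), all_types))
  for (ci in seq_len(n_cells)) {
    corr <- r1$correlations[ci, ]
    qc <- round1_qc(corr, group_of_type, neural_of_type)
    res$round1_best_type[ci] <- qc$best_type
    res$round1_best_cor[ci] <- max(corr, na.rm = TRUE)
    if (!qc$pass) { res$qc_reason[ci] <- qc$reason; next }
    res$qc_pass[ci] <- TRUE
    res$group[ci] <- qc$group
    confs <- list()
    for (ai in seq_along(prep)) {
      cen <- prep[[ai]][[qc$group]]
      if (is.null(cen)) next
      confs[[length(confs) + 1L]] <- bootstrap_confidence(
        qlog[, ci], cen, n_boot = n_boot,
        seed = derive_seed(seed, ci * 131L + ai))
    }
    if (!length(confs)) next
    fin <- consensus_assignment(confs)
    res$final_type[ci] <- fin$final_type
    res$final_confidence[ci] <- max(fin$consensus)
    cons_mat[ci, names(fin$consensus)] <- fin$consensus
  }
  list(assignments = res, consensus = cons_mat)
}
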