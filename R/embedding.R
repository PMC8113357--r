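#' PCA with a fixed sign convention
#'
#' Principal components where each loading vector's largest-magnitude
#' entry is positive, so representations are reproducible across runs.
#'
#' @param m Cells x variables matrix (standardized by the caller).
#' @param n_pcs Number of components to keep.
#' @return List with `scores` (cells x n_pcs) and `rotation`.
#' @keywords internal
pca_fixed_sign <- function(m, n_pcs) {
  p <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  k <- min(n_pcs, ncol(p$rotation))
  rot <- p$rotation[, seq_len(k), drop = FALSE]
  flip <- vapply(seq_len(k), function(j)
    sign(rot[which.max(abs(rot[, j])), j]), numeric(1))
  rot <- sweep(rot, 2, flip, `*`)
  scores <- sweep(p$x[, seq_len(k), drop = FALSE], 2, flip, `*`)
  list(scores = scores, rotation = rot)
}

#' Electrophysiological representation
#'
#' Standardizes the complete 17-feature vectors, transforms them with
#' PCA, and scales all PCs by the standard deviation of PC1 (so PC1 has
#' unit variance and the remaining PCs keep their relative variances).
#'
#' @param features Cells x 17 matrix of analysis vectors (complete
#'   rows only).
#' @param n_pcs PCs retained: 17 for the electrophysiology-only
#'   representation, 16 when building the combined morpho-electric
#'   block.
#' @return Cells x `n_pcs` matrix.
#' @export
build_ephys_representation <- function(features, n_pcs = 17) {
  m <- as.matrix(features)
  if (any(!is.finite(m))) stop("features must be complete", call. = FALSE)
  if (nrow(m) < ncol(m)) stop("need at least as many cells as features",
                              call. = FALSE)
  p <- pca_fixed_sign(scale(m), n_pcs)
  s1 <- stats::sd(p$scores[, 1])
  out <- p$scores / s1
  rownames(out) <- rownames(features)
  out
}

# one class's 24-dim block: 20 morphometric PCs (scaled by sd of PC1)
# + z-profile PCs 2..5 (scaled by sd of PC2)
morph_class_block <- function(morpho, zprof, n_morph_pcs = 20) {
  pm <- pca_fixed_sign(scale(as.matrix(morpho)), n_morph_pcs)
  mb <- pm$scores / stats::sd(pm$scores[, 1])
  pz <- pca_fixed_sign(as.matrix(zprof), 5)
  if (ncol(pz$scores) < 5)
    stop("z-profiles must support 5 PCs", call. = FALSE)
  zb <- pz$scores[, 2:5, drop = FALSE] / stats::sd(pz$scores[, 2])
  cbind(mb, zb)
}

#' Morphological representation
#'
#' Built separately per cell class (dendritic z-profiles for excitatory
#' cells, axonal for inhibitory): standardized morphometrics reduced to
#' 20 PCs scaled by the sd of PC1, plus z-profile PCs 2-5 (PC1 is
#' discarded as a soma-depth surrogate) scaled by the sd of PC2. The two
#' 24-dim class blocks are assembled block-diagonally into 48 columns
#' and a constant `offset` is added to the excitatory block to separate
#' the populations.
#'
#' @param morphometrics Named list with `excitatory` and `inhibitory`
#'   cells x features matrices (either may be NULL).
#' @param z_profiles Named list with per-class cells x 20 profile
#'   matrices (dendritic for excitatory, axonal for inhibitory).
#' @param n_morph_pcs Morphometric PCs per class (default 20).
#' @param offset Constant added to the excitatory block (default 0.25).
#' @return Cells x 48 matrix (rows: excitatory cells then inhibitory
#'   cells) with attribute `cell_class`.
#' @export
build_morph_representation <- function(morphometrics, z_profiles,
                                       n_morph_pcs = 20, offset = 0.25) {
  blocks <- list()
  for (cls in c("excitatory", "inhibitory")) {
    mo <- morphometrics[[cls]]
    zp <- z_profiles[[cls]]
    if (is.null(mo) || is.null(zp)) next
    ok <- stats::complete.cases(mo) & stats::complete.cases(zp)
    b <- morph_class_block(mo[ok, , drop = FALSE], zp[ok, , drop = FALSE],
                           n_morph_pcs)
    rownames(b) <- rownames(mo)[ok] %||% NULL
    blocks[[cls]] <- b
  }
  if (!length(blocks)) stop("no cells with morphology", call. = FALSE)
  width <- vapply(blocks, ncol, integer(1))
  total <- sum(width)
  out <- matrix(0, sum(vapply(blocks, nrow, integer(1))), total)
  rn <- character(0); cls_v <- character(0)
  row0 <- 0L; col0 <- 0L
  for (cls in names(blocks)) {
    b <- blocks[[cls]]
    rows <- row0 + seq_len(nrow(b))
    cols <- col0 + seq_len(ncol(b))
    out[rows, cols] <- b
    if (cls == "excitatory") out[rows, cols] <- out[rows, cols] + offset
    rn <- c(rn, rownames(b) %||% paste0(cls, seq_len(nrow(b))))
    cls_v <- c(cls_v, rep(cls, nrow(b)))
    row0 <- row0 + nrow(b); col0 <- col0 + ncol(b)
  }
  rownames(out) <- rn
  attr(out, "cell_class") <- cls_v
  out
}

#' Combined morpho-electric representation
#'
#' Stacks the 48-dim morphological representation with the 16-dim
#' electrophysiological representation for cells present in both,
#' multiplying the electrophysiological block by sqrt(2) to put its
#' total variance on the scale of the two morphological PC sets.
#'
#' @param morph_rep Output of [build_morph_representation()].
#' @param ephys_rep Output of [build_ephys_representation()] with 16
#'   PCs.
#' @return Cells x (48 + 16) matrix.
#' @export
build_combined_representation <- function(morph_rep, ephys_rep) {
  shared <- intersect(rownames(morph_rep), rownames(ephys_rep))
  if (!length(shared)) stop("no cells in both modalities", call. = FALSE)
  cbind(morph_rep[shared, , drop = FALSE],
        sqrt(2) * ephys_rep[shared, , drop = FALSE])
}

#' Scaled PCA initialization for t-SNE
#'
#' First two PCs rescaled so that PC1 has standard deviation 1e-4 (the
#' conventional scale for t-SNE initialization).
#'
#' @param X Cells x dims matrix.
#' @return Cells x 2 matrix.
#' @export
scaled_pca_init <- function(X) {
  p <- pca_fixed_sign(scale(X, scale = FALSE), 2)
  p$scores / stats::sd(p$scores[, 1]) * 1e-4
}

#' t-SNE embedding through an external optimizer
#'
#' Embeds a representation in 2-D with t-SNE, treated as an external
#' algorithm with a pinned parameter contract: perplexity, early
#' exaggeration 4, learning rate n/12 and a caller-supplied (by default
#' scaled-PCA) initialization. The default engine runs scikit-learn's
#' TSNE through the `python` interpreter on the PATH; a custom engine
#' function `(X, init, params) -> n x 2 matrix` may be supplied.
#'
#' @param X Cells x dims representation.
#' @param perplexity t-SNE perplexity (default 30).
#' @param early_exaggeration Early exaggeration factor (default 4).
#' @param learning_rate Learning rate; default n/12.
#' @param init n x 2 initialization; default [scaled_pca_init()].
#' @param seed Random seed passed to the optimizer.
#' @param engine Embedding engine function; default
#'   [tsne_python_engine].
#' @return n x 2 matrix of positions with a `provenance` attribute
#'   recording the parameters.
#' @export
embed_tsne <- function(X, perplexity = 30, early_exaggeration = 4,
                       learning_rate = NULL, init = NULL, seed = 1L,
                       engine = tsne_python_engine) {
  n <- nrow(X)
  if (n < 3 * perplexity)
    warning("fewer than 3 * perplexity points; reduce perplexity")
  learning_rate <- learning_rate %||% (n / 12)
  init <- init %||% scaled_pca_init(X)
  params <- list(perplexity = perplexity,
                 early_exaggeration = early_exaggeration,
                 learning_rate = learning_rate, seed = seed,
                 init = "caller-supplied")
  pos <- engine(X, init, params)
  rownames(pos) <- rownames(X)
  attr(pos, "provenance") <- params
  pos
}

#' @rdname embed_tsne
#' @param params List of optimizer parameters (see [embed_tsne()]).
#' @export
tsne_python_engine <- function(X, init, params) {
  xin <- tempfile(fileext = ".csv"); iin <- tempfile(fileext = ".csv")
  xout <- tempfile(fileext = ".csv")
  on.exit(unlink(c(xin, iin, xout)))
  utils::write.table(X, xin, row.names = FALSE, col.names = FALSE,
                     sep = ",")
  utils::write.table(init, iin, row.names = FALSE, col.names = FALSE,
                     sep = ",")
  script <- sprintf(
    "import numpy as np\nfrom sklearn.manifold import TSNE\nX = np.loadtxt(%s, delimiter=',')\ninit = np.loadtxt(%s, delimiter=',')\nts = TSNE(n_components=2, perplexity=%g, early_exaggeration=%g, learning_rate=%g, init=init, random_state=%d)\nnp.savetxt(%s, ts.fit_transform(X), delimiter=',')\n",
    shQuote(xin), shQuote(iin), params$perplexity,
    params$early_exaggeration, params$learning_rate,
    as.integer(params$seed), shQuote(xout))
  status <- system2("python", "-", input = script,
                    stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(xout))
    stop("external t-SNE engine failed", call. = FALSE)
  as.matrix(utils::read.table(xout, sep = ","))
}

#' Position query cells on a reference embedding
#'
#' Each query cell is placed at the coordinate-wise median of the 2-D
#' positions of its `k` nearest reference cells, by Pearson correlation
#' distance in the shared high-dimensional log-expression space. No
#' optimizer runs, so positioning is deterministic.
#'
#' @param query Genes x query-cells log-expression matrix.
#' @param reference Genes x reference-cells log-expression matrix.
#' @param ref_positions Reference-cells x 2 embedding positions.
#' @param k Neighbour count (default 10).
#' @return Query-cells x 2 positions.
#' @export
position_on_reference <- function(query, reference, ref_positions,
                                  k = 10) {
  if (k > ncol(reference))
    stop("k exceeds the reference size", call. = FALSE)
  shared <- intersect(rownames(query), rownames(reference))
  cc <- suppressWarnings(stats::cor(query[shared, , drop = FALSE],
                                    reference[shared, , drop = FALSE]))
  t(apply(cc, 1, function(r) {
    nn <- order(1 - r)[seq_len(k)]
    apply(ref_positions[nn, , drop = FALSE], 2, stats::median)
  }))
}

#' Leave-one-out kNN family classification
#'
#' Classifies each cell by the majority family among its `k` nearest
#' neighbours (Euclidean distance, the cell itself excluded). Majority
#' ties are broken by the family of the single nearest neighbour.
#'
#' @param X Cells x dims representation.
#' @param families Character vector of family labels per cell.
#' @param k Neighbour count (default 10).
#' @return List with `predicted` (per cell), `accuracy`, and
#'   `confusion`: a row-normalized matrix in percent (rows = true
#'   family, each row sums to 100).
#' @export
knn_family_classify <- function(X, families, k = 10) {
  n <- nrow(X)
  stopifnot(length(families) == n)
  small <- names(which(table(families) < k + 1))
  if (length(small))
    warning("families with fewer than k + 1 cells: ",
            paste(small, collapse = ", "))
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  pred <- character(n)
  for (i in seq_len(n)) {
    nn <- order(D[i, ])[seq_len(min(k, n - 1))]
    tab <- table(families[nn])
    top <- names(tab)[tab == max(tab)]
    pred[i] <- if (length(top) == 1) top else {
      first <- families[nn][families[nn] %in% top][1]
      first
    }
  }
  lev <- sort(unique(families))
  cm <- table(factor(families, lev), factor(pred, lev))
  cm <- sweep(cm, 1, rowSums(cm), `/`) * 100
  list(predicted = pred, accuracy = mean(pred == families),
       confusion = as.matrix(cm))
}

#' Coverage ellipse of a 2-D point cloud
#'
#' Mean and covariance contour containing the stated probability mass
#' under a Gaussian model (chi-squared radius with 2 degrees of
#' freedom).
#'
#' @param points n x 2 matrix.
#' @param level Coverage level (default 0.8).
#' @return List with `center`, `cov`, `radius2` (squared Mahalanobis
#'   radius) and `contains(p)`, a function testing points.
#' @export
coverage_ellipse <- function(points, level = 0.8) {
  mu <- colMeans(points)
  S <- stats::cov(points)
  r2 <- stats::qchisq(level, df = 2)
  Sinv <- solve(S)
  list(center = mu, cov = S, radius2 = r2,
       contains = function(p) {
         p <- matrix(p, ncol = 2)
         d <- sweep(p, 2, mu)
         rowSums((d %*% Sinv) * d) <= r2
       })
}
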