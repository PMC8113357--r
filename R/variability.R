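#' Normalized total variance of a t-type
#'
#' The sum over feature dimensions of the within-type (population)
#' variance, divided by the sum over dimensions of the whole-data-set
#' (population) variance. 0 means all member cells have identical
#' features; 1 means the type is as variable as the entire data set.
#'
#' @param X Cells x features matrix (the same representation used for
#'   embeddings).
#' @param members Logical vector or index vector selecting the type's
#'   cells (>= 2 required).
#' @return Scalar >= 0 (`NA` if fewer than 2 member cells).
#' @export
normalized_total_variance <- function(X, members) {
  X <- as.matrix(X)
  sub <- X[members, , drop = FALSE]
  if (nrow(sub) < 2) return(NA_real_)
  num <- sum(apply(sub, 2, pop_var))
  den <- sum(apply(X, 2, pop_var))
  if (den == 0) return(NA_real_)
  num / den
}

#' k-means homogeneity baseline
#'
#' Clusters the cells into `K` clusters with k-means and returns the
#' minimum and maximum normalized total variance over clusters: the band
#' of variances attainable by maximally homogeneous groups of this data
#' set.
#'
#' @param X Cells x features matrix.
#' @param K Number of clusters (the number of qualifying t-types).
#' @param seed Seed for the k-means initialization.
#' @param nstart Restarts (default 10).
#' @return List with `band` (c(min, max)), `cluster_variance` per
#'   cluster, and the cluster assignment.
#' @export
kmeans_baseline <- function(X, K, seed = 1L, nstart = 10) {
  X <- as.matrix(X)
  if (K > nrow(X)) stop("K exceeds the number of cells", call. = FALSE)
  set.seed(seed)
  km <- stats::kmeans(X, centers = K, nstart = nstart)
  v <- vapply(seq_len(K), function(k)
    normalized_total_variance(X, km$cluster == k), numeric(1))
  list(band = c(min(v, na.rm = TRUE), max(v, na.rm = TRUE)),
       cluster_variance = v, cluster = km$cluster)
}

knn_graph <- function(X, k = 10) {
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  n <- nrow(D)
  edges <- integer(0)
  for (i in seq_len(n)) {
    nn <- order(D[i, ])[seq_len(min(k, n - 1))]
    edges <- c(edges, rbind(i, nn))
  }
  g <- igraph::make_graph(edges, n = n, directed = FALSE)
  igraph::simplify(g)
}

# binary-search the Leiden resolution to hit a target cluster count +- 1
tune_leiden_resolution <- function(g, target, seed = 1L, max_iter = 30) {
  ncl <- function(res) {
    set.seed(seed)
    length(unique(igraph::membership(igraph::cluster_leiden(
      g, objective_function = "modularity",
      resolution = res))))
  }
  lo <- 1e-3; hi <- 1
  while (ncl(hi) < target && hi < 1e4) hi <- hi * 2
  for (it in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)
    k <- ncl(mid)
    if (abs(k - target) <= 1) return(mid)
    if (k < target) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

#' Per-type entropy of Leiden phenotype clusters
#'
#' Builds the kNN graph (k = 10) of the representation, clusters it with
#' the Leiden algorithm (resolution tuned to a target cluster count),
#' and for every t-type with at least `min_cells` cells measures the
#' Shannon entropy (bits) of the cluster-ID distribution after
#' subsampling the type to `min_cells` cells. The procedure is repeated
#' `n_rep` times with fresh clustering and subsampling seeds.
#'
#' @param X Cells x features representation.
#' @param types Character vector of t-type labels per cell.
#' @param target_clusters Target number of Leiden clusters (used to tune
#'   the resolution); alternatively pass `resolution` directly.
#' @param resolution Optional fixed resolution parameter.
#' @param n_rep Repetitions (default 100).
#' @param k Neighbour count of the graph (default 10).
#' @param min_cells Minimum (and subsample) type size (default 10).
#' @param seed Master seed.
#' @return Matrix of entropies, qualifying types x repetitions, plus
#'   attribute `resolution`.
#' @export
leiden_entropy <- function(X, types, target_clusters = NULL,
                           resolution = NULL, n_rep = 100, k = 10,
                           min_cells = 10, seed = 1L) {
  g <- knn_graph(X, k)
  if (is.null(resolution)) {
    if (is.null(target_clusters))
      stop("give target_clusters or resolution", call. = FALSE)
    resolution <- tune_leiden_resolution(g, target_clusters, seed)
  }
  sizes <- table(types)
  quals <- names(sizes)[sizes >= min_cells]
  if (!length(quals)) stop("no t-type with enough cells", call. = FALSE)
  out <- matrix(NA_real_, length(quals), n_rep,
                dimnames = list(quals, NULL))
  for (r in seq_len(n_rep)) {
    set.seed(derive_seed(seed, r))
    memb <- igraph::membership(igraph::cluster_leiden(
      g, objective_function = "modularity",
      resolution = resolution))
    for (ty in quals) {
      idx <- which(types == ty)
      sub <- sample(idx, min_cells)
      out[ty, r] <- entropy_bits(memb[sub])
    }
  }
  attr(out, "resolution") <- resolution
  out
}

#' Pairwise distances between t-types within families
#'
#' For every pair of qualifying t-types (>= `min_cells` cells) from the
#' same family: transcriptomic distance (1 - Pearson correlation between
#' the types' average log2 UMI expression over the variable-gene set),
#' electrophysiological distance (Euclidean distance between average
#' feature vectors), and soma-depth distance (absolute difference of
#' average normalized soma depths).
#'
#' @param centroids Types x genes average log-expression matrix.
#' @param features Cells x dims feature representation.
#' @param types Type label per cell.
#' @param family_of_type Named family label per type.
#' @param soma_depth Optional normalized soma depth per cell.
#' @param min_cells Minimum cells per qualifying type (default 5).
#' @return Data frame with columns `family`, `type_a`, `type_b`,
#'   `transcriptomic`, `ephys` and (when depths are given)
#'   `soma_depth`.
#' @export
pairwise_type_distances <- function(centroids, features, types,
                                    family_of_type, soma_depth = NULL,
                                    min_cells = 5) {
  sizes <- table(types)
  quals <- intersect(names(sizes)[sizes >= min_cells], rownames(centroids))
  rows <- list()
  for (fam in unique(family_of_type[quals])) {
    tys <- quals[family_of_type[quals] == fam]
    if (length(tys) < 2) next
    for (a in seq_along(tys)) for (b in seq_len(a - 1L)) {
      ta <- tys[a]; tb <- tys[b]
      td <- 1 - stats::cor(centroids[ta, ], centroids[tb, ])
      fa <- colMeans(features[types == ta, , drop = FALSE])
      fb <- colMeans(features[types == tb, , drop = FALSE])
      row <- data.frame(family = fam, type_a = ta, type_b = tb,
                        transcriptomic = td,
                        ephys = sqrt(sum((fa - fb)^2)))
      if (!is.null(soma_depth))
        row$soma_depth <- abs(mean(soma_depth[types == ta]) -
                              mean(soma_depth[types == tb]))
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (!length(rows))
    return(data.frame(family = character(0), type_a = character(0),
                      type_b = character(0), transcriptomic = numeric(0),
                      ephys = numeric(0)))
  do.call(rbind, rows)
}

#' Correlation between distance modalities across type pairs
#'
#' Pooled Pearson correlation between two distance columns of a
#' [pairwise_type_distances()] table, with per-family correlations as a
#' secondary output.
#'
#' @param table Distance-pair data frame.
#' @param x,y Column names to correlate (defaults "transcriptomic",
#'   "ephys").
#' @return List with `r` (pooled) and `per_family` (named vector).
#' @export
distance_correlation <- function(table, x = "transcriptomic",
                                 y = "ephys") {
  if (nrow(table) < 3) stop("need >= 3 pairs", call. = FALSE)
  if (stats::sd(table[[x]]) == 0 || stats::sd(table[[y]]) == 0)
    return(list(r = NA_real_, per_family = NULL))
  per <- vapply(split(table, table$family), function(d)
    if (nrow(d) >= 3 && stats::sd(d[[x]]) > 0 && stats::sd(d[[y]]) > 0)
      stats::cor(d[[x]], d[[y]]) else NA_real_, numeric(1))
  list(r = stats::cor(table[[x]], table[[y]]), per_family = per)
}
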