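#' Preprocess features and expression for reduced-rank regression
#'
#' Electrophysiological features are standardized. Exon and intron
#' counts are length-normalized and summed (see
#' [normalize_expression()]), converted to counts per million,
#' log2(x + 1)-transformed, restricted to the most variable genes
#' (selected on raw exonic counts), and standardized.
#'
#' @param features Cells x features numeric matrix (complete rows).
#' @param bundle An [expression_bundle()] for the same cells (columns in
#'   the same order as the feature rows).
#' @param n_genes Number of variable genes to retain (default 1000).
#' @param gene_set Optional explicit gene set overriding the variable
#'   gene selection (e.g. an ion-channel list).
#' @return List with `Y` (standardized features), `X` (standardized
#'   log-CPM of the selected genes, cells x genes). Zero-variance
#'   columns are dropped with a warning.
#' @export
rrr_preprocess <- function(features, bundle, n_genes = 1000,
                           gene_set = NULL) {
  Y <- as.matrix(features)
  if (ncol(bundle$exon_counts) != nrow(Y))
    stop("cell number mismatch between features and expression",
         call. = FALSE)
  norm <- 2^normalize_expression(bundle) - 1   # length-normalized counts
  cpm <- t(t(norm) / colSums(norm)) * 1e6
  logcpm <- log2(cpm + 1)
  if (is.null(gene_set)) {
    gene_set <- suppressWarnings(select_variable_genes(
      bundle$exon_counts, min(n_genes, nrow(logcpm))))
  }
  X <- t(logcpm[intersect(gene_set, rownames(logcpm)), , drop = FALSE])
  list(Y = standardize_columns(Y), X = standardize_columns(X))
}

standardize_columns <- function(m) {
  sds <- apply(m, 2, stats::sd)
  bad <- sds == 0 | !is.finite(sds)
  if (any(bad)) {
    warning(sprintf("dropping %d zero-variance column(s)", sum(bad)))
    m <- m[, !bad, drop = FALSE]
    sds <- sds[!bad]
  }
  scale(m, center = TRUE, scale = sds)
}

#' Convert counts to counts per million
#'
#' @param counts Genes x cells matrix.
#' @return CPM matrix of the same shape.
#' @export
cpm <- function(counts) t(t(counts) / colSums(counts)) * 1e6

#' Sparse reduced-rank regression
#'
#' Finds a rank-`rank` linear map from gene expression `X` (n x p) to
#' features `Y` (n x q): `Y ~ X W V'` with `V` orthonormal and
#' row-sparse `W` selected by an elastic-net penalty. Fitted by
#' alternating optimization: with `V` fixed, `W` solves a multi-response
#' elastic-net regression of `Y V` on `X` (group penalty over rows, so
#' whole genes are selected); with `W` fixed, `V` is the orthogonal
#' Procrustes solution from the SVD of `Y' X W`. Iterates until the
#' relative loss change falls below `tol` or `max_iter` is reached.
#'
#' @param X,Y Standardized predictor and response matrices.
#' @param rank Latent dimensionality (>= 1).
#' @param alpha Elastic-net mixing (1 = pure lasso, i.e. zero ridge).
#' @param lambda Penalty strength (glmnet per-observation convention).
#' @param max_iter,tol Convergence controls.
#' @param seed Seed for the initialization jitter used on degenerate
#'   spectra.
#' @return Object of class `rrr_model`: `W` (p x rank), `V` (q x rank,
#'   orthonormal), `selected_genes` (nonzero rows of `W`), `rank`,
#'   `alpha`, `lambda`, `loss` trace, `converged`.
#' @export
fit_rrr <- function(X, Y, rank = 5, alpha = 1, lambda = 0.5,
                    max_iter = 100, tol = 1e-6, seed = 1L) {
  stopifnot(nrow(X) == nrow(Y), rank >= 1)
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  rank <- min(rank, q)
  # initialization: top right singular vectors of Y'X_ridge_fit
  ridge <- crossprod(X, Y)          # proportional to the ridge fit at large penalty
  sv <- svd(ridge, nu = 0, nv = rank)
  if (length(sv$d) >= rank && rank > 1 &&
      abs(sv$d[rank] - sv$d[rank - 1]) < 1e-12 * max(sv$d)) {
    set.seed(seed)
    sv$v <- qr.Q(qr(sv$v + matrix(stats::rnorm(q * rank, 0, 1e-8), q)))
  }
  V <- sv$v
  loss <- numeric(0)
  W <- matrix(0, p, ncol(V))
  penalty <- function(W) {
    rn <- sqrt(rowSums(W^2))
    lambda * (alpha * sum(rn) + (1 - alpha) / 2 * sum(rn^2))
  }
  for (it in seq_len(max_iter)) {
    Z <- Y %*% V
    if (lambda == 0) {
      # unpenalized subproblem: exact least squares
      W <- qr.coef(qr(X), Z)
      W[!is.finite(W)] <- 0
    } else {
      fit <- glmnet::glmnet(X, Z, family = "mgaussian", alpha = alpha,
                            lambda = lambda, intercept = FALSE,
                            standardize = FALSE,
                            standardize.response = FALSE,
                            thresh = 1e-12)
      co <- stats::coef(fit)
      W <- do.call(cbind, lapply(co, function(b) as.numeric(b)[-1]))
    }
    XW <- X %*% W
    sv2 <- svd(crossprod(Y, XW), nu = rank, nv = rank)
    V <- sv2$u %*% t(sv2$v)
    l <- sum((Y - XW %*% t(V))^2) / (2 * n) + penalty(W)
    loss <- c(loss, l)
    if (it > 1 && abs(loss[it - 1] - l) <=
        tol * max(abs(loss[it - 1]), 1e-12)) break
  }
  rownames(W) <- colnames(X)
  rownames(V) <- colnames(Y)
  nz <- rowSums(W != 0) > 0
  structure(list(W = W, V = V, rank = rank, alpha = alpha,
                 lambda = lambda,
                 selected_genes = rownames(W)[nz],
                 n_selected = sum(nz), loss = loss,
                 converged = length(loss) < max_iter),
            class = "rrr_model")
}

#' @export
print.rrr_model <- function(x, ...) {
  cat(sprintf("<rrr_model> rank %d, alpha %g, lambda %g, %d genes selected\n",
              x$rank, x$alpha, x$lambda, x$n_selected))
  invisible(x)
}

#' Closed-form reduced-rank regression (no penalty)
#'
#' The classical solution: the OLS fit projected onto the top-`rank`
#' principal axes of the fitted values. Used as an independent reference
#' for the unpenalized limit of [fit_rrr()].
#'
#' @inheritParams fit_rrr
#' @return List with coefficient matrix `B` (p x q), `W`, `V`.
#' @export
rrr_closed_form <- function(X, Y, rank) {
  B_ols <- qr.coef(qr(X), Y)
  fitted <- X %*% B_ols
  sv <- svd(fitted, nu = 0, nv = rank)
  V <- sv$v[, seq_len(rank), drop = FALSE]
  list(B = B_ols %*% V %*% t(V), W = B_ols %*% V, V = V)
}

#' Predict features from an RRR model
#'
#' @param object An `rrr_model`.
#' @param newdata Cells x genes matrix on the model's predictor scale.
#' @param ... Unused.
#' @return Predicted feature matrix.
#' @export
predict.rrr_model <- function(object, newdata, ...) {
  newdata %*% object$W %*% t(object$V)
}

#' Tune the lasso penalty to a target gene count
#'
#' Binary search over `lambda` for the penalty strength at which
#' [fit_rrr()] selects (approximately) `target_genes` genes, mirroring
#' the convention of reporting a model "tuned to yield" a fixed
#' selection size.
#'
#' @inheritParams fit_rrr
#' @param target_genes Desired number of selected genes.
#' @param lambda_range Search interval.
#' @param max_iter Bisection steps.
#' @return The tuned lambda (attribute `n_selected` reports the
#'   achieved count).
#' @export
rrr_tune_lambda <- function(X, Y, rank = 5, alpha = 1, target_genes = 25,
                            lambda_range = c(1e-3, 10), max_iter = 25,
                            seed = 1L) {
  n_sel <- function(l)
    fit_rrr(X, Y, rank = rank, alpha = alpha, lambda = l,
            seed = seed)$n_selected
  lo <- lambda_range[1]; hi <- lambda_range[2]
  for (it in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)
    k <- n_sel(mid)
    if (k == target_genes) { lo <- hi <- mid; break }
    if (k > target_genes) lo <- mid else hi <- mid
  }
  out <- sqrt(lo * hi)
  attr(out, "n_selected") <- n_sel(out)
  out
}

#' Cross-validate sparse RRR over a parameter grid
#'
#' For every (rank, alpha, lambda) combination, 10-fold cross-validation
#' of the test R-squared `1 - ||Y - X W V'||^2 / ||Y||^2`, the mean
#' number of selected genes, and the mean per-component test correlation
#' `cor(X W_k, Y V_k)`.
#'
#' @inheritParams fit_rrr
#' @param ranks,alphas,lambdas Grid values.
#' @param folds Number of CV folds (default 10).
#' @param seed Seed controlling the fold split.
#' @return Data frame with one row per grid point: `rank`, `alpha`,
#'   `lambda`, `r2`, `n_genes`, `cor_1` ... `cor_rmax`.
#' @export
rrr_cv <- function(X, Y, ranks = 5, alphas = 1, lambdas = 0.5,
                   folds = 10, seed = 1L) {
  n <- nrow(X)
  if (n < 2 * folds) stop("too few cells for the fold count", call. = FALSE)
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), n))
  grid <- expand.grid(rank = ranks, alpha = alphas, lambda = lambdas,
                      KEEP.OUT.ATTRS = FALSE)
  rmax <- max(ranks)
  res <- cbind(grid, r2 = NA_real_, n_genes = NA_real_,
               matrix(NA_real_, nrow(grid), rmax,
                      dimnames = list(NULL, paste0("cor_", seq_len(rmax)))))
  for (gi in seq_len(nrow(grid))) {
    r2s <- ng <- numeric(folds)
    cors <- matrix(NA_real_, folds, grid$rank[gi])
    for (f in seq_len(folds)) {
      tr <- fold_id != f; te <- !tr
      fit <- fit_rrr(X[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                     rank = grid$rank[gi], alpha = grid$alpha[gi],
                     lambda = grid$lambda[gi], seed = seed)
      pred <- predict(fit, X[te, , drop = FALSE])
      r2s[f] <- 1 - sum((Y[te, ] - pred)^2) / sum(Y[te, ]^2)
      ng[f] <- fit$n_selected
      XWt <- X[te, , drop = FALSE] %*% fit$W
      YVt <- Y[te, , drop = FALSE] %*% fit$V
      for (k in seq_len(ncol(XWt)))
        if (stats::sd(XWt[, k]) > 0 && stats::sd(YVt[, k]) > 0)
          cors[f, k] <- stats::cor(XWt[, k], YVt[, k])
    }
    res$r2[gi] <- mean(r2s)
    res$n_genes[gi] <- mean(ng)
    res[gi, paste0("cor_", seq_len(grid$rank[gi]))] <-
      colMeans(cors, na.rm = TRUE)
  }
  res
}

#' Biplot correlations with the latent dimensions
#'
#' Correlations of every gene (column of `X`) and every feature (column
#' of `Y`) with each latent score `X W_k`, plus the display mask used in
#' bibiplots: a variable is shown when the length of its correlation
#' vector over the first two latent dimensions exceeds
#' `display_threshold` (0.4 of the unit-circle radius).
#'
#' @param model An `rrr_model`.
#' @param X,Y The matrices the model was fit on.
#' @param display_threshold Minimum 2-D correlation-vector length.
#' @return List with `genes` and `features` (correlation matrices,
#'   variables x latent dims) and logical masks `genes_shown`,
#'   `features_shown`. Constant columns yield `NA` and are masked out.
#' @export
rrr_biplot_correlations <- function(model, X, Y,
                                    display_threshold = 0.4) {
  scores <- X %*% model$W
  safe_cor <- function(m) {
    out <- suppressWarnings(stats::cor(m, scores))
    out[!is.finite(out)] <- NA
    out
  }
  cg <- safe_cor(X)
  cf <- safe_cor(Y)
  len2 <- function(cm) {
    k <- min(2L, ncol(cm))
    sqrt(rowSums(cm[, seq_len(k), drop = FALSE]^2))
  }
  list(genes = cg, features = cf,
       genes_shown = !is.na(len2(cg)) & len2(cg) > display_threshold,
       features_shown = !is.na(len2(cf)) & len2(cf) > display_threshold)
}
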