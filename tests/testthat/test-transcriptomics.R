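test_that("length normalization follows the exon + intron formula", {
  exon <- matrix(10, 1, 1, dimnames = list("g1", "c1"))
  intron <- matrix(5, 1, 1, dimnames = list("g1", "c1"))
  b <- expression_bundle(exon, intron, exonic_length_kb = c(g1 = 2),
                         intronic_length_kb = c(g1 = 5))
  # 10/2 + 5/(5 + 1e-6) + 1 = 7 -> log2(7)
  expect_equal(normalize_expression(b)[1, 1], log2(7), tolerance = 1e-6)
  # zero counts -> 0
  b0 <- expression_bundle(exon * 0, intron * 0,
                          exonic_length_kb = c(g1 = 2),
                          intronic_length_kb = c(g1 = 5))
  expect_identical(normalize_expression(b0)[1, 1], 0)
  # intronless gene with zero intron count stays finite
  bg <- expression_bundle(exon, intron * 0,
                          exonic_length_kb = c(g1 = 2),
                          intronic_length_kb = c(g1 = 0))
  expect_true(is.finite(normalize_expression(bg)[1, 1]))
  expect_equal(normalize_expression(bg)[1, 1], log2(6))
  # UMI platform: no length normalization
  expect_equal(normalize_expression(matrix(3, 1, 1)), matrix(2, 1, 1))
  expect_error(normalize_expression(matrix(-1, 1, 1)), "non-negative")
})

make_count_cloud <- function(n_genes = 400, n_cells = 120, seed = 1) {
  set.seed(seed)
  means <- exp(rnorm(n_genes, 3.5, 1.6))
  counts <- matrix(rnbinom(n_genes * n_cells,
                           mu = rep(means, n_cells), size = 1.2),
                   nrow = n_genes)
  rownames(counts) <- sprintf("g%04d", seq_len(n_genes))
  counts
}

test_that("the minimum-cells eligibility rule excludes sparse genes", {
  counts <- make_count_cloud()
  # a gene with counts >= c_min in exactly 9 cells is excluded
  counts["g0001", ] <- 0
  counts["g0001", 1:9] <- 50
  sel <- suppressWarnings(
    select_variable_genes(counts, 100, c_min = 32, min_cells = 10))
  expect_false("g0001" %in% sel)
  # with 10 qualifying cells the same gene is eligible
  counts["g0001", 1:10] <- 50
  mu <- attr(suppressWarnings(
    select_variable_genes(counts, 100, c_min = 32)), "mu")
  expect_true("g0001" %in% names(mu))
})

test_that("binary search returns exactly the requested gene count", {
  counts <- make_count_cloud(n_genes = 600, n_cells = 150, seed = 4)
  for (target in c(50, 137, 300)) {
    sel <- select_variable_genes(counts, target, c_min = 32)
    expect_length(sel, target)
    # independent brute-force sweep over the offset agrees
    oracle <- select_genes_oracle(counts, target, c_min = 32)
    expect_setequal(sel, oracle)
  }
})

test_that("requesting all eligible genes returns them with a warning", {
  counts <- make_count_cloud(n_genes = 120, n_cells = 80, seed = 2)
  expect_warning(sel <- select_variable_genes(counts, 1e5, c_min = 32),
                 "returning all")
  expect_gt(length(sel), 0)
})

test_that("centroids average log expression per type", {
  lg <- matrix(c(1, 2, 3, 5, 2, 8), nrow = 3,
               dimnames = list(paste0("g", 1:3), c("c1", "c2")))
  # one cell per type: centroid equals the cell
  cen <- build_centroids(lg, c("A", "B"))
  expect_equal(cen["A", ], c(g1 = 1, g2 = 2, g3 = 3))
  # two identical cells give the same centroid
  cen2 <- build_centroids(lg[, c(1, 1)], c("A", "A"))
  expect_equal(cen2["A", ], c(g1 = 1, g2 = 2, g3 = 3))
  # missing genes are recorded
  cen3 <- build_centroids(lg, c("A", "B"), gene_set = c("g1", "g9"))
  expect_equal(attr(cen3, "missing_genes"), "g9")
  expect_error(build_centroids(lg, c("A", "B"), gene_set = "g9"),
               "common")
})

test_that("Pearson mapping is exact and affine invariant", {
  set.seed(3)
  cen <- matrix(rnorm(5 * 40), 5, 40,
                dimnames = list(paste0("t", 1:5), paste0("g", 1:40)))
  cell <- cen["t3", ]
  m <- map_cells(cell, cen)
  expect_equal(m$best_type, "t3")
  expect_equal(unname(m$best_cor), 1, tolerance = 1e-12)
  # affine transform of the same centroid maps identically
  m2 <- map_cells(2.5 * cell + 7, cen)
  expect_equal(m2$best_type, "t3")
  # a constant cell is unmappable
  m3 <- map_cells(setNames(rep(1, 40), paste0("g", 1:40)), cen)
  expect_true(is.na(m3$best_type))
})

test_that("round-1 QC applies the three exclusion rules", {
  types <- c(A = "MGE", B = "CGE", C = "excitatory")
  neural <- c(A = TRUE, B = TRUE, C = TRUE, NN = FALSE)
  # low correlation
  r <- c(A = 0.35, B = 0.1, C = 0.1, NN = 0.2)
  q <- round1_qc(r, types, neural)
  expect_false(q$pass); expect_equal(q$reason, "low_correlation")
  # non-neural winner
  r <- c(A = 0.5, B = 0.3, C = 0.2, NN = 0.8)
  q <- round1_qc(r, types, neural)
  expect_false(q$pass); expect_equal(q$reason, "non_neural")
  # ambiguous group margin: 0.80 vs 0.79 < 0.02
  r <- c(A = 0.80, B = 0.79, C = 0.2, NN = 0.1)
  q <- round1_qc(r, types, neural)
  expect_false(q$pass); expect_equal(q$reason, "ambiguous_group")
  # clean pass
  r <- c(A = 0.80, B = 0.75, C = 0.2, NN = 0.1)
  q <- round1_qc(r, types, neural)
  expect_true(q$pass); expect_equal(q$group, "MGE")
})

test_that("bootstrap confidences sum to one and are reproducible", {
  set.seed(5)
  cen <- matrix(rnorm(3 * 60), 3, 60,
                dimnames = list(paste0("t", 1:3), paste0("g", 1:60)))
  cell <- cen["t2", ] + rnorm(60, 0, 0.1)
  c1 <- bootstrap_confidence(cell, cen, n_boot = 100, seed = 7)
  c2 <- bootstrap_confidence(cell, cen, n_boot = 100, seed = 7)
  expect_identical(c1, c2)
  expect_equal(sum(c1), 1, tolerance = 1e-9)
  # well-separated centroid -> confidence concentrates on the true type
  expect_gt(c1["t2"], 0.95)
  # near-identical centroids split the confidence symmetrically
  base <- cen["t2", ]
  cen2 <- rbind(t1 = base + rnorm(60, 0, 0.02),
                t2 = base + rnorm(60, 0, 0.02))
  cs <- bootstrap_confidence(cell, cen2, n_boot = 100, seed = 3)
  expect_true(all(cs > 0.1))
})

test_that("consensus averages atlas confidences and picks the argmax", {
  confs <- list(c(t1 = 0.6, t2 = 0.4), c(t1 = 0.2, t2 = 0.8))
  cons <- consensus_assignment(confs)
  expect_equal(cons$consensus, c(t1 = 0.4, t2 = 0.6))
  expect_equal(cons$final_type, "t2")
  # a single atlas passes through unchanged
  one <- consensus_assignment(confs[1])
  expect_equal(one$consensus, confs[[1]])
  expect_equal(one$final_type, "t1")
})

test_that("the two-round workflow maps well-separated cells correctly", {
  spec <- atlas_spec(n_types = 9, n_genes = 500, n_cells_per_type = 25,
                     type_separation = 3, n_nonneural = 1, seed = 13)
  sim <- generate_expression_bundle(spec, n_query_cells = 30,
                                    query_noise = 0.2, n_atlases = 2)
  res <- assign_ttypes(sim$query, sim$atlases[[1]], sim$atlases,
                       n_round1_genes = 400, n_round2_genes = 200,
                       n_boot = 50, seed = 5)
  a <- res$assignments
  expect_gte(mean(a$final_type == sim$true_type, na.rm = TRUE), 0.95)
  sums <- rowSums(res$consensus[a$qc_pass, , drop = FALSE], na.rm = TRUE)
  expect_true(all(abs(sums - 1) < 1e-9))
  # the exclusion list removes cells up front
  res2 <- assign_ttypes(sim$query, sim$atlases[[1]], sim$atlases,
                        n_round1_genes = 400, n_round2_genes = 200,
                        n_boot = 10, seed = 5,
                        exclude = a$cell[1:2])
  expect_equal(nrow(res2$assignments), nrow(a) - 2)
})

test_that("counts round-trip through MatrixMarket + TSV", {
  counts <- make_count_cloud(n_genes = 30, n_cells = 10)
  colnames(counts) <- paste0("c", 1:10)
  d <- file.path(tempdir(), "mtx_test")
  write_counts_mtx(counts, d)
  back <- read_counts_mtx(d)
  expect_equal(back, counts, ignore_attr = TRUE)
  expect_identical(dimnames(back), dimnames(counts))
})
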