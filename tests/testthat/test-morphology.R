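test_that("normalization places the soma at its planted depth", {
  m <- line_morphology(soma_depth = 0.5, thickness = 1000)
  norm <- load_and_normalize(m$nodes, 1000, 0.5)
  expect_equal(norm$nodes$z[norm$nodes$id == 1], 500)
  # reloading a written SWC round-trips the coordinates
  f <- tempfile(fileext = ".swc")
  write_swc(norm$nodes, f)
  back <- read_swc(f)
  expect_equal(back$z, norm$nodes$z, tolerance = 1e-12)
  expect_equal(back$parent, norm$nodes$parent)
})

test_that("malformed trees are rejected and deep nodes warned about", {
  nodes <- line_morphology(20)$nodes
  bad <- nodes; bad$parent[2] <- 3L; bad$parent[3] <- 2L  # cycle
  expect_error(load_and_normalize(bad, 1000, 0.5), "cyclic|disconnected")
  bad2 <- nodes; bad2$parent[5] <- 99L
  expect_error(load_and_normalize(bad2, 1000, 0.5), "disconnected")
  bad3 <- nodes; bad3$parent[c(1, 5)] <- -1L
  expect_error(load_and_normalize(bad3, 1000, 0.5), "one root")
  # node below white matter: kept with a warning
  deep <- line_morphology(300, soma_depth = 0.9, thickness = 300)$nodes
  expect_warning(m <- load_and_normalize(deep, 300, 0.9), "white-matter")
  expect_equal(nrow(m$nodes), nrow(deep))
})

test_that("neurite smoothing touches only y and shrinks planted noise", {
  set.seed(8)
  m <- line_morphology(300)
  straight <- smooth_neurites(m)
  expect_identical(straight$nodes$x, m$nodes$x)
  expect_identical(straight$nodes$z, m$nodes$z)
  # a straight line is reproduced by the cubic filter
  expect_lt(max(abs(straight$nodes$y - m$nodes$y)), 1e-6)
  # planted y-noise on the straight branch is damped by at least half
  noisy <- m
  noisy$nodes$y <- noisy$nodes$y + rnorm(nrow(noisy$nodes), 0, 0.5)
  noisy$nodes$y[1] <- 0
  sm <- smooth_neurites(noisy)
  expect_lt(sd(sm$nodes$y[-1]), 0.5 * sd(noisy$nodes$y[-1]))
  expect_identical(sm$nodes$z, noisy$nodes$z)
})

test_that("z-profiles are unit-mass 20-bin histograms", {
  # all mass at depth 0.5 -> the bin containing 0.5 (bin 11)
  m <- structure(list(
    nodes = data.frame(id = 1:3, type = c(1, 3, 3),
                       x = c(0, 1, 2), y = 0, z = 500,
                       radius = c(6, 0.5, 0.5), parent = c(-1, 1, 2)),
    cortical_thickness_um = 1000, soma_depth_normalized = 0.5,
    soma_id = 1L), class = "morphology")
  zp <- z_profile(m, "dendrite")
  expect_length(zp, 20)
  expect_equal(sum(zp), 1)
  expect_equal(zp[11], 1)
  # empty compartment: zero vector, flagged
  za <- z_profile(m, "axon")
  expect_true(attr(za, "empty"))
  expect_equal(sum(za), 0)
})

test_that("vectorized binning equals the per-point oracle", {
  for (seed in 1:5) {
    m <- generate_morphology(morph_spec(
      soma_depth_normalized = runif(1, 0.2, 0.8), seed = seed))
    for (comp in c("axon", "dendrite")) {
      expect_equal(as.numeric(z_profile(m, comp)),
                   zprofile_oracle(m, comp), tolerance = 1e-12)
    }
  }
})

test_that("z-profile is invariant to x/y rigid motions", {
  m <- generate_morphology(morph_spec(seed = 6))
  zp <- z_profile(m, "axon")
  th <- 0.7
  rot <- m
  xy <- as.matrix(m$nodes[, c("x", "y")]) %*%
    matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot$nodes$x <- xy[, 1] + 50
  rot$nodes$y <- xy[, 2] - 20
  expect_equal(z_profile(rot, "axon"), zp)
})

test_that("morphometrics of simple trees are exact", {
  # unbranched 100-um neurite
  m <- line_morphology(100)
  s <- morphometrics(m, "inhibitory")
  expect_equal(unname(s["dendrite_total_length"]), 100)
  expect_equal(unname(s["dendrite_n_tips"]), 1)
  expect_equal(unname(s["dendrite_n_branch_points"]), 0)
  expect_equal(unname(s["dendrite_max_branch_order"]), 0)
  expect_equal(unname(s["soma_depth"]), 0.5)
  # axon features are missing without an axon
  expect_true(is.na(s["axon_total_length"]))

  # Y-shaped tree: stem of 10, two branches of 10
  yn <- data.frame(
    id = 1:7, type = c(1, rep(3, 6)),
    x = c(0, 0, 0, -5, -10, 5, 10),
    y = 0,
    z = 500 + c(0, 5, 10, 15, 20, 15, 25),
    radius = c(6, rep(0.5, 6)), parent = c(-1, 1, 2, 3, 4, 3, 6))
  ym <- structure(list(nodes = yn, cortical_thickness_um = 1000,
                       soma_depth_normalized = 0.5, soma_id = 1L),
                  class = "morphology")
  sy <- morphometrics(ym, "inhibitory")
  expect_equal(unname(sy["dendrite_n_branch_points"]), 1)
  expect_equal(unname(sy["dendrite_n_tips"]), 2)
  expect_equal(unname(sy["dendrite_max_branch_order"]), 1)
  # width 20 (x from -10 to 10), height 20 -> log ratio 0
  expect_equal(unname(sy["dendrite_width"]), 20)
  expect_equal(unname(sy["dendrite_width_height_log_ratio"]), 0)
})

test_that("the width/height log-ratio follows extents", {
  # 200 um wide x 100 um high arbour -> log(2)
  nodes <- data.frame(
    id = 1:5, type = c(1, 2, 2, 2, 2),
    x = c(0, -100, 100, 0, 0), y = 0,
    z = c(500, 500, 500, 450, 550),
    radius = c(6, rep(0.5, 4)), parent = c(-1, 1, 1, 1, 1))
  m <- structure(list(nodes = nodes, cortical_thickness_um = 1000,
                      soma_depth_normalized = 0.5, soma_id = 1L),
                 class = "morphology")
  s <- morphometrics(m, "inhibitory")
  expect_equal(unname(s["axon_width_height_log_ratio"]), log(2))
})

test_that("excitatory cells report apical but not axonal features", {
  m <- generate_morphology(morph_spec(seed = 9))
  s <- morphometrics(m, "excitatory")
  expect_true(any(startsWith(names(s), "apical_")))
  expect_false(any(startsWith(names(s), "axon_")))
  # no feature name refers to the slice-depth direction
  expect_false(any(grepl("^y_|_y$|depth_y", names(s))))
  # morphometrics are invariant to node reindexing
  perm <- m
  set.seed(1)
  new_ids <- c(1L, 1L + sample(nrow(m$nodes) - 1L))
  lut <- c(-1L, new_ids)[match(c(-1L, m$nodes$id), c(-1L, m$nodes$id))]
  perm$nodes$id <- new_ids[match(m$nodes$id, m$nodes$id)]
  perm$nodes$parent <- ifelse(m$nodes$parent == -1L, -1L,
                              new_ids[match(m$nodes$parent, m$nodes$id)])
  perm$nodes <- perm$nodes[order(perm$nodes$id), ]
  perm$soma_id <- new_ids[1]
  expect_equal(morphometrics(perm, "excitatory"), s, tolerance = 1e-9)
})

test_that("total length is additive over branches", {
  m1 <- line_morphology(60)
  m2 <- line_morphology(40)
  # graft the second neurite onto the first soma
  n2 <- m2$nodes[-1, ]
  n2$id <- n2$id + 1000L
  n2$parent <- ifelse(n2$parent == 1L, 1L, n2$parent + 1000L)
  both <- m1
  both$nodes <- rbind(m1$nodes, n2)
  expect_equal(
    unname(morphometrics(both, "inhibitory")["dendrite_total_length"]),
    unname(morphometrics(m1, "inhibitory")["dendrite_total_length"]) +
      unname(morphometrics(m2, "inhibitory")["dendrite_total_length"]),
    tolerance = 1e-9)
})

test_that("the CV filter drops only low-variation positive features", {
  set.seed(2)
  tbl <- cbind(constant = rep(3, 50),
               negative = rnorm(50),          # never dropped
               lowcv = 100 + runif(50, -1, 1), # CV ~ 0.006
               highcv = exp(rnorm(50)))        # CV > 0.25
  out <- filter_features_by_cv(tbl)
  expect_setequal(attr(out, "dropped"), c("constant", "lowcv"))
  expect_true(all(c("negative", "highcv") %in% colnames(out)))
  # CV of exactly 0.3 is retained
  x <- c(7, 13)  # mean 10, sd ~4.24 -> CV 0.42
  expect_false("x" %in% attr(filter_features_by_cv(cbind(x = x)),
                             "dropped"))
})

test_that("layer assignment uses the boundaries with ties going deeper", {
  expect_equal(assign_layer(0.05), "L1")
  expect_equal(assign_layer(0.07), "L2/3")
  expect_equal(assign_layer(0.30), "L5")
  expect_equal(assign_layer(0.73), "L6")
  expect_equal(assign_layer(c(0, 1)), c("L1", "L6"))
  expect_error(assign_layer(1.2), "0, 1")
  expect_error(assign_layer(0.5, boundaries = c(0.3, 0.2, 0.7)),
               "increasing")
})
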