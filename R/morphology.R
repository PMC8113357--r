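#' Read and write SWC reconstructions
#'
#' Standard 7-column ASCII SWC (`id type x y z radius parent`), `#`
#' comments. Coordinates are micrometres. Compartment types follow the
#' SWC convention: 1 soma, 2 axon, 3 (basal) dendrite, 4 apical
#' dendrite.
#'
#' @param path File path.
#' @return `read_swc` returns a data frame of nodes; `write_swc` writes
#'   one and returns `path` invisibly.
#' @export
read_swc <- function(path) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("id", "type", "x", "y", "z",
                                         "radius", "parent"))
  tab$id <- as.integer(tab$id); tab$parent <- as.integer(tab$parent)
  tab
}

#' @rdname read_swc
#' @param nodes Data frame with columns id, type, x, y, z, radius,
#'   parent.
#' @export
write_swc <- function(nodes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# SWC reconstruction", con)
  utils::write.table(format(nodes, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Load a reconstruction and normalize its reference frame
#'
#' Validates tree structure (exactly one root, no cycles, connected),
#' soma-centres the x (slice width) and y (slice depth) coordinates, and
#' aligns z (cortical depth) so that z = 0 is the pia: the soma is
#' placed at `soma_depth_normalized * thickness`. Nodes deeper than the
#' white-matter border (z > thickness) are kept with a warning.
#'
#' @param swc Path to an SWC file or a node data frame from
#'   [read_swc()].
#' @param cortical_thickness_um Pia-to-white-matter thickness (> 0).
#' @param soma_depth_normalized Soma depth as a fraction of thickness
#'   (in [0, 1]).
#' @return Object of class `morphology`: list with `nodes`,
#'   `cortical_thickness_um`, `soma_depth_normalized`, `soma_id`.
#' @export
load_and_normalize <- function(swc, cortical_thickness_um,
                               soma_depth_normalized) {
  nodes <- if (is.character(swc)) read_swc(swc) else swc
  stopifnot_scalar(cortical_thickness_um, "cortical_thickness_um",
                   positive = TRUE)
  if (soma_depth_normalized < 0 || soma_depth_normalized > 1)
    stop("soma_depth_normalized must be in [0, 1]", call. = FALSE)
  roots <- nodes$id[nodes$parent == -1]
  if (length(roots) != 1)
    stop(sprintf("expected exactly one root, found %d", length(roots)),
         call. = FALSE)
  idx <- match(nodes$parent, nodes$id)
  if (any(is.na(idx) & nodes$parent != -1))
    stop("disconnected SWC: parent ids missing", call. = FALSE)
  # cycle / connectivity check by walking to the root from every node
  depth <- rep(NA_integer_, nrow(nodes))
  depth[nodes$parent == -1] <- 0L
  for (pass in seq_len(nrow(nodes))) {
    todo <- is.na(depth) & !is.na(depth[idx])
    if (!any(todo)) break
    depth[todo] <- depth[idx[todo]] + 1L
  }
  if (any(is.na(depth)))
    stop("cyclic or disconnected SWC", call. = FALSE)
  soma_id <- roots
  s <- nodes[nodes$id == soma_id, ]
  nodes$x <- nodes$x - s$x
  nodes$y <- nodes$y - s$y
  nodes$z <- nodes$z - s$z + soma_depth_normalized * cortical_thickness_um
  if (any(nodes$z > cortical_thickness_um))
    warning("nodes below the white-matter border (z > thickness); kept")
  if (any(nodes$z < -1))
    warning("nodes above the pia (z < 0); kept")
  structure(list(nodes = nodes,
                 cortical_thickness_um = cortical_thickness_um,
                 soma_depth_normalized = soma_depth_normalized,
                 soma_id = soma_id),
            class = "morphology")
}

#' @export
print.morphology <- function(x, ...) {
  cat(sprintf("<morphology> %d nodes, thickness %g um, soma depth %.3f\n",
              nrow(x$nodes), x$cortical_thickness_um,
              x$soma_depth_normalized))
  invisible(x)
}

children_list <- function(nodes) {
  split(nodes$id[nodes$parent != -1], factor(nodes$parent[nodes$parent != -1],
                                             levels = nodes$id))
}

# unbranched paths: maximal node chains between soma/branch points/tips
branch_paths <- function(morph, compartment_types = NULL) {
  nodes <- morph$nodes
  if (!is.null(compartment_types)) {
    keep <- nodes$type %in% c(1, compartment_types)
    nodes <- nodes[keep, ]
    nodes$parent[!nodes$parent %in% nodes$id] <- -1L
  }
  ch <- children_list(nodes)
  n_children <- lengths(ch)[as.character(nodes$id)]
  is_junction <- nodes$parent == -1 | n_children >= 2
  paths <- list()
  for (start in nodes$id[is_junction]) {
    for (c1 in ch[[as.character(start)]] %||% integer(0)) {
      path <- c(start, c1)
      cur <- c1
      repeat {
        nxt <- ch[[as.character(cur)]] %||% integer(0)
        if (length(nxt) != 1) break
        cur <- nxt
        path <- c(path, cur)
      }
      paths[[length(paths) + 1L]] <- path
    }
  }
  list(paths = paths, nodes = nodes)
}

# resample a polyline (matrix of xyz rows) to max 1 um spacing
resample_polyline <- function(xyz, spacing = 1) {
  if (nrow(xyz) < 2) return(xyz)
  seglen <- sqrt(rowSums(diff(xyz)^2))
  s <- c(0, cumsum(seglen))
  total <- s[length(s)]
  if (total == 0) return(xyz[1, , drop = FALSE])
  n <- max(2L, ceiling(total / spacing) + 1L)
  si <- seq(0, total, length.out = n)
  apply(xyz, 2, function(col) stats::approx(s, col, xout = si)$y)
}

#' Smooth neurites in the slice-depth dimension
#'
#' Applies a Savitzky-Golay filter (order 3, window 21) to the y
#' coordinate of every unbranched neurite path, after resampling the
#' path to at most 1 um spacing; the smoothed y is mapped back to the
#' original nodes by arc-length interpolation. x and z are untouched and
#' the topology is unchanged. Paths shorter than the filter window are
#' mirror-padded.
#'
#' @param morph A `morphology`.
#' @param order,window Savitzky-Golay polynomial order and window
#'   length.
#' @return The morphology with smoothed y coordinates.
#' @export
smooth_neurites <- function(morph, order = 3, window = 21) {
  nodes <- morph$nodes
  bp <- branch_paths(morph)
  for (path in bp$paths) {
    ii <- match(path, nodes$id)
    if (length(ii) < 3) next
    xyz <- as.matrix(nodes[ii, c("x", "y", "z")])
    rs <- resample_polyline(xyz)
    y <- rs[, 2]
    if (length(y) < window) {
      half <- window
      ypad <- c(rev(y[seq_len(min(half, length(y) - 1)) + 1]), y,
                rev(y[length(y) - seq_len(min(half, length(y) - 1))]))
      while (length(ypad) < window) ypad <- c(ypad[1], ypad, ypad[length(ypad)])
      off <- (length(ypad) - length(y)) %/% 2
      ysm <- signal::sgolayfilt(ypad, p = order, n = window)
      ysm <- ysm[off + seq_along(y)]
    } else {
      ysm <- signal::sgolayfilt(y, p = order, n = window)
    }
    # arc-length positions of original nodes along the resampled path
    s_orig <- c(0, cumsum(sqrt(rowSums(diff(xyz)^2))))
    s_rs <- c(0, cumsum(sqrt(rowSums(diff(rs)^2))))
    nodes$y[ii] <- stats::approx(s_rs, ysm, xout = pmin(s_orig, max(s_rs)))$y
  }
  morph$nodes <- nodes
  morph
}

swc_compartments <- list(axon = 2, dendrite = c(3, 4))

# resampled point cloud of one compartment (edges at <= 1 um spacing)
compartment_points <- function(morph, compartment, spacing = 1) {
  types <- swc_compartments[[compartment]]
  nodes <- morph$nodes
  idx <- match(nodes$parent, nodes$id)
  pts <- list()
  for (i in which(nodes$type %in% types)) {
    pi <- idx[i]
    if (is.na(pi)) next
    a <- as.numeric(nodes[pi, c("x", "y", "z")])
    b <- as.numeric(nodes[i, c("x", "y", "z")])
    L <- sqrt(sum((b - a)^2))
    n <- max(1L, ceiling(L / spacing))
    frac <- seq_len(n) / n
    pts[[length(pts) + 1L]] <- cbind(a[1] + frac * (b[1] - a[1]),
                                     a[2] + frac * (b[2] - a[2]),
                                     a[3] + frac * (b[3] - a[3]))
  }
  if (!length(pts)) return(matrix(numeric(0), ncol = 3))
  do.call(rbind, pts)
}

#' Normalized depth profile (z-profile)
#'
#' Projects the compartment's resampled point cloud onto the cortical
#' depth axis, normalizes by cortical thickness, and histograms the
#' depths into 20 equal bins spanning [0, 1] (half-open bins, last bin
#' closed; depths are clamped into [0, 1]). The profile is normalized to
#' sum to 1 for non-empty compartments.
#'
#' @param morph A `morphology`.
#' @param compartment `"axon"` or `"dendrite"`.
#' @param nbins Number of depth bins (default 20).
#' @return Numeric vector of length `nbins` summing to 1 (all zeros,
#'   flagged via attribute `empty`, for a missing compartment).
#' @export
z_profile <- function(morph, compartment = c("axon", "dendrite"),
                      nbins = 20) {
  compartment <- match.arg(compartment)
  pts <- compartment_points(morph, compartment)
  out <- numeric(nbins)
  if (!nrow(pts)) {
    attr(out, "empty") <- TRUE
    return(out)
  }
  depth <- pmin(pmax(pts[, 3] / morph$cortical_thickness_um, 0), 1)
  bin <- pmin(floor(depth * nbins) + 1L, nbins)
  tab <- tabulate(bin, nbins)
  out <- tab / sum(tab)
  attr(out, "empty") <- FALSE
  out
}

compartment_total_length <- function(morph, compartment) {
  types <- swc_compartments[[compartment]]
  nodes <- morph$nodes
  idx <- match(nodes$parent, nodes$id)
  sel <- which(nodes$type %in% types & !is.na(idx))
  if (!length(sel)) return(0)
  sum(sqrt((nodes$x[sel] - nodes$x[idx[sel]])^2 +
           (nodes$y[sel] - nodes$y[idx[sel]])^2 +
           (nodes$z[sel] - nodes$z[idx[sel]])^2))
}

# per-compartment scalar morphometrics on a node table
compartment_stats <- function(morph, compartment) {
  types <- swc_compartments[[compartment]]
  nodes <- morph$nodes
  sub <- nodes[nodes$type %in% c(1, types), ]
  neur <- sub[sub$type %in% types, ]
  out <- c(total_length = NA_real_, n_branch_points = NA_real_,
           n_tips = NA_real_, max_branch_order = NA_real_,
           max_path_dist = NA_real_, max_euclid_dist = NA_real_,
           width = NA_real_, height = NA_real_,
           width_height_log_ratio = NA_real_,
           mean_branch_length = NA_real_, sd_branch_length = NA_real_,
           mean_tortuosity = NA_real_, mean_bifurcation_angle = NA_real_)
  if (!nrow(neur)) return(out)
  out["total_length"] <- compartment_total_length(morph, compartment)
  ids <- sub$id
  idx <- match(sub$parent, ids)
  ch <- children_list(sub)
  nch <- lengths(ch)[as.character(ids)]
  is_neurite <- sub$type %in% types
  out["n_branch_points"] <- sum(nch >= 2 & is_neurite)
  out["n_tips"] <- sum(nch == 0 & is_neurite)
  # branch order: number of bifurcations passed from the root
  ord <- rep(0L, nrow(sub)); pathd <- rep(0, nrow(sub))
  edge <- sqrt((sub$x - sub$x[idx])^2 + (sub$y - sub$y[idx])^2 +
               (sub$z - sub$z[idx])^2)
  for (pass in seq_len(nrow(sub))) {
    todo <- which(!is.na(idx))
    done <- TRUE
    for (i in todo) {
      p <- idx[i]
      o <- ord[p] + as.integer(nch[p] >= 2)
      d <- pathd[p] + edge[i]
      if (ord[i] != o || pathd[i] != d) {
        ord[i] <- o; pathd[i] <- d; done <- FALSE
      }
    }
    if (done) break
  }
  out["max_branch_order"] <- max(ord[is_neurite])
  out["max_path_dist"] <- max(pathd[is_neurite])
  s <- nodes[nodes$id == morph$soma_id, ]
  out["max_euclid_dist"] <- sqrt(max((neur$x - s$x)^2 + (neur$y - s$y)^2 +
                                     (neur$z - s$z)^2))
  w <- diff(range(neur$x)); h <- diff(range(neur$z))
  out["width"] <- w; out["height"] <- h
  if (w > 0 && h > 0) out["width_height_log_ratio"] <- log(w / h)
  bp <- branch_paths(morph, types)
  if (length(bp$paths)) {
    lens <- tors <- numeric(0)
    for (path in bp$paths) {
      ii <- match(path, bp$nodes$id)
      xyz <- as.matrix(bp$nodes[ii, c("x", "y", "z")])
      L <- sum(sqrt(rowSums(diff(xyz)^2)))
      E <- sqrt(sum((xyz[nrow(xyz), ] - xyz[1, ])^2))
      lens <- c(lens, L)
      if (E > 0) tors <- c(tors, L / E)
    }
    out["mean_branch_length"] <- mean(lens)
    out["sd_branch_length"] <- if (length(lens) > 1) stats::sd(lens) else 0
    out["mean_tortuosity"] <- if (length(tors)) mean(tors) else NA_real_
  }
  # bifurcation angles between the two outgoing directions
  angs <- numeric(0)
  for (b in as.character(ids[nch >= 2 & is_neurite])) {
    kids <- ch[[b]]
    bi <- match(as.integer(b), ids)
    for (a1 in seq_along(kids)) for (a2 in seq_len(a1 - 1L)) {
      v1 <- as.numeric(sub[match(kids[a1], ids), c("x", "y", "z")]) -
        as.numeric(sub[bi, c("x", "y", "z")])
      v2 <- as.numeric(sub[match(kids[a2], ids), c("x", "y", "z")]) -
        as.numeric(sub[bi, c("x", "y", "z")])
      d <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
      angs <- c(angs, acos(pmin(pmax(d, -1), 1)) * 180 / pi)
    }
  }
  out["mean_bifurcation_angle"] <- if (length(angs)) mean(angs) else NA_real_
  out
}

# apical dendrite := dendritic subtree with the longest total path length
apical_subtree <- function(morph) {
  nodes <- morph$nodes
  ch <- children_list(nodes)
  stems <- ch[[as.character(morph$soma_id)]] %||% integer(0)
  stems <- stems[nodes$type[match(stems, nodes$id)] %in% c(3, 4)]
  if (!length(stems)) return(NULL)
  collect <- function(root) {
    ids <- root
    frontier <- root
    while (length(frontier)) {
      nxt <- unlist(ch[as.character(frontier)], use.names = FALSE)
      ids <- c(ids, nxt)
      frontier <- nxt
    }
    ids
  }
  best <- NULL; best_len <- -1
  for (s in stems) {
    ids <- collect(s)
    sub <- nodes[nodes$id %in% ids, ]
    idx <- match(sub$parent, nodes$id)
    L <- sum(sqrt((sub$x - nodes$x[idx])^2 + (sub$y - nodes$y[idx])^2 +
                  (sub$z - nodes$z[idx])^2), na.rm = TRUE)
    if (L > best_len) { best_len <- L; best <- ids }
  }
  sub <- nodes[nodes$id %in% c(morph$soma_id, best), ]
  m2 <- morph
  m2$nodes <- sub
  m2$nodes$type[m2$nodes$type == 3] <- 4
  m2
}

#' Scalar morphometrics
#'
#' Computes the registered morphometric statistics for a cell. For
#' excitatory cells only dendritic, apical-dendrite (the dendrite with
#' the longest total path length) and somatic features are returned;
#' for inhibitory cells axonal, dendritic, somatic and axon-dendrite
#' overlap features. No feature measures the slice-depth (y) direction.
#'
#' @param morph A `morphology`.
#' @param cell_class `"excitatory"` or `"inhibitory"`.
#' @return Named numeric vector; features of a missing compartment are
#'   `NA`.
#' @export
morphometrics <- function(morph, cell_class = c("inhibitory", "excitatory")) {
  cell_class <- match.arg(cell_class)
  nodes <- morph$nodes
  soma <- nodes[nodes$id == morph$soma_id, ]
  out <- c(soma_radius = soma$radius,
           soma_depth = soma$z / morph$cortical_thickness_um)
  dend <- compartment_stats(morph, "dendrite")
  names(dend) <- paste0("dendrite_", names(dend))
  out <- c(out, dend)
  if (cell_class == "excitatory") {
    ap <- apical_subtree(morph)
    a <- if (is.null(ap))
      stats::setNames(rep(NA_real_, 13),
                      names(compartment_stats(morph, "dendrite")))
    else compartment_stats(ap, "dendrite")
    names(a) <- paste0("apical_", names(a))
    out <- c(out, a)
  } else {
    ax <- compartment_stats(morph, "axon")
    names(ax) <- paste0("axon_", names(ax))
    out <- c(out, ax)
    pa <- z_profile(morph, "axon")
    pd <- z_profile(morph, "dendrite")
    overlap <- if (!attr(pa, "empty") && !attr(pd, "empty"))
      sum(pmin(pa, pd)) else NA_real_
    za <- suppressWarnings(range(nodes$z[nodes$type == 2]))
    zd <- suppressWarnings(range(nodes$z[nodes$type %in% c(3, 4)]))
    ext_overlap <- if (all(is.finite(c(za, zd)))) {
      inter <- max(0, min(za[2], zd[2]) - max(za[1], zd[1]))
      uni <- max(za[2], zd[2]) - min(za[1], zd[1])
      if (uni > 0) inter / uni else NA_real_
    } else NA_real_
    out <- c(out, axon_dendrite_profile_overlap = overlap,
             axon_dendrite_extent_overlap = ext_overlap)
  }
  out
}

#' Drop low-variation positive features
#'
#' Among features whose values are all positive, those with a
#' coefficient of variation below `min_cv` are removed.
#'
#' @param features Cells x features numeric matrix or data frame.
#' @param min_cv CV threshold (default 0.25).
#' @return The filtered matrix, with attribute `dropped` naming the
#'   removed features.
#' @export
filter_features_by_cv <- function(features, min_cv = 0.25) {
  m <- as.matrix(features)
  drop <- vapply(seq_len(ncol(m)), function(j) {
    x <- m[, j]
    x <- x[is.finite(x)]
    if (!length(x) || any(x <= 0)) return(FALSE)
    stats::sd(x) / mean(x) < min_cv
  }, logical(1))
  out <- m[, !drop, drop = FALSE]
  attr(out, "dropped") <- colnames(m)[drop]
  out
}

#' Assign a cortical layer from normalized depth
#'
#' Default boundaries 0.07 (L1/L2-3), 0.29 (L2-3/L5) and 0.73 (L5/L6);
#' a depth equal to a boundary goes to the deeper layer.
#'
#' @param depth Normalized depth(s) in [0, 1].
#' @param boundaries Strictly increasing boundary depths.
#' @param labels Layer labels (length = boundaries + 1).
#' @return Character vector of layer labels.
#' @export
assign_layer <- function(depth, boundaries = c(0.07, 0.29, 0.73),
                         labels = c("L1", "L2/3", "L5", "L6")) {
  if (any(depth < 0 | depth > 1))
    stop("depth must be in [0, 1]", call. = FALSE)
  if (any(diff(boundaries) <= 0))
    stop("boundaries must be strictly increasing", call. = FALSE)
  stopifnot(length(labels) == length(boundaries) + 1)
  labels[findInterval(depth, boundaries, left.open = FALSE) + 1L]
}
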