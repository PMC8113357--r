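#' Specification of a synthetic reconstruction
#'
#' Plants a branching morphology with a known normalized depth profile
#' per compartment, branch counts and segment-length distributions, for
#' validating the morphology pipeline against ground truth.
#'
#' @param soma_depth_normalized Soma depth in [0, 1].
#' @param cortical_thickness_um Cortical thickness (> 0).
#' @param n_branches Named list (`axon`, `dendrite`) of branch counts;
#'   0 omits the compartment.
#' @param mean_branch_length_um Named list of mean branch lengths (um).
#' @param z_profile Named list of planted 20-bin depth profiles
#'   (non-negative, summing to 1); `NULL` entries default to a broad
#'   unimodal profile around the soma depth.
#' @param seed Integer seed.
#' @return Object of class `morph_spec`.
#' @export
morph_spec <- function(soma_depth_normalized = 0.4,
                       cortical_thickness_um = 1000,
                       n_branches = list(axon = 12, dendrite = 8),
                       mean_branch_length_um = list(axon = 150,
                                                    dendrite = 100),
                       z_profile = list(axon = NULL, dendrite = NULL),
                       seed = 1L) {
  if (soma_depth_normalized < 0 || soma_depth_normalized > 1)
    stop("soma_depth_normalized must be in [0, 1]", call. = FALSE)
  stopifnot_scalar(cortical_thickness_um, "cortical_thickness_um",
                   positive = TRUE)
  default_profile <- function() {
    mids <- (seq_len(20) - 0.5) / 20
    p <- exp(-(mids - soma_depth_normalized)^2 / (2 * 0.12^2))
    p / sum(p)
  }
  for (comp in c("axon", "dendrite")) {
    p <- z_profile[[comp]]
    if (is.null(p)) z_profile[[comp]] <- default_profile()
    else {
      if (length(p) != 20 || any(p < 0))
        stop("planted z_profile must be 20 non-negative masses",
             call. = FALSE)
      z_profile[[comp]] <- p / sum(p)
    }
  }
  structure(list(soma_depth_normalized = soma_depth_normalized,
                 cortical_thickness_um = cortical_thickness_um,
                 n_branches = n_branches,
                 mean_branch_length_um = mean_branch_length_um,
                 z_profile = z_profile, seed = as.integer(seed)),
            class = "morph_spec")
}

#' Generate a synthetic SWC morphology
#'
#' Builds a connected tree rooted at the soma. For each compartment,
#' node depths are sampled from the planted 20-bin profile (uniform
#' within bins), sorted into contiguous runs forming branches, and each
#' branch is attached to the existing node nearest in depth, so that the
#' realized depth profile matches the planted one up to binning and
#' edge-interpolation error.
#'
#' @param spec A [morph_spec()].
#' @return A `morphology` (see [load_and_normalize()]) whose
#'   `ground_truth` attribute carries the spec.
#' @export
generate_morphology <- function(spec) {
  stopifnot(inherits(spec, "morph_spec"))
  set.seed(spec$seed)
  th <- spec$cortical_thickness_um
  soma_z <- spec$soma_depth_normalized * th
  nodes <- data.frame(id = 1L, type = 1L, x = 0, y = 0, z = soma_z,
                      radius = 6, parent = -1L)
  next_id <- 2L
  for (comp in c("dendrite", "axon")) {
    nb <- spec$n_branches[[comp]] %||% 0
    if (nb < 1) next
    type_code <- if (comp == "axon") 2L else 3L
    mbl <- spec$mean_branch_length_um[[comp]]
    prof <- spec$z_profile[[comp]]
    n_pts <- max(nb * 3L, round(nb * mbl / 2))  # ~2 um node spacing
    bins <- sample.int(20, n_pts, replace = TRUE, prob = prof)
    zs <- sort((bins - stats::runif(n_pts)) / 20 * th)
    chunks <- split(zs, cut(seq_along(zs), nb, labels = FALSE))
    comp_first <- next_id
    for (b in seq_len(nb)) {
      z <- chunks[[b]]
      if (!length(z)) next
      # attach to the existing compartment node (or soma) nearest in
      # depth; if that node is a tip, attach to its parent instead so
      # the attachment creates a bifurcation
      cand <- nodes[nodes$type %in% c(1L, type_code), ]
      attach_i <- cand$id[which.min(abs(cand$z - z[1]))]
      if (attach_i != 1L && !attach_i %in% nodes$parent) {
        p <- nodes$parent[nodes$id == attach_i]
        if (p > 0) attach_i <- p
      }
      ax <- nodes$x[nodes$id == attach_i]
      ay <- nodes$y[nodes$id == attach_i]
      dx <- cumsum(stats::rnorm(length(z), 0, 1))
      dy <- cumsum(stats::rnorm(length(z), 0, 1))
      ids <- next_id + seq_along(z) - 1L
      nodes <- rbind(nodes, data.frame(
        id = ids, type = type_code,
        x = ax + dx, y = ay + dy, z = z, radius = 0.5,
        parent = c(attach_i, ids[-length(ids)])))
      next_id <- next_id + length(z)
    }
  }
  m <- structure(list(nodes = nodes,
                      cortical_thickness_um = th,
                      soma_depth_normalized = spec$soma_depth_normalized,
                      soma_id = 1L),
                 class = "morphology")
  attr(m, "ground_truth") <- spec
  m
}
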