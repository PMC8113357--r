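#' Pipeline configuration
#'
#' Single configuration object driving [run_patchseq_pipeline()] on
#' synthetic data: which modalities to generate, their sizes, and all
#' seeds. The configuration round-trips through YAML.
#'
#' @param seed Master seed; every stage derives its own stream from it.
#' @param n_types,n_genes,n_cells Synthetic atlas and query sizes.
#' @param ephys,morphology Logical: generate and analyse these
#'   modalities.
#' @param n_boot Bootstrap draws for t-type mapping.
#' @param current_steps_pA Protocol currents for the synthetic
#'   recordings (a reduced ladder by default to keep runs fast).
#' @param out_dir Optional output directory for CSV/JSON results.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_types = 6, n_genes = 600,
                            n_cells = 36, ephys = TRUE,
                            morphology = TRUE, n_boot = 50,
                            current_steps_pA = seq(-200, 400, by = 20),
                            out_dir = NULL) {
  structure(list(seed = as.integer(seed), n_types = n_types,
                 n_genes = n_genes, n_cells = n_cells, ephys = ephys,
                 morphology = morphology, n_boot = n_boot,
                 current_steps_pA = current_steps_pA,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @return The path (write) or a `pipeline_config` (read).
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(pipeline_config, x)
}

# type-dependent electrophysiology parameters: smooth gradients over the
# type index so transcriptomic neighbours have similar phenotypes
type_ephys_spec <- function(type_index, n_types, protocol, seed) {
  u <- (type_index - 1) / max(1, n_types - 1)
  rheo <- 60 + 160 * u                     # pA
  gain <- 0.06 - 0.03 * u                  # spikes per pA above rheobase
  spikes <- list()
  for (cur in protocol$current_steps_pA) {
    if (cur <= rheo) next
    n_sp <- max(1L, round((cur - rheo) * gain))
    if (n_sp >= 1)
      spikes[[as.character(cur)]] <-
        protocol$onset_s + 0.01 +
        seq(0, protocol$duration_s - 0.05, length.out = n_sp + 1)[seq_len(n_sp)]
  }
  trace_spec(
    resting_potential_mV = -75 + 10 * u,
    input_resistance_MOhm = 100 + 120 * u,
    membrane_tau_ms = 10 + 15 * u,
    sag_amplitude_mV = 6 * u, sag_tau_ms = 40,
    rebound_mV = 3 * u,
    spike_times_s = spikes,
    ap_shape = ap_template(threshold_mV = -44 + 6 * u,
                           amplitude_mV = 65 - 15 * u,
                           upstroke_Vps = 300 - 100 * u,
                           halfwidth_ms = 0.7 + 0.8 * u,
                           ahp_mV = 8 + 8 * u),
    noise_sd_mV = 0.15, seed = seed)
}

type_morph_spec <- function(type_index, n_types, seed) {
  u <- (type_index - 1) / max(1, n_types - 1)
  depth <- 0.15 + 0.6 * u
  mids <- (seq_len(20) - 0.5) / 20
  prof <- function(center, width) {
    p <- exp(-(mids - center)^2 / (2 * width^2))
    p / sum(p)
  }
  morph_spec(soma_depth_normalized = depth,
             cortical_thickness_um = 1000,
             n_branches = list(axon = 8 + round(6 * u), dendrite = 6),
             mean_branch_length_um = list(axon = 120, dendrite = 90),
             z_profile = list(axon = prof(depth - 0.08 * u, 0.1),
                              dendrite = prof(depth, 0.08 + 0.1 * u)),
             seed = seed)
}

#' Run the multimodal pipeline end-to-end on synthetic data
#'
#' Generates a synthetic reference atlas and query cells, maps the query
#' cells to t-types (two rounds, bootstrap, consensus), synthesizes and
#' analyses per-cell current-clamp recordings (29 features + 17-feature
#' analysis vectors) and SWC morphologies (z-profiles + morphometrics),
#' builds the electrophysiological representation, classifies
#' transcriptomic families with leave-one-out kNN, and computes
#' per-type normalized total variances with a k-means baseline. Stages
#' for disabled modalities are skipped; all randomness derives from the
#' config seed, so reruns are bit-identical.
#'
#' @param config A [pipeline_config()].
#' @return List with per-stage results (`assignments`,
#'   `ephys_features`, `analysis_vectors`, `morphology`,
#'   `representation`, `knn`, `variability`) and `provenance`.
#' @export
run_patchseq_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  prov <- list(package_version = as.character(utils::packageVersion("patchseqr")),
               seed = seed, config = unclass(config),
               timestamp = format(Sys.time(), tz = "UTC"))

  # --- transcriptomics ---------------------------------------------------
  spec <- atlas_spec(n_types = config$n_types, n_genes = config$n_genes,
                     n_cells_per_type = 30, type_separation = 3,
                     seed = derive_seed(seed, 1L))
  sim <- generate_expression_bundle(spec, n_query_cells = config$n_cells,
                                    query_noise = 0.2, n_atlases = 2)
  map <- assign_ttypes(sim$query, sim$atlases[[1]], sim$atlases,
                       n_round1_genes = min(config$n_genes, 3000),
                       n_round2_genes = min(config$n_genes, 500),
                       n_boot = config$n_boot,
                       seed = derive_seed(seed, 2L))
  res <- list(assignments = map$assignments,
              consensus = map$consensus,
              true_type = sim$true_type)
  true_idx <- match(sim$true_type, spec$t_types)

  # --- electrophysiology -------------------------------------------------
  if (isTRUE(config$ephys)) {
    proto <- stimulus_protocol(current_steps_pA = config$current_steps_pA,
                               sample_rate_hz = 5000)
    feats <- t(vapply(seq_len(config$n_cells), function(i) {
      ts <- type_ephys_spec(true_idx[i], config$n_types, proto,
                            derive_seed(seed, 100L + i))
      extract_ephys_features(generate_sweep_set(ts, proto))
    }, numeric(29)))
    rownames(feats) <- colnames(sim$query$exon_counts)
    av <- assemble_analysis_vector(feats)
    res$ephys_features <- feats
    res$analysis_vectors <- av
    complete <- attr(av, "complete")
    if (sum(complete) > 17) {
      rep_e <- build_ephys_representation(av[complete, , drop = FALSE])
      res$representation <- rep_e
      fam <- spec$family_of_type[sim$true_type][complete]
      if (length(unique(fam)) > 1) {
        k_knn <- max(1, min(10, min(table(fam)) - 1))
        res$knn <- knn_family_classify(rep_e, fam, k = k_knn)
      }
      tys <- sim$true_type[complete]
      sizes <- table(tys)
      quals <- names(sizes)[sizes >= 2]
      ntv <- vapply(quals, function(ty)
        normalized_total_variance(rep_e, tys == ty), numeric(1))
      res$variability <- list(
        normalized_total_variance = ntv,
        kmeans = kmeans_baseline(rep_e, length(quals),
                                 seed = derive_seed(seed, 3L)))
    }
  }

  # --- morphology --------------------------------------------------------
  if (isTRUE(config$morphology)) {
    morphs <- lapply(seq_len(config$n_cells), function(i)
      generate_morphology(type_morph_spec(true_idx[i], config$n_types,
                                          derive_seed(seed, 200L + i))))
    zp <- t(vapply(morphs, z_profile, numeric(20),
                   compartment = "axon"))
    mm <- t(vapply(morphs, morphometrics, cell_class = "inhibitory",
                   FUN.VALUE = numeric(
                     length(morphometrics(morphs[[1]], "inhibitory")))))
    rownames(zp) <- rownames(mm) <- colnames(sim$query$exon_counts)
    res$morphology <- list(z_profiles = zp, morphometrics = mm)
  }

  res$provenance <- prov
  if (!is.null(config$out_dir)) write_pipeline_outputs(res, config$out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$assignments, file.path(out_dir, "assignments.csv"),
                   row.names = FALSE)
  if (!is.null(res$ephys_features))
    utils::write.csv(res$ephys_features,
                     file.path(out_dir, "ephys_features.csv"))
  if (!is.null(res$morphology)) {
    utils::write.csv(res$morphology$z_profiles,
                     file.path(out_dir, "z_profiles.csv"))
    utils::write.csv(res$morphology$morphometrics,
                     file.path(out_dir, "morphometrics.csv"))
  }
  jsonlite::write_json(res$provenance,
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Write counts as MatrixMarket + TSV sidecars
#'
#' @param counts Genes x cells matrix.
#' @param dir Output directory (created if needed); writes
#'   `counts.mtx`, `genes.tsv`, `cells.tsv`.
#' @return The directory invisibly.
#' @export
write_counts_mtx <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE),
                  file.path(dir, "counts.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "cells.tsv"))
  invisible(dir)
}

#' @rdname write_counts_mtx
#' @export
read_counts_mtx <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "counts.mtx")))
  rownames(m) <- readLines(file.path(dir, "genes.tsv"))
  colnames(m) <- readLines(file.path(dir, "cells.tsv"))
  m
}
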