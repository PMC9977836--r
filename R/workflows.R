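.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

.config_hash <- function(cfg) {
  # order-insensitive digest of a flat config list
  s <- paste(sort(vapply(names(cfg), function(n) {
    paste0(n, "=", paste(format(cfg[[n]], digits = 15), collapse = ","))
  }, character(1))), collapse = ";")
  sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 1e9
}

.stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

.read_transforms <- function(path, n) {
  if (is.null(path)) return(NULL)
  tr <- jsonlite::read_json(path)
  lapply(seq_len(n), function(i) {
    t <- if (!is.null(names(tr))) tr[[i]] else tr[[i]]
    if (is.null(t)) NULL else matrix(unlist(t), 2, 3, byrow = TRUE)
  })
}

#' Run the spatial clustering workflow
#'
#' Reads a slide, preprocesses it, builds the spot graph, trains the
#' representation, clusters (optionally refined), and writes `labels.tsv`,
#' `embeddings.csv`, `loss_history.csv` and `report.json` to `out_dir`. The
#' report records the configuration hash and seed and, when truth labels are
#' available, the adjusted Rand index.
#'
#' @param input path to an MTX directory or CSV matrix (or an in-memory
#'   [spatial_dataset()]).
#' @param out_dir output directory.
#' @param format input format for [read_spatial_dataset()].
#' @param n_clusters cluster count; if NULL, selected by silhouette over
#'   `k_range`.
#' @param k_range candidate cluster counts when `n_clusters` is NULL.
#' @param k graph neighbours (default 3).
#' @param n_hvg highly variable genes (default 3000).
#' @param refine apply spatial label refinement (default FALSE).
#' @param r refinement radius (default 50).
#' @param cfg a [train_config()].
#' @param seed global seed; fans out to the stage seeds.
#' @return invisibly, a list with `labels`, `representation`, `report`.
#' @export
run_cluster <- function(input, out_dir, format = "mtx_dir", n_clusters = NULL,
                        k_range = 2:8, k = 3, n_hvg = 3000, refine = FALSE,
                        r = 50, cfg = NULL, seed = 0) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- .stage("preprocess/read", {
    if (inherits(input, "spatial_dataset")) input
    else read_spatial_dataset(input, format = format)
  })
  if (is.null(cfg)) cfg <- train_config(seed = seed)
  feats <- .stage("preprocess", normalize_select_scale(ds, n_hvg = n_hvg))
  g <- .stage("graph", build_knn_graph(ds$coords, k = k))
  rep_out <- .stage("representation", train_representation(feats, g, cfg))
  if (is.null(n_clusters)) {
    n_clusters <- .stage("clustering",
                         choose_cluster_count(rep_out$H_s, k_range,
                                              seed = seed + 1))
  }
  labels <- .stage("clustering",
                   fit_mixture_clusters(rep_out$H_s, n_clusters,
                                        seed = seed + 1))
  if (refine) {
    labels <- .stage("clustering", spatial_refine(labels, ds$coords, r = r))
  }
  lab_df <- as.data.frame(labels, spot_ids = ds$spot_ids)
  utils::write.table(lab_df, file.path(out_dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.csv(data.frame(spot_id = ds$spot_ids, rep_out$Z_s),
                   file.path(out_dir, "embeddings.csv"), row.names = FALSE)
  utils::write.csv(rep_out$loss_history,
                   file.path(out_dir, "loss_history.csv"), row.names = FALSE)
  report <- list(task = "cluster", seed = seed, n_clusters = n_clusters,
                 k = k, n_hvg = n_hvg, refine = refine, r = r,
                 epochs = cfg$epochs,
                 config_hash = .config_hash(cfg),
                 final_loss = utils::tail(rep_out$loss_history$total, 1))
  if (!is.null(ds$truth_labels)) {
    report$ari <- adjusted_rand_index(labels, as.integer(factor(ds$truth_labels)) - 1L)
  }
  .write_json(report, file.path(out_dir, "report.json"))
  invisible(list(labels = labels, representation = rep_out, report = report,
                 dataset = ds))
}

#' Run the multi-slice integration workflow
#'
#' Integrates two or more slices over a joint graph, clusters the joint
#' embedding, and writes joint labels, per-slice ARIs (when truth labels are
#' present) and an iLISI report comparing the joint embedding against an
#' uncorrected PCA embedding of the pooled features.
#'
#' @param inputs list of [spatial_dataset()] objects or paths to MTX dirs.
#' @param out_dir output directory.
#' @param transforms optional path to a transforms JSON (per-slice 2 x 3
#'   rigid matrices) or a list of matrices.
#' @param n_clusters joint cluster count; NULL selects by silhouette.
#' @param k_range candidate counts when `n_clusters` is NULL.
#' @param k graph neighbours. @param n_hvg pooled HVG count.
#' @param cfg a [train_config()]. @param seed global seed.
#' @return invisibly, a list with `integrated`, `labels`, `report`.
#' @export
run_integrate <- function(inputs, out_dir, transforms = NULL,
                          n_clusters = NULL, k_range = 2:8, k = 3,
                          n_hvg = 3000, cfg = NULL, seed = 0) {
  if (length(inputs) < 2) stop("[integrate] need at least 2 slices")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  slices <- .stage("preprocess/read", lapply(inputs, function(x) {
    if (inherits(x, "spatial_dataset")) x else read_spatial_dataset(x)
  }))
  if (is.character(transforms)) {
    transforms <- .read_transforms(transforms, length(slices))
  }
  if (is.null(cfg)) cfg <- train_config(seed = seed)
  integ <- .stage("integration",
                  integrate_slices(slices, transforms = transforms, cfg = cfg,
                                   k = k, n_hvg = n_hvg))
  if (is.null(n_clusters)) {
    n_clusters <- .stage("clustering",
                         choose_cluster_count(integ$H_joint, k_range,
                                              seed = seed + 1))
  }
  labels <- .stage("clustering",
                   fit_mixture_clusters(integ$H_joint, n_clusters,
                                        seed = seed + 1))
  batch <- integ$combined$batch
  ili_joint <- .stage("metrics", ilisi_score(integ$Z_joint, batch))
  pca <- .pca_scores(integ$features$values, 20)
  ili_pca <- .stage("metrics", ilisi_score(pca, batch))
  lab_df <- as.data.frame(labels, spot_ids = integ$combined$spot_ids)
  lab_df$batch <- batch
  utils::write.table(lab_df, file.path(out_dir, "joint_labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report <- list(task = "integrate", seed = seed, n_slices = length(slices),
                 n_clusters = n_clusters, k = k, epochs = cfg$epochs,
                 config_hash = .config_hash(cfg),
                 ilisi_joint = ili_joint, ilisi_uncorrected_pca = ili_pca)
  truth <- integ$combined$truth_labels
  if (!is.null(truth)) {
    tnum <- as.integer(factor(truth)) - 1L
    aris <- vapply(unique(batch), function(b) {
      sel <- batch == b
      adjusted_rand_index(labels$labels[sel], tnum[sel])
    }, numeric(1))
    report$per_slice_ari <- as.list(stats::setNames(aris, unique(batch)))
  }
  .write_json(report, file.path(out_dir, "ilisi_report.json"))
  invisible(list(integrated = integ, labels = labels, report = report))
}

#' Run the cell-type deconvolution workflow
#'
#' Preprocesses the spatial slide and single-cell reference, restricts both
#' to their common genes, trains the spot representation and the reference
#' autoencoder, fits the cell-to-spot mapping matrix, transfers annotations
#' (when present) to spots and domains, and writes the mapping matrix,
#' `P_spot`/`P_domain` tables and a metrics JSON (when truth proportions are
#' supplied).
#'
#' @param spatial a [spatial_dataset()] or path to an MTX directory.
#' @param reference list with `counts` (cells x genes) and optional
#'   `labels`, or a path to a counts CSV (cells x genes, first column cell
#'   ids) with an optional annotations CSV (`cell_id,label`) next to it as
#'   `annotations.csv`.
#' @param out_dir output directory.
#' @param truth_proportions optional spots x types matrix for evaluation.
#' @param domains optional [domain_labels()] (or per-spot labels) for
#'   domain-targeted transfer; if NULL and annotation labels exist, domains
#'   come from clustering with `n_clusters`.
#' @param n_clusters cluster count for domain transfer (default 4).
#' @param k graph neighbours. @param n_hvg HVG count per modality.
#' @param top_frac top-cell fraction retained per spot (default 0.1).
#' @param cfg a [train_config()] (epochs default 1200 for this task).
#' @param map_cfg a [mapping_config()]. @param seed global seed.
#' @return invisibly, a list with `mapping`, `P_spot`, `P_domain`,
#'   `proportions`, `metrics`, `report`.
#' @export
run_deconvolve <- function(spatial, reference, out_dir,
                           truth_proportions = NULL, domains = NULL,
                           n_clusters = 4, k = 3, n_hvg = 3000,
                           top_frac = 0.1, cfg = NULL, map_cfg = NULL,
                           seed = 0) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- .stage("preprocess/read", {
    if (inherits(spatial, "spatial_dataset")) spatial
    else read_spatial_dataset(spatial)
  })
  ref <- .stage("preprocess/read", {
    if (is.list(reference) && !is.null(reference$counts)) reference
    else {
      counts <- as.matrix(utils::read.csv(reference, row.names = 1,
                                          check.names = FALSE))
      apath <- file.path(dirname(reference), "annotations.csv")
      labels <- NULL
      if (file.exists(apath)) {
        adf <- utils::read.csv(apath, stringsAsFactors = FALSE)
        labels <- adf$label[match(rownames(counts), adf$cell_id)]
      }
      list(counts = counts, labels = labels)
    }
  })
  if (is.null(cfg)) cfg <- train_config(epochs = 1200, seed = seed)
  if (is.null(map_cfg)) map_cfg <- mapping_config(seed = seed + 3)

  st_feats <- .stage("preprocess", normalize_select_scale(ds, n_hvg = n_hvg))
  sc_feats <- .stage("preprocess",
                     normalize_select_scale(ref$counts, n_hvg = n_hvg))
  both <- .stage("preprocess", intersect_genes(st_feats, sc_feats))
  g <- .stage("graph", build_knn_graph(ds$coords, k = k))
  rep_out <- .stage("representation",
                    train_representation(both$st, g, cfg))
  ae <- .stage("deconvolution",
               train_reference_autoencoder(both$sc, epochs = cfg$epochs,
                                           seed = seed + 2))
  mapping <- .stage("deconvolution",
                    fit_mapping_matrix(rep_out$H_s, ae$H_c, g, map_cfg))
  utils::write.table(round(mapping$M, 8),
                     file.path(out_dir, "mapping_matrix.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)

  P_spot <- NULL; P_domain <- NULL; props <- NULL; metrics <- NULL
  if (!is.null(ref$labels)) {
    S_cell <- annotation_matrix(ref$labels)
    P_spot <- .stage("deconvolution",
                     annotations_to_spots(mapping, S_cell,
                                          top_frac = top_frac))
    props <- proportions_from_scores(P_spot)
    utils::write.table(round(P_spot, 8), file.path(out_dir, "P_spot.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    if (is.null(domains)) {
      domains <- .stage("clustering",
                        fit_mixture_clusters(rep_out$H_s, n_clusters,
                                             seed = seed + 1))
    }
    S_spot <- annotation_matrix(paste0("domain", .label_vector(domains)))
    P_domain <- annotations_to_domains(P_spot, S_spot)
    utils::write.table(round(P_domain, 8),
                       file.path(out_dir, "P_domain.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    if (!is.null(truth_proportions)) {
      metrics <- .stage("metrics",
                        deconvolution_metrics(props, truth_proportions))
    }
  } else {
    warning("reference has no annotation labels; mapping and predicted ",
            "expression produced, annotation transfer skipped")
  }
  report <- list(task = "deconvolve", seed = seed,
                 n_cells = nrow(ref$counts), n_spots = nrow(ds$counts),
                 n_common_genes = length(both$st$feature_ids),
                 epochs = cfg$epochs, map_epochs = map_cfg$epochs,
                 config_hash = .config_hash(map_cfg),
                 final_mapping_objective = utils::tail(mapping$loss_history, 1))
  if (!is.null(metrics)) report$metrics <- as.list(metrics$means)
  .write_json(report, file.path(out_dir, "metrics.json"))
  invisible(list(mapping = mapping, P_spot = P_spot, P_domain = P_domain,
                 proportions = props, metrics = metrics, report = report,
                 representation = rep_out, autoencoder = ae))
}

#' Write a synthetic fixture to disk
#'
#' Generates one of the synthetic datasets and writes it in the MTX + CSV
#' convention so the reading path is exercised end to end.
#'
#' @param kind `"domain"`, `"replicates"` or `"mixture"`.
#' @param out_dir output directory.
#' @param seed RNG seed.
#' @param ... passed to the corresponding generator.
#' @return invisibly, the generated object(s).
#' @export
run_simulate <- function(kind = c("domain", "replicates", "mixture"),
                         out_dir, seed = 0, ...) {
  kind <- match.arg(kind)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (kind == "domain") {
    ds <- simulate_domain_slide(fixture_spec(seed = seed, ...))
    write_spatial_dataset(ds, out_dir)
    invisible(ds)
  } else if (kind == "replicates") {
    slices <- simulate_replicate_slices(
      fixture_spec(grid = c(20, 20), seed = seed, ...))
    for (i in seq_along(slices)) {
      write_spatial_dataset(slices[[i]], file.path(out_dir, paste0("slice", i)))
    }
    invisible(slices)
  } else {
    sim <- simulate_reference_and_spots(seed = seed, ...)
    write_spatial_dataset(sim$spots, file.path(out_dir, "spots"))
    utils::write.csv(sim$reference$counts,
                     file.path(out_dir, "reference_counts.csv"))
    utils::write.csv(data.frame(cell_id = sim$reference$cell_ids,
                                label = sim$reference$labels),
                     file.path(out_dir, "annotations.csv"), row.names = FALSE)
    utils::write.csv(round(sim$proportions, 8),
                     file.path(out_dir, "true_proportions.csv"))
    invisible(sim)
  }
}
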