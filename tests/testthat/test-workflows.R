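small_cfg <- function(seed = 0) train_config(epochs = 40, seed = seed)

test_that("cluster workflow writes labels, embeddings and a report", {
  ds <- tiny_dataset(n_row = 8, n_col = 8, n_genes = 60, seed = 1)
  out_dir <- withr::local_tempdir()
  res <- run_cluster(ds, out_dir, n_clusters = 2, cfg = small_cfg(1), seed = 1)
  expect_true(file.exists(file.path(out_dir, "labels.tsv")))
  expect_true(file.exists(file.path(out_dir, "embeddings.csv")))
  expect_true(file.exists(file.path(out_dir, "report.json")))
  rep <- jsonlite::read_json(file.path(out_dir, "report.json"))
  expect_equal(rep$task, "cluster")
  expect_true(is.numeric(rep$ari))
  lab <- utils::read.delim(file.path(out_dir, "labels.tsv"))
  expect_equal(nrow(lab), 64)

  # reruns with the same config are bitwise identical
  out_dir2 <- withr::local_tempdir()
  run_cluster(ds, out_dir2, n_clusters = 2, cfg = small_cfg(1), seed = 1)
  expect_identical(readLines(file.path(out_dir, "labels.tsv")),
                   readLines(file.path(out_dir2, "labels.tsv")))
})

test_that("cluster workflow runs from an MTX directory on disk", {
  ds <- tiny_dataset(n_row = 6, n_col = 6, n_genes = 40, seed = 2)
  in_dir <- withr::local_tempdir()
  write_spatial_dataset(ds, in_dir)
  out_dir <- withr::local_tempdir()
  res <- run_cluster(in_dir, out_dir, n_clusters = 2, cfg = small_cfg(2))
  expect_s3_class(res$labels, "domain_labels")
})

test_that("workflow errors carry their stage name", {
  expect_error(run_cluster("/nonexistent/path", withr::local_tempdir(),
                           cfg = small_cfg()),
               "\\[preprocess/read\\]")
  expect_error(run_integrate(list(tiny_dataset()), withr::local_tempdir()),
               "\\[integrate\\]")
})

test_that("integrate workflow reports iLISI for joint and PCA embeddings", {
  spec <- fixture_spec(grid = c(8, 8), n_genes = 60, n_marker_per_domain = 8,
                       seed = 4)
  slices <- simulate_replicate_slices(spec)
  out_dir <- withr::local_tempdir()
  res <- run_integrate(slices, out_dir, n_clusters = 4, cfg = small_cfg(3),
                       seed = 3)
  rep <- res$report
  expect_true(is.numeric(rep$ilisi_joint))
  expect_true(is.numeric(rep$ilisi_uncorrected_pca))
  expect_named(rep$per_slice_ari, c("slice1", "slice2"))
  lab <- utils::read.delim(file.path(out_dir, "joint_labels.tsv"))
  expect_equal(nrow(lab), 128)
})

test_that("deconvolve workflow produces mapping, transfers and metrics", {
  sim <- simulate_reference_and_spots(n_types = 3, cells_per_type = 20,
                                      n_spots = 36, n_genes = 60,
                                      n_marker_per_type = 12,
                                      dirichlet_alpha = rep(0.5, 3), seed = 5)
  out_dir <- withr::local_tempdir()
  res <- run_deconvolve(sim$spots,
                        list(counts = sim$reference$counts,
                             labels = sim$reference$labels),
                        out_dir, truth_proportions = sim$proportions,
                        n_clusters = 3,
                        cfg = train_config(epochs = 60, seed = 5),
                        map_cfg = mapping_config(epochs = 60, seed = 6),
                        seed = 5)
  expect_true(file.exists(file.path(out_dir, "mapping_matrix.tsv")))
  expect_true(file.exists(file.path(out_dir, "P_spot.tsv")))
  expect_true(file.exists(file.path(out_dir, "P_domain.tsv")))
  expect_true(is.list(res$report$metrics))
  expect_equal(dim(res$P_spot), c(36L, 3L))

  # without labels the transfer is skipped but the mapping is produced
  out_dir2 <- withr::local_tempdir()
  expect_warning(
    res2 <- run_deconvolve(sim$spots,
                           list(counts = sim$reference$counts),
                           out_dir2,
                           cfg = train_config(epochs = 30, seed = 5),
                           map_cfg = mapping_config(epochs = 30, seed = 6)),
    "skipped")
  expect_s3_class(res2$mapping, "mapping_matrix")
  expect_null(res2$P_spot)
})

test_that("simulate workflow writes fixtures the readers can consume", {
  out_dir <- withr::local_tempdir()
  run_simulate("domain", out_dir, seed = 1, grid = c(6, 6), n_genes = 30,
               n_marker_per_domain = 5)
  back <- read_spatial_dataset(out_dir, format = "mtx_dir")
  expect_equal(dim(back$counts), c(36L, 30L))
  expect_false(is.null(back$truth_labels))

  out2 <- withr::local_tempdir()
  run_simulate("mixture", out2, seed = 2, n_types = 3, cells_per_type = 10,
               n_spots = 16, n_genes = 45, n_marker_per_type = 10,
               dirichlet_alpha = rep(1, 3))
  expect_true(file.exists(file.path(out2, "reference_counts.csv")))
  expect_true(file.exists(file.path(out2, "annotations.csv")))
  spots <- read_spatial_dataset(file.path(out2, "spots"), format = "mtx_dir")
  expect_equal(nrow(spots$counts), 16)
})

test_that("plot helpers return ggplot objects", {
  ds <- tiny_dataset(seed = 1)
  lab <- domain_labels(as.integer(factor(ds$truth_labels)) - 1L)
  p <- plot_spatial_domains(ds, lab)
  expect_s3_class(p, "ggplot")
})
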