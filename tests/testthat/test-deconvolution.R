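test_that("reference autoencoder compresses a low-rank matrix", {
  set.seed(1)
  basis <- matrix(rnorm(2 * 30), 2, 30)
  loadings <- matrix(rnorm(200 * 2), 200, 2)
  X <- feature_matrix(loadings %*% basis,
                      paste0("g", 1:30), paste0("c", 1:200))
  ae <- train_reference_autoencoder(X, d_latent = 8, epochs = 400, seed = 2)
  init_mse <- ae$loss_history[1]
  expect_lt(tail(ae$loss_history, 1), 0.05 * init_mse)
})

test_that("autoencoder respects the shape contract and determinism", {
  set.seed(2)
  X <- feature_matrix(matrix(rnorm(50 * 10), 50, 10),
                      paste0("g", 1:10), paste0("c", 1:50))
  ae0 <- train_reference_autoencoder(X, d_latent = 4, epochs = 0, seed = 1)
  expect_equal(dim(ae0$H_c), c(50L, 10L))
  a <- train_reference_autoencoder(X, d_latent = 4, epochs = 30, seed = 9)
  b <- train_reference_autoencoder(X, d_latent = 4, epochs = 30, seed = 9)
  expect_identical(a$H_c, b$H_c)
})

test_that("mapping predictions are convex combinations of cell profiles", {
  H_c <- rbind(c(1, 2), c(3, 4), c(5, 6), c(7, 8))
  M <- matrix(0, 4, 2)
  M[3, 1] <- 1                      # spot 1 gets exactly cell 3
  M[c(1, 2), 2] <- 0.5              # spot 2 averages cells 1 and 2
  Hp <- spot_expression_from_mapping(M, H_c)
  expect_equal(Hp[1, ], H_c[3, ])
  expect_equal(Hp[2, ], c(2, 3))

  const <- matrix(7, 4, 2)
  expect_true(all(spot_expression_from_mapping(M, const) == 7))
  expect_error(spot_expression_from_mapping(M[1:3, ], H_c), "match")
})

test_that("mapping objective reproduces closed forms and the loop oracle", {
  # identical rows, each spot one neighbour: every softmax ratio is 1/2
  H <- matrix(1, 3, 4)
  g1 <- structure(list(neighbor_sets = list(2L, 3L, 1L)),
                  class = "neighbor_graph")
  cfg <- mapping_config(alpha = 1, beta = 10)
  expect_equal(mapping_objective(H, H, g1, cfg), 3 * log(2),
               tolerance = 1e-12)

  # beta term vanishes when prediction equals the target
  set.seed(3)
  coords <- matrix(runif(6), 3, 2)
  g <- build_knn_graph(coords, k = 1)
  H_s <- matrix(rnorm(12), 3, 4)
  o_same <- mapping_objective(H_s, H_s, g, mapping_config(alpha = 0))
  expect_equal(o_same, 0)

  # random instance vs brute-force loop oracle
  set.seed(4)
  coords5 <- matrix(runif(10), 5, 2)
  g5 <- build_knn_graph(coords5, k = 2)
  A <- matrix(rnorm(20), 5, 4); B <- matrix(rnorm(20), 5, 4)
  cfg2 <- mapping_config(alpha = 1.3, beta = 2.5, tau = 0.8)
  expect_equal(mapping_objective(A, B, g5, cfg2),
               mapping_objective_oracle(A, B, g5, 1.3, 2.5, 0.8),
               tolerance = 1e-10)
})

test_that("fitted mapping stays column-stochastic and reduces the objective", {
  set.seed(5)
  sim <- simulate_reference_and_spots(n_types = 3, cells_per_type = 20,
                                      n_spots = 25, n_genes = 60,
                                      n_marker_per_type = 10,
                                      dirichlet_alpha = rep(0.5, 3), seed = 8)
  st <- normalize_select_scale(sim$spots, n_hvg = 60)
  sc <- normalize_select_scale(sim$reference$counts, n_hvg = 60)
  both <- intersect_genes(st, sc)
  g <- build_knn_graph(sim$spots$coords, k = 3)
  cfg <- mapping_config(epochs = 50, seed = 1)
  map <- fit_mapping_matrix(both$st$values, both$sc$values, g, cfg)
  expect_true(all(abs(colSums(map$M) - 1) < 1e-5))
  expect_true(all(map$M >= 0))
  expect_lt(tail(map$loss_history, 1), map$loss_history[1])
})

test_that("mapping fit is equivariant under cell permutation", {
  set.seed(6)
  coords <- matrix(runif(16), 8, 2)
  g <- build_knn_graph(coords, k = 2)
  H_s <- matrix(rnorm(8 * 5), 8, 5)
  H_c <- matrix(rnorm(12 * 5), 12, 5)
  init <- matrix(rnorm(12 * 8, sd = 0.1), 12, 8)
  cfg <- mapping_config(epochs = 20, seed = 2)
  base <- fit_mapping_matrix(H_s, H_c, g, cfg, init_logits = init)
  perm <- sample(12)
  permuted <- fit_mapping_matrix(H_s, H_c[perm, ], g, cfg,
                                 init_logits = init[perm, ])
  expect_equal(permuted$M, base$M[perm, ], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("annotation transfer filters, selects and conserves mass", {
  S <- annotation_matrix(c("T", "B", "T", "B", "NK"))
  expect_equal(dim(S$S), c(5L, 3L))
  expect_true(all(rowSums(S$S) == 1))

  # one-hot mapping with top_frac = 1 reproduces the cell's annotation row
  M <- matrix(0, 5, 2); M[2, 1] <- 1; M[5, 2] <- 1
  P <- annotations_to_spots(M, S, top_frac = 1)
  expect_equal(P[1, ], c(B = 1, NK = 0, T = 0))
  expect_equal(P[2, ], c(B = 0, NK = 1, T = 0))

  # exactly ceil(top_frac * N_cell) cells retained per spot
  set.seed(7)
  M10 <- apply(matrix(rexp(10 * 4), 10, 4), 2, function(x) x / sum(x))
  S10 <- annotation_matrix(rep(c("a", "b"), 5))
  P10 <- annotations_to_spots(M10, S10, top_frac = 0.1)
  expect_true(all(rowSums(P10 > 0) <= 1))   # one cell retained -> one label

  # top_frac = 1 conserves all probability mass
  Pfull <- annotations_to_spots(M10, S10, top_frac = 1)
  expect_equal(sum(Pfull), 4, tolerance = 1e-12)
  expect_equal(unname(rowSums(Pfull)), rep(1, 4), tolerance = 1e-12)

  expect_error(annotations_to_spots(M10, S10, top_frac = 0), "top_frac")
})

test_that("domain aggregation equals brute-force group sums", {
  set.seed(8)
  P_spot <- matrix(runif(12), 6, 2, dimnames = list(NULL, c("x", "y")))
  dom <- c("d1", "d2", "d1", "d1", "d2", "d2")
  S_spot <- annotation_matrix(dom)
  P_dom <- annotations_to_domains(P_spot, S_spot)
  oracle <- rbind(colSums(P_spot[dom == "d1", ]),
                  colSums(P_spot[dom == "d2", ]))
  expect_equal(unname(P_dom), oracle, tolerance = 1e-12, ignore_attr = TRUE)

  # one spot per domain: rows pass through
  S1 <- annotation_matrix(paste0("d", 1:6))
  expect_equal(unname(annotations_to_domains(P_spot, S1)), unname(P_spot))
  # all spots in one domain: total aggregation
  Sall <- annotation_matrix(rep("d", 6))
  expect_equal(as.vector(annotations_to_domains(P_spot, Sall)),
               unname(colSums(P_spot)))
})

test_that("deconvolution metrics hit identity and swap closed forms", {
  set.seed(9)
  truth <- proportions_from_scores(matrix(runif(40), 20, 2))
  m_id <- deconvolution_metrics(truth, truth)
  expect_equal(unname(m_id$means["pcc"]), 1, tolerance = 1e-12)
  expect_equal(unname(m_id$means["ssim"]), 1, tolerance = 1e-6)
  expect_equal(unname(m_id$means["rmse"]), 0, tolerance = 1e-12)
  expect_equal(unname(m_id$means["jsd"]), 0, tolerance = 1e-12)

  # est = 1 - truth on a 2-type simplex: per-type JSD of swapped columns
  est <- 1 - truth
  m_swap <- deconvolution_metrics(est, truth)
  jsd_hand <- function(p, q) {
    p <- p / sum(p); q <- q / sum(q); m <- (p + q) / 2
    kl <- function(a, b) sum(ifelse(a > 0, a * log(a / b), 0))
    0.5 * kl(p, m) + 0.5 * kl(q, m)
  }
  expect_equal(m_swap$per_type$jsd[1], jsd_hand(est[, 1], truth[, 1]),
               tolerance = 1e-12)
  expect_true(all(m_swap$per_type$jsd >= 0 &
                    m_swap$per_type$jsd <= log(2) + 1e-12))
  expect_equal(m_swap$jsd_base, "e")

  w <- testthat::capture_warnings(
    m_const <- deconvolution_metrics(matrix(0.5, 20, 2), truth))
  expect_true(all(grepl("constant", w)))
  expect_length(w, 2)   # one warning per constant column
  expect_equal(m_const$per_type$pcc, c(0, 0))
})
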