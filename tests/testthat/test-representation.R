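test_that("gcn layer matches hand-computed propagation", {
  # identity adjacency: plain affine map with ReLU clip
  out <- gcn_layer(matrix(c(1, -2), 1, 2), diag(1), diag(2), c(0, 0), "relu")
  expect_equal(out, matrix(c(1, 0), 1, 2), ignore_attr = TRUE)

  a <- matrix(0.5, 2, 2)
  x <- rbind(c(2, 0), c(0, 2))
  expect_equal(gcn_layer(x, a, diag(2), c(0, 0), "identity"),
               matrix(1, 2, 2), ignore_attr = TRUE)

  expect_error(gcn_layer(x, a, diag(3), rep(0, 3)), "W rows")
})

test_that("one encoder pass equals a dense matrix oracle on a tiny graph", {
  set.seed(10)
  coords <- matrix(runif(10), 5, 2)
  g <- build_knn_graph(coords, k = 2)
  An <- symmetric_normalize(g)
  X <- matrix(rnorm(15), 5, 3)
  W <- matrix(rnorm(6), 3, 2); b <- rnorm(2)
  got <- gcn_layer(X, An, W, b, "relu")
  dense <- as.matrix(An$matrix)
  oracle <- pmax(dense %*% X %*% W + matrix(b, 5, 2, byrow = TRUE), 0)
  expect_equal(got, oracle, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("reconstruction loss is the squared Frobenius norm", {
  expect_equal(reconstruction_loss(matrix(1:4, 2), matrix(1:4, 2)), 0)
  expect_equal(reconstruction_loss(matrix(c(1, 0), 1), matrix(0, 1, 2)), 1)
  set.seed(1)
  X <- matrix(rnorm(20), 4, 5); H <- matrix(rnorm(20), 4, 5)
  base <- reconstruction_loss(X, H)
  expect_equal(reconstruction_loss(X, X + 3 * (H - X)), 9 * base)
  expect_error(reconstruction_loss(X, H[, 1:3]), "mismatch")
})

test_that("local summaries are neighbour means through a sigmoid", {
  g <- build_knn_graph(rbind(c(0, 0), c(1, 0)), k = 1)
  expect_equal(local_summary(matrix(0, 2, 3), g), matrix(0.5, 2, 3),
               ignore_attr = TRUE)
  # one neighbour with z = ln 3 gives sigmoid(ln 3) = 3/4
  Z <- matrix(c(log(3), log(3)), 2, 1)
  expect_equal(local_summary(Z, g)[1, 1], 0.75)
  # cancelling neighbours give 0.5
  g3 <- structure(list(adjacency = Matrix::sparseMatrix(
    i = c(1, 1, 2, 3), j = c(2, 3, 1, 1), x = 1, dims = c(3, 3)),
    neighbor_sets = list(c(2L, 3L), 1L, 1L)), class = "neighbor_graph")
  Z3 <- rbind(c(0, 0), c(1, 1), c(-1, -1))
  expect_equal(local_summary(Z3, g3)[1, ], c(0.5, 0.5))
})

test_that("discriminator scores follow the bilinear closed form", {
  expect_equal(discriminator_score(c(1, 2), c(3, 4), matrix(0, 2, 2)), 0.5)
  e1 <- c(1, 0)
  expect_equal(discriminator_score(e1, e1, diag(2)), plogis(1),
               tolerance = 1e-12)
  # bilinearity: doubling z doubles the logit
  set.seed(2)
  z <- rnorm(3); g <- rnorm(3); W <- matrix(rnorm(9), 3, 3)
  logit <- qlogis(discriminator_score(z, g, W))
  expect_equal(qlogis(discriminator_score(2 * z, g, W)), 2 * logit,
               tolerance = 1e-9)
})

test_that("contrastive loss sits at ln 2 with a zero discriminator", {
  set.seed(5)
  g <- build_knn_graph(matrix(runif(40), 20, 2), k = 3)
  Z <- matrix(rnorm(20 * 4), 20, 4)
  Zp <- Z[sample(20), ]
  l <- symmetric_contrastive_loss(Z, Zp, g, matrix(0, 4, 4))
  expect_equal(l$scl, log(2), tolerance = 1e-6)
  expect_equal(l$scl_corrupt, log(2), tolerance = 1e-6)
})

test_that("contrastive loss matches the scalar BCE oracle", {
  set.seed(6)
  coords <- matrix(runif(8), 4, 2)
  g <- build_knn_graph(coords, k = 1)
  Z <- matrix(rnorm(8), 4, 2)
  Zp <- matrix(rnorm(8), 4, 2)
  W <- diag(2)
  got <- symmetric_contrastive_loss(Z, Zp, g, W)
  oracle <- contrastive_loss_oracle(Z, Zp, g, W)
  expect_equal(got$scl, oracle$scl, tolerance = 1e-10)
  expect_equal(got$scl_corrupt, oracle$scl_corrupt, tolerance = 1e-10)
})

test_that("total loss combines components with the default weights", {
  cfg <- train_config()
  expect_equal(total_loss(0, 0, 0, cfg), 0)
  expect_equal(total_loss(0.1, log(2), log(2), cfg), 1 + 2 * log(2))
  cfg0 <- train_config(lambda2 = 0)
  expect_equal(total_loss(0.3, 5, 7, cfg0), 3)
})

test_that("training reduces the total and contrastive losses", {
  ds <- tiny_dataset(n_row = 8, n_col = 8, n_genes = 60, seed = 1)
  fm <- normalize_select_scale(ds, n_hvg = 60)
  g <- build_knn_graph(ds$coords, k = 3)
  cfg <- train_config(epochs = 150, seed = 3)
  out <- train_representation(fm, g, cfg)
  h <- out$loss_history
  expect_lt(tail(h$total, 1), h$total[1])
  expect_equal(h$scl[1], log(2), tolerance = 1e-6)
  expect_lt(tail(h$scl, 1), log(2))
})

test_that("training is deterministic and frozen at a zero objective", {
  ds <- tiny_dataset(n_row = 5, n_col = 5, n_genes = 30, seed = 2)
  fm <- normalize_select_scale(ds, n_hvg = 30)
  g <- build_knn_graph(ds$coords, k = 3)
  cfg <- train_config(epochs = 20, seed = 7)
  a <- train_representation(fm, g, cfg)
  b <- train_representation(fm, g, cfg)
  expect_identical(a$loss_history, b$loss_history)
  expect_identical(a$Z_s, b$Z_s)

  cfg0 <- train_config(epochs = 10, lambda1 = 0, lambda2 = 0, seed = 7)
  frozen <- train_representation(fm, g, cfg0)
  init <- local({
    set.seed(7)
    list(W_e = spatialcontrast:::glorot_init(ncol(fm$values), 64),
         b_e = rep(0, 64))
  })
  expect_equal(frozen$params$W_e, init$W_e, ignore_attr = TRUE)
  expect_equal(as.vector(frozen$params$b_e), init$b_e)
})

test_that("trained embeddings are smoother along edges than non-edges", {
  ds <- tiny_dataset(n_row = 8, n_col = 8, n_genes = 60, seed = 4)
  fm <- normalize_select_scale(ds, n_hvg = 60)
  g <- build_knn_graph(ds$coords, k = 3)
  out <- train_representation(fm, g, train_config(epochs = 150, seed = 1))
  Z <- out$Z_s
  cosim <- function(i, j) {
    a <- Z[i, ]; b <- Z[j, ]
    sum(a * b) / sqrt(sum(a * a) * sum(b * b))
  }
  tm <- methods::as(g$adjacency, "TsparseMatrix")
  edges <- cbind(tm@i + 1L, tm@j + 1L)
  edges <- edges[edges[, 1] < edges[, 2], ]
  set.seed(42)
  n <- nrow(Z)
  non <- matrix(sample(n, 2 * nrow(edges), replace = TRUE), ncol = 2)
  keep <- non[, 1] != non[, 2] & g$adjacency[non] == 0
  non <- non[keep, ][seq_len(min(sum(keep), nrow(edges))), ]
  edge_sim <- mean(apply(edges, 1, function(e) cosim(e[1], e[2])))
  non_sim <- mean(apply(non, 1, function(e) cosim(e[1], e[2])))
  expect_gt(edge_sim, non_sim)
})
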