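#' Training configuration for the representation model
#'
#' @param d_latent latent dimensionality of the spot embedding (default 64).
#' @param lr Adam learning rate (default 1e-3).
#' @param epochs training epochs; 600 for clustering and multi-slice
#'   integration, 1200 when the representation feeds deconvolution.
#' @param lambda1 weight of the expression self-reconstruction loss
#'   (default 10).
#' @param lambda2 weight of the symmetric contrastive loss (default 1).
#' @param weight_decay Adam weight decay (default 0).
#' @param seed RNG seed controlling initialization and the per-epoch
#'   corruption permutations.
#' @return An object of class `train_config`.
#' @export
train_config <- function(d_latent = 64, lr = 1e-3, epochs = 600,
                         lambda1 = 10, lambda2 = 1, weight_decay = 0,
                         seed = 0) {
  stopifnot(epochs >= 0, lambda1 >= 0, lambda2 >= 0, d_latent >= 1, lr > 0)
  structure(list(d_latent = as.integer(d_latent), lr = lr,
                 epochs = as.integer(epochs), lambda1 = lambda1,
                 lambda2 = lambda2, weight_decay = weight_decay,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Single graph-convolution layer
#'
#' Computes `activation(A_norm %*% X %*% W + b)`: each item's features are
#' aggregated over its (self-loop-augmented) neighbourhood before the linear
#' map. The encoder uses ReLU, the decoder output layer the identity.
#'
#' @param X items x features input matrix.
#' @param A_norm a [symmetric_normalize()] result (or plain matrix).
#' @param W weight matrix (features x output).
#' @param b bias vector (length output).
#' @param activation `"relu"` or `"identity"`.
#' @return items x output matrix.
#' @export
gcn_layer <- function(X, A_norm, W, b, activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  a <- if (inherits(A_norm, "normalized_adjacency")) A_norm$matrix else A_norm
  X <- as.matrix(X)
  if (nrow(X) != ncol(a)) stop("X rows must match adjacency dimension")
  if (ncol(X) != nrow(W)) stop("W rows must match X columns")
  if (length(b) != ncol(W)) stop("bias length must match W columns")
  out <- as.matrix(a %*% X) %*% W
  out <- sweep(out, 2, b, "+")
  if (activation == "relu") out <- pmax(out, 0)
  out
}

#' Expression self-reconstruction loss
#'
#' Squared Frobenius norm of `X - H`, i.e. the sum over spots of the squared
#' distance between original and reconstructed expression.
#'
#' @param X original features.
#' @param H reconstruction of the same shape.
#' @return non-negative scalar.
#' @export
reconstruction_loss <- function(X, H) {
  X <- as.matrix(X); H <- as.matrix(H)
  if (!all(dim(X) == dim(H))) stop("shape mismatch between X and H")
  sum((X - H)^2)
}

# Row-normalized adjacency (no self-loops): row i averages over N_i.
.neighbor_mean_operator <- function(g) {
  a <- g$adjacency
  deg <- Matrix::rowSums(a)
  Matrix::Diagonal(nrow(a), ifelse(deg > 0, 1 / deg, 0)) %*% a
}

#' Local context summaries
#'
#' For each spot, the sigmoid of the mean embedding of its immediate graph
#' neighbours (self excluded). Spots with an empty neighbour set (cannot
#' occur after graph construction) fall back to their own embedding.
#'
#' @param Z items x d embedding matrix.
#' @param g a [build_knn_graph()] result aligned with the rows of `Z`.
#' @return items x d matrix of summaries in (0, 1).
#' @export
local_summary <- function(Z, g) {
  Z <- as.matrix(Z)
  if (nrow(Z) != nrow(g$adjacency)) stop("Z rows must match graph nodes")
  s <- .neighbor_mean_operator(g)
  m <- as.matrix(s %*% Z)
  empty <- Matrix::rowSums(g$adjacency) == 0
  if (any(empty)) m[empty, ] <- Z[empty, , drop = FALSE]
  stats::plogis(m)
}

#' Bilinear discriminator score
#'
#' Probability that an (embedding, local summary) pair is a positive pair:
#' `sigmoid(z' W g)`.
#'
#' @param z embedding vector or items x d matrix.
#' @param g summary vector or items x d matrix (rows paired with `z`).
#' @param W d x d bilinear weight matrix.
#' @return probability (vector when matrices are passed).
#' @export
discriminator_score <- function(z, g, W) {
  z <- rbind(z); g <- rbind(g)
  if (ncol(z) != nrow(W) || ncol(g) != ncol(W)) stop("dimension mismatch")
  logit <- rowSums((z %*% W) * g)
  out <- stats::plogis(logit)
  if (length(out) == 1) out <- unname(out[1])
  out
}

.clamped_log <- function(p, eps = 1e-12) log(pmax(p, eps))

#' Symmetric contrastive loss
#'
#' Deep-Graph-Infomax-style binary cross-entropy over positive pairs
#' (embedding, own local summary) and negative pairs (corrupted embedding,
#' same summary), plus the mirrored loss computed with the corrupted view's
#' summaries. Probabilities are clamped at 1e-12 before taking logs.
#'
#' @param Z clean-view embeddings.
#' @param Z_prime corrupted-view embeddings (same graph, shuffled features).
#' @param g the shared [build_knn_graph()] result.
#' @param W_disc bilinear discriminator weights.
#' @return list with elements `scl` and `scl_corrupt`.
#' @export
symmetric_contrastive_loss <- function(Z, Z_prime, g, W_disc) {
  Z <- as.matrix(Z); Z_prime <- as.matrix(Z_prime)
  if (!all(dim(Z) == dim(Z_prime))) stop("Z and Z_prime must share a shape")
  n <- nrow(Z)
  G1 <- local_summary(Z, g)
  G2 <- local_summary(Z_prime, g)
  pos1 <- discriminator_score(Z, G1, W_disc)
  neg1 <- discriminator_score(Z_prime, G1, W_disc)
  pos2 <- discriminator_score(Z_prime, G2, W_disc)
  neg2 <- discriminator_score(Z, G2, W_disc)
  scl <- -(sum(.clamped_log(pos1)) + sum(.clamped_log(1 - neg1))) / (2 * n)
  sclc <- -(sum(.clamped_log(pos2)) + sum(.clamped_log(1 - neg2))) / (2 * n)
  list(scl = scl, scl_corrupt = sclc)
}

#' Combine the training losses
#'
#' `lambda1 * L_recon + lambda2 * (L_SCL + L_SCL_corrupt)`.
#'
#' @param L_recon reconstruction loss.
#' @param L_SCL contrastive loss on the clean view.
#' @param L_SCL_corrupt mirrored contrastive loss on the corrupted view.
#' @param cfg a [train_config()].
#' @return scalar total loss.
#' @export
total_loss <- function(L_recon, L_SCL, L_SCL_corrupt, cfg = train_config()) {
  stopifnot(is.finite(L_recon), is.finite(L_SCL), is.finite(L_SCL_corrupt))
  cfg$lambda1 * L_recon + cfg$lambda2 * (L_SCL + L_SCL_corrupt)
}

#' Train the graph contrastive autoencoder
#'
#' One-layer GCN encoder (genes to `d_latent`, ReLU) and one-layer GCN
#' decoder (`d_latent` back to genes, identity), trained with Adam on the
#' weighted sum of the expression self-reconstruction loss and the symmetric
#' contrastive loss. Each epoch draws a fresh corruption permutation of the
#' feature rows; both views share the encoder and the graph. The bilinear
#' discriminator starts at zero, so the contrastive losses start exactly at
#' chance level log(2). Gradients are computed analytically.
#'
#' @param X a [feature_matrix()] (or matrix) of preprocessed expression,
#'   rows aligned with the graph nodes.
#' @param g a [build_knn_graph()] result.
#' @param cfg a [train_config()].
#' @param A_norm optional precomputed [symmetric_normalize()] result.
#' @return An object of class `representation_output` with `Z_s` (latent
#'   embeddings), `H_s` (reconstructed expression), `loss_history`
#'   (data.frame: epoch, total, recon, scl, scl_corrupt), `params`, and
#'   `config`.
#' @export
train_representation <- function(X, g, cfg = train_config(), A_norm = NULL) {
  fm <- inherits(X, "feature_matrix")
  vals <- if (fm) X$values else as.matrix(X)
  n <- nrow(vals); p <- ncol(vals); d <- cfg$d_latent
  if (n != nrow(g$adjacency)) stop("X rows must align with graph nodes")
  if (is.null(A_norm)) A_norm <- symmetric_normalize(g)
  At <- A_norm$matrix
  S <- .neighbor_mean_operator(g)
  St <- Matrix::t(S)

  set.seed(cfg$seed)
  params <- list(W_e = glorot_init(p, d), b_e = rep(0, d),
                 W_d = glorot_init(d, p), b_d = rep(0, p),
                 W_disc = matrix(0, d, d))
  state <- adam_state(params)
  AX <- as.matrix(At %*% vals)

  hist <- matrix(NA_real_, max(cfg$epochs, 0), 5)
  lam1 <- cfg$lambda1; lam2 <- cfg$lambda2

  for (epoch in seq_len(cfg$epochs)) {
    perm <- sample.int(n)
    Xp <- vals[perm, , drop = FALSE]
    AXp <- as.matrix(At %*% Xp)

    # forward
    U <- sweep(AX %*% params$W_e, 2, params$b_e, "+");  Z <- pmax(U, 0)
    Up <- sweep(AXp %*% params$W_e, 2, params$b_e, "+"); Zp <- pmax(Up, 0)
    AZ <- as.matrix(At %*% Z)
    H <- sweep(AZ %*% params$W_d, 2, params$b_d, "+")
    R <- H - vals
    l_rec <- sum(R * R)

    M1 <- as.matrix(S %*% Z);  G1 <- stats::plogis(M1)
    M2 <- as.matrix(S %*% Zp); G2 <- stats::plogis(M2)
    ZW <- Z %*% params$W_disc
    ZpW <- Zp %*% params$W_disc
    a_pos1 <- rowSums(ZW * G1);  a_neg1 <- rowSums(ZpW * G1)
    a_pos2 <- rowSums(ZpW * G2); a_neg2 <- rowSums(ZW * G2)
    l_scl <- -(sum(logsigmoid(a_pos1)) + sum(logsigmoid(-a_neg1))) / (2 * n)
    l_sclc <- -(sum(logsigmoid(a_pos2)) + sum(logsigmoid(-a_neg2))) / (2 * n)
    tot <- lam1 * l_rec + lam2 * (l_scl + l_sclc)
    hist[epoch, ] <- c(epoch, tot, l_rec, l_scl, l_sclc)
    if (!is.finite(tot)) {
      stop(sprintf("non-finite loss at epoch %d (recon=%g scl=%g scl_corrupt=%g)",
                   epoch, l_rec, l_scl, l_sclc))
    }

    # backward: BCE gradients w.r.t. logits, scaled by lambda2/(2n)
    sc <- lam2 / (2 * n)
    cP1 <- sc * (stats::plogis(a_pos1) - 1)
    cN1 <- sc * stats::plogis(a_neg1)
    cP2 <- sc * (stats::plogis(a_pos2) - 1)
    cN2 <- sc * stats::plogis(a_neg2)

    dW_disc <- crossprod(Z * cP1, G1) + crossprod(Zp * cN1, G1) +
      crossprod(Zp * cP2, G2) + crossprod(Z * cN2, G2)

    GWt1 <- G1 %*% t(params$W_disc)
    GWt2 <- G2 %*% t(params$W_disc)
    dZ <- cP1 * GWt1 + cN2 * GWt2
    dZp <- cN1 * GWt1 + cP2 * GWt2
    dG1 <- cP1 * ZW + cN1 * ZpW
    dG2 <- cP2 * ZpW + cN2 * ZW
    dZ <- dZ + as.matrix(St %*% (dG1 * G1 * (1 - G1)))
    dZp <- dZp + as.matrix(St %*% (dG2 * G2 * (1 - G2)))

    # reconstruction path
    Rw <- 2 * lam1 * R
    dW_d <- crossprod(AZ, Rw)
    db_d <- colSums(Rw)
    dZ <- dZ + as.matrix(At %*% Rw) %*% t(params$W_d)

    dU <- dZ * (U > 0)
    dUp <- dZp * (Up > 0)
    dW_e <- crossprod(AX, dU) + crossprod(AXp, dUp)
    db_e <- colSums(dU) + colSums(dUp)

    upd <- adam_step(params,
                     list(W_e = dW_e, b_e = db_e, W_d = dW_d, b_d = db_d,
                          W_disc = dW_disc),
                     state, cfg$lr, weight_decay = cfg$weight_decay)
    params <- upd$params
    state <- upd$state
  }

  # final forward pass with trained parameters
  U <- sweep(AX %*% params$W_e, 2, params$b_e, "+")
  Z <- pmax(U, 0)
  H <- sweep(as.matrix(At %*% Z) %*% params$W_d, 2, params$b_d, "+")
  ids <- if (fm) X$item_ids else rownames(vals)
  rownames(Z) <- ids
  dimnames(H) <- list(ids, if (fm) X$feature_ids else colnames(vals))
  loss_history <- stats::setNames(as.data.frame(hist),
                                  c("epoch", "total", "recon", "scl", "scl_corrupt"))
  structure(list(Z_s = Z, H_s = H, loss_history = loss_history,
                 params = params, config = cfg, A_norm = A_norm),
            class = "representation_output")
}

#' @export
print.representation_output <- function(x, ...) {
  cat(sprintf("representation_output: %d spots, d_latent = %d, %d epochs\n",
              nrow(x$Z_s), ncol(x$Z_s), nrow(x$loss_history)))
  if (nrow(x$loss_history) > 0) {
    cat(sprintf(" final loss: total %.4g (recon %.4g, scl %.4g, scl_corrupt %.4g)\n",
                utils::tail(x$loss_history$total, 1),
                utils::tail(x$loss_history$recon, 1),
                utils::tail(x$loss_history$scl, 1),
                utils::tail(x$loss_history$scl_corrupt, 1)))
  }
  invisible(x)
}
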