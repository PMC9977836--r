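#' Configuration for mapping-matrix training
#'
#' @param alpha weight of the spatially informed contrastive term
#'   (default 1).
#' @param beta weight of the expression alignment term (default 10).
#' @param tau softmax temperature for the cosine similarities (default 1).
#' @param lr Adam learning rate (default 1e-3).
#' @param epochs training epochs (default 1200).
#' @param seed RNG seed.
#' @param negatives `"all"` (denominator over all spots p != i, the default)
#'   or `"nonneighbors"` (denominator over the positive plus spatially
#'   non-adjacent spots only).
#' @return An object of class `mapping_config`.
#' @export
mapping_config <- function(alpha = 1, beta = 10, tau = 1, lr = 1e-3,
                           epochs = 1200, seed = 0,
                           negatives = c("all", "nonneighbors")) {
  stopifnot(tau > 0, alpha >= 0, beta >= 0, epochs >= 0)
  structure(list(alpha = alpha, beta = beta, tau = tau, lr = lr,
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 negatives = match.arg(negatives)),
            class = "mapping_config")
}

#' Train the single-cell reference autoencoder
#'
#' One-hidden-layer dense autoencoder (genes -> `d_latent` with ReLU,
#' `d_latent` -> genes with identity) trained on mean squared reconstruction
#' error with Adam. Its reconstruction `H_c` supplies the denoised cell
#' expression used by the mapping matrix. `epochs = 0` returns the untrained
#' forward pass.
#'
#' @param X_c a [feature_matrix()] (cells x genes) restricted to the genes
#'   shared with the spatial data.
#' @param d_latent hidden width (default 64).
#' @param lr Adam learning rate (default 1e-3).
#' @param epochs training epochs (default 1200).
#' @param seed RNG seed.
#' @return An object of class `reference_autoencoder` with `H_c`
#'   (reconstructed cell expression), `Q` (latent cell representations),
#'   `params` and `loss_history` (per-epoch MSE).
#' @export
train_reference_autoencoder <- function(X_c, d_latent = 64, lr = 1e-3,
                                        epochs = 1200, seed = 0) {
  fm <- inherits(X_c, "feature_matrix")
  X <- if (fm) X_c$values else as.matrix(X_c)
  n <- nrow(X); p <- ncol(X)
  set.seed(seed)
  params <- list(W1 = glorot_init(p, d_latent), b1 = rep(0, d_latent),
                 W2 = glorot_init(d_latent, p), b2 = rep(0, p))
  state <- adam_state(params)
  hist <- numeric(epochs)
  for (epoch in seq_len(epochs)) {
    U <- sweep(X %*% params$W1, 2, params$b1, "+")
    Q <- pmax(U, 0)
    Y <- sweep(Q %*% params$W2, 2, params$b2, "+")
    R <- Y - X
    mse <- mean(R * R)
    hist[epoch] <- mse
    if (!is.finite(mse)) stop(sprintf("non-finite loss at epoch %d", epoch))
    dY <- 2 * R / length(R)
    dW2 <- crossprod(Q, dY); db2 <- colSums(dY)
    dQ <- dY %*% t(params$W2)
    dU <- dQ * (U > 0)
    dW1 <- crossprod(X, dU); db1 <- colSums(dU)
    upd <- adam_step(params, list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2),
                     state, lr)
    params <- upd$params; state <- upd$state
  }
  U <- sweep(X %*% params$W1, 2, params$b1, "+")
  Q <- pmax(U, 0)
  H_c <- sweep(Q %*% params$W2, 2, params$b2, "+")
  dimnames(H_c) <- dimnames(X)
  rownames(Q) <- rownames(X)
  structure(list(H_c = H_c, Q = Q, params = params, d_latent = d_latent,
                 loss_history = hist),
            class = "reference_autoencoder")
}

#' @export
print.reference_autoencoder <- function(x, ...) {
  cat(sprintf("reference_autoencoder: %d cells x %d genes, d_latent = %d\n",
              nrow(x$H_c), ncol(x$H_c), x$d_latent))
  invisible(x)
}

.mapping_M <- function(M) {
  if (inherits(M, "mapping_matrix")) M$M else as.matrix(M)
}

#' Predict spot expression from the mapping matrix
#'
#' `H'_s = t(M) %*% H_c`: each spot's predicted profile is the
#' probability-weighted average of the cell profiles mapped onto it.
#'
#' @param M a `mapping_matrix` (or cells x spots column-stochastic matrix).
#' @param H_c cells x genes expression matrix.
#' @return spots x genes predicted expression.
#' @export
spot_expression_from_mapping <- function(M, H_c) {
  M <- .mapping_M(M)
  H_c <- as.matrix(H_c)
  if (nrow(M) != nrow(H_c)) stop("M rows must match H_c rows (cells)")
  crossprod(M, H_c)
}

.row_normalize_unit <- function(H, warn = TRUE) {
  nrm <- sqrt(rowSums(H * H))
  zero <- nrm == 0
  if (any(zero) && warn) warning("zero-norm rows; their cosine set to 0")
  Hn <- H / ifelse(nrm > 0, nrm, 1)
  Hn[zero, ] <- 0
  Hn
}

.logsumexp_rows_excl_diag <- function(L) {
  # log sum_{p != i} exp(L[i, p]) for each row i
  n <- nrow(L)
  vapply(seq_len(n), function(i) {
    v <- L[i, -i]
    m <- max(v)
    m + log(sum(exp(v - m)))
  }, numeric(1))
}

#' Spatially informed mapping objective
#'
#' InfoNCE-style contrastive term over spatial neighbours plus an expression
#' alignment term: for each spot i the positives are its graph neighbours
#' j (cosine similarity between the predicted profile of i and the
#' reconstructed profiles h_j, temperature `tau`), with the softmax
#' denominator over all spots p != i; plus `beta * ||H_s - H'_s||_F^2`.
#'
#' @param H_s spots x genes reconstructed spot expression.
#' @param H_prime spots x genes predicted spot expression.
#' @param g a [build_knn_graph()] result over the spots.
#' @param cfg a [mapping_config()].
#' @return scalar objective value.
#' @export
mapping_objective <- function(H_s, H_prime, g, cfg = mapping_config()) {
  H_s <- as.matrix(H_s); H_prime <- as.matrix(H_prime)
  if (!all(dim(H_s) == dim(H_prime))) stop("shape mismatch")
  n <- nrow(H_s)
  Un <- .row_normalize_unit(H_prime)
  Vn <- .row_normalize_unit(H_s)
  S <- Un %*% t(Vn) / cfg$tau
  term1 <- 0
  if (cfg$alpha > 0) {
    if (cfg$negatives == "all") {
      lse <- .logsumexp_rows_excl_diag(S)
      for (i in seq_len(n)) {
        nbr <- g$neighbor_sets[[i]]
        term1 <- term1 - cfg$alpha * sum(S[i, nbr] - lse[i])
      }
    } else {
      for (i in seq_len(n)) {
        nbr <- g$neighbor_sets[[i]]
        neg <- setdiff(seq_len(n), c(i, nbr))
        for (j in nbr) {
          v <- S[i, c(j, neg)]
          m <- max(v)
          term1 <- term1 - cfg$alpha * (S[i, j] - (m + log(sum(exp(v - m)))))
        }
      }
    }
  }
  term2 <- cfg$beta * sum((H_s - H_prime)^2)
  term1 + term2
}

#' Fit the cell-to-spot mapping matrix
#'
#' Learns a cells x spots probability matrix M, parametrized as a per-column
#' softmax over cells so every column sums to one by construction, by
#' minimizing [mapping_objective()] with Adam. Training uses only expression
#' and the spot graph; no annotation labels are consulted.
#'
#' @param H_s spots x genes reconstructed spot expression (from
#'   [train_representation()]).
#' @param H_c cells x genes reconstructed cell expression (from
#'   [train_reference_autoencoder()]).
#' @param g a [build_knn_graph()] result over the spots.
#' @param cfg a [mapping_config()].
#' @param init_logits optional cells x spots matrix initializing the
#'   unconstrained parameters (default: seeded Gaussian, sd 0.1).
#' @return An object of class `mapping_matrix` with `M` (column-stochastic),
#'   `logits` and `loss_history`.
#' @export
fit_mapping_matrix <- function(H_s, H_c, g, cfg = mapping_config(),
                               init_logits = NULL) {
  H_s <- as.matrix(H_s)
  H_c <- if (inherits(H_c, "reference_autoencoder")) H_c$H_c else as.matrix(H_c)
  if (ncol(H_s) != ncol(H_c)) stop("H_s and H_c must share the gene axis")
  n_spot <- nrow(H_s); n_cell <- nrow(H_c)
  if (n_spot != nrow(g$adjacency)) stop("graph must align with spots")
  set.seed(cfg$seed)
  logits <- if (is.null(init_logits)) {
    matrix(stats::rnorm(n_cell * n_spot, sd = 0.1), n_cell, n_spot)
  } else {
    stopifnot(all(dim(init_logits) == c(n_cell, n_spot)))
    as.matrix(init_logits)
  }
  state <- adam_state(list(logits = logits))
  Vn <- .row_normalize_unit(H_s, warn = FALSE)
  # neighbour indicator matrix and per-spot neighbour counts
  nbr_counts <- vapply(g$neighbor_sets, length, numeric(1))
  Nb <- as.matrix(g$adjacency > 0) * 1
  hist <- numeric(cfg$epochs)
  col_softmax <- function(L) {
    e <- exp(sweep(L, 2, apply(L, 2, max), "-"))
    sweep(e, 2, colSums(e), "/")
  }
  for (epoch in seq_len(cfg$epochs)) {
    M <- col_softmax(logits)
    Hp <- crossprod(M, H_c)                    # spots x genes
    nrm <- sqrt(rowSums(Hp * Hp))
    zero <- nrm == 0
    safe <- ifelse(nrm > 0, nrm, 1)
    Un <- Hp / safe
    Un[zero, ] <- 0
    S <- Un %*% t(Vn) / cfg$tau

    # loss
    lse <- .logsumexp_rows_excl_diag(S)
    term1 <- -cfg$alpha * sum((rowSums(S * Nb)) - nbr_counts * lse)
    D <- Hp - H_s
    term2 <- cfg$beta * sum(D * D)
    hist[epoch] <- term1 + term2
    if (!is.finite(hist[epoch])) {
      stop(sprintf("non-finite mapping objective at epoch %d", epoch))
    }

    # gradient wrt similarity entries: -alpha/tau * (Nb - |N_i| * softmax)
    P <- exp(S - lse)                           # softmax over p != i, rowwise
    diag(P) <- 0
    Wg <- (-cfg$alpha / cfg$tau) * (Nb - nbr_counts * P)
    # cosine backprop onto Hp (targets Vn are constants)
    rs <- rowSums(Wg * S) * cfg$tau            # sum_p w_ip * s_ip (unscaled sim)
    dHp <- (Wg %*% Vn - rs * Un) / safe
    dHp[zero, ] <- 0
    dHp <- dHp + 2 * cfg$beta * D
    dM <- H_c %*% t(dHp)                        # cells x spots
    dlogits <- M * sweep(dM, 2, colSums(M * dM), "-")
    upd <- adam_step(list(logits = logits), list(logits = dlogits), state,
                     cfg$lr)
    logits <- upd$params$logits
    state <- upd$state
  }
  M <- col_softmax(logits)
  dimnames(M) <- list(rownames(H_c), rownames(H_s))
  structure(list(M = M, logits = logits, loss_history = hist, config = cfg),
            class = "mapping_matrix")
}

#' @export
print.mapping_matrix <- function(x, ...) {
  cat(sprintf("mapping_matrix: %d cells x %d spots (columns sum to 1)\n",
              nrow(x$M), ncol(x$M)))
  invisible(x)
}

#' One-hot annotation matrix
#'
#' @param labels per-item annotation labels.
#' @param label_names optional ordered label universe (defaults to the
#'   sorted unique labels).
#' @return An object of class `annotation_matrix` wrapping the one-hot
#'   items x labels matrix `S`.
#' @export
annotation_matrix <- function(labels, label_names = NULL) {
  labels <- as.character(labels)
  if (is.null(label_names)) label_names <- sort(unique(labels))
  if (!all(labels %in% label_names)) stop("labels outside label_names")
  S <- matrix(0, length(labels), length(label_names),
              dimnames = list(names(labels), label_names))
  S[cbind(seq_along(labels), match(labels, label_names))] <- 1
  structure(list(S = S, label_names = label_names),
            class = "annotation_matrix")
}

.annot_S <- function(x) if (inherits(x, "annotation_matrix")) x$S else as.matrix(x)

#' Transfer cell annotations onto spots
#'
#' For each spot (column of M), only the `ceiling(top_frac * N_cell)`
#' highest-probability cells are retained (the rest are zeroed, without
#' renormalization unless requested), then `P_spot = t(M_filtered) %*%
#' S_cell`.
#'
#' @param M a `mapping_matrix` or cells x spots matrix.
#' @param S_cell an [annotation_matrix()] over cells (or one-hot matrix).
#' @param top_frac fraction of cells retained per spot (default 0.1).
#' @param renormalize renormalize retained scores to sum 1 per spot
#'   (default FALSE, matching the plain top-fraction filter).
#' @return spots x labels probability matrix.
#' @export
annotations_to_spots <- function(M, S_cell, top_frac = 0.1,
                                 renormalize = FALSE) {
  M <- .mapping_M(M)
  S <- .annot_S(S_cell)
  if (nrow(S) != nrow(M)) stop("S_cell rows must align with M rows")
  if (top_frac <= 0 || top_frac > 1) stop("top_frac must be in (0, 1]")
  n_keep <- ceiling(top_frac * nrow(M))
  Mf <- apply(M, 2, function(col) {
    keep <- order(col, decreasing = TRUE)[seq_len(n_keep)]
    out <- numeric(length(col))
    out[keep] <- col[keep]
    if (renormalize && sum(out) > 0) out <- out / sum(out)
    out
  })
  P <- crossprod(Mf, S)
  dimnames(P) <- list(colnames(M), colnames(S))
  P
}

#' Aggregate spot annotation probabilities into domains
#'
#' `P_domain = t(S_spot) %*% P_spot`: per-domain sums of the member spots'
#' annotation probability rows.
#'
#' @param P_spot spots x labels probability matrix.
#' @param S_spot an [annotation_matrix()] over spots (one-hot spot x domain).
#' @return domains x labels matrix.
#' @export
annotations_to_domains <- function(P_spot, S_spot) {
  S <- .annot_S(S_spot)
  P_spot <- as.matrix(P_spot)
  if (nrow(S) != nrow(P_spot)) stop("S_spot rows must align with P_spot rows")
  out <- crossprod(S, P_spot)
  dimnames(out) <- list(colnames(S), colnames(P_spot))
  out
}

#' Per-spot cell-type proportions from spot annotation scores
#'
#' Rows of `P_spot` normalized to sum 1 (zero rows stay zero) so they are
#' comparable to true mixture proportions.
#'
#' @param P_spot spots x labels matrix of non-negative scores.
#' @return spots x labels proportion matrix.
#' @export
proportions_from_scores <- function(P_spot) {
  P_spot <- as.matrix(P_spot)
  rs <- rowSums(P_spot)
  P_spot / ifelse(rs > 0, rs, 1)
}

.minmax <- function(x) {
  r <- range(x)
  if (r[2] == r[1]) return(rep(0, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

.jsd <- function(p, q) {
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    sel <- a > 0
    sum(a[sel] * log(a[sel] / b[sel]))
  }
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

.ssim_1d <- function(x, y, K1 = 0.01, K2 = 0.03, L = 1) {
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  mx <- mean(x); my <- mean(y)
  vx <- stats::var(x); vy <- stats::var(y)
  cxy <- stats::cov(x, y)
  ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
}

#' Deconvolution accuracy metrics
#'
#' Per cell type (column across spots): Pearson correlation (PCC; constant
#' columns reported as 0 with a warning), SSIM and RMSE on min-max-scaled
#' vectors (global, non-windowed SSIM with standard constants K1=0.01,
#' K2=0.03, L=1), and Jensen-Shannon divergence (natural log, so bounded by
#' log 2) between the column vectors each normalized to sum 1.
#'
#' @param est spots x types estimated proportions.
#' @param truth spots x types true proportions (rows on the simplex).
#' @return list with `per_type` (data.frame: type, pcc, ssim, rmse, jsd),
#'   `means` (named vector), and `jsd_base = "e"`.
#' @export
deconvolution_metrics <- function(est, truth) {
  est <- as.matrix(est); truth <- as.matrix(truth)
  if (!all(dim(est) == dim(truth))) stop("shape mismatch")
  types <- colnames(truth)
  if (is.null(types)) types <- paste0("type", seq_len(ncol(truth)))
  per <- lapply(seq_len(ncol(truth)), function(j) {
    e <- est[, j]; t <- truth[, j]
    pcc <- if (stats::sd(e) == 0 || stats::sd(t) == 0) {
      warning("constant column; PCC reported as 0")
      0
    } else stats::cor(e, t)
    es <- .minmax(e); ts <- .minmax(t)
    data.frame(type = types[j], pcc = pcc,
               ssim = .ssim_1d(es, ts),
               rmse = sqrt(mean((es - ts)^2)),
               jsd = if (sum(e) > 0 && sum(t) > 0) .jsd(e, t) else NA_real_)
  })
  per <- do.call(rbind, per)
  means <- c(pcc = mean(per$pcc), ssim = mean(per$ssim),
             rmse = mean(per$rmse), jsd = mean(per$jsd, na.rm = TRUE))
  list(per_type = per, means = means, jsd_base = "e")
}
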