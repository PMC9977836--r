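#' Integrate multiple slices through a joint graph
#'
#' Pools two or more (pre-aligned) slices, preprocesses the pooled counts
#' with a single highly-variable-gene set, builds one k-NN graph on the
#' pooled coordinates so neighbourhoods cross slice boundaries, and trains
#' the representation model on the joint data. No explicit batch covariate
#' enters the model: batch effects are removed implicitly through
#' cross-slice neighbourhood smoothing and contrastive learning.
#'
#' @param slices list of at least two [spatial_dataset()] objects.
#' @param transforms optional per-slice 2 x 3 rigid transforms (see
#'   [build_joint_graph()]).
#' @param cfg a [train_config()].
#' @param k neighbours per spot in the joint graph (default 3).
#' @param n_hvg highly variable genes for the pooled preprocessing.
#' @return An object of class `integrated_dataset` with `combined`
#'   (pooled [spatial_dataset()] carrying batch labels), `joint_graph`,
#'   `features` (pooled [feature_matrix()]), `Z_joint` and `H_joint`.
#' @export
integrate_slices <- function(slices, transforms = NULL, cfg = train_config(),
                             k = 3, n_hvg = 3000) {
  jg <- build_joint_graph(slices, transforms = transforms, k = k)
  feats <- normalize_select_scale(jg$combined, n_hvg = n_hvg)
  rep_out <- train_representation(feats, jg$graph, cfg)
  structure(list(combined = jg$combined, joint_graph = jg$graph,
                 features = feats, Z_joint = rep_out$Z_s,
                 H_joint = rep_out$H_s, representation = rep_out),
            class = "integrated_dataset")
}

#' @export
print.integrated_dataset <- function(x, ...) {
  cat(sprintf("integrated_dataset: %d spots from %d slices\n",
              nrow(x$Z_joint), length(unique(x$combined$batch))))
  invisible(x)
}

#' Integration local inverse Simpson's index (iLISI)
#'
#' For each item, Gaussian-kernel weights over its 3 x perplexity nearest
#' neighbours are calibrated by binary search on the bandwidth so the weight
#' entropy matches `log(perplexity)`; the weighted batch-frequency vector p
#' then gives the local inverse Simpson index `1 / sum(p^2)`. The returned
#' score is the mean over items: 1 means no mixing, B means perfect mixing
#' of B batches. Invariant to rotation/translation of the embedding.
#'
#' @param embeddings items x d matrix.
#' @param batch_labels per-item batch labels.
#' @param perplexity effective neighbourhood size (default 30); must be
#'   smaller than N - 1.
#' @return mean iLISI (scalar >= 1).
#' @export
ilisi_score <- function(embeddings, batch_labels, perplexity = 30) {
  emb <- as.matrix(embeddings)
  n <- nrow(emb)
  if (n < 2) stop("need at least 2 items")
  if (length(batch_labels) != n) stop("batch label length mismatch")
  if (perplexity >= n - 1) stop("perplexity must be < N - 1")
  batch <- as.integer(factor(batch_labels))
  nb <- length(unique(batch))
  if (nb == 1) return(1)
  k <- min(n - 1, max(3, floor(3 * perplexity)))
  d2 <- as.matrix(stats::dist(emb))^2
  diag(d2) <- Inf
  target <- log(perplexity)
  scores <- vapply(seq_len(n), function(i) {
    ord <- order(d2[i, ])[seq_len(k)]
    di <- d2[i, ord]
    beta <- 1
    lo <- -Inf; hi <- Inf
    for (iter in 1:60) {
      w <- exp(-beta * (di - di[1]))
      sw <- sum(w)
      h <- log(sw) + beta * sum(w * (di - di[1])) / sw
      if (abs(h - target) < 1e-6) break
      if (h > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    w <- exp(-beta * (di - di[1]))
    p <- w / sum(w)
    freq <- vapply(seq_len(nb), function(b) sum(p[batch[ord] == b]), numeric(1))
    1 / sum(freq^2)
  }, numeric(1))
  mean(scores)
}
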