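#' Domain label container
#'
#' @param labels integer vector of 0-based domain ids (one per spot).
#' @param n_domains number of domains.
#' @param method provenance tag.
#' @return An object of class `domain_labels`.
#' @export
domain_labels <- function(labels, n_domains = length(unique(labels)),
                          method = "manual") {
  labels <- as.integer(labels)
  if (any(labels < 0) || any(labels >= n_domains)) {
    stop("labels must lie in [0, n_domains)")
  }
  structure(list(labels = labels, n_domains = as.integer(n_domains),
                 method = method),
            class = "domain_labels")
}

#' @export
print.domain_labels <- function(x, ...) {
  cat(sprintf("domain_labels: %d spots in %d domains (%s)\n",
              length(x$labels), x$n_domains, x$method))
  print(table(x$labels))
  invisible(x)
}

.label_vector <- function(x) {
  if (inherits(x, "domain_labels")) x$labels else x
}

.pca_scores <- function(H, n_pcs) {
  H <- as.matrix(H)
  r <- min(n_pcs, ncol(H), nrow(H) - 1)
  stats::prcomp(H, center = TRUE, scale. = FALSE, rank. = r)$x
}

#' Gaussian-mixture clustering of spot representations
#'
#' Reduces the representation (typically the reconstructed expression) to
#' `n_pcs` principal components and fits a Gaussian mixture with covariance
#' shared across components (mclust model "EEE"), assigning each spot its
#' maximum-posterior component. Falls back to a diagonal shared covariance
#' ("EEI", with a warning) if the shared full covariance is singular, and to
#' k-means as a last resort.
#'
#' @param H spots x features representation matrix (or a
#'   `representation_output`, in which case `H_s` is used).
#' @param n_clusters number of mixture components.
#' @param n_pcs number of principal components (default 20).
#' @param seed RNG seed.
#' @return A [domain_labels()] with 0-based labels.
#' @export
fit_mixture_clusters <- function(H, n_clusters, n_pcs = 20, seed = 0) {
  if (inherits(H, "representation_output")) H <- H$H_s
  H <- as.matrix(H)
  if (n_clusters < 1) stop("n_clusters must be >= 1")
  if (nrow(H) <= n_clusters) stop("need more spots than clusters")
  scores <- .pca_scores(H, n_pcs)
  set.seed(seed)
  if (n_clusters == 1) {
    return(domain_labels(rep(0L, nrow(H)), 1L, method = "gmm_eee"))
  }
  fit <- suppressWarnings(
    Mclust(scores, G = n_clusters, modelNames = "EEE",
                   verbose = FALSE))
  method <- "gmm_eee"
  if (is.null(fit)) {
    warning("shared full covariance was singular; falling back to diagonal")
    fit <- suppressWarnings(
      Mclust(scores, G = n_clusters, modelNames = "EEI",
                     verbose = FALSE))
    method <- "gmm_eei"
  }
  if (is.null(fit)) {
    warning("mixture fit failed; falling back to k-means")
    cl <- stats::kmeans(scores, centers = n_clusters, nstart = 10)
    return(domain_labels(cl$cluster - 1L, n_clusters, method = "kmeans"))
  }
  domain_labels(fit$classification - 1L, n_clusters, method = method)
}

#' Select the cluster count by silhouette
#'
#' Clusters the representation for each candidate count and returns the one
#' with the highest mean silhouette width on the PCA embedding (ties go to
#' the smaller count).
#'
#' @param H spots x features representation matrix.
#' @param k_range integer vector of candidate cluster counts, each in
#'   `[2, N-1]` (a single value is returned as-is).
#' @param n_pcs number of principal components (default 20).
#' @param seed RNG seed.
#' @return the selected cluster count (integer).
#' @export
choose_cluster_count <- function(H, k_range, n_pcs = 20, seed = 0) {
  if (inherits(H, "representation_output")) H <- H$H_s
  H <- as.matrix(H)
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) == 0) stop("empty cluster-count range")
  if (length(k_range) == 1) return(k_range)
  if (any(k_range < 2) || any(k_range > nrow(H) - 1)) {
    stop("cluster counts must lie in [2, N-1]")
  }
  scores <- .pca_scores(H, n_pcs)
  dmat <- stats::dist(scores)
  sil <- vapply(k_range, function(k) {
    lab <- fit_mixture_clusters(scores, k, n_pcs = ncol(scores), seed = seed)
    if (length(unique(lab$labels)) < 2) return(-Inf)
    mean(cluster::silhouette(lab$labels + 1L, dmat)[, "sil_width"])
  }, numeric(1))
  k_range[which.max(sil)]
}

#' Spatial refinement of domain labels
#'
#' One synchronous majority-vote pass: each spot collects the labels of all
#' other spots within Euclidean radius `r` (in the input coordinate units)
#' and is reassigned to the most frequent neighbourhood label. Ties between
#' top labels and empty neighbourhoods keep the current label; all votes are
#' taken from the pre-pass labels. Recommended only for coarse domains.
#'
#' @param labels a [domain_labels()] (or integer vector).
#' @param coords spots x 2 coordinate matrix.
#' @param r neighbourhood radius (default 50 coordinate units).
#' @return A [domain_labels()] of the same size.
#' @export
spatial_refine <- function(labels, coords, r = 50) {
  lab <- .label_vector(labels)
  coords <- as.matrix(coords)
  if (length(lab) != nrow(coords)) stop("coords must align with labels")
  if (r <= 0) stop("r must be positive")
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  out <- lab
  for (i in seq_along(lab)) {
    nbr <- which(d[i, ] <= r)
    if (length(nbr) == 0) next
    tab <- table(lab[nbr])
    mx <- max(tab)
    winners <- as.integer(names(tab)[tab == mx])
    if (length(winners) == 1 && winners != lab[i]) out[i] <- winners
  }
  nd <- if (inherits(labels, "domain_labels")) labels$n_domains else max(out) + 1L
  domain_labels(out, nd, method = "refined")
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions, computed with the
#' closed-form permutation-model formula from the contingency table.
#' Symmetric in its arguments and invariant to label permutation.
#'
#' @param pred predicted labels (a [domain_labels()] or vector).
#' @param truth reference labels (vector of the same length).
#' @return ARI in `[-1, 1]`; 1 for identical partitions, ~0 at chance.
#' @export
adjusted_rand_index <- function(pred, truth) {
  a <- .label_vector(pred)
  b <- .label_vector(truth)
  if (length(a) != length(b)) stop("label vectors must have equal length")
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  total <- comb2(n)
  expected <- sum_a * sum_b / total
  maxidx <- (sum_a + sum_b) / 2
  if (maxidx == expected) return(if (sum_ij == expected) 1 else 0)
  (sum_ij - expected) / (maxidx - expected)
}

#' Tidy domain labels into a data frame
#'
#' @param x a [domain_labels()].
#' @param spot_ids optional spot identifiers.
#' @param ... unused.
#' @return data.frame with columns `spot_id` (if given) and `domain`.
#' @export
as.data.frame.domain_labels <- function(x, spot_ids = NULL, ...) {
  df <- data.frame(domain = x$labels)
  if (!is.null(spot_ids)) df <- cbind(data.frame(spot_id = spot_ids), df)
  df
}
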