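#' Build the k-nearest-neighbour spot graph
#'
#' Each spot is connected to its `k` nearest other spots by Euclidean
#' distance; the adjacency returned is the symmetric OR of the directed
#' k-NN relation, with a zero diagonal. Distance ties are broken
#' deterministically: first by smaller index gap to the querying spot, then
#' by smaller spot index. The gap rule makes the construction symmetric when
#' aligned replicate slices are stacked (every spot and its duplicate then
#' receive mirror-image neighbourhoods instead of all tied edges draining
#' into the first slice).
#'
#' @param coords numeric matrix (spots x 2) of coordinates, or a
#'   [spatial_dataset()].
#' @param k number of nearest neighbours (default 3, the setting that works
#'   best on most spot-resolution platforms).
#' @return An object of class `neighbor_graph` with fields `adjacency`
#'   (sparse binary, symmetric), `neighbor_sets` (per-spot integer index
#'   lists from the symmetrized graph), `directed_neighbors` (spots x k
#'   matrix of the raw k-NN indices), `k`, and `coords`.
#' @export
build_knn_graph <- function(coords, k = 3) {
  if (inherits(coords, "spatial_dataset")) coords <- coords$coords
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (!all(is.finite(coords))) stop("coords must be finite")
  if (k >= n) stop(sprintf("k (%d) must be smaller than the number of spots (%d)", k, n))
  if (k < 1) stop("k must be >= 1")
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  idx <- seq_len(n)
  nn <- t(vapply(idx, function(i) {
    order(d[i, ], abs(idx - i), idx)[seq_len(k)]
  }, integer(k)))
  if (k == 1) nn <- matrix(nn, n, 1)
  a <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k),
                            j = as.vector(t(nn)), x = 1, dims = c(n, n))
  sym <- a + Matrix::t(a)
  sym@x <- rep(1, length(sym@x))
  sym <- methods::as(sym, "CsparseMatrix")
  # column j of the symmetric pattern lists j's neighbours
  ptr <- sym@p
  idx <- sym@i + 1L
  nbr <- lapply(seq_len(n), function(j) {
    idx[seq.int(ptr[j] + 1L, length.out = ptr[j + 1L] - ptr[j])]
  })
  structure(list(adjacency = sym, neighbor_sets = nbr,
                 directed_neighbors = nn, k = k, coords = coords),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("neighbor_graph: %d spots, k = %d, %d undirected edges\n",
              nrow(x$adjacency), x$k, sum(x$adjacency) / 2))
  invisible(x)
}

#' Symmetrically normalize an adjacency matrix
#'
#' Computes \eqn{D^{-1/2} \hat A D^{-1/2}} where \eqn{\hat A} is the
#' adjacency with optional self-loops added and \eqn{D} its diagonal degree
#' matrix. Zero-degree rows (impossible once self-loops are added) map to
#' zero rows.
#'
#' @param g a [build_knn_graph()] result or a symmetric non-negative matrix.
#' @param add_self_loops add the identity before normalizing (default TRUE)
#'   so each spot retains its own signal during aggregation.
#' @return An object of class `normalized_adjacency` with fields `matrix`
#'   (sparse) and `self_loops`.
#' @export
symmetric_normalize <- function(g, add_self_loops = TRUE) {
  a <- if (inherits(g, "neighbor_graph")) g$adjacency else methods::as(Matrix::Matrix(g, sparse = TRUE), "CsparseMatrix")
  if (max(abs(a - Matrix::t(a))) > 0) stop("adjacency must be symmetric")
  if (any(a@x < 0)) stop("adjacency must be non-negative")
  n <- nrow(a)
  if (add_self_loops) a <- a + Matrix::Diagonal(n)
  deg <- Matrix::rowSums(a)
  dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  norm <- Matrix::Diagonal(n, dinv) %*% a %*% Matrix::Diagonal(n, dinv)
  structure(list(matrix = methods::as(norm, "CsparseMatrix"),
                 self_loops = add_self_loops),
            class = "normalized_adjacency")
}

#' Corrupt a feature matrix by shuffling rows
#'
#' Generates the corrupted view for contrastive learning: a seeded uniform
#' random permutation of the item rows. The neighbourhood graph is not
#' touched, so the corruption pairs shuffled expression profiles with the
#' original topology.
#'
#' @param X a [feature_matrix()] or plain matrix.
#' @param seed integer seed for the permutation.
#' @return Object of the same kind as `X` with permuted rows; the permutation
#'   used is attached as attribute `"perm"`.
#' @export
permute_features <- function(X, seed) {
  vals <- if (inherits(X, "feature_matrix")) X$values else as.matrix(X)
  n <- nrow(vals)
  perm <- local({ set.seed(seed); sample.int(n) })
  out_vals <- vals[perm, , drop = FALSE]
  rownames(out_vals) <- rownames(vals)
  if (inherits(X, "feature_matrix")) {
    out <- feature_matrix(out_vals, X$feature_ids, X$item_ids, X$scaling_stats)
  } else {
    out <- out_vals
  }
  attr(out, "perm") <- perm
  out
}

#' Apply a rigid transform to coordinates
#'
#' @param coords spots x 2 matrix.
#' @param transform 2 x 3 matrix `[[cos,-sin,tx],[sin,cos,ty]]`, or NULL for
#'   identity.
#' @return transformed spots x 2 matrix.
#' @keywords internal
apply_rigid_transform <- function(coords, transform = NULL) {
  if (is.null(transform)) return(coords)
  transform <- matrix(unlist(transform), nrow = 2, byrow = is.list(transform))
  if (!all(dim(transform) == c(2, 3))) stop("transform must be 2 x 3")
  out <- coords %*% t(transform[, 1:2]) +
    matrix(transform[, 3], nrow(coords), 2, byrow = TRUE)
  dimnames(out) <- dimnames(coords)
  out
}

#' Build a joint graph over multiple slices
#'
#' Concatenates two or more slices (restricted to their common genes, in the
#' first slice's gene order), applies optional per-slice rigid transforms to
#' place all slices in one coordinate frame, and builds a single k-NN graph
#' on the pooled coordinates so that neighbour sets may cross slice
#' boundaries. Batch labels record the slice of origin.
#'
#' @param slices list of [spatial_dataset()] objects (at least 2).
#' @param transforms optional list of per-slice 2 x 3 rigid transforms
#'   (NULL entries mean identity); default all-identity for pre-aligned data.
#' @param k neighbours per spot for the pooled graph (default 3).
#' @return A list with `combined` (a [spatial_dataset()] with `batch` set)
#'   and `graph` (a [build_knn_graph()] result on the pooled coordinates).
#' @export
build_joint_graph <- function(slices, transforms = NULL, k = 3) {
  if (!is.list(slices) || length(slices) < 2) {
    stop("need at least 2 slices")
  }
  common <- slices[[1]]$gene_ids
  for (s in slices[-1]) common <- common[common %in% s$gene_ids]
  if (length(common) == 0) stop("slices share no genes")
  names(slices) <- if (is.null(names(slices))) {
    paste0("slice", seq_along(slices))
  } else names(slices)
  parts <- lapply(seq_along(slices), function(i) {
    s <- slices[[i]]
    tr <- if (!is.null(transforms)) transforms[[i]] else NULL
    counts <- s$counts[, match(common, s$gene_ids), drop = FALSE]
    coords <- apply_rigid_transform(s$coords, tr)
    list(counts = counts, coords = coords,
         batch = rep(names(slices)[i], nrow(counts)),
         truth = s$truth_labels,
         ids = paste(names(slices)[i], s$spot_ids, sep = "_"))
  })
  counts <- do.call(rbind, lapply(parts, `[[`, "counts"))
  coords <- do.call(rbind, lapply(parts, `[[`, "coords"))
  truths <- lapply(parts, `[[`, "truth")
  truth <- if (!any(vapply(truths, is.null, logical(1)))) {
    unlist(truths, use.names = FALSE)
  } else NULL
  ids <- unlist(lapply(parts, `[[`, "ids"), use.names = FALSE)
  rownames(counts) <- ids
  combined <- spatial_dataset(counts, coords, common, ids,
                              batch = unlist(lapply(parts, `[[`, "batch")),
                              truth_labels = truth)
  list(combined = combined, graph = build_knn_graph(combined$coords, k = k))
}

#' Write a graph edge list
#'
#' @param g a [build_knn_graph()] result.
#' @param path output TSV path (columns spot_i, spot_j; each undirected edge
#'   once with i < j).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  tm <- methods::as(g$adjacency, "TsparseMatrix")
  keep <- tm@i < tm@j
  utils::write.table(data.frame(spot_i = tm@i[keep] + 1L,
                                spot_j = tm@j[keep] + 1L),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
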