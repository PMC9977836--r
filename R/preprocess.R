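#' Preprocessed feature matrix
#'
#' Items x features matrix after library-size normalization, log transform,
#' highly-variable-gene restriction and per-gene scaling, together with the
#' scaling statistics used.
#'
#' @param values numeric matrix (items x features).
#' @param feature_ids ordered feature (gene) identifiers.
#' @param item_ids ordered item (spot or cell) identifiers.
#' @param scaling_stats data.frame with columns `gene`, `mean`, `sd` recording
#'   the per-gene statistics applied at the scaling step.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, feature_ids = colnames(values),
                           item_ids = rownames(values), scaling_stats = NULL) {
  values <- as.matrix(values)
  dimnames(values) <- list(item_ids, feature_ids)
  structure(list(values = values, feature_ids = feature_ids,
                 item_ids = item_ids, scaling_stats = scaling_stats),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d items x %d features\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

.colvars <- function(m) {
  n <- nrow(m)
  if (n < 2) return(rep(0, ncol(m)))
  mu <- colMeans(m)
  (colSums(m * m) - n * mu^2) / (n - 1)
}

#' Rank genes by normalized dispersion
#'
#' Seurat-flavour highly-variable-gene statistic on log-normalized data:
#' per-gene mean and dispersion (variance/mean) are computed on the
#' de-logged values, genes are binned into 20 mean bins and dispersions
#' z-scored within each bin. Higher is more variable.
#'
#' @param logvalues matrix of log1p library-size-normalized expression
#'   (items x genes).
#' @param n_bins number of mean bins (default 20).
#' @return numeric vector of normalized dispersions (NA for zero-mean genes).
#' @keywords internal
normalized_dispersion <- function(logvalues, n_bins = 20) {
  x <- expm1(logvalues)
  mu <- colMeans(x)
  v <- .colvars(x)
  disp <- ifelse(mu > 0, v / mu, NA_real_)
  lmu <- log1p(mu)
  ok <- is.finite(disp) & disp > 0
  out <- rep(NA_real_, length(disp))
  if (!any(ok)) return(out)
  brk <- unique(stats::quantile(lmu[ok], probs = seq(0, 1, length.out = n_bins + 1)))
  bins <- if (length(brk) > 2) {
    cut(lmu[ok], breaks = brk, include.lowest = TRUE)
  } else {
    factor(rep(1L, sum(ok)))
  }
  ld <- log(disp[ok])
  z <- ld
  for (b in levels(bins)) {
    sel <- bins == b
    m <- mean(ld[sel])
    s <- stats::sd(ld[sel])
    z[sel] <- if (is.na(s) || s == 0) 0 else (ld[sel] - m) / s
  }
  out[ok] <- z
  out
}

#' Normalize, select highly variable genes, and scale
#'
#' The standard preprocessing pipeline for spot or cell expression:
#' (1) library-size normalize each item to `target_sum` total counts,
#' (2) log1p transform, (3) rank genes by normalized dispersion and keep the
#' top `min(n_hvg, available)`, (4) scale each retained gene to zero mean and
#' unit variance. Genes with zero variance are dropped before scaling.
#' Items with zero total counts are left as zero rows through the
#' normalization (and become the column means' negatives after scaling).
#'
#' @param ds a [spatial_dataset()] or a plain counts matrix (items x genes).
#' @param n_hvg number of highly variable genes to retain (default 3000).
#' @param target_sum per-item total after library-size normalization
#'   (default 1e4).
#' @return A [feature_matrix()] whose `scaling_stats` records the per-gene
#'   mean/sd applied.
#' @export
normalize_select_scale <- function(ds, n_hvg = 3000, target_sum = 1e4) {
  counts <- if (inherits(ds, "spatial_dataset")) ds$counts else as.matrix(ds)
  if (n_hvg < 1) stop("n_hvg must be >= 1")
  if (nrow(counts) < 2) stop("need at least 2 items")
  lib <- rowSums(counts)
  norm <- counts
  nz <- lib > 0
  norm[nz, ] <- counts[nz, , drop = FALSE] * (target_sum / lib[nz])
  lv <- log1p(norm)

  v <- .colvars(lv)
  if (all(v == 0)) stop("all genes are constant; nothing to select")
  nd <- normalized_dispersion(lv)
  nd[v == 0] <- NA_real_                      # constant genes never selected
  ok <- which(!is.na(nd))
  keep_n <- min(n_hvg, length(ok))
  sel <- ok[order(nd[ok], decreasing = TRUE)[seq_len(keep_n)]]
  sel <- sort(sel)                            # preserve input gene order
  x <- lv[, sel, drop = FALSE]

  mu <- colMeans(x)
  sdv <- sqrt(.colvars(x))
  scaled <- sweep(sweep(x, 2, mu, "-"), 2, ifelse(sdv > 0, sdv, 1), "/")
  stats_df <- data.frame(gene = colnames(counts)[sel], mean = mu, sd = sdv,
                         stringsAsFactors = FALSE)
  feature_matrix(scaled, feature_ids = colnames(counts)[sel],
                 item_ids = rownames(counts), scaling_stats = stats_df)
}

#' Restrict two feature matrices to their common genes
#'
#' Both matrices are subset to the shared gene list, ordered by the first
#' (spatial) matrix's gene ordering.
#'
#' @param st spatial [feature_matrix()].
#' @param sc single-cell [feature_matrix()].
#' @return A list with elements `st` and `sc`, both restricted to the shared,
#'   identically ordered genes.
#' @export
intersect_genes <- function(st, sc) {
  stopifnot(inherits(st, "feature_matrix"), inherits(sc, "feature_matrix"))
  common <- st$feature_ids[st$feature_ids %in% sc$feature_ids]
  if (length(common) == 0) {
    stop(sprintf(
      "no genes in common; spatial genes start %s ... single-cell genes start %s",
      paste(utils::head(st$feature_ids, 5), collapse = ","),
      paste(utils::head(sc$feature_ids, 5), collapse = ",")))
  }
  sub <- function(fm, genes) {
    idx <- match(genes, fm$feature_ids)
    ss <- fm$scaling_stats
    if (!is.null(ss)) ss <- ss[match(genes, ss$gene), , drop = FALSE]
    feature_matrix(fm$values[, idx, drop = FALSE], genes, fm$item_ids, ss)
  }
  list(st = sub(st, common), sc = sub(sc, common))
}
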