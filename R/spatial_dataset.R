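#' Construct a spatial expression dataset
#'
#' Bundles a spots x genes count matrix with 2-D spot coordinates and optional
#' per-spot batch and ground-truth domain labels. Counts must be non-negative;
#' coordinates align row-for-row with the counts. Duplicate gene identifiers
#' are deduplicated first-wins with numeric suffixes.
#'
#' @param counts numeric matrix (spots x genes) of non-negative counts.
#' @param coords numeric matrix or data.frame (spots x 2) of spot coordinates.
#' @param gene_ids character vector of gene identifiers (defaults to counts
#'   colnames).
#' @param spot_ids character vector of spot barcodes (defaults to counts
#'   rownames).
#' @param batch optional per-spot slice/batch label.
#' @param truth_labels optional per-spot ground-truth domain label
#'   (fixtures and benchmarks only).
#' @return An object of class `spatial_dataset`.
#' @export
spatial_dataset <- function(counts, coords, gene_ids = colnames(counts),
                            spot_ids = rownames(counts), batch = NULL,
                            truth_labels = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L) stop("coords must have exactly 2 columns")
  if (nrow(coords) != nrow(counts)) {
    stop(sprintf("coords rows (%d) do not align with counts rows (%d)",
                 nrow(coords), nrow(counts)))
  }
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(counts)))
  if (is.null(spot_ids)) spot_ids <- paste0("spot", seq_len(nrow(counts)))
  gene_ids <- as.character(gene_ids)
  spot_ids <- as.character(spot_ids)
  if (length(gene_ids) != ncol(counts)) stop("gene_ids length mismatch")
  if (length(spot_ids) != nrow(counts)) stop("spot_ids length mismatch")
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    gene_ids <- make.unique(gene_ids, sep = ".")
    message(sprintf("deduplicated %d duplicate gene id(s): %s",
                    length(dup), paste(utils::head(dup, 5), collapse = ", ")))
  }
  if (!is.null(batch) && length(batch) != nrow(counts)) {
    stop("batch length mismatch")
  }
  if (!is.null(truth_labels) && length(truth_labels) != nrow(counts)) {
    stop("truth_labels length mismatch")
  }
  zero <- rowSums(counts) == 0
  if (any(zero)) {
    message(sprintf("%d spot(s) have all-zero counts and are retained: %s",
                    sum(zero),
                    paste(utils::head(spot_ids[zero], 5), collapse = ", ")))
  }
  dimnames(counts) <- list(spot_ids, gene_ids)
  rownames(coords) <- spot_ids
  colnames(coords) <- c("x", "y")
  structure(list(counts = counts, coords = coords, gene_ids = gene_ids,
                 spot_ids = spot_ids, batch = batch,
                 truth_labels = truth_labels),
            class = "spatial_dataset")
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat(sprintf("spatial_dataset: %d spots x %d genes\n",
              nrow(x$counts), ncol(x$counts)))
  if (!is.null(x$batch)) {
    cat(" batches:", paste(unique(x$batch), collapse = ", "), "\n")
  }
  if (!is.null(x$truth_labels)) {
    cat(" truth domains:", length(unique(x$truth_labels)), "\n")
  }
  invisible(x)
}

#' @export
dim.spatial_dataset <- function(x) dim(x$counts)

.read_coords_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("spot_id", "x", "y")
  if (!all(need %in% names(df))) {
    stop("coordinate file must have columns spot_id,x,y: ", path)
  }
  df
}

.match_coords <- function(spot_ids, coord_df) {
  idx <- match(spot_ids, coord_df$spot_id)
  if (anyNA(idx)) {
    missing <- spot_ids[is.na(idx)]
    stop(sprintf("missing coordinates for %d spot(s): %s", length(missing),
                 paste(utils::head(missing, 10), collapse = ", ")))
  }
  as.matrix(coord_df[idx, c("x", "y")])
}

#' Read a spatial dataset from disk
#'
#' Supports the 10x-style MatrixMarket directory convention
#' (`matrix.mtx` with genes as rows, `barcodes.tsv`, `features.tsv`, plus a
#' sidecar `coords.csv` with columns `spot_id,x,y`) and dense CSV matrices
#' (spots as rows, genes as columns, first column spot ids). Coordinates may
#' alternatively be supplied through `coords_path`. Optional
#' `truth.tsv` (columns `spot_id`, `domain`) in an MTX directory is read into
#' `truth_labels`.
#'
#' @param path directory (mtx_dir) or file (csv).
#' @param format one of `"mtx_dir"`, `"csv"`, `"h5ad"`.
#' @param coords_path optional path to a `spot_id,x,y` CSV overriding the
#'   sidecar convention.
#' @return A [spatial_dataset()].
#' @export
read_spatial_dataset <- function(path, format = c("mtx_dir", "csv", "h5ad"),
                                 coords_path = NULL) {
  format <- match.arg(format)
  if (format == "h5ad") {
    stop("h5ad input is not supported by this build (no HDF5 reader ",
         "available); convert to an MTX directory or CSV first")
  }
  if (!file.exists(path)) stop("path does not exist: ", path)
  if (format == "mtx_dir") {
    mtx <- file.path(path, "matrix.mtx")
    bc <- file.path(path, "barcodes.tsv")
    ft <- file.path(path, "features.tsv")
    for (f in c(mtx, bc, ft)) {
      if (!file.exists(f)) stop("required file missing from mtx_dir: ", f)
    }
    m <- Matrix::readMM(mtx)              # genes x spots, 10x convention
    barcodes <- readLines(bc)
    feat <- utils::read.delim(ft, header = FALSE, stringsAsFactors = FALSE)
    genes <- as.character(feat[[1]])
    if (ncol(m) != length(barcodes)) {
      stop(sprintf("matrix has %d columns but %d barcodes listed",
                   ncol(m), length(barcodes)))
    }
    if (nrow(m) != length(genes)) {
      stop(sprintf("matrix has %d rows but %d features listed",
                   nrow(m), length(genes)))
    }
    counts <- t(as.matrix(m))             # spots x genes
    rownames(counts) <- barcodes
    colnames(counts) <- genes
    cpath <- if (is.null(coords_path)) file.path(path, "coords.csv") else coords_path
    if (!file.exists(cpath)) stop("coordinate file not found: ", cpath)
    coords <- .match_coords(barcodes, .read_coords_csv(cpath))
    truth <- NULL
    tpath <- file.path(path, "truth.tsv")
    if (file.exists(tpath)) {
      tdf <- utils::read.delim(tpath, stringsAsFactors = FALSE)
      truth <- tdf$domain[match(barcodes, tdf$spot_id)]
    }
    spatial_dataset(counts, coords, genes, barcodes, truth_labels = truth)
  } else {
    df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
    counts <- as.matrix(df)
    if (is.null(coords_path)) {
      coords_path <- file.path(dirname(path), "coords.csv")
    }
    if (!file.exists(coords_path)) {
      stop("coordinate file not found: ", coords_path)
    }
    coords <- .match_coords(rownames(counts), .read_coords_csv(coords_path))
    spatial_dataset(counts, coords, colnames(counts), rownames(counts))
  }
}

#' Write a spatial dataset as an MTX directory
#'
#' Writes `matrix.mtx` (genes x spots), `barcodes.tsv`, `features.tsv`,
#' `coords.csv` and, when truth labels are present, `truth.tsv`, so that the
#' MTX reading path can be exercised end to end.
#'
#' @param ds a [spatial_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_spatial_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "spatial_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::Matrix(t(ds$counts), sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(ds$spot_ids, file.path(dir, "barcodes.tsv"))
  utils::write.table(data.frame(id = ds$gene_ids, name = ds$gene_ids),
                     file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.csv(data.frame(spot_id = ds$spot_ids,
                              x = ds$coords[, 1], y = ds$coords[, 2]),
                   file.path(dir, "coords.csv"), row.names = FALSE)
  if (!is.null(ds$truth_labels)) {
    utils::write.table(data.frame(spot_id = ds$spot_ids,
                                  domain = ds$truth_labels),
                       file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
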