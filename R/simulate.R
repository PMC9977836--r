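#' Specification of a synthetic spatial-domain slide
#'
#' Defaults describe the reference fixture used throughout the package: a
#' 32 x 32 grid (spacing 30 coordinate units, so the default refinement
#' radius of 50 spans the 8 surrounding spots) split into 4 contiguous
#' domains, 200 genes of which 25 per domain are markers elevated by 3 on
#' the log scale over a shared baseline, with Gaussian noise (sd 1 in log
#' space) or negative-binomial counts (dispersion 0.3).
#'
#' @param grid c(rows, cols) of the spot lattice.
#' @param n_domains number of contiguous spatial domains (>= 2).
#' @param n_genes total genes.
#' @param n_marker_per_domain markers per domain (disjoint across domains).
#' @param effect_size marker mean shift on the log scale.
#' @param noise_model `"gaussian"` (log-space noise) or
#'   `"negative_binomial"` (integer counts).
#' @param noise_sd Gaussian log-space noise sd.
#' @param nb_dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param batch_shift sd of the per-batch, per-gene additive log-space
#'   offset used by [simulate_replicate_slices()].
#' @param spacing grid spacing in coordinate units.
#' @param coord_jitter sd of the per-slice coordinate jitter applied by
#'   [simulate_replicate_slices()] (default spacing/10), emulating the
#'   imperfect registration of serial sections: aligned spots land close to,
#'   but never exactly on, their counterparts.
#' @param seed RNG seed.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(grid = c(32, 32), n_domains = 4, n_genes = 200,
                         n_marker_per_domain = 25, effect_size = 3,
                         noise_model = c("gaussian", "negative_binomial"),
                         noise_sd = 1, nb_dispersion = 0.3, batch_shift = 2,
                         spacing = 30, coord_jitter = spacing / 10, seed = 0) {
  noise_model <- match.arg(noise_model)
  if (n_domains < 2) stop("n_domains must be >= 2")
  if (n_domains * n_marker_per_domain > n_genes) {
    stop("markers exceed gene count")
  }
  if (prod(grid) < n_domains) stop("more domains than spots")
  structure(list(grid = as.integer(grid), n_domains = as.integer(n_domains),
                 n_genes = as.integer(n_genes),
                 n_marker_per_domain = as.integer(n_marker_per_domain),
                 effect_size = effect_size, noise_model = noise_model,
                 noise_sd = noise_sd, nb_dispersion = nb_dispersion,
                 batch_shift = batch_shift, spacing = spacing,
                 coord_jitter = coord_jitter, seed = as.integer(seed)),
            class = "fixture_spec")
}

# Contiguous domain partition of a rows x cols grid: quadrant blocks when
# n_domains = 4 and both dims are even, vertical stripes otherwise.
.domain_partition <- function(grid, n_domains) {
  rows <- grid[1]; cols <- grid[2]
  rc <- expand.grid(row = seq_len(rows), col = seq_len(cols))
  if (n_domains == 4 && rows %% 2 == 0 && cols %% 2 == 0) {
    2L * (rc$row > rows / 2) + (rc$col > cols / 2) + 1L
  } else {
    pmin(((rc$col - 1L) * n_domains) %/% cols + 1L, n_domains)
  }
}

.grid_coords <- function(grid, spacing) {
  rc <- expand.grid(row = seq_len(grid[1]), col = seq_len(grid[2]))
  cbind(x = rc$col * spacing, y = rc$row * spacing)
}

# log-scale mean expression: shared per-gene baseline + marker elevation
.domain_logmeans <- function(spec) {
  base <- stats::runif(spec$n_genes, log(2), log(8))
  mu <- matrix(rep(base, each = spec$n_domains), spec$n_domains,
               spec$n_genes)
  for (d in seq_len(spec$n_domains)) {
    idx <- ((d - 1) * spec$n_marker_per_domain + 1):(d * spec$n_marker_per_domain)
    mu[d, idx] <- mu[d, idx] + spec$effect_size
  }
  mu
}

.draw_counts <- function(logmean, spec) {
  n <- length(logmean)
  if (spec$noise_model == "gaussian") {
    round(exp(logmean + stats::rnorm(n, sd = spec$noise_sd)))
  } else {
    stats::rnbinom(n, size = 1 / spec$nb_dispersion, mu = exp(logmean))
  }
}

#' Simulate a single spatial-domain slide
#'
#' Spots on a regular grid are partitioned into contiguous domains; each
#' domain elevates its own disjoint marker genes over a shared per-gene
#' baseline, and counts are drawn under the requested noise model.
#' Deterministic given the spec's seed.
#'
#' @param spec a [fixture_spec()].
#' @return A [spatial_dataset()] with `truth_labels` filled.
#' @export
simulate_domain_slide <- function(spec = fixture_spec()) {
  set.seed(spec$seed)
  dom <- .domain_partition(spec$grid, spec$n_domains)
  coords <- .grid_coords(spec$grid, spec$spacing)
  mu <- .domain_logmeans(spec)
  n_spot <- prod(spec$grid)
  counts <- matrix(0, n_spot, spec$n_genes)
  for (i in seq_len(n_spot)) {
    counts[i, ] <- .draw_counts(mu[dom[i], ], spec)
  }
  counts[counts < 0] <- 0
  rownames(counts) <- sprintf("spot%04d", seq_len(n_spot))
  colnames(counts) <- sprintf("gene%03d", seq_len(spec$n_genes))
  spatial_dataset(counts, coords, truth_labels = paste0("domain", dom))
}

#' Simulate replicate slices with batch effects
#'
#' All slices share one domain layout and marker structure; each slice draws
#' independent noise and receives its own per-gene additive offset in log
#' space with sd `spec$batch_shift`, emulating serial sections with batch
#' effects, plus a per-slice coordinate jitter of sd `spec$coord_jitter`
#' emulating imperfect inter-section registration. Batch labels are set on
#' every slice.
#'
#' @param spec a [fixture_spec()].
#' @param n_slices number of replicate slices (default 2).
#' @return list of [spatial_dataset()] objects with identical
#'   `truth_labels` and per-slice `batch` labels.
#' @export
simulate_replicate_slices <- function(spec = fixture_spec(grid = c(20, 20)),
                                      n_slices = 2) {
  if (n_slices < 2) stop("n_slices must be >= 2")
  set.seed(spec$seed)
  dom <- .domain_partition(spec$grid, spec$n_domains)
  coords <- .grid_coords(spec$grid, spec$spacing)
  mu <- .domain_logmeans(spec)
  n_spot <- prod(spec$grid)
  lapply(seq_len(n_slices), function(s) {
    shift <- stats::rnorm(spec$n_genes, sd = spec$batch_shift)
    jitter <- matrix(stats::rnorm(n_spot * 2, sd = spec$coord_jitter),
                     n_spot, 2)
    counts <- matrix(0, n_spot, spec$n_genes)
    for (i in seq_len(n_spot)) {
      counts[i, ] <- .draw_counts(mu[dom[i], ] + shift, spec)
    }
    counts[counts < 0] <- 0
    rownames(counts) <- sprintf("spot%04d", seq_len(n_spot))
    colnames(counts) <- sprintf("gene%03d", seq_len(spec$n_genes))
    spatial_dataset(counts, coords + jitter,
                    batch = rep(paste0("slice", s), n_spot),
                    truth_labels = paste0("domain", dom))
  })
}

#' Simulate a single-cell reference and mixed spots
#'
#' Per-type expression programs with disjoint marker genes generate
#' reference cells; each spot on a grid draws a Dirichlet proportion vector
#' that is then blended with its grid neighbours (weight `blend`) so
#' neighbouring spots have similar compositions, matching the locality
#' assumption of the spatial model. Spot counts are the column sums of
#' `spot_cell_count` reference-style cells sampled according to those
#' proportions; the realized composition of each spot is returned as the
#' ground truth (`proportions`), alongside the pre-sampling blended
#' Dirichlet vectors (`expected_proportions`).
#'
#' @param n_types number of cell types (default 5).
#' @param cells_per_type reference cells per type (default 60).
#' @param n_spots number of spots; must be a perfect square for the grid
#'   layout (default 100).
#' @param dirichlet_alpha Dirichlet concentration vector (default 0.5 each).
#' @param spot_cell_count cells summed into each spot (default 12).
#' @param n_genes total genes (default 150; 20 markers per type).
#' @param n_marker_per_type markers per type (default 20).
#' @param effect_size marker elevation on the log scale (default 3).
#' @param blend weight given to the neighbour average when spatially
#'   smoothing proportions (default 0.5).
#' @param spacing grid spacing (default 30).
#' @param seed RNG seed.
#' @return list with `reference` (cells [spatial_dataset()]-like list:
#'   `counts`, `cell_ids`, `labels`), `annotation` (an
#'   [annotation_matrix()] over cells), `spots` (a [spatial_dataset()]),
#'   `proportions` (spots x types realized truth), and
#'   `expected_proportions`.
#' @export
simulate_reference_and_spots <- function(n_types = 5, cells_per_type = 60,
                                         n_spots = 100,
                                         dirichlet_alpha = rep(0.5, n_types),
                                         spot_cell_count = 12, n_genes = 150,
                                         n_marker_per_type = 20,
                                         effect_size = 3, blend = 0.5,
                                         spacing = 30, seed = 0) {
  if (length(dirichlet_alpha) != n_types) {
    stop("dirichlet_alpha length must equal n_types")
  }
  if (n_types * n_marker_per_type > n_genes) stop("markers exceed gene count")
  side <- round(sqrt(n_spots))
  if (side^2 != n_spots) stop("n_spots must be a perfect square")
  set.seed(seed)

  base <- stats::runif(n_genes, log(2), log(8))
  mu <- matrix(rep(base, each = n_types), n_types, n_genes)
  for (t in seq_len(n_types)) {
    idx <- ((t - 1) * n_marker_per_type + 1):(t * n_marker_per_type)
    mu[t, idx] <- mu[t, idx] + effect_size
  }

  draw_cell <- function(type) {
    stats::rpois(n_genes, lambda = exp(mu[type, ] +
                                         stats::rnorm(n_genes, sd = 0.3)))
  }
  types <- rep(seq_len(n_types), each = cells_per_type)
  ref_counts <- t(vapply(types, draw_cell, numeric(n_genes)))
  rownames(ref_counts) <- sprintf("cell%04d", seq_along(types))
  colnames(ref_counts) <- sprintf("gene%03d", seq_len(n_genes))
  type_names <- paste0("type", seq_len(n_types))
  labels <- type_names[types]

  # spatially autocorrelated proportions on a side x side grid
  rdirichlet1 <- function(alpha) {
    g <- stats::rgamma(length(alpha), shape = alpha)
    if (sum(g) == 0) g[sample.int(length(g), 1)] <- 1
    g / sum(g)
  }
  raw <- t(vapply(seq_len(n_spots), function(i) rdirichlet1(dirichlet_alpha),
                  numeric(n_types)))
  rc <- expand.grid(row = seq_len(side), col = seq_len(side))
  props <- raw
  for (i in seq_len(n_spots)) {
    nbr <- which(abs(rc$row - rc$row[i]) + abs(rc$col - rc$col[i]) == 1)
    if (length(nbr) > 0) {
      props[i, ] <- (1 - blend) * raw[i, ] + blend * colMeans(raw[nbr, , drop = FALSE])
    }
  }
  props <- props / rowSums(props)

  spot_counts <- matrix(0, n_spots, n_genes)
  realized <- matrix(0, n_spots, n_types)
  for (i in seq_len(n_spots)) {
    comp <- as.vector(stats::rmultinom(1, spot_cell_count, props[i, ]))
    realized[i, ] <- comp / spot_cell_count
    for (t in seq_len(n_types)) {
      if (comp[t] > 0) {
        for (c in seq_len(comp[t])) {
          spot_counts[i, ] <- spot_counts[i, ] + draw_cell(t)
        }
      }
    }
  }
  rownames(spot_counts) <- sprintf("spot%04d", seq_len(n_spots))
  colnames(spot_counts) <- colnames(ref_counts)
  colnames(realized) <- type_names
  colnames(props) <- type_names
  rownames(realized) <- rownames(spot_counts)
  coords <- cbind(x = rc$col * spacing, y = rc$row * spacing)

  list(reference = list(counts = ref_counts,
                        cell_ids = rownames(ref_counts), labels = labels),
       annotation = annotation_matrix(labels, type_names),
       spots = spatial_dataset(spot_counts, coords),
       proportions = realized,
       expected_proportions = props)
}
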