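#' Plot spatial domain assignments
#'
#' @param coords spots x 2 coordinate matrix (or a [spatial_dataset()]).
#' @param labels a [domain_labels()] or per-spot label vector.
#' @param point_size point size (default 2).
#' @return a ggplot object.
#' @export
plot_spatial_domains <- function(coords, labels, point_size = 2) {
  if (inherits(coords, "spatial_dataset")) coords <- coords$coords
  df <- data.frame(x = coords[, 1], y = coords[, 2],
                   domain = factor(.label_vector(labels)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$domain)) +
    ggplot2::geom_point(size = point_size) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal() +
    ggplot2::labs(colour = "domain")
}

#' Plot the training loss history
#'
#' @param x a `representation_output` (or its `loss_history` data.frame).
#' @return a ggplot object with one line per loss component.
#' @export
plot_loss_history <- function(x) {
  h <- if (inherits(x, "representation_output")) x$loss_history else x
  long <- do.call(rbind, lapply(c("total", "recon", "scl", "scl_corrupt"),
                                function(nm) {
    data.frame(epoch = h$epoch, loss = h[[nm]], component = nm)
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::theme_minimal()
}

#' Plot estimated cell-type proportions on the slide
#'
#' @param coords spots x 2 coordinates (or a [spatial_dataset()]).
#' @param proportions spots x types proportion matrix.
#' @param type column name (or index) to display.
#' @return a ggplot object.
#' @export
plot_spot_proportions <- function(coords, proportions, type = 1) {
  if (inherits(coords, "spatial_dataset")) coords <- coords$coords
  df <- data.frame(x = coords[, 1], y = coords[, 2],
                   p = as.matrix(proportions)[, type])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$p)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_viridis_c(name = "proportion") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}
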