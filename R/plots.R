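#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

grid_to_tibble <- function(grid) {
  tibble::tibble(
    row = rep(seq_len(nrow(grid)), times = ncol(grid)),
    col = rep(seq_len(ncol(grid)), each = nrow(grid)),
    value = as.vector(grid)
  )
}

diverging_scale <- function(limits, name) {
  ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                high = "#B2182B", midpoint = 0,
                                limits = limits, name = name)
}

#' Plot an expression portrait
#'
#' Renders a sample portrait as a tile map with the conventional
#' red-to-blue diverging scale (maximum to minimum expression).
#'
#' @param object A `som_portrait`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.som_portrait <- function(object, ...) {
  df <- grid_to_tibble(object$grid)
  lim <- max(abs(df$value))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    diverging_scale(c(-lim, lim), "log2\nexpression") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = object$sample_id, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a phenotype correlation map
#'
#' @param object A `correlation_map`.
#' @param ... Unused.
#' @return A ggplot object; the maximum-correlation unit is marked.
#' @export
autoplot.correlation_map <- function(object, ...) {
  df <- grid_to_tibble(object$grid)
  lim <- max(abs(df$value))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    diverging_scale(c(-lim, lim), "r") +
    ggplot2::annotate("point", x = object$argmax["col"],
                      y = object$argmax["row"], shape = 4, size = 3) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = object$feature, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the spot segmentation over the overexpression summary map
#'
#' @param object A `spot_set`.
#' @param ... Unused.
#' @return A ggplot object with spot letters at the spot centroids.
#' @export
autoplot.spot_set <- function(object, ...) {
  df <- grid_to_tibble(attr(object, "summary"))
  gc <- attr(object, "grid_cols")
  labs <- purrr::map2_dfr(object$spot_id, object$units, function(id, u) {
    tibble::tibble(spot_id = id,
                   row = mean((u - 1) %/% gc + 1),
                   col = mean((u - 1) %% gc + 1))
  })
  lim <- max(abs(df$value))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    diverging_scale(c(-lim, lim), "98th pctl\nexpression") +
    ggplot2::geom_text(data = labs, ggplot2::aes(label = .data$spot_id),
                       fontface = "bold") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of spot expression across samples ordered by subtype
#'
#' @param spots A `spot_set`.
#' @param assignment Optional `type_assignment` used to order samples.
#' @return A ggplot object.
#' @export
plot_spot_profiles <- function(spots, assignment = NULL) {
  prof <- attr(spots, "profiles")
  df <- tibble::as_tibble(prof, rownames = "spot_id") |>
    tidyr::pivot_longer(-"spot_id", names_to = "sample_id",
                        values_to = "expression")
  if (!is.null(assignment)) {
    ord <- assignment$sample_id[order(assignment$subtype)]
    df$sample_id <- factor(df$sample_id, levels = ord)
  }
  df$spot_id <- factor(df$spot_id, levels = rev(spots$spot_id))
  lim <- max(abs(df$expression))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$spot_id,
                                   fill = .data$expression)) +
    ggplot2::geom_raster() +
    diverging_scale(c(-lim, lim), "log2\nexpression") +
    ggplot2::labs(x = "samples", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}
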