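state_as_tibble <- function(state) {
  W <- nrow(state$sid); H <- ncol(state$sid)
  id <- as.vector(state$sid)
  cl <- comp_to_cluster(state, id)
  tibble::tibble(
    x = rep(seq_len(W), times = H),
    y = rep(seq_len(H), each = W),
    compartment = id,
    cluster = cl,
    cell_type = ifelse(id == 0L, "medium", state$clus_cell_type[pmax(cl, 1L)]),
    compartment_type = ifelse(id == 0L, "medium",
                              state$comp_type[pmax(id, 1L)])
  )
}

luad_type_palette <- c(
  medium = "white", cancer = "#c0392b", normal_epithelial = "#2980b9",
  stromal = "#e8c3a0", ecm = "#d8b48a", mucus = "#b8e0d2"
)

#' Plot a lattice state
#'
#' Tissue view of the site map: pixels coloured by cell type, with apical and
#' basal sub-compartments darkened/lightened so epithelial polarity is
#' visible.
#'
#' @param object A `cpm_state`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cpm_state <- function(object, ...) {
  df <- state_as_tibble(object)
  df$fill <- luad_type_palette[df$cell_type]
  dark <- df$compartment_type == "apical"
  light <- df$compartment_type == "basal"
  df$fill[dark] <- grDevices::adjustcolor(df$fill[dark], 0.9, 0.6, 0.6, 0.6)
  df$fill[light] <- grDevices::adjustcolor(df$fill[light], 1, 1.3, 1.3, 1.3)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' Plot the metric time course of a trajectory
#'
#' Connection-category fractions of the cancer cells over simulated time.
#'
#' @param object A `cpm_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cpm_trajectory <- function(object, ...) {
  df <- object$records |>
    dplyr::select("mcs", dplyr::all_of(paste0("cat", 1:5))) |>
    tidyr::pivot_longer(-"mcs", names_to = "category", values_to = "fraction",
                        names_prefix = "cat")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mcs, y = .data$fraction,
                                   colour = .data$category)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "MCS", y = "fraction of cancer cells",
                  colour = "category") +
    ggplot2::theme_minimal()
}

#' Replicate-averaged heatmap of morphology metrics
#'
#' Tile plot of an [aggregate_replicates()] table, mirroring the published
#' category / neighbour-count heatmaps.
#'
#' @param aggregated Output of [aggregate_replicates()], optionally
#'   row-bound across models with a `model` column.
#' @return A ggplot.
#' @export
plot_metric_heatmap <- function(aggregated) {
  if (!"model" %in% names(aggregated)) aggregated$model <- "model"
  ggplot2::ggplot(aggregated,
                  ggplot2::aes(x = factor(.data$bin), y = .data$model,
                               fill = .data$mean)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~metric, scales = "free_x") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "category / cancer neighbours", y = NULL,
                  fill = "mean fraction") +
    ggplot2::theme_minimal()
}

#' Plot a spot set coloured by the distance flag
#'
#' 2D projection of a 3D spot set, highlighting spots whose mean distance to
#' their k nearest neighbours exceeds the cutoff.
#'
#' @param spots Output of [knn_mean_distances()] or
#'   [spot_distances_by_spheroid()].
#' @return A ggplot.
#' @export
plot_spots <- function(spots) {
  stopifnot(all(c("x_um", "y_um", "mean_distance", "flagged") %in% names(spots)))
  ggplot2::ggplot(spots, ggplot2::aes(x = .data$x_um, y = .data$y_um,
                                      colour = .data$flagged)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "magenta")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  colour = "> cutoff") +
    ggplot2::theme_minimal()
}
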