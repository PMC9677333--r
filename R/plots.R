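#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

matrix_to_long <- function(m, value_name = "value") {
  tibble::tibble(
    row = rep(seq_len(nrow(m)) - 1, ncol(m)),
    col = rep(seq_len(ncol(m)) - 1, each = nrow(m)),
    value = as.vector(m)
  ) |>
    stats::setNames(c("row", "col", value_name))
}

#' Plot a radiograph
#' @param object A [radiograph()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.radiograph <- function(object, ...) {
  df <- matrix_to_long(object$image)
  df$row_mm <- df$row * object$pixel_pitch_mm
  df$col_mm <- df$col * object$pixel_pitch_mm
  ggplot2::ggplot(df, ggplot2::aes(.data$col_mm, .data$row_mm,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", fill = "intensity")
}

#' Plot a damage tile map
#' @param object A [damage_map()] result.
#' @param ... Unused.
#' @return A ggplot of the per-tile damaged fraction.
#' @export
autoplot.damage_tile_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$tile_col, .data$tile_row,
                                       fill = .data$ratio)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey80", limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "tile column", y = "tile row",
                  fill = "damaged\nfraction")
}

#' Plot a dose / damage profile
#' @param object A [profile_correlation()] result.
#' @param ... Unused.
#' @return A ggplot with both profiles on normalised scales.
#' @export
autoplot.profile_report <- function(object, ...) {
  prof <- object$profile
  norm <- function(x) (x - min(x, na.rm = TRUE)) /
    max(1e-12, diff(range(x, na.rm = TRUE)))
  df <- tidyr::pivot_longer(
    tibble::tibble(coord_mm = prof$coord_mm,
                   dose = norm(prof$dose), damage = norm(prof$damage)),
    -"coord_mm", names_to = "quantity", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$coord_mm, .data$value,
                                   colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position along beam (mm)", y = "normalised value",
                  subtitle = sprintf("Pearson r = %.3f over %d bins",
                                     object$r, object$n_bins))
}

#' Plot observer-agreement Jaccard coefficients
#' @param object An [agreement_study()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.agreement_report <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::mutate(object$inter, kind = "inter-observer"),
    dplyr::mutate(object$intra, kind = "intra-observer")
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$kind, .data$jaccard)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "Jaccard coefficient")
}

#' Detectability-versus-frames curve
#' @param tbl A [detectability_vs_frames()] table.
#' @return A ggplot of CNR and smallest detectable feature versus frames.
#' @export
plot_detectability <- function(tbl) {
  ggplot2::ggplot(tbl, ggplot2::aes(.data$n_frames)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$cnr)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$cnr)) +
    ggplot2::labs(x = "number of frames", y = "CNR (reference feature)")
}
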