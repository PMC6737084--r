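#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heat map of a cross-correlation matrix
#'
#' @param object a `cross_correlation`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cross_correlation <- function(object, ...) {
  n <- length(object$atom_ids)
  df <- tidyr::expand_grid(i = seq_len(n), j = seq_len(n))
  df$cc <- as.numeric(object$values)[(df$j - 1) * n + df$i]
  df$atom_i <- object$atom_ids[df$i]
  df$atom_j <- object$atom_ids[df$j]
  ggplot2::ggplot(df, ggplot2::aes(.data$atom_i, .data$atom_j,
                                   fill = .data$cc)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-1, 1), name = "CC") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "atom i", y = "atom j",
                  title = "Dynamic cross-correlation map")
}

#' Heat map of inter-segment correlation scores
#'
#' @param object a `segment_correlation` tibble.
#' @param ... unused.
#' @export
autoplot.segment_correlation <- function(object, ...) {
  both <- dplyr::bind_rows(
    object,
    dplyr::rename(object, segment_i = "segment_j", segment_j = "segment_i"))
  ggplot2::ggplot(both, ggplot2::aes(.data$segment_i, .data$segment_j,
                                     fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  name = "CS") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste0("Segment correlation scores (|CC| >= ",
                                 attr(object, "threshold"), ")"))
}

#' Per-residue correlation profile plot
#'
#' @param object a `residue_profile` tibble.
#' @param ... unused.
#' @export
autoplot.residue_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$residue_index, .data$score)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::facet_wrap(~chain_id, ncol = 1) +
    ggplot2::labs(x = "residue",
                  y = paste0("sum CC to ", attr(object, "focus_segment")),
                  title = "Per-residue cross-correlation profile")
}

#' Free-energy surface plot
#'
#' 1-CV surfaces as a line, 2-CV surfaces as a filled map with contours.
#'
#' @param object a `free_energy_surface`.
#' @param ... unused.
#' @export
autoplot.free_energy_surface <- function(object, ...) {
  tab <- fes_cell_index(object)
  if (length(object$axes) == 1) {
    ggplot2::ggplot(tab, ggplot2::aes(.data$x, .data$value)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "CV", y = "free energy (kJ/mol)",
                    title = "Reconstructed free-energy profile")
  } else {
    ggplot2::ggplot(tab, ggplot2::aes(.data$x, .data$y, fill = .data$value,
                                      z = .data$value)) +
      ggplot2::geom_raster() +
      ggplot2::geom_contour(colour = "grey30", linewidth = 0.2) +
      ggplot2::scale_fill_viridis_c(name = "F (kJ/mol)") +
      ggplot2::labs(x = "CV1", y = "CV2",
                    title = "Reconstructed free-energy surface")
  }
}
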