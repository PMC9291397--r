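# ggplot2 views of the main result types.

#' Plot per-column logo statistics
#'
#' Stack height is the column information (bits), bar width the non-gap
#' fraction, colored by the most frequent residue.
#'
#' @param stats output of [logo_stats()].
#' @return a ggplot.
#' @export
plot_logo <- function(stats) {
  ggplot2::ggplot(stats, ggplot2::aes(
    x = .data$position, y = .data$information,
    width = pmax(.data$width, 0.05), fill = .data$top_residue
  )) +
    ggplot2::geom_col(color = NA, show.legend = FALSE) +
    ggplot2::labs(x = "alignment position", y = "information (bits)") +
    ggplot2::ylim(0, log2(20)) +
    ggplot2::theme_minimal()
}

#' Plot distance-to-closest-eukaryote distributions
#'
#' One panel per metric; resistant bacteria highlighted when the records
#' are joined with a taxonomy carrying `resistant`. The published figures
#' show the analogous per-family distributions with the top-200 cut.
#'
#' @param records proximity records ([proximity_records()]), optionally
#'   with a `resistant` column.
#' @param k optional cut: mark the k closest species per metric.
#' @return a ggplot.
#' @export
plot_proximity <- function(records, k = NULL) {
  long <- records |>
    tidyr::pivot_longer(dplyr::any_of(c("dist_E", "dist_T", "dist_S")),
                        names_to = "metric", values_to = "distance") |>
    filter(!is.na(.data$distance)) |>
    group_by(.data$family, .data$metric) |>
    arrange(.data$distance, .data$species_id, .by_group = TRUE) |>
    mutate(rank = row_number()) |>
    ungroup()
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$rank, y = .data$distance))
  if ("resistant" %in% names(long)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(color = factor(.data$resistant)),
                                 size = 0.8) +
      ggplot2::labs(color = "resistant")
  } else {
    p <- p + ggplot2::geom_point(size = 0.8)
  }
  if (!is.null(k)) {
    p <- p + ggplot2::geom_vline(xintercept = k + 0.5, linetype = "dashed")
  }
  p +
    ggplot2::facet_grid(ggplot2::vars(.data$metric),
                        ggplot2::vars(.data$family), scales = "free") +
    ggplot2::labs(x = "bacteria ranked by proximity",
                  y = "distance to closest eukaryotic homolog") +
    ggplot2::theme_minimal()
}

#' Plot the species-by-family presence matrix
#'
#' @param presence output of [build_presence()].
#' @return a ggplot tile map, rows grouped by clade.
#' @export
plot_presence <- function(presence) {
  fams <- setdiff(names(presence),
                  c("species_id", "clade", "genus", "resistant"))
  long <- presence |>
    tidyr::pivot_longer(dplyr::all_of(fams), names_to = "family",
                        values_to = "present") |>
    arrange(.data$clade, .data$species_id)
  long$species_id <- factor(long$species_id, levels = unique(long$species_id))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$family, y = .data$species_id, fill = .data$present
  )) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_manual(values = c("FALSE" = "white", "TRUE" = "steelblue")) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 5))
}
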