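# ggplot2 helpers mirroring the pipeline's standard summary panels.

#' Information-content profile of a fitted motif
#'
#' @param object A `zoops_motif`.
#' @param ... Unused.
#' @return A ggplot: per-column information content in bits.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.zoops_motif <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$column, y = .data$ic)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$consensus, y = 0),
                       vjust = 1.4, size = 3) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "Motif column", y = "Information content (bits)",
                  title = object$id) +
    ggplot2::ylim(-0.2, 2) +
    ggplot2::theme_minimal()
}

#' Motif positions relative to the start codon
#'
#' @param hits Retained hit tibble.
#' @return A ggplot of CDS-relative midpoint distributions per motif.
#' @export
plot_motif_positions <- function(hits) {
  df <- dplyr::mutate(hits, midpoint = (.data$start + .data$end) / 2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$motif_id, y = .data$midpoint)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, fill = "grey85") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Position relative to start codon (bp)") +
    ggplot2::theme_minimal()
}

#' Spacer-distance distributions per lineage
#'
#' @param spacers Spacer tibble from [spacer_distances()], joined with a
#'   `lineage` column.
#' @return A ggplot of spacer distances per lineage.
#' @export
plot_spacer_distribution <- function(spacers) {
  ggplot2::ggplot(spacers,
                  ggplot2::aes(x = .data$lineage, y = .data$d_spacer)) +
    ggplot2::geom_boxplot(fill = "grey85", outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "Spacer distance (bp)") +
    ggplot2::theme_minimal()
}

#' Element accessibility fold changes across cell types
#'
#' Dashed line marks the promoter average (fold change 1).
#'
#' @param records Accessibility record tibble from [box_fold_change()].
#' @return A ggplot.
#' @export
plot_accessibility <- function(records) {
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$element_id, y = .data$FC,
                               colour = .data$stage)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, size = 2) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "red") +
    ggplot2::labs(x = NULL, y = "Fold change over promoter mean",
                  colour = "Stage") +
    ggplot2::theme_minimal()
}
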