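# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot RSCU values of a codon profile
#'
#' Bar chart of RSCU per codon, grouped by amino acid and coloured by
#' classification (overrepresented / high-frequency / normal /
#' underrepresented).
#'
#' @param object A `codon_profile` with RSCU computed.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.codon_profile <- function(object, ...) {
  df <- tidy(object)
  df <- df[!is.na(df$rscu), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$codon, y = .data$rscu,
                                   fill = .data$classification)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(0.6, 1, 1.6), linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::facet_grid(~amino_acid, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = "RSCU") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       size = 6))
}

#' Plot SSR counts by motif category
#'
#' @param ssrs An SSR locus tibble from [find_ssrs()] (one or more genomes).
#' @param by Grouping column: `"category"`, `"region"`, `"context"` or
#'   `"length_bin"`.
#' @return A ggplot object.
#' @export
plot_ssr_summary <- function(ssrs, by = c("category", "region", "context", "length_bin")) {
  by <- rlang::arg_match(by)
  if (by == "category" && !"category" %in% names(ssrs)) {
    ssrs <- dplyr::mutate(ssrs, category = c("mono", "di", "tri", "tetra",
                                             "penta", "hexa")[.data$unit_len])
  }
  ggplot2::ggplot(ssrs, ggplot2::aes(x = .data[[by]], fill = .data$genome)) +
    ggplot2::geom_bar(position = "dodge") +
    ggplot2::labs(x = by, y = "SSR loci") +
    ggplot2::theme_minimal()
}

#' Plot ranked divergence hotspots
#'
#' SV bars with nucleotide diversity overlaid as points for the top-ranked
#' loci of a [scan_hotspots()] table.
#'
#' @param hotspots A hotspot tibble.
#' @param top Number of loci to show.
#' @return A ggplot object.
#' @export
plot_hotspots <- function(hotspots, top = 20) {
  df <- utils::head(hotspots, top)
  df$locus <- factor(df$locus, levels = rev(df$locus))
  scale <- max(df$sv) / max(df$pi + 1e-9)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$locus)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$sv), fill = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$pi * scale), colour = "firebrick") +
    ggplot2::coord_flip() +
    ggplot2::scale_y_continuous(
      name = "SV (%)",
      sec.axis = ggplot2::sec_axis(~ . / scale, name = "pi")
    ) +
    ggplot2::labs(x = NULL) +
    ggplot2::theme_minimal()
}
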