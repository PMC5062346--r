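#' Plot a site profile
#'
#' Entropy along the alignment, coloured by site class, with loop
#' segments shaded — the classic conservation landscape of a barcode
#' region.
#'
#' @param object A `site_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot site_profile
#' @export
autoplot.site_profile <- function(object, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                        y = .data$entropy))
  loops <- df |>
    filter(.data$segment_type == "loop") |>
    group_by(segment = .data$segment) |>
    summarise(xmin = min(.data$position) - 0.5,
              xmax = max(.data$position) + 0.5, .groups = "drop")
  if (nrow(loops) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = loops,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "grey90")
  }
  p +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$position, yend = 0,
                                       colour = .data$class)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "Alignment column", y = "Entropy (nats)",
                  colour = "Site class") +
    ggplot2::theme_minimal()
}

#' Plot a codon-wise selection profile
#'
#' @param object A `codon_selection_profile`.
#' @param ... Unused.
#' @return A ggplot object: per-codon dN/dS on a log scale with the
#'   neutral expectation at 1 marked.
#' @method autoplot codon_selection_profile
#' @export
autoplot.codon_selection_profile <- function(object, ...) {
  df <- as_tibble(object) |> filter(!is.na(.data$dnds), .data$dnds > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$codon, y = .data$dnds)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Codon", y = "dN/dS") +
    ggplot2::theme_minimal()
}

#' Plot a substitution matrix
#'
#' @param object A `substitution_matrix`.
#' @param ... Unused.
#' @return A ggplot tile plot of the twelve directional rates
#'   (off-diagonal sum 100).
#' @method autoplot substitution_matrix
#' @export
autoplot.substitution_matrix <- function(object, ...) {
  df <- as.data.frame(as.table(unclass(object)))
  names(df) <- c("from", "to", "rate")
  df <- df[df$from != df$to, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$to, y = .data$from,
                                   fill = .data$rate)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$rate))) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = "To", y = "From", fill = "Rate") +
    ggplot2::theme_minimal()
}
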