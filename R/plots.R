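#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_text
#'   geom_hline geom_vline labs theme_minimal scale_size_continuous
#'   scale_colour_manual position_stack
NULL

#' @export
ggplot2::autoplot

#' Volcano plot of a differential-expression result
#'
#' @param object A `tsrna_de` tibble from [differential_expression()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot tsrna_de
autoplot.tsrna_de <- function(object, ...) {
  alpha <- attr(object, "alpha")
  fc <- attr(object, "fc")
  df <- as_tibble(object)
  ggplot(df, aes(x = .data$log2fc, y = -log10(.data$p_value),
                 colour = .data$status)) +
    geom_point(size = 1) +
    geom_vline(xintercept = c(-log2(fc), log2(fc)), linetype = "dashed") +
    geom_hline(yintercept = -log10(alpha), linetype = "dotted") +
    scale_colour_manual(values = c(down = "#2166ac", ns = "grey70",
                                   up = "#b2182b")) +
    labs(x = sprintf("log2 fold change (%s / %s)", attr(object, "case"),
                     attr(object, "control")),
         y = "-log10 p", colour = NULL) +
    theme_minimal()
}

#' Sequence logo of a position frequency matrix
#'
#' Letters stacked per position, scaled by base frequency — the textual
#' equivalent of a seed / 3'-end sequence logo.
#'
#' @param object A `tsrna_pfm` from [position_frequency_matrix()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot tsrna_pfm
autoplot.tsrna_pfm <- function(object, ...) {
  df <- tidy(object) |> filter(.data$freq > 0)
  ggplot(df, aes(x = .data$position, y = .data$freq, fill = .data$base,
                 label = .data$base)) +
    geom_col(position = position_stack(), width = 0.9, alpha = 0.2) +
    geom_text(aes(size = .data$freq),
              position = position_stack(vjust = 0.5), show.legend = FALSE) +
    scale_size_continuous(range = c(2, 8)) +
    labs(x = sprintf("position (%s window)",
                     sub("three_prime", "3' end", object$window)),
         y = "base frequency", fill = NULL) +
    theme_minimal()
}

#' Bar chart of a fragment length distribution
#'
#' @param distribution A tibble from [length_distribution()].
#' @return A ggplot.
#' @export
plot_length_distribution <- function(distribution) {
  ggplot(distribution, aes(x = .data$length, y = 100 * .data$fraction)) +
    geom_col(fill = "#4393c3") +
    labs(x = "fragment length (nt)", y = "% of expression") +
    theme_minimal()
}

#' Bar chart of a tsRNA type composition
#'
#' @param composition A tibble from [type_composition()].
#' @return A ggplot.
#' @export
plot_type_composition <- function(composition) {
  ggplot(composition, aes(x = stats::reorder(.data$type, -.data$fraction),
                          y = 100 * .data$fraction)) +
    geom_col(fill = "#d6604d") +
    labs(x = NULL, y = "% of expression") +
    theme_minimal()
}
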