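#' Sequence logo plot of a frequency matrix
#'
#' Letters are stacked per position, each letter's height its frequency times
#' the position's information content in bits (the standard logo scaling).
#'
#' @param fm A `freq_matrix` from [frequency_matrix()].
#' @param min_freq Residues below this frequency are not drawn.
#' @return A ggplot object.
#' @export
plot_logo <- function(fm, min_freq = 0.02) {
  ic <- information_content(fm)
  df <- tidy(fm) |>
    mutate(ic = ic[.data$position],
           height = .data$frequency * .data$ic) |>
    filter(.data$frequency >= min_freq) |>
    arrange(.data$position, .data$height) |>
    group_by(.data$position) |>
    mutate(ymax = cumsum(.data$height),
           ymid = .data$ymax - .data$height / 2,
           size = .data$height) |>
    ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$ymid)) +
    ggplot2::geom_text(ggplot2::aes(label = .data$residue,
                                    size = .data$size,
                                    colour = .data$residue),
                       fontface = "bold", show.legend = FALSE) +
    ggplot2::scale_size(range = c(1, 8)) +
    ggplot2::scale_x_continuous(breaks = seq_len(max(df$position))) +
    ggplot2::labs(x = "position", y = "bits") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.freq_matrix <- function(object, ...) plot_logo(object, ...)

#' Coupling-strength heatmap of a Potts model
#'
#' Upper triangle of the (optionally APC-corrected) Frobenius norms of the
#' zero-sum-gauge coupling blocks.
#'
#' @param model A [potts_model()].
#' @param apc Use APC-corrected norms?
#' @return A ggplot object.
#' @export
plot_couplings <- function(model, apc = TRUE) {
  tc <- top_coupled_pairs(model, apc = apc) |> select(-"residue_pairs")
  ggplot2::ggplot(tc, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "position i", y = "position j",
                  fill = if (apc) "APC norm" else "Frobenius") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.potts_model <- function(object, ...) plot_couplings(object, ...)

#' Prediction distribution of a generation round
#'
#' Histogram of the predicted Ki of the novel pool (log10 molar) with the
#' selection threshold marked.
#'
#' @param object A `generation_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.generation_result <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = log10(.data$predicted_ki))) +
    ggplot2::geom_histogram(bins = 40, fill = "grey60") +
    ggplot2::geom_vline(xintercept = log10(object$threshold),
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "predicted Ki (log10 M)", y = "novel sequences") +
    ggplot2::theme_minimal()
}
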