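# ggplot2 views of a profile.

#' Plot an isomiR profile
#'
#' `autoplot()` shows per-category read counts; `plot_length_distribution()`
#' the abundance by read length and category.
#'
#' @param object An `isomir_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot isomir_profile
#' @export
autoplot.isomir_profile <- function(object, ...) {
  s <- object$summary
  d <- tibble(
    category = factor(c("exclusive", "ambiguous", "variant", "unmapped"),
                      levels = c("exclusive", "ambiguous", "variant",
                                 "unmapped")),
    reads = c(s$exclusive_reads, s$ambiguous_reads, s$variant_reads,
              s$unmapped_reads))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$category, y = .data$reads)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "reads",
                  title = "Read mapping categories") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname autoplot.isomir_profile
#' @param profile An `isomir_profile`.
#' @export
plot_length_distribution <- function(profile) {
  d <- profile$hits |>
    mutate(length = nchar(.data$seq)) |>
    group_by(.data$length, .data$category) |>
    summarise(reads = sum(.data$count), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$length, y = .data$reads,
                                  fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "read length (nt)", y = "reads",
                  title = "isomiR length distribution") +
    ggplot2::theme_minimal()
}
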