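#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the GIF contribution by pairwise genetic distance
#'
#' Side-by-side bars of the case and mean-control contribution to the GIF
#' statistic per meiotic distance class — the standard diagnostic for
#' whether excess relatedness is confined to close relatives (suggesting
#' shared environment) or extends to distant ones (suggesting shared
#' genetics).
#'
#' @param object A `gif_test`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gif_test <- function(object, ...) {
  df <- contribution_plot_data(object) |>
    tidyr::pivot_longer(-"distance", names_to = "group",
                        values_to = "contribution") |>
    dplyr::mutate(group = dplyr::recode(.data$group,
                                        case_contribution = "cases",
                                        mean_control_contribution = "controls"))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$distance),
                                   y = .data$contribution,
                                   fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = "pairwise genetic distance (meioses)",
      y = "contribution to GIF",
      fill = NULL,
      title = sprintf("%s contribution by genetic distance (p = %.3g)",
                      if (object$variant == "distant") "distant GIF" else "GIF",
                      object$empirical_p)) +
    ggplot2::theme_minimal()
}

#' Plot the matched-control GIF distribution
#'
#' Histogram of the control-set GIF values with the case GIF marked; the
#' empirical p-value is the (add-one) fraction of control sets at or above
#' the case line.
#'
#' @param r A `gif_test`.
#' @return A ggplot.
#' @export
plot_control_distribution <- function(r) {
  stopifnot(inherits(r, "gif_test"))
  ggplot2::ggplot(tibble::tibble(gif = r$control_gifs),
                  ggplot2::aes(x = .data$gif)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = r$case_gif, colour = "red",
                        linewidth = 1) +
    ggplot2::labs(x = "control-set GIF", y = "count",
                  title = sprintf("case GIF %.2f vs %d control sets (p = %.3g)",
                                  r$case_gif, r$n_sets, r$empirical_p)) +
    ggplot2::theme_minimal()
}

#' Plot a relative-risk table
#'
#' Point estimates with 95% confidence intervals by relationship degree,
#' faceted by proband age stratum; the dashed line marks RR = 1.
#'
#' @param object An `rr_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rr_table <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = factor(.data$degree), y = .data$rr)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::facet_wrap(~age_stratum) +
    ggplot2::labs(x = "relationship degree",
                  y = "relative risk (observed / expected)") +
    ggplot2::theme_minimal()
}

#' Plot a pedigree scan
#'
#' Observed/expected excess against expected count per founder pedigree,
#' with flagged pedigrees highlighted.
#'
#' @param object A `pedigree_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pedigree_scan <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::filter(.data$n_desc_with_cert > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$expected, y = .data$observed,
                                   colour = .data$flagged)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = "expected disease deaths", y = "observed disease deaths",
                  colour = "flagged") +
    ggplot2::theme_minimal()
}
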