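#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a GIF test: the contribution-by-distance table
#'
#' @param x A `gif_test`.
#' @param ... Unused.
#' @return Tibble with one row per meiotic distance class (see
#'   [contribution_plot_data()]).
#' @export
tidy.gif_test <- function(x, ...) contribution_plot_data(x)

#' One-row summary of a GIF test
#'
#' @param x A `gif_test`.
#' @param ... Unused.
#' @return Tibble: `variant`, `n_cases`, `n_sets`, `case_gif`,
#'   `mean_control_gif`, `empirical_p`.
#' @export
glance.gif_test <- function(x, ...) {
  tibble::tibble(
    variant = x$variant,
    n_cases = x$n_cases,
    n_sets = x$n_sets,
    case_gif = x$case_gif,
    mean_control_gif = x$mean_control_gif,
    empirical_p = x$empirical_p
  )
}

#' @export
tidy.rr_table <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.rr_table <- function(x, ...) {
  tibble::tibble(
    n_rows = nrow(x),
    n_significant = sum(x$p_value < 0.05, na.rm = TRUE),
    max_rr = suppressWarnings(max(x$rr, na.rm = TRUE))
  )
}

#' @export
tidy.pedigree_scan <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.pedigree_scan <- function(x, ...) {
  tibble::tibble(
    n_pedigrees = nrow(x),
    n_flagged = sum(x$flagged),
    min_p = suppressWarnings(min(x$p_value, na.rm = TRUE))
  )
}
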