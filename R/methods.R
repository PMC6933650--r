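#' @export
print.ppi_anneal <- function(x, ...) {
  cat(
    "<ppi_anneal> f(A) = ", format(x$best_score, digits = 6), ": ",
    length(x$selected), "/", nrow(x$candidates), " candidate edges selected, ",
    dplyr::n_distinct(x$alignment$matchset), " matchsets (",
    x$trajectory$level[nrow(x$trajectory)], " levels run, seed ",
    x$seed %||% NA, ")\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy methods for annealing fits
#'
#' `tidy()` returns the alignment as a matchset table, `glance()` a one-row
#' run summary, and `autoplot()` the per-level score and acceptance-rate
#' trajectories.
#'
#' @param x A `ppi_anneal` fit from [anneal()].
#' @param ... Unused.
#' @return `tidy()`: a tibble with `matchset`, `protein`; `glance()`: a
#'   one-row tibble; `autoplot()`: a ggplot object.
#' @export
tidy.ppi_anneal <- function(x, ...) x$alignment

#' @rdname tidy.ppi_anneal
#' @export
glance.ppi_anneal <- function(x, ...) {
  tibble::tibble(
    best_score = x$best_score,
    n_selected = length(x$selected),
    n_candidates = nrow(x$candidates),
    n_matchsets = dplyr::n_distinct(x$alignment$matchset),
    n_aligned = nrow(x$alignment),
    levels_run = nrow(x$trajectory),
    alpha = x$alpha,
    s = x$s,
    seed = x$seed %||% NA_integer_
  )
}

#' @rdname tidy.ppi_anneal
#' @param object A `ppi_anneal` fit.
#' @export
autoplot.ppi_anneal <- function(object, ...) {
  object$trajectory |>
    tidyr::pivot_longer(
      c("current_score", "best_score", "acceptance_rate"),
      names_to = "series", values_to = "value"
    ) |>
    ggplot2::ggplot(ggplot2::aes(
      x = .data$level, y = .data$value, colour = .data$series
    )) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(
      ggplot2::vars(.data$series == "acceptance_rate"),
      scales = "free_y",
      labeller = ggplot2::as_labeller(
        c("TRUE" = "acceptance rate", "FALSE" = "alignment score f(A)")
      )
    ) +
    ggplot2::labs(
      x = "temperature level", y = NULL, colour = NULL,
      title = "Simulated-annealing trajectory"
    ) +
    ggplot2::theme_minimal()
}

#' Feature-vector heat map of a network
#'
#' Plots the normalized 5-tuple feature coordinates of every node, a quick
#' visual check of which proteins dominate each coordinate.
#'
#' @param network A [ppi_network].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_features <- function(network, ...) {
  normalize_features(node_features(network)) |>
    tidyr::pivot_longer(
      dplyr::all_of(feature_cols()),
      names_to = "coordinate", values_to = "value"
    ) |>
    dplyr::mutate(
      coordinate = factor(.data$coordinate, levels = feature_cols())
    ) |>
    ggplot2::ggplot(ggplot2::aes(
      x = .data$coordinate, y = .data$node, fill = .data$value
    )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(
      x = "feature coordinate", y = NULL, fill = "normalized\nvalue",
      title = paste0("Topological features: ", network_id(network))
    ) +
    ggplot2::theme_minimal()
}
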