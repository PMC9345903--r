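#' Funnel plot of an SL screen
#'
#' Bars of the candidate-pair counts passing each procedure and the final
#' conjunction.
#'
#' @param object An `sl_screen`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot sl_screen
autoplot.sl_screen <- function(object, ...) {
  g <- glance.sl_screen(object)
  df <- tibble::tibble(
    stage = factor(
      c("tested", "diff. expression", "co-expression", "functional sim.", "mutual excl.", "all four"),
      levels = c("tested", "diff. expression", "co-expression", "functional sim.", "mutual excl.", "all four")
    ),
    n = c(g$n_pairs, g$n_pass_de, g$n_pass_coexpr, g$n_pass_fss, g$n_pass_mutex, g$n_pass_all)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "candidate pairs", title = "SL screen funnel") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' RAS bar plot of a ranked candidate table
#'
#' @param object An `sl_ranking`.
#' @param top Show at most this many pairs.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot sl_ranking
autoplot.sl_ranking <- function(object, top = 30L, ...) {
  df <- dplyr::slice_head(tibble::as_tibble(object), n = top) |>
    dplyr::mutate(pair = paste(.data$driver, .data$partner, sep = " - "))
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$pair, .data$ras), y = .data$ras
  )) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "rank aggregation score (-log2 Stuart p)",
      title = "Aggregated SL candidate ranking"
    ) +
    ggplot2::theme_minimal()
}

#' Layered plot of the driver-target-drug network
#'
#' Drivers, targets and drugs on three vertical layers with typed edges.
#'
#' @param object A `dmdg_network`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot dmdg_network
autoplot.dmdg_network <- function(object, ...) {
  layer_x <- c(driver = 0, target = 1, drug = 2)
  nodes <- object$nodes |>
    dplyr::group_by(.data$type) |>
    dplyr::mutate(
      x = layer_x[.data$type[1]],
      y = seq(0, 1, length.out = max(dplyr::n(), 2))[seq_len(dplyr::n())]
    ) |>
    dplyr::ungroup()
  pos <- nodes |> dplyr::select("id", "x", "y")
  edges <- object$edges |>
    dplyr::left_join(pos, by = c(from = "id")) |>
    dplyr::left_join(pos, by = c(to = "id"), suffix = c("", "_to"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(
        x = .data$x, y = .data$y, xend = .data$x_to, yend = .data$y_to,
        color = .data$type
      ),
      alpha = 0.6
    ) +
    ggplot2::geom_point(data = nodes, ggplot2::aes(x = .data$x, y = .data$y, shape = .data$type), size = 3) +
    ggplot2::geom_text(
      data = nodes, ggplot2::aes(x = .data$x, y = .data$y, label = .data$id),
      vjust = -1, size = 2.6
    ) +
    ggplot2::scale_x_continuous(
      breaks = unname(layer_x),
      labels = c("drivers", "targets", "drugs"), limits = c(-0.3, 2.3)
    ) +
    ggplot2::labs(x = NULL, y = NULL, title = "Driver - target - drug network") +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.y = ggplot2::element_blank(),
      panel.grid = ggplot2::element_blank()
    )
}
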