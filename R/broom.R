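#' Tidy an SL screen result
#'
#' @param x An `sl_screen` tibble.
#' @param ... Unused.
#' @return A plain tibble of per-pair statistics and flags.
#' @export
#' @method tidy sl_screen
tidy.sl_screen <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' One-row summary of an SL screen
#'
#' @param x An `sl_screen` tibble.
#' @param ... Unused.
#' @return Tibble with pair counts passing each procedure and all four.
#' @export
#' @method glance sl_screen
glance.sl_screen <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x),
    n_pass_de = sum(x$pass_de, na.rm = TRUE),
    n_pass_coexpr = sum(x$pass_coexpr, na.rm = TRUE),
    n_pass_fss = sum(x$pass_fss, na.rm = TRUE),
    n_pass_mutex = sum(x$pass_mutex, na.rm = TRUE),
    n_pass_all = sum(x$pass_all, na.rm = TRUE)
  )
}

#' @rdname tidy.sl_screen
#' @export
#' @method tidy sl_ranking
tidy.sl_ranking <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' One-row summary of a rank aggregation
#'
#' @param x An `sl_ranking` tibble.
#' @param ... Unused.
#' @return Tibble: number of pairs, RAS range.
#' @export
#' @method glance sl_ranking
glance.sl_ranking <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x),
    max_ras = max(x$ras),
    min_ras = min(x$ras)
  )
}

#' Tidy an elastic-net mutation classifier
#'
#' @param x An `en_model`.
#' @param ... Unused.
#' @return Tibble of nonzero coefficients at the selected lambda.
#' @export
#' @method tidy en_model
tidy.en_model <- function(x, ...) {
  co <- as.matrix(coef(x$fit, s = "lambda.min"))
  tibble::tibble(term = rownames(co), estimate = co[, 1]) |>
    dplyr::filter(.data$estimate != 0)
}

#' One-row summary of an elastic-net mutation classifier
#'
#' @param x An `en_model`.
#' @param ... Unused.
#' @return Tibble: alpha, lambda, nonzero coefficient count.
#' @export
#' @method glance en_model
glance.en_model <- function(x, ...) {
  tibble::tibble(
    alpha = x$alpha,
    lambda = x$lambda,
    n_genes = length(x$genes),
    n_nonzero = nrow(tidy.en_model(x)) - 1L # minus intercept
  )
}

#' Tidy a driver-target-drug network into an edge table
#'
#' @param x A `dmdg_network`.
#' @param ... Unused.
#' @return Edge tibble with node types joined on.
#' @export
#' @method tidy dmdg_network
tidy.dmdg_network <- function(x, ...) {
  types <- setNames(x$nodes$type, x$nodes$id)
  dplyr::mutate(x$edges,
    from_type = unname(types[.data$from]),
    to_type = unname(types[.data$to])
  )
}

#' One-row summary of a driver-target-drug network
#'
#' @param x A `dmdg_network`.
#' @param ... Unused.
#' @return Tibble of node and edge counts by type.
#' @export
#' @method glance dmdg_network
glance.dmdg_network <- function(x, ...) {
  tibble::tibble(
    n_drivers = sum(x$nodes$type == "driver"),
    n_targets = sum(x$nodes$type == "target"),
    n_drugs = sum(x$nodes$type == "drug"),
    n_sl_edges = sum(x$edges$type == "sl"),
    n_target_edges = sum(x$edges$type == "targets"),
    n_effective_edges = sum(x$edges$type == "effective")
  )
}

#' @export
print.dmdg_network <- function(x, ...) {
  g <- glance.dmdg_network(x)
  cat(sprintf(
    "<dmdg_network> %d drivers, %d targets, %d drugs; %d sl / %d targets / %d effective edges\n",
    g$n_drivers, g$n_targets, g$n_drugs,
    g$n_sl_edges, g$n_target_edges, g$n_effective_edges
  ))
  invisible(x)
}
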