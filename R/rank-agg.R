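#' Normalize per-criterion ranks of screened pairs
#'
#' Ranks the final candidate pairs under each criterion — FSS (higher
#' better), log2 fold change (higher better), Spearman rho (higher better),
#' mutual-exclusivity adjusted p (lower better) — with average ranks for
#' ties, and normalizes to `rank / n` so each criterion contributes a value
#' in (0, 1] with 1/n the best.
#'
#' @param candidates Tibble with columns `fss`, `log2fc`, `rho`,
#'   `mutex_padj` (an `sl_screen` restricted to its final set, typically).
#' @param directions Named character vector mapping criterion column to
#'   `"desc"` (larger is better) or `"asc"`.
#' @return `candidates` with normalized rank columns `r_fss`, `r_log2fc`,
#'   `r_rho`, `r_mutex_padj`.
#' @export
normalize_ranks <- function(candidates,
                            directions = c(
                              fss = "desc", log2fc = "desc",
                              rho = "desc", mutex_padj = "asc"
                            )) {
  candidates <- tibble::as_tibble(candidates)
  n <- nrow(candidates)
  stopifnot(n >= 1L)
  for (col in names(directions)) {
    if (!col %in% names(candidates)) abort(sprintf("missing criterion column '%s'", col))
    v <- candidates[[col]]
    if (anyNA(v)) {
      abort(sprintf(
        "criterion '%s' undefined for pair(s): %s", col,
        paste(head(which(is.na(v)), 3), collapse = ", ")
      ))
    }
    r <- if (directions[[col]] == "desc") rank(-v, ties.method = "average") else rank(v, ties.method = "average")
    candidates[[paste0("r_", col)]] <- r / n
  }
  candidates
}

#' Stuart order-statistics p-value
#'
#' Probability that m independent uniforms have all order statistics below
#' the given normalized rank vector: `P(U_(k) <= r_k for every k)`,
#' computed by the stable recursion `V_0 = 1`,
#' `V_k = sum_{i=1..k} (-1)^(i-1) (V_{k-i} / i!) r_{m-k+1}^i`, with
#' `p = m! * V_m`. Small values mean the pair ranks near the top under all
#' criteria at once.
#'
#' @param r Normalized ranks in (0, 1], sorted ascending.
#' @return p-value in (0, 1].
#' @export
#' @examples
#' stuart_p(c(0.2, 0.4)) # 0.12
stuart_p <- function(r) {
  stopifnot(length(r) >= 1L, all(r > 0), all(r <= 1))
  if (is.unsorted(r)) abort("`r` must be sorted ascending")
  m <- length(r)
  v <- c(1, rep(0, m))
  for (k in seq_len(m)) {
    i <- seq_len(k)
    v[k + 1] <- sum((-1)^(i - 1) * v[k - i + 1] / factorial(i) * r[m - k + 1]^i)
  }
  min(max(factorial(m) * v[m + 1], 0), 1)
}

#' Rank aggregation score
#'
#' `RAS = -log2(p)`: 0 for p = 1, larger for more concordant rankings.
#' Zero p-values are capped at `floor` with a warning.
#'
#' @param p Stuart p-value(s) in (0, 1].
#' @param floor Smallest admissible p.
#' @return Non-negative score(s).
#' @export
ras <- function(p, floor = 1e-300) {
  if (any(p < 0 | p > 1)) abort("p must lie in [0, 1]")
  if (any(p == 0)) {
    warn(sprintf("p-value(s) of 0 capped at %g", floor))
    p <- pmax(p, floor)
  }
  -log2(p)
}

#' Aggregate the four screening criteria into a ranked candidate table
#'
#' Normalizes the per-criterion ranks, evaluates the Stuart order-statistics
#' p-value per pair (criteria sorted internally, so their input order is
#' irrelevant), converts to RAS, and sorts by RAS descending with a
#' deterministic tie-break on (driver, partner).
#'
#' @param candidates Final screened pairs with `fss`, `log2fc`, `rho`,
#'   `mutex_padj` columns (and `driver`, `partner` identifiers).
#' @param directions Passed to [normalize_ranks()].
#' @return An `sl_ranking` tibble with `stuart_p`, `ras`, `final_rank`.
#' @export
aggregate_ranks <- function(candidates,
                            directions = c(
                              fss = "desc", log2fc = "desc",
                              rho = "desc", mutex_padj = "asc"
                            )) {
  ranked <- normalize_ranks(candidates, directions)
  rcols <- paste0("r_", names(directions))
  rmat <- as.matrix(ranked[rcols])
  p <- apply(rmat, 1, function(r) stuart_p(sort(r)))
  out <- ranked |>
    dplyr::mutate(stuart_p = p, ras = ras(p)) |>
    dplyr::arrange(dplyr::desc(.data$ras), .data$driver, .data$partner) |>
    dplyr::mutate(final_rank = dplyr::row_number())
  structure(out, class = c("sl_ranking", class(out)))
}
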