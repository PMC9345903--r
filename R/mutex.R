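#' Margin-aware background model for a binary mutation matrix
#'
#' Fits per-cell mutation probabilities `p_ij = plogis(u_i + v_j)` (gene
#' effect + sample-burden effect) so that expected row sums match observed
#' per-gene mutation counts and expected column sums match observed
#' per-sample burdens. The fit alternates one-dimensional Newton solves on
#' the row and column margins until the largest margin residual is below
#' `tol`. All-zero or all-one rows and columns are dropped first with a
#' warning (their margin equations have no interior solution).
#'
#' @param mut Binary genes x samples matrix with dimnames.
#' @param max_iter Maximum alternation sweeps.
#' @param tol Margin tolerance.
#' @return A `mutex_background` object: `p` (probability matrix), `u`, `v`,
#'   and `fit_report` (achieved max row/column residuals, iterations).
#' @export
mutex_background <- function(mut, max_iter = 200L, tol = 1e-8) {
  stopifnot(is.matrix(mut), all(mut %in% c(0L, 1L)))
  rs <- rowSums(mut)
  keep_r <- rs > 0 & rs < ncol(mut)
  if (any(!keep_r)) {
    warn(sprintf("dropping %d all-zero/all-one gene row(s)", sum(!keep_r)))
    mut <- mut[keep_r, , drop = FALSE]
  }
  cs <- colSums(mut)
  keep_c <- cs > 0 & cs < nrow(mut)
  if (any(!keep_c)) {
    warn(sprintf("dropping %d all-zero/all-one sample column(s)", sum(!keep_c)))
    mut <- mut[, keep_c, drop = FALSE]
  }
  if (!nrow(mut) || !ncol(mut)) abort("no non-degenerate rows/columns remain")
  r <- rowSums(mut)
  c_ <- colSums(mut)
  u <- qlogis(pmin(pmax(r / ncol(mut), 1e-6), 1 - 1e-6))
  v <- rep(0, ncol(mut))

  newton_margin <- function(offset, eta, target) {
    # solve sum(plogis(offset + eta_j)) = target for offset
    for (it in 1:50) {
      p <- plogis(offset + eta)
      f <- sum(p) - target
      if (abs(f) < tol / 4) break
      fp <- sum(p * (1 - p))
      offset <- offset - f / max(fp, 1e-12)
    }
    offset
  }
  iter <- 0L
  repeat {
    iter <- iter + 1L
    for (i in seq_along(u)) u[i] <- newton_margin(u[i], v, r[i])
    for (j in seq_along(v)) v[j] <- newton_margin(v[j], u, c_[j])
    p <- plogis(outer(u, v, `+`))
    err_r <- max(abs(rowSums(p) - r))
    err_c <- max(abs(colSums(p) - c_))
    if (max(err_r, err_c) < tol || iter >= max_iter) break
  }
  if (max(err_r, err_c) >= tol) {
    abort(sprintf(
      "margin fit did not converge in %d sweeps (row residual %.3g, column residual %.3g)",
      max_iter, err_r, err_c
    ))
  }
  dimnames(p) <- dimnames(mut)
  structure(
    list(
      p = p, u = setNames(u, rownames(mut)), v = setNames(v, colnames(mut)),
      fit_report = list(row_residual = err_r, col_residual = err_c, iterations = iter)
    ),
    class = "mutex_background"
  )
}

# exact lower tail P(C <= cap) of a Poisson-binomial count with success
# probabilities q, by truncated DP (mass above cap is discarded)
poisbinom_lower_tail <- function(q, cap) {
  cap <- min(cap, length(q))
  if (cap < 0) {
    return(0)
  }
  dp <- c(1, rep(0, cap))
  for (qi in q) {
    dp <- dp * (1 - qi) + c(0, dp[-length(dp)]) * qi
  }
  min(sum(dp), 1)
}

#' Mutual-exclusivity test for gene pairs
#'
#' For each pair, the observed co-mutation count is compared with its null
#' distribution under independence given the background model: the
#' co-mutation count is Poisson-binomial with per-sample success
#' probabilities `p_a,i * p_b,i`, and the one-sided p-value is the exact
#' lower tail `P(C <= n_co)` computed by dynamic-programming convolution.
#' Small p-values mean fewer co-mutations than the margins predict —
#' evidence of mutual exclusivity.
#'
#' @param mut Binary mutation matrix (genes x samples).
#' @param pairs Tibble with columns `gene_a`, `gene_b`.
#' @param rates A [mutex_background()] fitted on `mut` (fitted on the fly
#'   when omitted).
#' @return Tibble: gene_a, gene_b, n_co, expected_co, p_value.
#' @export
mutex_test <- function(mut, pairs, rates = NULL) {
  pairs <- tibble::as_tibble(pairs)
  stopifnot(all(c("gene_a", "gene_b") %in% names(pairs)))
  rates <- rates %||% mutex_background(mut)
  samples <- colnames(rates$p)
  n_co <- integer(nrow(pairs))
  expected <- p_value <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    a <- pairs$gene_a[k]
    b <- pairs$gene_b[k]
    if (!a %in% rownames(rates$p) || !b %in% rownames(rates$p)) {
      abort(sprintf("pair (%s, %s) not covered by the background model", a, b))
    }
    q <- rates$p[a, ] * rates$p[b, ]
    n_co[k] <- sum(mut[a, samples] == 1L & mut[b, samples] == 1L)
    expected[k] <- sum(q)
    p_value[k] <- poisbinom_lower_tail(q, n_co[k])
  }
  dplyr::mutate(pairs, n_co = n_co, expected_co = expected, p_value = p_value)
}

#' Benjamini-Hochberg adjustment and pass flags for mutual exclusivity
#'
#' The adjustment family is all pairs in `results` (one screening run).
#' The default threshold 0.15 and the stricter 0.1 are both in routine use;
#' pick via `threshold`.
#'
#' @param results Output of [mutex_test()].
#' @param threshold Pass iff `p_adjust < threshold`.
#' @return `results` with `p_adjust` and logical `pass` columns.
#' @export
adjust_and_flag <- function(results, threshold = 0.15) {
  stopifnot(nrow(results) >= 1L)
  dplyr::mutate(
    tibble::as_tibble(results),
    p_adjust = p.adjust(.data$p_value, method = "BH"),
    pass = .data$p_adjust < threshold
  )
}

# curveball trades on a list of per-row mutated-column index sets: each
# trade picks two rows and redistributes the columns in which exactly one
# of them is mutated; row and column sums are invariant
curveball_chain <- function(rows, n_trades) {
  moved <- 0L
  n <- length(rows)
  ii <- sample.int(n, n_trades, replace = TRUE)
  jj <- sample.int(n - 1L, n_trades, replace = TRUE)
  jj <- ifelse(jj >= ii, jj + 1L, jj) # j != i, uniform over the rest
  for (s in seq_len(n_trades)) {
    ri <- rows[[ii[s]]]
    rj <- rows[[jj[s]]]
    only_i <- ri[!(ri %in% rj)]
    only_j <- rj[!(rj %in% ri)]
    if (!length(only_i) || !length(only_j)) next
    pool <- sample(c(only_i, only_j))
    new_i <- pool[seq_along(only_i)]
    rows[[ii[s]]] <- c(ri[ri %in% rj], new_i)
    rows[[jj[s]]] <- c(rj[rj %in% ri], pool[-seq_along(only_i)])
    moved <- moved + 1L
  }
  list(rows = rows, moved = moved)
}

mat_to_rowsets <- function(mut) {
  lapply(seq_len(nrow(mut)), function(i) which(mut[i, ] == 1L))
}

rowsets_to_mat <- function(rows, template) {
  m <- template
  m[] <- 0L
  for (i in seq_along(rows)) m[i, rows[[i]]] <- 1L
  m
}

#' Curveball randomization of a binary matrix
#'
#' Applies `n_trades` random pair-of-rows trades, each preserving every row
#' and column sum exactly.
#'
#' @param mut Binary matrix.
#' @param n_trades Number of attempted trades (default `5 * nrow`).
#' @return List: the permuted matrix `m` and `moved`, the number of trades
#'   that changed the matrix.
#' @export
curveball_permute <- function(mut, n_trades = 5L * nrow(mut)) {
  ch <- curveball_chain(mat_to_rowsets(mut), n_trades)
  list(m = rowsets_to_mat(ch$rows, mut), moved = ch$moved)
}

#' Permutation oracle for the mutual-exclusivity p-value
#'
#' Estimates `P(co-mutation count <= observed)` under the exact
#' fixed-margin null by a curveball Markov chain: after a burn-in, each of
#' `n_perm` draws is separated by `5 * nrow(mut)` trades and contributes its
#' co-mutation count for the pair. Empirical p uses the add-one rule
#' `(1 + #{draws <= observed}) / (n_perm + 1)`.
#'
#' @param mut Binary matrix.
#' @param pair Character vector of two gene identifiers.
#' @param n_perm Number of permutation draws (>= 100).
#' @param seed Integer seed.
#' @return List: `p`, `observed`, `draws`.
#' @export
mutex_permutation_p <- function(mut, pair, n_perm = 1000L, seed = 1L) {
  stopifnot(length(pair) == 2L, n_perm >= 100L)
  with_seed(child_seed(seed, 606L), {
    obs <- sum(mut[pair[1], ] == 1L & mut[pair[2], ] == 1L)
    ia <- match(pair[1], rownames(mut))
    ib <- match(pair[2], rownames(mut))
    step <- 5L * nrow(mut)
    rows <- mat_to_rowsets(mut)
    burn <- curveball_chain(rows, 4L * step)
    rows <- burn$rows
    total_moved <- burn$moved
    draws <- integer(n_perm)
    for (k in seq_len(n_perm)) {
      ch <- curveball_chain(rows, step)
      rows <- ch$rows
      total_moved <- total_moved + ch$moved
      draws[k] <- sum(rows[[ia]] %in% rows[[ib]])
    }
    if (total_moved == 0L) {
      warn("matrix admits no checkerboard swap; permutation p-value is 1")
      return(list(p = 1, observed = obs, draws = draws))
    }
    list(p = (1 + sum(draws <= obs)) / (n_perm + 1), observed = obs, draws = draws)
  })
}
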