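#' Thresholds for the four-procedure SL screen
#'
#' @param de_padj BH-adjusted Wilcoxon threshold for differential partner
#'   expression (pass additionally requires log2 fold change > 0).
#' @param min_group_size Minimum mutant and wild-type group sizes for the
#'   differential-expression procedure.
#' @param rho_cut Spearman coefficient floor for co-expression in normals.
#' @param coexpr_padj BH-adjusted p threshold for co-expression.
#' @param fss_threshold Pass iff FSS strictly exceeds this (default 0.45).
#' @param mutex_threshold BH-adjusted mutual-exclusivity threshold; 0.15 by
#'   default with 0.1 the documented stricter alternative.
#' @param low_expr_detect Druggable genes detected (expression > 0) in less
#'   than this fraction of tumors, or with zero variance, are dropped.
#' @return A named list of class `screen_config`.
#' @export
screen_config <- function(de_padj = 0.05, min_group_size = 5L,
                          rho_cut = 0.1, coexpr_padj = 0.05,
                          fss_threshold = 0.45, mutex_threshold = 0.15,
                          low_expr_detect = 0.2) {
  assert_fraction(de_padj, "de_padj", closed_hi = TRUE)
  assert_fraction(coexpr_padj, "coexpr_padj", closed_hi = TRUE)
  assert_fraction(fss_threshold, "fss_threshold", closed_hi = TRUE)
  assert_fraction(mutex_threshold, "mutex_threshold", closed_hi = TRUE)
  assert_fraction(low_expr_detect, "low_expr_detect", closed_hi = TRUE)
  structure(
    list(
      de_padj = de_padj, min_group_size = as.integer(min_group_size),
      rho_cut = rho_cut, coexpr_padj = coexpr_padj,
      fss_threshold = fss_threshold, mutex_threshold = mutex_threshold,
      low_expr_detect = low_expr_detect
    ),
    class = "screen_config"
  )
}

#' Procedure 1: differential partner expression in driver-mutant tumors
#'
#' Two-sided Wilcoxon rank-sum test of each candidate partner's tumor
#' expression between driver-mutant and wild-type samples, BH-adjusted
#' across the candidates of this driver. A candidate passes only when it is
#' *up*-regulated in the mutant group (log2 fold change, difference of
#' log2(TPM+1) means, > 0) and `p_adjust` clears the threshold.
#'
#' @param cohort An `sl_cohort`.
#' @param driver Driver gene (must be a row of the mutation matrix).
#' @param candidates Candidate partner genes.
#' @param config A [screen_config()].
#' @return Tibble: partner, log2fc, de_p, de_padj, pass_de. When either
#'   group is smaller than `min_group_size` the driver is skipped with a
#'   warning and all flags are `FALSE`.
#' @export
screen_de <- function(cohort, driver, candidates, config = screen_config()) {
  stopifnot(inherits(cohort, "sl_cohort"))
  if (!driver %in% rownames(cohort$mut)) abort(sprintf("driver '%s' not in mutation matrix", driver))
  status <- cohort$mut[driver, colnames(cohort$expr_tumor)]
  mutant <- names(status)[status == 1L]
  wt <- names(status)[status == 0L]
  if (length(mutant) < config$min_group_size || length(wt) < config$min_group_size) {
    warn(sprintf(
      "driver '%s' skipped: group sizes %d/%d below %d",
      driver, length(mutant), length(wt), config$min_group_size
    ))
    return(tibble::tibble(
      partner = candidates, log2fc = NA_real_, de_p = NA_real_,
      de_padj = NA_real_, pass_de = FALSE
    ))
  }
  res <- purrr::map(candidates, function(g) {
    x <- cohort$expr_tumor[g, mutant]
    y <- cohort$expr_tumor[g, wt]
    p <- suppressWarnings(wilcox.test(x, y)$p.value)
    tibble::tibble(partner = g, log2fc = log2_fc(x, y), de_p = p)
  }) |> dplyr::bind_rows()
  dplyr::mutate(res,
    de_padj = p.adjust(.data$de_p, "BH"),
    pass_de = .data$de_padj < config$de_padj & .data$log2fc > 0
  )
}

#' Procedure 2: pairwise co-expression in normal tissue
#'
#' Spearman correlation of each (driver, partner) pair across normal
#' samples, BH-adjusted across all pairs. Pass requires both
#' `rho > rho_cut` and `p_adjust < coexpr_padj`; a constant expression
#' vector leaves `rho` undefined and fails with a warning.
#'
#' @param cohort An `sl_cohort` with `expr_normal`.
#' @param pairs Tibble with columns `driver`, `partner`.
#' @param config A [screen_config()].
#' @return Tibble: driver, partner, rho, coexpr_p, coexpr_padj, pass_coexpr.
#' @export
screen_coexpression <- function(cohort, pairs, config = screen_config()) {
  stopifnot(inherits(cohort, "sl_cohort"))
  if (is.null(cohort$expr_normal) || ncol(cohort$expr_normal) < 5L) {
    abort("co-expression needs >= 5 normal samples")
  }
  pairs <- tibble::as_tibble(pairs)
  en <- cohort$expr_normal
  rho <- p <- rep(NA_real_, nrow(pairs))
  n_const <- 0L
  for (k in seq_len(nrow(pairs))) {
    x <- en[pairs$driver[k], ]
    y <- en[pairs$partner[k], ]
    if (sd(x) == 0 || sd(y) == 0) {
      n_const <- n_const + 1L
      next
    }
    ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
    rho[k] <- unname(ct$estimate)
    p[k] <- ct$p.value
  }
  if (n_const > 0L) {
    warn(sprintf("%d pair(s) with constant expression: rho undefined, pair fails", n_const))
  }
  dplyr::mutate(pairs,
    rho = rho, coexpr_p = p,
    coexpr_padj = p.adjust(p, "BH"),
    pass_coexpr = !is.na(rho) & rho > config$rho_cut &
      !is.na(.data$coexpr_padj) & .data$coexpr_padj < config$coexpr_padj
  )
}

#' Procedure 3: functional-similarity filter
#'
#' Computes the FSS (geometric mean of Wang MF and CC gene similarities)
#' for each pair; pass requires a defined FSS strictly greater than the
#' threshold, so unannotated genes fail.
#'
#' @param pairs Tibble with `driver`, `partner`.
#' @param graph A [go_graph()].
#' @param annotation Gene annotation tibble.
#' @param config A [screen_config()].
#' @return Tibble: driver, partner, ss_mf, ss_cc, fss, pass_fss.
#' @export
screen_fss <- function(pairs, graph, annotation, config = screen_config()) {
  pairs <- tibble::as_tibble(pairs)
  res <- fss_table(
    dplyr::transmute(pairs, gene_a = .data$driver, gene_b = .data$partner),
    graph, annotation
  )
  dplyr::mutate(pairs,
    ss_mf = res$ss_mf, ss_cc = res$ss_cc, fss = res$fss,
    pass_fss = !is.na(res$fss) & res$fss > config$fss_threshold
  )
}

#' Run the full four-procedure SL screen
#'
#' Crosses every driver with every druggable gene surviving the
#' low-expression drop, runs the four procedures independently
#' (differential expression, co-expression, functional similarity, mutual
#' exclusivity), and conjoins their pass flags into `pass_all`. BH families:
#' per driver for differential expression, all pairs for co-expression and
#' mutual exclusivity — recorded in the manifest attribute together with
#' thresholds and drop counts.
#'
#' @param cohort An `sl_cohort`.
#' @param drivers Driver gene identifiers (rows of the mutation matrix).
#' @param druggable Druggable gene identifiers (rows of the expression
#'   matrices).
#' @param graph,annotation GO graph and gene annotation.
#' @param config A [screen_config()].
#' @return An `sl_screen` tibble: one row per tested pair with all four
#'   procedure statistics and flags; attribute `manifest`.
#' @export
run_sl_screen <- function(cohort, drivers, druggable, graph, annotation,
                          config = screen_config()) {
  stopifnot(inherits(cohort, "sl_cohort"))
  if (!length(drivers) || !length(druggable)) abort("empty driver or druggable-gene list")
  bad <- setdiff(drivers, rownames(cohort$mut))
  if (length(bad)) abort(sprintf("driver(s) not in mutation matrix: %s", paste(bad, collapse = ", ")))
  bad <- setdiff(druggable, rownames(cohort$expr_tumor))
  if (length(bad)) abort(sprintf("druggable gene(s) not in expression: %s", paste(bad, collapse = ", ")))

  et <- cohort$expr_tumor[druggable, , drop = FALSE]
  detect <- rowMeans(et > 0)
  keep <- detect >= config$low_expr_detect & apply(et, 1, sd) > 0
  n_dropped_dg <- sum(!keep)
  druggable <- druggable[keep]
  if (!length(druggable)) abort("no druggable genes survive the low-expression drop")

  pairs <- tidyr::expand_grid(driver = drivers, partner = druggable)

  de <- purrr::map(drivers, function(d) {
    dplyr::mutate(
      screen_de(cohort, d, druggable, config),
      driver = d, .before = 1
    )
  }) |> dplyr::bind_rows()

  co <- screen_coexpression(cohort, pairs, config)
  fs <- screen_fss(pairs, graph, annotation, config)

  rates <- mutex_background(cohort$mut)
  mx <- mutex_test(
    cohort$mut,
    dplyr::transmute(pairs, gene_a = .data$driver, gene_b = .data$partner),
    rates
  ) |>
    adjust_and_flag(threshold = config$mutex_threshold) |>
    dplyr::rename(
      driver = "gene_a", partner = "gene_b",
      mutex_p = "p_value", mutex_padj = "p_adjust", pass_mutex = "pass"
    )

  out <- pairs |>
    dplyr::left_join(de, by = c("driver", "partner")) |>
    dplyr::left_join(co, by = c("driver", "partner")) |>
    dplyr::left_join(fs, by = c("driver", "partner")) |>
    dplyr::left_join(mx, by = c("driver", "partner")) |>
    dplyr::mutate(pass_all = .data$pass_de & .data$pass_coexpr &
      .data$pass_fss & .data$pass_mutex)

  structure(
    out,
    class = c("sl_screen", class(out)),
    manifest = list(
      thresholds = unclass(config),
      n_drivers = length(drivers),
      n_druggable = length(druggable),
      n_druggable_dropped = n_dropped_dg,
      bh_families = list(
        de = "per driver across candidates",
        coexpression = "all pairs", mutex = "all pairs"
      ),
      mutex_fit = rates$fit_report
    )
  )
}
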