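#' Prepare a cell-line pharmacogenomic panel for model training
#'
#' Applies the standard panel filters in order: drop cell lines from
#' excluded lineages (haematopoietic/lymphoid by default), drop compounds
#' whose AUC is missing in more than `na_threshold` of the remaining lines,
#' then impute the remaining missing AUCs by K-nearest-neighbour averaging
#' over compound profiles (neighbours by Euclidean distance on shared
#' observed cell lines). Idempotent: re-preparing a prepared panel is a
#' no-op.
#'
#' @param panel A `drug_panel` (see [simulate_ccl_panel()] for the layout).
#' @param na_threshold Maximum tolerated missing fraction per compound.
#' @param knn_k Neighbours for imputation; reduced with a warning when
#'   fewer are available.
#' @param exclude_lineages Lineage labels to drop.
#' @return A prepared `drug_panel` with complete AUC matrix.
#' @export
prep_drug_panel <- function(panel, na_threshold = 0.2, knn_k = 10L,
                            exclude_lineages = "haematopoietic_and_lymphoid_tissue") {
  stopifnot(inherits(panel, "drug_panel"))
  keep_ccl <- panel$ccl_meta$ccl[!panel$ccl_meta$lineage %in% exclude_lineages]
  auc <- panel$auc[intersect(rownames(panel$auc), keep_ccl), , drop = FALSE]
  na_frac <- colMeans(is.na(auc))
  if (any(na_frac == 1)) {
    warn(sprintf("%d compound(s) with no AUC data dropped", sum(na_frac == 1)))
  }
  auc <- auc[, na_frac <= na_threshold, drop = FALSE]
  if (!ncol(auc)) abort("no compounds survive the missingness filter")
  auc <- knn_impute_columns(auc, k = knn_k)
  structure(
    list(
      ccl_expr = panel$ccl_expr[, intersect(colnames(panel$ccl_expr), rownames(auc)), drop = FALSE],
      auc = auc,
      ccl_meta = dplyr::filter(panel$ccl_meta, .data$ccl %in% rownames(auc))
    ),
    class = "drug_panel",
    auc_true = attr(panel, "auc_true")
  )
}

# KNN imputation over columns of a (rows x columns) matrix: a missing cell
# (i, j) is the mean over the k columns nearest to j (Euclidean distance on
# rows observed in both) that are observed at row i
knn_impute_columns <- function(m, k = 10L) {
  if (!anyNA(m)) {
    return(m)
  }
  nc <- ncol(m)
  if (k >= nc) {
    warn(sprintf("k reduced from %d to %d (available neighbour columns)", k, nc - 1L))
    k <- nc - 1L
  }
  d <- matrix(Inf, nc, nc)
  for (a in seq_len(nc - 1L)) {
    for (b in (a + 1L):nc) {
      shared <- !is.na(m[, a]) & !is.na(m[, b])
      if (any(shared)) {
        d[a, b] <- d[b, a] <- sqrt(mean((m[shared, a] - m[shared, b])^2))
      }
    }
  }
  out <- m
  for (j in seq_len(nc)) {
    miss <- which(is.na(m[, j]))
    if (!length(miss)) next
    nb <- order(d[, j])
    nb <- nb[nb != j & is.finite(d[nb, j])]
    for (i in miss) {
      usable <- nb[!is.na(m[i, nb])]
      if (!length(usable)) {
        out[i, j] <- mean(m[, j], na.rm = TRUE) # isolated cell: column mean
      } else {
        out[i, j] <- mean(m[i, head(usable, k)])
      }
    }
  }
  out
}

#' Train per-compound ridge models of drug response
#'
#' For each compound, regresses AUC on standardized cell-line expression
#' with a ridge penalty (`glmnet`, alpha 0); lambda is chosen by 10-fold
#' cross-validated mean squared error over a log-spaced grid. Predictors
#' are standardized on the training lines and the scaling is stored with
#' the model, so clinical predictions use training-set statistics.
#'
#' @param panel A prepared `drug_panel` (no missing AUCs).
#' @param compounds Compounds to train (default: all columns of `auc`).
#' @param lambda_grid Ridge penalty grid.
#' @param cv_folds Cross-validation folds.
#' @param seed Integer seed fixing the fold assignment.
#' @param min_ccl Minimum lines with AUC per compound.
#' @return A `drug_model_set`: named list of models (genes, center, scale,
#'   intercept, beta, lambda, cv MSE) plus a metadata tibble.
#' @export
train_drug_models <- function(panel, compounds = colnames(panel$auc),
                              lambda_grid = 10^seq(-3, 3, length.out = 13),
                              cv_folds = 10L, seed = 1L, min_ccl = 20L) {
  stopifnot(inherits(panel, "drug_panel"))
  if (anyNA(panel$auc)) abort("panel has missing AUCs; run prep_drug_panel() first")
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  x_all <- t(panel$ccl_expr)
  models <- list()
  for (cpd in compounds) {
    y <- panel$auc[rownames(x_all), cpd]
    ok <- !is.na(y)
    if (sum(ok) < min_ccl) abort(sprintf("compound '%s' has < %d cell lines", cpd, min_ccl))
    if (sum(ok) < cv_folds) abort("fewer cell lines than folds")
    x <- x_all[ok, , drop = FALSE]
    ctr <- colMeans(x)
    scl <- apply(x, 2, sd)
    use <- scl > 0
    z <- sweep(sweep(x[, use, drop = FALSE], 2, ctr[use]), 2, scl[use], "/")
    foldid <- with_seed(
      child_seed(seed, 707L + match(cpd, compounds)),
      sample(rep_len(seq_len(cv_folds), nrow(z)))
    )
    if (sd(y[ok]) == 0) {
      # constant response: intercept-only model
      models[[cpd]] <- list(
        genes = colnames(z), center = ctr[use], scale = scl[use],
        intercept = y[ok][1], beta = setNames(rep(0, ncol(z)), colnames(z)),
        lambda = NA_real_, cv_mse = 0
      )
      next
    }
    cv <- glmnet::cv.glmnet(z, y[ok],
      alpha = 0, lambda = lambda_grid,
      foldid = foldid, standardize = FALSE
    )
    co <- as.matrix(coef(cv, s = "lambda.min"))
    models[[cpd]] <- list(
      genes = colnames(z), center = ctr[use], scale = scl[use],
      intercept = co[1, 1],
      beta = setNames(co[-1, 1], rownames(co)[-1]),
      lambda = cv$lambda.min,
      cv_mse = min(cv$cvm)
    )
  }
  structure(
    list(
      models = models,
      meta = tibble::tibble(
        compound = names(models),
        lambda = vapply(models, `[[`, numeric(1), "lambda"),
        cv_mse = vapply(models, `[[`, numeric(1), "cv_mse")
      )
    ),
    class = "drug_model_set"
  )
}

#' Predict drug response (AUC) in clinical samples
#'
#' Applies each trained ridge model to a clinical expression matrix on the
#' same log2 scale. Model genes absent from the clinical matrix are imputed
#' at the training mean (zero after standardization); if fewer than
#' `min_overlap` of a model's genes are present the prediction is refused.
#'
#' @param models A `drug_model_set`.
#' @param expr Clinical genes x samples matrix (log2 scale).
#' @param min_overlap Minimum fraction of model genes present.
#' @return Samples x compounds matrix of estimated AUC.
#' @export
predict_drug_response <- function(models, expr, min_overlap = 0.5) {
  stopifnot(inherits(models, "drug_model_set"))
  out <- matrix(NA_real_,
    nrow = ncol(expr), ncol = length(models$models),
    dimnames = list(colnames(expr), names(models$models))
  )
  for (cpd in names(models$models)) {
    m <- models$models[[cpd]]
    present <- intersect(m$genes, rownames(expr))
    if (length(present) < min_overlap * length(m$genes)) {
      abort(sprintf(
        "compound '%s': only %d/%d model genes present in the clinical matrix",
        cpd, length(present), length(m$genes)
      ))
    }
    z <- matrix(0, nrow = ncol(expr), ncol = length(m$genes), dimnames = list(colnames(expr), m$genes))
    z[, present] <- sweep(
      sweep(t(expr[present, , drop = FALSE]), 2, m$center[present]),
      2, m$scale[present], "/"
    )
    out[, cpd] <- m$intercept + as.numeric(z %*% m$beta[m$genes])
  }
  out
}

#' Differential estimated drug response between mutant and wild-type samples
#'
#' Compares estimated AUC between driver-mutant and wild-type samples per
#' compound: `logFC = log2(mean AUC mutant / mean AUC wild-type)` and a
#' two-sided Wilcoxon rank-sum p-value. A compound is SL-associated
#' (`sl_flag`) only when the mutant group is *more* sensitive — lower
#' estimated AUC, `logFC < 0` — with `p < p_cut`. Compounds with a
#' non-positive group mean are skipped with a warning.
#'
#' @param estimates Samples x compounds AUC matrix from
#'   [predict_drug_response()].
#' @param mutation_status Named 0/1 vector over samples (one driver).
#' @param compounds Compounds to test (default all).
#' @param p_cut Significance threshold.
#' @return Tibble: compound, logfc, p_value, sl_flag.
#' @export
differential_drug_response <- function(estimates, mutation_status,
                                       compounds = colnames(estimates),
                                       p_cut = 0.05) {
  status <- mutation_status[rownames(estimates)]
  mut <- rownames(estimates)[status == 1L]
  wt <- rownames(estimates)[status == 0L]
  if (length(mut) < 3L || length(wt) < 3L) {
    abort("both mutant and wild-type groups need >= 3 samples")
  }
  res <- purrr::map(compounds, function(cpd) {
    a <- estimates[mut, cpd]
    b <- estimates[wt, cpd]
    if (mean(a) <= 0 || mean(b) <= 0) {
      warn(sprintf("compound '%s' skipped: non-positive mean estimated AUC", cpd))
      return(tibble::tibble(
        compound = cpd, logfc = NA_real_, p_value = NA_real_, sl_flag = FALSE
      ))
    }
    tibble::tibble(
      compound = cpd,
      logfc = log2(mean(a) / mean(b)),
      p_value = suppressWarnings(wilcox.test(a, b)$p.value)
    ) |>
      dplyr::mutate(sl_flag = .data$logfc < 0 & .data$p_value < p_cut)
  })
  dplyr::bind_rows(res)
}
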