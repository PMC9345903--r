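#' Select differentially expressed genes between mutant and wild-type
#'
#' Two-sided Wilcoxon rank-sum test per gene on log2(TPM+1) expression with
#' BH adjustment; a gene is selected when `|log2FC| > lfc_cut` (strict) and
#' `p_adjust < padj_cut`. Returned in a deterministic order (by gene id).
#'
#' @param expr Genes x samples matrix (log2 scale).
#' @param labels Named 0/1 vector over samples.
#' @param lfc_cut Absolute log2 fold-change cut (default 1.5; 1.0 is the
#'   documented looser alternative).
#' @param padj_cut BH-adjusted p cut.
#' @return Character vector of selected genes.
#' @export
select_de_genes <- function(expr, labels, lfc_cut = 1.5, padj_cut = 0.05) {
  labels <- labels[colnames(expr)]
  pos <- names(labels)[labels == 1L]
  neg <- names(labels)[labels == 0L]
  if (length(pos) < 5L || length(neg) < 5L) abort("both classes need >= 5 samples")
  lfc <- rowMeans(expr[, pos, drop = FALSE]) - rowMeans(expr[, neg, drop = FALSE])
  p <- apply(expr, 1, function(v) {
    suppressWarnings(wilcox.test(v[pos], v[neg])$p.value)
  })
  padj <- p.adjust(p, "BH")
  sel <- sort(rownames(expr)[abs(lfc) > lfc_cut & padj < padj_cut])
  if (!length(sel)) {
    abort("no genes pass the selection thresholds; consider relaxing lfc_cut/padj_cut")
  }
  sel
}

#' Train an elastic-net classifier of mutation status
#'
#' Binomial elastic net at mixing parameter `alpha` (0.9 by default: mostly
#' lasso with a ridge stabilizer) over the supplied genes; the
#' regularization strength is chosen by cross-validated deviance with a
#' seed-fixed fold assignment.
#'
#' @param expr Genes x samples matrix restricted to the model genes
#'   (log2 scale).
#' @param labels Named 0/1 vector.
#' @param alpha Elastic-net mixing parameter in \[0, 1\].
#' @param cv_folds CV folds for lambda selection.
#' @param seed Integer seed.
#' @return An `en_model`: glmnet fit, selected lambda, gene set, alpha.
#' @export
train_mutation_classifier <- function(expr, labels, alpha = 0.9,
                                      cv_folds = 10L, seed = 1L) {
  labels <- labels[colnames(expr)]
  if (length(unique(labels)) < 2L) abort("labels contain a single class")
  if (min(table(labels)) < 2L) abort("both classes need >= 2 samples")
  x <- t(expr)
  foldid <- with_seed(child_seed(seed, 808L), sample(rep_len(seq_len(cv_folds), nrow(x))))
  cv <- glmnet::cv.glmnet(x, labels,
    family = "binomial", alpha = alpha,
    foldid = foldid, type.measure = "deviance"
  )
  structure(
    list(
      fit = cv, lambda = cv$lambda.min, alpha = alpha,
      genes = rownames(expr), seed = seed, cv_folds = cv_folds
    ),
    class = "en_model"
  )
}

#' Predict mutation probability from an elastic-net model
#'
#' @param object An `en_model`.
#' @param expr Genes x samples matrix containing the model genes.
#' @param ... Unused.
#' @return Named probability vector.
#' @export
predict.en_model <- function(object, expr, ...) {
  x <- t(expr[object$genes, , drop = FALSE])
  as.numeric(predict(object$fit, newx = x, s = "lambda.min", type = "response")) |>
    setNames(colnames(expr))
}

#' ROC AUC via the Mann-Whitney statistic
#'
#' `AUC = U / (n_pos * n_neg)` — the probability a random positive scores
#' above a random negative, ties counted one half.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels 0/1 labels.
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0)) # 0.75
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) abort("both classes must be present")
  r <- rank(scores) # average ranks make ties count 0.5
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Leave-one-study-out cross-validation of the mutation classifier
#'
#' For each study, the model is trained on all other studies with gene
#' selection redone inside the loop (the held-out study never influences
#' the gene set or the fit), then evaluated on the held-out study:
#' accuracy at probability 0.5 and ROC AUC (reported `NA` when the held-out
#' study has a single class).
#'
#' @param expr Genes x samples matrix (log2 scale).
#' @param labels Named 0/1 vector.
#' @param study Named study label per sample.
#' @param alpha Elastic-net mixing parameter.
#' @param lfc_cut,padj_cut Gene-selection thresholds.
#' @param cv_folds Inner CV folds for lambda.
#' @param seed Integer seed.
#' @return Tibble: study, n, accuracy, auc, n_genes.
#' @export
loso_cv <- function(expr, labels, study, alpha = 0.9,
                    lfc_cut = 1.5, padj_cut = 0.05,
                    cv_folds = 10L, seed = 1L) {
  labels <- labels[colnames(expr)]
  study <- study[colnames(expr)]
  studies <- unique(study)
  if (length(studies) < 2L) abort("leave-one-study-out needs >= 2 studies")
  res <- purrr::map(studies, function(s) {
    train <- names(study)[study != s]
    test <- names(study)[study == s]
    genes <- select_de_genes(expr[, train, drop = FALSE], labels[train],
      lfc_cut = lfc_cut, padj_cut = padj_cut
    )
    model <- train_mutation_classifier(
      expr[genes, train, drop = FALSE], labels[train],
      alpha = alpha, cv_folds = cv_folds, seed = seed
    )
    prob <- predict(model, expr[genes, test, drop = FALSE])
    acc <- mean((prob > 0.5) == (labels[test] == 1L))
    auc <- if (length(unique(labels[test])) < 2L) NA_real_ else roc_auc(prob, labels[test])
    tibble::tibble(
      study = s, n = length(test), accuracy = acc, auc = auc,
      n_genes = length(genes)
    )
  })
  dplyr::bind_rows(res)
}
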