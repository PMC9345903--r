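toy_panel_from_files <- function() {
  auc_df <- readr::read_tsv(
    system.file("extdata", "toy_ccl_auc.tsv", package = "slscreen"),
    show_col_types = FALSE
  )
  auc <- as.matrix(auc_df[-1])
  rownames(auc) <- auc_df$ccl
  expr <- read_expression(
    system.file("extdata", "toy_ccl_expr.tsv", package = "slscreen"), "log2tpm"
  )
  meta <- readr::read_tsv(
    system.file("extdata", "toy_ccl_meta.tsv", package = "slscreen"),
    show_col_types = FALSE
  )
  structure(list(ccl_expr = expr, auc = auc, ccl_meta = meta), class = "drug_panel")
}

test_that("panel preparation applies the documented filters on the packaged fixture", {
  panel <- toy_panel_from_files()
  expect_warning(prepped <- prep_drug_panel(panel, knn_k = 10), "k reduced")
  # haematopoietic line C6 excluded; cpd3 (40% NA after exclusion) dropped
  expect_identical(sort(rownames(prepped$auc)), c("C1", "C2", "C3", "C4", "C5"))
  expect_identical(colnames(prepped$auc), c("cpd1", "cpd2", "cpd4"))
  expect_false(anyNA(prepped$auc))
  expect_false(any(prepped$ccl_meta$lineage == "haematopoietic_and_lymphoid_tissue"))
})

test_that("panel preparation is idempotent", {
  panel <- toy_panel_from_files()
  p1 <- suppressWarnings(prep_drug_panel(panel, knn_k = 2))
  p2 <- suppressWarnings(prep_drug_panel(p1, knn_k = 2))
  expect_identical(p1$auc, p2$auc)
  expect_identical(p1$ccl_expr, p2$ccl_expr)
})

test_that("single-neighbour imputation copies the nearest compound profile", {
  m <- matrix(c(
    0.7, 0.71, 5,
    0.8, 0.81, 6,
    NA, 0.92, 7
  ), 3, byrow = TRUE, dimnames = list(c("c1", "c2", "c3"), c("d1", "d2", "d3")))
  out <- slscreen:::knn_impute_columns(m, k = 1)
  # d2 is d1's nearest neighbour; the missing (c3, d1) cell takes d2's value
  expect_equal(out["c3", "d1"], 0.92)
})

test_that("noiseless single-gene response is recovered near-exactly at small lambda", {
  set.seed(5)
  genes <- sprintf("g%02d", 1:5)
  ccls <- sprintf("c%03d", 1:120)
  expr <- matrix(rnorm(5 * 120, 5), 5, 120, dimnames = list(genes, ccls))
  auc <- matrix(2 - expr["g01", ], 120, 1, dimnames = list(ccls, "cpdX"))
  panel <- structure(
    list(ccl_expr = expr[, 1:100], auc = auc[1:100, , drop = FALSE],
         ccl_meta = tibble::tibble(ccl = ccls[1:100], lineage = "kidney")),
    class = "drug_panel"
  )
  models <- train_drug_models(panel, lambda_grid = c(10^seq(-3, 3, length.out = 13), 1e-8), seed = 1)
  pred <- predict_drug_response(models, expr[, 101:120])
  expect_equal(unname(pred[, "cpdX"]), unname(2 - expr["g01", 101:120]), tolerance = 1e-6)
})

test_that("constant response yields an intercept-only model", {
  genes <- sprintf("g%02d", 1:3)
  ccls <- sprintf("c%03d", 1:30)
  expr <- matrix(rnorm(90, 5), 3, 30, dimnames = list(genes, ccls))
  auc <- matrix(0.7, 30, 1, dimnames = list(ccls, "flat"))
  panel <- structure(
    list(ccl_expr = expr, auc = auc,
         ccl_meta = tibble::tibble(ccl = ccls, lineage = "kidney")),
    class = "drug_panel"
  )
  models <- train_drug_models(panel, seed = 1)
  expect_equal(unname(models$models$flat$beta), rep(0, 3))
  pred <- predict_drug_response(models, expr)
  expect_equal(unname(pred[, 1]), rep(0.7, 30))
})

test_that("training is deterministic under a fixed seed", {
  st <- tiny_study(seed = 3)
  prepped <- prep_drug_panel(st$panel)
  m1 <- train_drug_models(prepped, compounds = colnames(prepped$auc)[1:2], seed = 9)
  m2 <- train_drug_models(prepped, compounds = colnames(prepped$auc)[1:2], seed = 9)
  expect_identical(m1$meta, m2$meta)
  expect_identical(m1$models[[1]]$beta, m2$models[[1]]$beta)
})

test_that("predictions are invariant to affine rescaling of one input gene", {
  st <- tiny_study(seed = 3)
  prepped <- prep_drug_panel(st$panel)
  cpd <- colnames(prepped$auc)[1]
  models <- train_drug_models(prepped, compounds = cpd, seed = 2)
  clin <- st$sim$cohort$expr_tumor
  base <- predict_drug_response(models, clin)

  scaled_panel <- prepped
  g <- rownames(scaled_panel$ccl_expr)[1]
  scaled_panel$ccl_expr[g, ] <- 10 * scaled_panel$ccl_expr[g, ] + 3
  models2 <- train_drug_models(scaled_panel, compounds = cpd, seed = 2)
  clin2 <- clin
  clin2[g, ] <- 10 * clin2[g, ] + 3
  rescaled <- predict_drug_response(models2, clin2)
  expect_equal(base, rescaled, tolerance = 1e-6)
})

test_that("prediction requires half the model genes and mean-imputes the rest", {
  st <- tiny_study(seed = 3)
  prepped <- prep_drug_panel(st$panel)
  cpd <- colnames(prepped$auc)[1]
  models <- train_drug_models(prepped, compounds = cpd, seed = 2)
  m <- models$models[[cpd]]
  few <- st$sim$cohort$expr_tumor[m$genes[1:3], , drop = FALSE]
  expect_error(predict_drug_response(models, few), "model genes")
  # a sample sitting at the training mean everywhere predicts the intercept
  at_mean <- matrix(m$center, ncol = 1, dimnames = list(m$genes, "s"))
  expect_equal(unname(predict_drug_response(models, at_mean)[1, 1]), m$intercept)
})

test_that("differential response follows the exact Wilcoxon example and direction rule", {
  est <- matrix(c(0.2, 0.3, 0.25, 0.8, 0.9, 0.85), 6, 1,
    dimnames = list(sprintf("s%d", 1:6), "cpd")
  )
  status <- setNames(c(1L, 1L, 1L, 0L, 0L, 0L), rownames(est))
  res <- differential_drug_response(est, status)
  expect_lt(res$logfc, 0)
  expect_equal(res$p_value, 0.1, tolerance = 1e-12) # 2 of 20 splits
  expect_false(res$sl_flag) # n too small for 0.05

  flat <- matrix(rep(c(0.5, 0.5), each = 3), 6, 1,
    dimnames = list(rownames(est), "cpd")
  )
  expect_false(differential_drug_response(flat, status)$sl_flag) # logFC = 0

  worse <- est[c(4:6, 1:3), , drop = FALSE]
  rownames(worse) <- rownames(est)
  res3 <- differential_drug_response(worse, status)
  expect_gt(res3$logfc, 0)
  expect_false(res3$sl_flag) # mutant less sensitive: never flagged
})
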