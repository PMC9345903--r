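# hand-built 2-driver cohort for targeted procedure tests
toy_cohort <- function() {
  set.seed(404)
  genes <- c("DRV1", "DRV2", "PG1", "PG2")
  tumors <- sprintf("t%02d", 1:6)
  normals <- sprintf("n%02d", 1:6)
  et <- matrix(5, 4, 6, dimnames = list(genes, tumors))
  # DRV1 mutant in t1-t3; PG1 up-shifted there, PG2 interleaved (null, no ties)
  et["PG1", 1:3] <- c(10, 11, 12)
  et["PG1", 4:6] <- c(1, 2, 3)
  et["PG2", 1:3] <- c(1, 4, 5)
  et["PG2", 4:6] <- c(2, 3, 6)
  en <- matrix(rnorm(24, 5), 4, 6, dimnames = list(genes, normals))
  en["PG1", ] <- en["DRV1", ] + 0.01 * rnorm(6) # near-monotone co-expression
  mut <- matrix(0L, 4, 6, dimnames = list(genes, tumors))
  mut["DRV1", 1:3] <- 1L
  mut["DRV2", c(1, 4)] <- 1L
  structure(
    list(
      expr_tumor = et, expr_normal = en, mut = mut,
      clinical = tibble::tibble(sample = tumors, time = 1:6, event = 1L),
      batch = tibble::tibble(sample = tumors, batch = "B1"),
      scale = "log2tpm"
    ),
    class = "sl_cohort"
  )
}

test_that("differential expression matches the exact Wilcoxon enumeration", {
  cohort <- toy_cohort()
  cfg <- screen_config(min_group_size = 3)
  res <- screen_de(cohort, "DRV1", c("PG1", "PG2"), cfg)
  # {10,11,12} vs {1,2,3}: 2 of the 20 rank splits are as extreme
  expect_equal(res$de_p[res$partner == "PG1"], 0.1, tolerance = 1e-12)
  expect_gt(res$log2fc[res$partner == "PG1"], 0)
  # identical distributions: p = 1 under the exact test
  expect_equal(res$de_p[res$partner == "PG2"], 1)
})

test_that("down-regulated partners fail regardless of significance", {
  cohort <- toy_cohort()
  cohort$expr_tumor["PG1", 1:3] <- c(1, 2, 3) # flip direction
  cohort$expr_tumor["PG1", 4:6] <- c(10, 11, 12)
  cfg <- screen_config(min_group_size = 3, de_padj = 0.2)
  res <- screen_de(cohort, "DRV1", c("PG1"), cfg)
  expect_lt(res$log2fc, 0)
  expect_false(res$pass_de)
})

test_that("small mutant groups skip the driver with a warning", {
  cohort <- toy_cohort()
  expect_warning(res <- screen_de(cohort, "DRV2", c("PG1"), screen_config()), "skipped")
  expect_false(res$pass_de)
})

test_that("co-expression reproduces hand-computed Spearman cases", {
  cohort <- toy_cohort()
  cohort$expr_normal["DRV1", ] <- c(1, 2, 3, 4, 5, 6)
  cohort$expr_normal["PG1", ] <- c(2, 4, 6, 7, 9, 11) # perfectly monotone
  res <- screen_coexpression(cohort, tibble::tibble(driver = "DRV1", partner = "PG1"))
  expect_equal(res$rho, 1)

  # rho = 1 - 6 * sum(d^2) / (n (n^2 - 1)) by hand for (1,2,3) vs (3,1,2)
  x <- c(1, 2, 3, 4, 5) # pad to meet the 5-normal floor with exact ranks
  cohort$expr_normal <- cohort$expr_normal[, 1:5]
  cohort$expr_normal["DRV1", ] <- c(1, 2, 3, 4, 5)
  cohort$expr_normal["PG1", ] <- c(3, 1, 2, 5, 4)
  res <- screen_coexpression(cohort, tibble::tibble(driver = "DRV1", partner = "PG1"))
  d2 <- sum((rank(c(1, 2, 3, 4, 5)) - rank(c(3, 1, 2, 5, 4)))^2)
  expect_equal(res$rho, 1 - 6 * d2 / (5 * 24), tolerance = 1e-12)
})

test_that("the correlation-coefficient threshold binds independently of p", {
  cohort <- toy_cohort()
  cohort$expr_normal <- cohort$expr_normal[, 1:6]
  cohort$expr_normal["DRV1", ] <- 1:6
  cohort$expr_normal["PG1", ] <- c(1, 2, 3, 4, 6, 5) # one swap: rho = 0.943
  res <- screen_coexpression(
    cohort, tibble::tibble(driver = "DRV1", partner = "PG1"),
    screen_config(rho_cut = 0.95)
  )
  expect_lt(res$coexpr_padj, 0.05)
  expect_false(res$pass_coexpr) # despite significance, rho below the cut
})

test_that("constant expression yields an undefined rho and a failed pair", {
  cohort <- toy_cohort()
  cohort$expr_normal["PG2", ] <- 4
  expect_warning(
    res <- screen_coexpression(cohort, tibble::tibble(driver = "DRV1", partner = "PG2")),
    "constant"
  )
  expect_true(is.na(res$rho))
  expect_false(res$pass_coexpr)
})

test_that("FSS pass requires a defined score strictly above the threshold", {
  g <- go_graph(
    tibble::tibble(term = c("M", "C"), namespace = c("MF", "CC")),
    tibble::tibble(child = character(0), parent = character(0), type = character(0))
  )
  ann <- tibble::tibble(
    gene = c("a", "a", "b", "b", "c"),
    term = c("M", "C", "M", "C", "M"),
    aspect = c("F", "C", "F", "C", "F")
  )
  pairs <- tibble::tibble(driver = c("a", "a"), partner = c("b", "c"))
  res <- screen_fss(pairs, g, ann, screen_config())
  expect_true(res$pass_fss[1]) # FSS = 1 > 0.45
  expect_false(res$pass_fss[2]) # undefined -> fail
  # strict inequality: a pair sitting exactly at the threshold fails
  res2 <- screen_fss(pairs[1, ], g, ann, screen_config(fss_threshold = 1))
  expect_false(res2$pass_fss)
})

test_that("the full screen recovers a planted pair and rejects decoys end to end", {
  st <- tiny_study(seed = 19)
  scr <- run_sl_screen(
    st$sim$cohort, st$sim$truth$drivers, st$sim$truth$druggable,
    st$go$graph, st$go$annotation
  )
  expect_identical(nrow(scr), 5L * 30L)
  expect_identical(scr$pass_all, scr$pass_de & scr$pass_coexpr & scr$pass_fss & scr$pass_mutex)
  hits <- dplyr::inner_join(
    dplyr::filter(scr, pass_all), st$sim$truth$planted_pairs,
    by = c("driver", "partner")
  )
  expect_gte(nrow(hits), 3L) # most planted pairs survive at this cohort size
  decoys <- dplyr::anti_join(
    dplyr::filter(scr, pass_all), st$sim$truth$planted_pairs,
    by = c("driver", "partner")
  )
  expect_lte(nrow(decoys), 2L)

  # determinism: rerunning the screen reproduces the table
  scr2 <- run_sl_screen(
    st$sim$cohort, st$sim$truth$drivers, st$sim$truth$druggable,
    st$go$graph, st$go$annotation
  )
  expect_equal(tidy(scr), tidy(scr2))
})

test_that("tightening any single threshold never adds a pair to the final set", {
  st <- tiny_study(seed = 19)
  run <- function(cfg) {
    scr <- run_sl_screen(
      st$sim$cohort, st$sim$truth$drivers, st$sim$truth$druggable,
      st$go$graph, st$go$annotation, cfg
    )
    dplyr::filter(scr, pass_all)[c("driver", "partner")]
  }
  base <- run(screen_config())
  for (cfg in list(
    screen_config(de_padj = 0.01), screen_config(rho_cut = 0.3),
    screen_config(fss_threshold = 0.7), screen_config(mutex_threshold = 0.05)
  )) {
    tightened <- run(cfg)
    expect_identical(nrow(dplyr::anti_join(tightened, base, by = c("driver", "partner"))), 0L)
  }
})

test_that("glance and autoplot summarise a screen without error", {
  st <- tiny_study(seed = 19)
  scr <- run_sl_screen(
    st$sim$cohort, st$sim$truth$drivers, st$sim$truth$druggable,
    st$go$graph, st$go$annotation
  )
  g <- glance(scr)
  expect_identical(g$n_pairs, nrow(scr))
  p <- autoplot(scr)
  expect_s3_class(p, "ggplot")
})
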