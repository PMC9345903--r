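test_that("identical config and seed reproduce every artifact byte for byte", {
  cfg <- sim_config(n_tumor = 40, n_normal = 10, n_drivers = 3, n_druggable = 12,
                    n_planted_pairs = 3, n_ccl = 30, seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  ga <- simulate_go_annotation(cfg, a$truth)
  gb <- simulate_go_annotation(cfg, b$truth)
  expect_identical(ga$annotation, gb$annotation)
  pa <- simulate_ccl_panel(cfg, a$truth, simulate_drug_catalog(a$truth, 5, seed = 7))
  pb <- simulate_ccl_panel(cfg, b$truth, simulate_drug_catalog(b$truth, 5, seed = 7))
  expect_identical(pa$auc, pb$auc)
})

test_that("config invariants are enforced", {
  expect_error(sim_config(n_normal = 2), "n_normal")
  expect_error(sim_config(n_drivers = 2, n_druggable = 3, n_planted_pairs = 7), "exceed")
  expect_error(sim_config(excl_factor = 1), "excl_factor")
  expect_error(sim_config(na_rate = 1.2), "na_rate")
  expect_error(sim_config(go_depth = 1), "go_depth")
})

test_that("planted differential-expression shift matches its configured value", {
  cfg <- sim_config(n_tumor = 200, n_normal = 20, de_shift = 2, seed = 11)
  sim <- simulate_cohort(cfg)
  shifts <- purrr::pmap_dbl(sim$truth$planted_pairs, function(driver, partner) {
    mutant <- sim$cohort$mut[driver, ] == 1L
    mean(sim$cohort$expr_tumor[partner, mutant]) -
      mean(sim$cohort$expr_tumor[partner, !mutant])
  })
  expect_true(all(abs(shifts - 2) < 0.75)) # per-pair Monte-Carlo spread
  expect_lt(abs(mean(shifts) - 2), 0.3)
})

test_that("normal-tissue co-expression is calibrated to the target Spearman rho", {
  cfg <- sim_config(n_tumor = 50, n_normal = 500, coexpr_rho = 0.6, seed = 3)
  sim <- simulate_cohort(cfg)
  rhos <- purrr::pmap_dbl(sim$truth$planted_pairs, function(driver, partner) {
    cor(sim$cohort$expr_normal[driver, ], sim$cohort$expr_normal[partner, ],
        method = "spearman")
  })
  expect_lt(abs(mean(rhos) - 0.6), 0.06)
})

test_that("excl_factor 0 forbids co-mutation of planted pairs", {
  cfg <- sim_config(n_tumor = 300, n_normal = 10, excl_factor = 0, seed = 5)
  sim <- simulate_cohort(cfg)
  co <- purrr::pmap_int(sim$truth$planted_pairs, function(driver, partner) {
    sum(sim$cohort$mut[driver, ] == 1L & sim$cohort$mut[partner, ] == 1L)
  })
  expect_identical(sum(co), 0L)
})

test_that("co-mutation deficit of planted pairs tracks excl_factor", {
  cfg <- sim_config(n_tumor = 400, n_normal = 10, excl_factor = 0.2, seed = 9)
  sim <- simulate_cohort(cfg)
  obs_exp <- purrr::pmap_dfr(sim$truth$planted_pairs, function(driver, partner) {
    fa <- mean(sim$cohort$mut[driver, ])
    fb <- mean(sim$cohort$mut[partner, ])
    tibble::tibble(
      obs = sum(sim$cohort$mut[driver, ] & sim$cohort$mut[partner, ]),
      expected_indep = fa * fb * 400
    )
  })
  ratio <- sum(obs_exp$obs) / sum(obs_exp$expected_indep)
  expect_lt(ratio, 0.4) # strong deficit relative to independence
})

test_that("go generator emits the advertised tree shape and acyclic graph", {
  cfg <- sim_config(n_tumor = 30, n_normal = 5, n_drivers = 2, n_druggable = 8,
                    n_planted_pairs = 2, go_depth = 2, go_branching = 2, seed = 1)
  sim <- simulate_cohort(cfg)
  go <- simulate_go_annotation(cfg, sim$truth)
  per_ns <- table(go$graph$terms$namespace)
  expect_equal(as.vector(per_ns[c("MF", "CC", "BP")]), rep(7L, 3)) # 1 + 2 + 4
  # go_graph() already rejects cycles at construction; reconstructing proves it
  expect_silent(go_graph(go$graph$terms, go$graph$edges))
})

test_that("planted pairs are annotated close enough for a high FSS", {
  st <- tiny_study(seed = 21)
  fss <- fss_table(
    dplyr::transmute(st$sim$truth$planted_pairs,
                     gene_a = driver, gene_b = partner),
    st$go$graph, st$go$annotation
  )
  expect_true(all(fss$fss > 0.45))
})

test_that("drug catalog covers every planted partner without duplicates", {
  st <- tiny_study(seed = 4)
  cat <- st$catalog
  expect_true(all(st$sim$truth$planted_pairs$partner %in% cat$target_gene))
  expect_identical(anyDuplicated(cat[c("drug_id", "target_gene")]), 0L)
  universe <- c(st$sim$truth$drivers, st$sim$truth$druggable)
  expect_true(all(cat$target_gene %in% universe))
})

test_that("noiseless responsive compounds are perfectly anticorrelated with target expression", {
  cfg <- sim_config(n_tumor = 30, n_normal = 5, n_drivers = 3, n_druggable = 10,
                    n_planted_pairs = 3, n_ccl = 50, auc_noise_sd = 0, na_rate = 0, seed = 2)
  sim <- simulate_cohort(cfg)
  cat <- simulate_drug_catalog(sim$truth, 5, seed = 2)
  panel <- simulate_ccl_panel(cfg, sim$truth, cat)
  resp <- attr(cat, "responsive")
  for (d in resp) {
    target <- cat$target_gene[cat$drug_id == d]
    expect_equal(
      cor(panel$auc[, d], panel$ccl_expr[target, ], method = "spearman"), -1
    )
  }
})

test_that("non-responsive compounds show only null correlation with their target", {
  cfg <- sim_config(n_tumor = 30, n_normal = 5, n_drivers = 3, n_druggable = 10,
                    n_planted_pairs = 3, n_ccl = 200, na_rate = 0, seed = 2)
  sim <- simulate_cohort(cfg)
  cat <- simulate_drug_catalog(sim$truth, 5, seed = 2)
  panel <- simulate_ccl_panel(cfg, sim$truth, cat)
  decoys <- setdiff(cat$drug_id, attr(cat, "responsive"))
  for (d in decoys) {
    target <- cat$target_gene[cat$drug_id == d][1]
    expect_lt(abs(cor(panel$auc[, d], panel$ccl_expr[target, ], method = "spearman")), 0.3)
  }
})

test_that("missing AUC cells appear at the configured rate", {
  cfg <- sim_config(n_tumor = 30, n_normal = 5, n_drivers = 3, n_druggable = 10,
                    n_planted_pairs = 3, n_ccl = 100, na_rate = 0.3, seed = 6)
  sim <- simulate_cohort(cfg)
  panel <- simulate_ccl_panel(cfg, sim$truth, simulate_drug_catalog(sim$truth, 10, seed = 6))
  frac <- mean(is.na(panel$auc))
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / length(panel$auc)))
})

test_that("written simulation files round-trip through the package readers", {
  st <- tiny_study(seed = 30)
  dir <- withr::local_tempdir()
  write_simulation(st$sim, dir, go = st$go, catalog = st$catalog, panel = st$panel)
  expr <- read_expression(file.path(dir, "expr_tumor.tsv"), "tpm")
  expect_equal(
    log2(expr + 1), st$sim$cohort$expr_tumor,
    ignore_attr = TRUE, tolerance = 1e-12
  )
  maf <- read_maf(file.path(dir, "mutations.maf.tsv"))
  expect_identical(nrow(maf), sum(st$sim$cohort$mut == 1L))
  graph <- read_obo(file.path(dir, "go.obo"))
  expect_identical(
    dplyr::arrange(graph$edges, child, parent),
    dplyr::arrange(st$go$graph$edges, child, parent)
  )
})
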