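test_that("background fit reproduces homogeneous margins exactly", {
  # circulant 4x4 with exactly 2 ones per row and column: frequency 0.5
  m <- matrix(0L, 4, 4, dimnames = list(paste0("g", 1:4), paste0("s", 1:4)))
  for (i in 1:4) m[i, c(i, i %% 4 + 1)] <- 1L
  bg <- mutex_background(m)
  expect_equal(unname(bg$p), matrix(0.5, 4, 4), tolerance = 1e-6)
})

test_that("background fit matches margins of the 2x2 identity", {
  m <- matrix(c(1L, 0L, 0L, 1L), 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  bg <- mutex_background(m)
  expect_equal(unname(rowSums(bg$p)), c(1, 1), tolerance = 1e-6)
  expect_equal(unname(colSums(bg$p)), c(1, 1), tolerance = 1e-6)
})

test_that("degenerate rows and columns are dropped with a warning", {
  m <- matrix(c(1L, 0L, 0L, 0L, 1L, 0L), 3, 2,
    dimnames = list(c("a", "b", "zero"), c("s1", "s2"))
  )
  expect_warning(bg <- mutex_background(m), "all-zero")
  expect_false("zero" %in% rownames(bg$p))
})

test_that("DP lower tail equals exhaustive enumeration for n <= 12", {
  set.seed(4)
  for (k in 1:20) {
    n <- sample(2:12, 1)
    q <- runif(n, 0, 0.6)
    cap <- sample(0:n, 1)
    expect_equal(
      slscreen:::poisbinom_lower_tail(q, cap),
      bf_poisbinom_tail(q, cap),
      tolerance = 1e-12
    )
  }
})

test_that("exclusivity p-values match hand-computed cases", {
  # three samples at joint rate 0.25 each, no co-mutation observed
  expect_equal(slscreen:::poisbinom_lower_tail(rep(0.25, 3), 0), 0.421875, tolerance = 1e-12)
  # co-mutated everywhere: the full lower tail
  expect_equal(slscreen:::poisbinom_lower_tail(rep(0.25, 3), 3), 1)
  # degenerate null: no mass anywhere, nothing observed
  expect_equal(slscreen:::poisbinom_lower_tail(rep(0, 5), 0), 1)
})

test_that("mutex_test wires counts, expectations and p-values per pair", {
  set.seed(2)
  m <- matrix(rbinom(40 * 100, 1, 0.3), 40, 100,
    dimnames = list(sprintf("g%02d", 1:40), sprintf("s%03d", 1:100))
  )
  bg <- suppressWarnings(mutex_background(m))
  pairs <- tibble::tibble(gene_a = c("g01", "g03"), gene_b = c("g02", "g04"))
  res <- mutex_test(m, pairs, bg)
  expect_identical(res$n_co[1], sum(m["g01", ] & m["g02", ]))
  expect_equal(res$expected_co[1], sum(bg$p["g01", ] * bg$p["g02", ]))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
})

test_that("BH adjustment and flags follow the step-up rule", {
  base <- tibble::tibble(gene_a = "a", gene_b = "b", n_co = 0L, expected_co = 1)
  one <- adjust_and_flag(dplyr::mutate(base, p_value = 0.2))
  expect_equal(one$p_adjust, 0.2) # BH identity at m = 1
  three <- adjust_and_flag(
    dplyr::bind_rows(
      dplyr::mutate(base, p_value = 0.01),
      dplyr::mutate(base, gene_a = "c", p_value = 0.02),
      dplyr::mutate(base, gene_a = "d", p_value = 0.03)
    ),
    threshold = 0.15
  )
  expect_equal(three$p_adjust, rep(0.03, 3))
  expect_true(all(three$pass))
  all_null <- adjust_and_flag(dplyr::mutate(base, p_value = 1))
  expect_false(any(all_null$pass))
})

test_that("curveball trades preserve margins and reach the 2x2 alternative", {
  set.seed(8)
  m <- matrix(rbinom(15 * 40, 1, 0.3), 15, 40,
    dimnames = list(sprintf("g%02d", 1:15), sprintf("s%02d", 1:40))
  )
  perm <- curveball_permute(m, n_trades = 200)
  expect_identical(rowSums(perm$m), rowSums(m))
  expect_identical(colSums(perm$m), colSums(m))

  id2 <- matrix(c(1L, 0L, 0L, 1L), 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  seen <- character(0)
  for (k in 1:40) {
    seen <- union(seen, paste(curveball_permute(id2, 3)$m, collapse = ""))
  }
  # exactly the two fixed-margin configurations exist and both are reached
  expect_setequal(seen, c("1001", "0110"))
})

test_that("analytic p agrees with the curveball oracle on a sparse panel", {
  set.seed(31)
  rate <- runif(100, 0.03, 0.08)
  m <- matrix(rbinom(100 * 300, 1, rate), 100, 300,
    dimnames = list(sprintf("g%03d", 1:100), sprintf("s%03d", 1:300))
  )
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  bg <- suppressWarnings(mutex_background(m))
  for (k in 1:3) {
    pr <- rownames(bg$p)[sample(nrow(bg$p), 2)]
    analytic <- mutex_test(m, tibble::tibble(gene_a = pr[1], gene_b = pr[2]), bg)$p_value
    oracle <- mutex_permutation_p(m, pr, n_perm = 100, seed = k)
    se <- max(sqrt(oracle$p * (1 - oracle$p) / 100), 1 / 101)
    expect_lt(abs(analytic - oracle$p), 3 * se)
  }
})

test_that("planted exclusivity is detected at high power", {
  # planted pairs with excl_factor 0.15 among rates ~0.2-0.3, n = 300
  set.seed(12)
  n <- 300
  hits <- 0
  n_pairs <- 40
  results <- list()
  mats <- list()
  rate <- runif(2 * n_pairs, 0.2, 0.3)
  m <- matrix(0L, 2 * n_pairs, n,
    dimnames = list(sprintf("g%03d", 1:(2 * n_pairs)), sprintf("s%03d", 1:n))
  )
  for (k in seq_len(n_pairs)) {
    pa <- rate[2 * k - 1]
    pb <- rate[2 * k]
    p11 <- 0.15 * pa * pb
    draw <- sample(4, n, replace = TRUE, prob = c(p11, pa - p11, pb - p11, 1 - pa - pb + p11))
    m[2 * k - 1, ] <- as.integer(draw %in% c(1L, 2L))
    m[2 * k, ] <- as.integer(draw %in% c(1L, 3L))
  }
  bg <- suppressWarnings(mutex_background(m))
  pairs <- tibble::tibble(
    gene_a = rownames(m)[seq(1, 2 * n_pairs, 2)],
    gene_b = rownames(m)[seq(2, 2 * n_pairs, 2)]
  )
  res <- adjust_and_flag(mutex_test(m, pairs, bg), threshold = 0.15)
  expect_gte(mean(res$pass), 0.8)
})
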