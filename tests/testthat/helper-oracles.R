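# Independent brute-force oracles, deliberately naive implementations that
# share no code with the package internals.

# S-value by exhaustive path enumeration: S(t) = max over directed paths
# term -> ... -> t of the product of edge weights (memo-free recursion)
bf_svalues <- function(term, edges, weights = c(is_a = 0.8, part_of = 0.6)) {
  best <- new.env(parent = emptyenv())
  rec <- function(node, prod) {
    cur <- best[[node]]
    if (is.null(cur) || prod > cur) best[[node]] <- prod
    up <- edges[edges$child == node, , drop = FALSE]
    for (k in seq_len(nrow(up))) {
      rec(up$parent[k], prod * weights[[up$type[k]]])
    }
  }
  rec(term, 1)
  unlist(as.list(best))
}

bf_term_sim <- function(a, b, edges) {
  sa <- bf_svalues(a, edges)
  sb <- bf_svalues(b, edges)
  common <- intersect(names(sa), names(sb))
  sum(sa[common] + sb[common]) / (sum(sa) + sum(sb))
}

# random single-namespace DAG: term i >= 2 draws 1-2 parents among 1..i-1
random_dag <- function(n_terms, seed) {
  set.seed(seed)
  terms <- sprintf("T%02d", seq_len(n_terms))
  edges <- list()
  for (i in 2:n_terms) {
    parents <- sample(seq_len(i - 1), min(sample(1:2, 1), i - 1))
    for (p in parents) {
      edges[[length(edges) + 1L]] <- data.frame(
        child = terms[i], parent = terms[p],
        type = sample(c("is_a", "part_of"), 1)
      )
    }
  }
  list(
    terms = tibble::tibble(term = terms, namespace = "MF"),
    edges = dplyr::bind_rows(edges)
  )
}

# exact Poisson-binomial lower tail by exhaustive outcome enumeration
bf_poisbinom_tail <- function(q, cap) {
  n <- length(q)
  total <- 0
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(n)]
    if (sum(bits) <= cap) {
      total <- total + prod(ifelse(bits == 1L, q, 1 - q))
    }
  }
  total
}

# ROC AUC by exhaustive pairwise comparison, ties counted one half
bf_roc_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) {
    for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Monte-Carlo estimate of the joint order-statistics probability
mc_stuart <- function(r, n_draws = 1e5, seed = 1) {
  set.seed(seed)
  m <- length(r)
  u <- matrix(runif(n_draws * m), ncol = m)
  us <- matrix(u[order(row(u), u)], ncol = m, byrow = TRUE) # row-wise sort
  mean(colSums(t(us) <= r) == m)
}

# small fully wired synthetic study used by several test files
tiny_study <- function(seed = 7, ...) {
  cfg <- sim_config(
    n_tumor = 200, n_normal = 40, n_drivers = 5, n_druggable = 30,
    n_planted_pairs = 5, n_ccl = 60, n_extra_drugs = 8, seed = seed, ...
  )
  sim <- simulate_cohort(cfg)
  go <- simulate_go_annotation(cfg, sim$truth)
  catalog <- simulate_drug_catalog(sim$truth, n_extra = cfg$n_extra_drugs, seed = seed)
  panel <- simulate_ccl_panel(cfg, sim$truth, catalog)
  list(cfg = cfg, sim = sim, go = go, catalog = catalog, panel = panel)
}
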