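#' Construct a validated GO graph
#'
#' A typed DAG over GO terms. Edges point child -> parent and carry type
#' `is_a` or `part_of`; endpoints must share a namespace and the graph must
#' be acyclic (one offending cycle is reported otherwise).
#'
#' @param terms Tibble: term, namespace (MF/CC/BP).
#' @param edges Tibble: child, parent, type.
#' @return A `go_graph` (list of `terms`, `edges`, plus a parent adjacency
#'   index used by the similarity routines).
#' @export
go_graph <- function(terms, edges) {
  terms <- tibble::as_tibble(terms)
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("term", "namespace") %in% names(terms)))
  if (nrow(edges)) {
    stopifnot(all(c("child", "parent", "type") %in% names(edges)))
    unknown <- setdiff(c(edges$child, edges$parent), terms$term)
    if (length(unknown)) {
      abort(sprintf("edge endpoint(s) not in term table: %s", paste(head(unknown, 3), collapse = ", ")))
    }
    if (!all(edges$type %in% c("is_a", "part_of"))) {
      abort("edge types must be is_a or part_of")
    }
    ns <- setNames(terms$namespace, terms$term)
    bad <- which(ns[edges$child] != ns[edges$parent])
    if (length(bad)) {
      abort(sprintf(
        "edge crosses namespaces: %s -> %s",
        edges$child[bad[1]], edges$parent[bad[1]]
      ))
    }
  }
  cyc <- find_cycle(terms$term, edges)
  if (!is.null(cyc)) {
    abort(sprintf("graph contains a cycle: %s", paste(cyc, collapse = " -> ")))
  }
  parent_index <- split(
    data.frame(parent = edges$parent, w = ifelse(edges$type == "is_a", 0.8, 0.6)),
    edges$child
  )
  structure(
    list(terms = terms, edges = edges, parent_index = parent_index),
    class = "go_graph"
  )
}

# Kahn topological sort; returns NULL if acyclic, else one cycle path
find_cycle <- function(terms, edges) {
  if (!nrow(edges)) {
    return(NULL)
  }
  out_deg <- table(factor(edges$child, levels = terms))
  adj <- split(edges$child, edges$parent) # parent -> children
  deg <- as.integer(out_deg)
  names(deg) <- terms
  queue <- terms[deg == 0L]
  seen <- 0L
  while (length(queue)) {
    t <- queue[[1]]
    queue <- queue[-1]
    seen <- seen + 1L
    for (c in adj[[t]] %||% character(0)) {
      deg[[c]] <- deg[[c]] - 1L
      if (deg[[c]] == 0L) queue <- c(queue, c)
    }
  }
  if (seen == length(terms)) {
    return(NULL)
  }
  # walk parent links from any remaining node until a repeat closes the cycle
  remaining <- names(deg)[deg > 0L]
  pmap <- split(edges$parent, edges$child)
  path <- remaining[[1]]
  repeat {
    nxt <- intersect(pmap[[path[length(path)]]], remaining)[1]
    if (nxt %in% path) {
      return(c(path[seq(match(nxt, path), length(path))], nxt))
    }
    path <- c(path, nxt)
  }
}

#' Wang S-values of a GO term
#'
#' The semantic contribution of every ancestor of `term` (including
#' itself): S(term) = 1 and, walking child -> parent edges, S(parent) is the
#' maximum over incoming contributions `w_edge * S(child)` with weights 0.8
#' for `is_a` and 0.6 for `part_of` edges.
#'
#' @param term Term identifier.
#' @param graph A [go_graph()].
#' @param weights Named edge weights.
#' @return Named numeric vector over the term's ancestor closure.
#' @export
#' @examples
#' g <- go_graph(
#'   tibble::tibble(term = c("a", "b", "r"), namespace = "MF"),
#'   tibble::tibble(child = c("a", "b"), parent = c("b", "r"), type = "is_a")
#' )
#' term_svalues("a", g) # a: 1, b: 0.8, r: 0.64
term_svalues <- function(term, graph, weights = c(is_a = 0.8, part_of = 0.6)) {
  stopifnot(inherits(graph, "go_graph"))
  if (!term %in% graph$terms$term) abort(sprintf("unknown term '%s'", term))
  default_w <- c(is_a = 0.8, part_of = 0.6)
  custom <- !identical(unname(weights[c("is_a", "part_of")]), unname(default_w))
  s <- c(1)
  names(s) <- term
  # worklist relaxation: weights < 1 on a DAG, so the max converges
  queue <- term
  while (length(queue)) {
    t <- queue[[1]]
    queue <- queue[-1]
    pe <- graph$parent_index[[t]]
    if (is.null(pe)) next
    w <- if (custom) {
      unname(weights[ifelse(pe$w == 0.8, "is_a", "part_of")])
    } else {
      pe$w
    }
    cand <- w * s[[t]]
    for (k in seq_len(nrow(pe))) {
      p <- pe$parent[k]
      cur <- s[p]
      if (is.na(cur) || cand[k] > cur) {
        s[p] <- cand[k]
        queue <- c(queue, p)
      }
    }
  }
  s
}

#' Wang semantic similarity between two GO terms
#'
#' `sim(a, b) = sum over shared ancestors t of (S_a(t) + S_b(t)) divided by
#' (SV(a) + SV(b))` where SV is the total S-value mass of a term. Symmetric,
#' in (0, 1], and 1 exactly for identical terms.
#'
#' @param a,b Term identifiers from the same namespace.
#' @param graph A [go_graph()].
#' @return Similarity in (0, 1].
#' @export
term_sim <- function(a, b, graph) {
  ns <- setNames(graph$terms$namespace, graph$terms$term)
  if (!a %in% names(ns) || !b %in% names(ns)) abort("unknown term")
  if (ns[[a]] != ns[[b]]) abort("terms are from different namespaces")
  sa <- term_svalues(a, graph)
  sb <- term_svalues(b, graph)
  common <- intersect(names(sa), names(sb))
  sum(sa[common] + sb[common]) / (sum(sa) + sum(sb))
}

# memoised pairwise term similarity table for one call tree
term_sim_cache <- function(graph) {
  env <- new.env(parent = emptyenv())
  function(a, b) {
    key <- if (a < b) paste0(a, "|", b) else paste0(b, "|", a)
    got <- env[[key]]
    if (!is.null(got)) {
      return(got)
    }
    val <- term_sim(a, b, graph)
    env[[key]] <- val
    val
  }
}

#' Gene-level semantic similarity (best-match average)
#'
#' Combines term-level Wang similarities over the two genes' annotation
#' sets in one namespace by the best-match average:
#' `(sum_a max_b sim + sum_b max_a sim) / (|A| + |B|)`. `NA` (undefined)
#' when either gene has no annotation in the namespace.
#'
#' @param gene_a,gene_b Gene identifiers.
#' @param namespace `"MF"`, `"CC"` or `"BP"`.
#' @param graph A [go_graph()].
#' @param annotation Tibble gene/term/aspect as from [read_gaf()].
#' @param .sim Optional memoised term-similarity function (internal reuse).
#' @return Similarity in \[0, 1\] or `NA`.
#' @export
gene_sim <- function(gene_a, gene_b, namespace, graph, annotation, .sim = NULL) {
  aspect <- c(MF = "F", CC = "C", BP = "P")[[namespace]]
  terms_a <- unique(annotation$term[annotation$gene == gene_a & annotation$aspect == aspect])
  terms_b <- unique(annotation$term[annotation$gene == gene_b & annotation$aspect == aspect])
  if (!length(terms_a) || !length(terms_b)) {
    return(NA_real_)
  }
  simfun <- .sim %||% term_sim_cache(graph)
  m <- matrix(0, length(terms_a), length(terms_b))
  for (i in seq_along(terms_a)) {
    for (j in seq_along(terms_b)) {
      m[i, j] <- simfun(terms_a[i], terms_b[j])
    }
  }
  (sum(apply(m, 1, max)) + sum(apply(m, 2, max))) / (length(terms_a) + length(terms_b))
}

#' Functional similarity score for gene pairs
#'
#' The FSS of a gene pair is the geometric mean of its gene-level Wang
#' similarities in the molecular-function and cellular-component
#' namespaces, `sqrt(SsMF * SsCC)`; it is undefined (`NA`) when either
#' namespace similarity is undefined. BP annotations are ignored.
#'
#' @param pairs Tibble with columns `gene_a`, `gene_b` (any extra columns
#'   are preserved).
#' @param graph A [go_graph()].
#' @param annotation Tibble gene/term/aspect.
#' @return `pairs` with columns `ss_mf`, `ss_cc`, `fss` appended.
#' @export
fss_table <- function(pairs, graph, annotation) {
  pairs <- tibble::as_tibble(pairs)
  stopifnot(all(c("gene_a", "gene_b") %in% names(pairs)))
  simfun <- term_sim_cache(graph)
  ss_mf <- ss_cc <- numeric(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    ss_mf[i] <- gene_sim(pairs$gene_a[i], pairs$gene_b[i], "MF", graph, annotation, .sim = simfun)
    ss_cc[i] <- gene_sim(pairs$gene_a[i], pairs$gene_b[i], "CC", graph, annotation, .sim = simfun)
  }
  dplyr::mutate(pairs, ss_mf = ss_mf, ss_cc = ss_cc, fss = sqrt(ss_mf * ss_cc))
}
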