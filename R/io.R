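#' Read an expression matrix from TSV
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers; every other cell numeric. Duplicated gene or sample
#' identifiers and non-numeric cells are rejected with the offending
#' identifier named.
#'
#' @param path TSV file.
#' @param scale_tag Declared scale, `"tpm"` (values must be non-negative) or
#'   `"log2tpm"`.
#' @return Numeric matrix (genes x samples) with attribute `scale_tag`.
#' @export
read_expression <- function(path, scale_tag = c("tpm", "log2tpm")) {
  scale_tag <- match.arg(scale_tag)
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(df) < 2L) abort(sprintf("expression file '%s' needs >= 2 columns", path))
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes)) {
    abort(sprintf(
      "duplicated gene identifier(s) in '%s': %s", path,
      paste(unique(genes[duplicated(genes)]), collapse = ", ")
    ))
  }
  samples <- colnames(df)[-1]
  if (anyDuplicated(samples)) {
    abort(sprintf("duplicated sample identifier(s) in '%s'", path))
  }
  vals <- df[-1]
  bad <- names(vals)[!vapply(vals, is.numeric, logical(1))]
  if (length(bad)) {
    abort(sprintf("non-numeric expression column(s) in '%s': %s", path, paste(bad, collapse = ", ")))
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  if (scale_tag == "tpm" && any(m < 0, na.rm = TRUE)) {
    abort(sprintf("negative values in '%s' but scale_tag = 'tpm'", path))
  }
  attr(m, "scale_tag") <- scale_tag
  m
}

#' Write an expression matrix as TSV
#'
#' @param m Numeric matrix genes x samples with dimnames.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  df <- tibble::as_tibble(m, rownames = "gene")
  # %.17g guarantees bit-exact numeric round-trips through the reader
  df[-1] <- lapply(df[-1], function(x) sprintf("%.17g", x))
  readr::write_tsv(df, path)
  invisible(path)
}

maf_vocabulary <- function() {
  c(
    "Frame_Shift_Del", "Frame_Shift_Ins", "Nonsense_Mutation",
    "Missense_Mutation", "Splice_Site", "In_Frame_Del", "In_Frame_Ins",
    "Nonstop_Mutation", "Translation_Start_Site", "Silent", "Other"
  )
}

#' Read a MAF-subset mutation table
#'
#' Only the three columns the downstream filters need are required:
#' `Tumor_Sample_Barcode`, `Hugo_Symbol`, `Variant_Classification`; extra
#' columns are ignored. Rows with a classification outside the controlled
#' vocabulary are kept with class `"Other"` and a warning. No filtering
#' happens here — silent-mutation exclusion and burden filters belong to
#' [filter_functional_mutations()].
#'
#' @param path TSV file.
#' @param vocabulary Allowed variant classifications.
#' @return Tibble: sample, gene, variant_classification.
#' @export
read_maf <- function(path, vocabulary = maf_vocabulary()) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("Tumor_Sample_Barcode", "Hugo_Symbol", "Variant_Classification")
  missing <- setdiff(need, colnames(df))
  if (length(missing)) {
    abort(sprintf("MAF file '%s' lacks column(s): %s", path, paste(missing, collapse = ", ")))
  }
  out <- tibble::tibble(
    sample = as.character(df$Tumor_Sample_Barcode),
    gene = as.character(df$Hugo_Symbol),
    variant_classification = as.character(df$Variant_Classification)
  )
  if (anyNA(out)) abort(sprintf("MAF file '%s' contains null fields", path))
  unknown <- !out$variant_classification %in% vocabulary
  if (any(unknown)) {
    warn(sprintf(
      "%d MAF row(s) with classifications outside the vocabulary kept as 'Other'",
      sum(unknown)
    ))
    out$variant_classification[unknown] <- "Other"
  }
  out
}

#' Read a GO DAG from an OBO subset
#'
#' Parses `[Term]` stanzas with `id`, `namespace`, `is_a` and
#' `relationship: part_of` lines; obsolete terms and other relationship
#' types are ignored (the Wang similarity weights only is_a/part_of edges).
#' Namespaces map to MF/CC/BP. Cycles are rejected with one cycle reported.
#'
#' @param path OBO file.
#' @return A `go_graph` object.
#' @export
read_obo <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  ns_map <- c(
    molecular_function = "MF", cellular_component = "CC",
    biological_process = "BP"
  )
  terms <- list()
  edges <- list()
  cur <- NULL
  flush <- function() {
    if (is.null(cur) || is.null(cur$id) || isTRUE(cur$obsolete)) {
      return()
    }
    terms[[length(terms) + 1L]] <<- tibble::tibble(
      term = cur$id, namespace = cur$ns %||% NA_character_
    )
    for (p in cur$is_a) {
      edges[[length(edges) + 1L]] <<- tibble::tibble(child = cur$id, parent = p, type = "is_a")
    }
    for (p in cur$part_of) {
      edges[[length(edges) + 1L]] <<- tibble::tibble(child = cur$id, parent = p, type = "part_of")
    }
  }
  in_term <- FALSE
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") {
      flush()
      cur <- list(is_a = character(0), part_of = character(0))
      in_term <- TRUE
    } else if (grepl("^\\[", ln)) {
      flush()
      cur <- NULL
      in_term <- FALSE
    } else if (in_term && nzchar(ln)) {
      if (startsWith(ln, "id:")) {
        cur$id <- trimws(sub("^id:", "", ln))
      } else if (startsWith(ln, "namespace:")) {
        cur$ns <- unname(ns_map[trimws(sub("^namespace:", "", ln))])
      } else if (startsWith(ln, "is_a:")) {
        cur$is_a <- c(cur$is_a, trimws(sub("!.*$", "", sub("^is_a:", "", ln))))
      } else if (startsWith(ln, "relationship: part_of")) {
        cur$part_of <- c(
          cur$part_of,
          trimws(sub("!.*$", "", sub("^relationship: part_of", "", ln)))
        )
      } else if (ln == "is_obsolete: true") {
        cur$obsolete <- TRUE
      }
    }
  }
  flush()
  terms <- dplyr::bind_rows(terms)
  edges <- if (length(edges)) dplyr::bind_rows(edges) else {
    tibble::tibble(child = character(0), parent = character(0), type = character(0))
  }
  go_graph(terms, edges)
}

#' Write a GO graph as an OBO subset
#'
#' @param graph A `go_graph`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_obo_subset <- function(graph, path) {
  ns_map <- c(MF = "molecular_function", CC = "cellular_component", BP = "biological_process")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  by_child <- split(graph$edges, graph$edges$child)
  for (i in seq_len(nrow(graph$terms))) {
    term <- graph$terms$term[i]
    writeLines(c("", "[Term]", paste0("id: ", term)), con)
    writeLines(paste0("namespace: ", ns_map[[graph$terms$namespace[i]]]), con)
    e <- by_child[[term]]
    if (!is.null(e)) {
      for (j in seq_len(nrow(e))) {
        if (e$type[j] == "is_a") {
          writeLines(paste0("is_a: ", e$parent[j]), con)
        } else {
          writeLines(paste0("relationship: part_of ", e$parent[j]), con)
        }
      }
    }
  }
  invisible(path)
}

#' Read gene annotations from a GAF subset
#'
#' Expects columns `gene`, `term`, `aspect` (F/C/P). Annotations to terms
#' absent from the graph are dropped with a warning count.
#'
#' @param path TSV file.
#' @param graph A `go_graph` used to validate term identifiers.
#' @return Tibble: gene, term, aspect.
#' @export
read_gaf <- function(path, graph) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("gene", "term", "aspect")
  missing <- setdiff(need, colnames(df))
  if (length(missing)) {
    abort(sprintf("GAF file '%s' lacks column(s): %s", path, paste(missing, collapse = ", ")))
  }
  if (!all(df$aspect %in% c("F", "C", "P"))) {
    abort(sprintf("GAF file '%s' has aspects outside F/C/P", path))
  }
  known <- df$term %in% graph$terms$term
  if (any(!known)) {
    warn(sprintf("dropped %d annotation(s) to terms absent from the graph", sum(!known)))
  }
  tibble::as_tibble(df[known, need])
}

#' Read a drug-target catalog TSV
#'
#' @param path TSV with columns drug_id, drug_name, target_gene.
#' @return Tibble, deduplicated on (drug_id, target_gene).
#' @export
read_drug_catalog <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("drug_id", "drug_name", "target_gene")
  missing <- setdiff(need, colnames(df))
  if (length(missing)) {
    abort(sprintf("catalog '%s' lacks column(s): %s", path, paste(missing, collapse = ", ")))
  }
  dplyr::distinct(tibble::as_tibble(df[need]), .data$drug_id, .data$target_gene, .keep_all = TRUE)
}

#' Write / read the DM-DG-drug network as JSON
#'
#' Lossless round-trip of the node and edge tables.
#'
#' @param network A `dmdg_network` object (see [build_drug_network()]).
#' @param path JSON file.
#' @return `path` invisibly for the writer; a `dmdg_network` for the reader.
#' @export
write_network_json <- function(network, path) {
  stopifnot(inherits(network, "dmdg_network"))
  jsonlite::write_json(
    list(nodes = network$nodes, edges = network$edges),
    path,
    dataframe = "rows", pretty = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  empty_nodes <- tibble::tibble(id = character(0), type = character(0))
  empty_edges <- tibble::tibble(from = character(0), to = character(0), type = character(0))
  nodes <- if (length(x$nodes)) tibble::as_tibble(x$nodes) else empty_nodes
  edges <- if (length(x$edges)) tibble::as_tibble(x$edges) else empty_edges
  structure(list(nodes = nodes, edges = edges), class = "dmdg_network")
}

#' Write a results table as TSV with stable column order
#'
#' @param table Data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(table, path) {
  readr::write_tsv(tibble::as_tibble(table), path)
  invisible(path)
}
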