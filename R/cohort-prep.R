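#' Convert raw counts to transcripts per million
#'
#' Divides each gene's count by its length in base pairs and rescales every
#' sample to sum to one million.
#'
#' @param counts Genes x samples count matrix with dimnames.
#' @param gene_lengths Named vector of gene lengths (bp), covering all rows.
#' @return TPM matrix (attribute `scale_tag = "tpm"`).
#' @export
#' @examples
#' counts <- matrix(c(10, 10), 2, dimnames = list(c("a", "b"), "s1"))
#' counts_to_tpm(counts, c(a = 1000, b = 2000))
counts_to_tpm <- function(counts, gene_lengths) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  missing <- setdiff(rownames(counts), names(gene_lengths))
  if (length(missing)) {
    abort(sprintf("no length for gene(s): %s", paste(head(missing, 3), collapse = ", ")))
  }
  len <- gene_lengths[rownames(counts)]
  if (any(len <= 0)) abort("gene lengths must be positive")
  rate <- counts / len
  denom <- colSums(rate)
  if (any(denom == 0)) {
    abort(sprintf(
      "all-zero sample(s): %s",
      paste(colnames(counts)[denom == 0], collapse = ", ")
    ))
  }
  tpm <- sweep(rate, 2, denom, "/") * 1e6
  attr(tpm, "scale_tag") <- "tpm"
  tpm
}

#' Functional-mutation filter and binary matrix construction
#'
#' Applies the cohort-construction rules for somatic mutation calls:
#' samples with fewer than `min_mutations` recorded mutations (counted over
#' all classes, before the class filter) are discarded as outliers; only
#' functional classes (default frameshift and nonsense) contribute to the
#' matrix; duplicated gene-sample records collapse to a single entry, so
#' each cell is 1 iff the sample carries at least one functional mutation
#' of the gene. Silent (synonymous) mutations are never functional.
#'
#' @param mtab Mutation tibble from [read_maf()] (sample, gene,
#'   variant_classification).
#' @param min_mutations Per-sample burden floor (default 10).
#' @param functional_classes Classes that count as functional.
#' @param burden_on_all Count the burden over all recorded mutations
#'   (default) or over functional ones only.
#' @return Binary genes x samples matrix.
#' @export
filter_functional_mutations <- function(mtab,
                                        min_mutations = 10L,
                                        functional_classes = c(
                                          "Frame_Shift_Del", "Frame_Shift_Ins",
                                          "Nonsense_Mutation"
                                        ),
                                        burden_on_all = TRUE) {
  mtab <- tibble::as_tibble(mtab)
  stopifnot(all(c("sample", "gene", "variant_classification") %in% names(mtab)))
  if ("Silent" %in% functional_classes) {
    abort("'Silent' cannot be a functional class")
  }
  burden_tab <- if (burden_on_all) {
    mtab
  } else {
    dplyr::filter(mtab, .data$variant_classification %in% functional_classes)
  }
  burden <- dplyr::count(burden_tab, .data$sample)
  keep_samples <- burden$sample[burden$n >= min_mutations]
  func <- dplyr::filter(
    mtab,
    .data$sample %in% keep_samples,
    .data$variant_classification %in% functional_classes
  ) |>
    dplyr::distinct(.data$sample, .data$gene)
  if (!nrow(func)) {
    abort("no samples survive the functional-mutation filters")
  }
  genes <- sort(unique(func$gene))
  samples <- sort(unique(keep_samples))
  m <- matrix(0L, length(genes), length(samples), dimnames = list(genes, samples))
  m[cbind(match(func$gene, genes), match(func$sample, samples))] <- 1L
  m
}

#' Align expression, mutation and clinical tables into one cohort bundle
#'
#' Intersects tumor-sample sets across all sources, reports drop counts per
#' source, and fixes the analysis scale at log2(TPM+1). Already-aligned
#' inputs pass through unchanged (idempotent).
#'
#' @param expr_tumor Tumor expression matrix; TPM or log2(TPM+1) per
#'   `scale_tag` attribute (TPM assumed when untagged and any value > 50).
#' @param mut Binary mutation matrix.
#' @param clinical Tibble: sample, time (> 0, years), event (0/1).
#' @param expr_normal Optional normal-tissue matrix (kept whole; normals
#'   are not part of the tumor intersection).
#' @param batch Optional tibble sample/batch; defaults to one batch.
#' @return An `sl_cohort` list: `expr_tumor`, `expr_normal`, `mut`,
#'   `clinical`, `batch`, `scale`, plus a `drop_report` attribute.
#' @export
align_cohorts <- function(expr_tumor, mut, clinical, expr_normal = NULL, batch = NULL) {
  clinical <- tibble::as_tibble(clinical)
  stopifnot(all(c("sample", "time", "event") %in% names(clinical)))
  if (any(clinical$time <= 0)) abort("clinical times must be > 0")
  tag <- attr(expr_tumor, "scale_tag") %||%
    (if (max(expr_tumor, na.rm = TRUE) > 50) "tpm" else "log2tpm")
  to_log2 <- function(m, tag) if (tag == "tpm") log2(m + 1) else m
  expr_tumor <- to_log2(expr_tumor, tag)
  if (!is.null(expr_normal)) {
    ntag <- attr(expr_normal, "scale_tag") %||%
      (if (max(expr_normal, na.rm = TRUE) > 50) "tpm" else "log2tpm")
    expr_normal <- to_log2(expr_normal, ntag)
  }
  common <- Reduce(intersect, list(colnames(expr_tumor), colnames(mut), clinical$sample))
  if (!length(common)) abort("no samples shared across expression, mutation and clinical inputs")
  drop_report <- c(
    expression = ncol(expr_tumor) - length(common),
    mutation = ncol(mut) - length(common),
    clinical = nrow(clinical) - length(common)
  )
  batch <- if (is.null(batch)) {
    tibble::tibble(sample = common, batch = "BATCH1")
  } else {
    dplyr::filter(tibble::as_tibble(batch), .data$sample %in% common)
  }
  structure(
    list(
      expr_tumor = expr_tumor[, common, drop = FALSE],
      expr_normal = expr_normal,
      mut = mut[, common, drop = FALSE],
      clinical = clinical[match(common, clinical$sample), ],
      batch = batch,
      scale = "log2tpm"
    ),
    class = "sl_cohort",
    drop_report = drop_report
  )
}

#' Per-batch median centering (optional plumbing)
#'
#' Subtracts each gene's per-batch median and restores the overall gene
#' median, a deliberately light alternative to model-based batch
#' correction. Off by default everywhere; provided for harmonized-enough
#' multi-study inputs.
#'
#' @param expr Genes x samples matrix.
#' @param batch Named batch label per sample (or tibble sample/batch).
#' @return Centered matrix.
#' @export
center_batches <- function(expr, batch) {
  if (is.data.frame(batch)) batch <- setNames(batch$batch, batch$sample)
  batch <- batch[colnames(expr)]
  overall <- apply(expr, 1, median)
  for (b in unique(batch)) {
    idx <- which(batch == b)
    med <- apply(expr[, idx, drop = FALSE], 1, median)
    expr[, idx] <- expr[, idx] - med + overall
  }
  expr
}
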