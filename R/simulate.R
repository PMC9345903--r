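#' Simulation configuration for synthetic SL cohorts
#'
#' Bundles every knob of the synthetic-data generator into one validated
#' list. The defaults define the package's reference benchmark: 300 tumors
#' with 60 adjacent normals, 15 driver genes crossed with 100 druggable
#' genes (1,500 candidate pairs), and 15 planted synthetic-lethal pairs that
#' carry all four screening signals — partner up-regulation in driver-mutant
#' tumors, co-expression in normals, mutual exclusivity of mutations, and a
#' shared GO annotation neighborhood.
#'
#' @param n_tumor,n_normal Tumor / adjacent-normal sample counts. At least
#'   3 normals are required (co-expression is undefined below that).
#' @param n_drivers,n_druggable Numbers of driver and druggable genes; the
#'   candidate-pair universe is their product.
#' @param n_planted_pairs Number of planted SL pairs (distinct partners,
#'   drivers recycled if needed); must not exceed `n_drivers * n_druggable`.
#' @param de_shift Partner up-regulation in driver-mutant tumors, in log2
#'   expression units.
#' @param coexpr_rho Target Spearman correlation of planted pairs in normal
#'   tissue; converted internally to the Pearson loading of a shared latent
#'   factor via `rho_pearson = 2 * sin(pi * rho_s / 6)`.
#' @param excl_factor Multiplier in `[0, 1)` applied to the independent
#'   co-mutation probability of planted pairs; 0 forbids co-mutation.
#' @param base_mut_rate_range Per-gene functional-mutation frequency range
#'   for background genes.
#' @param planted_mut_rate_range Frequency range for genes that belong to a
#'   planted pair; kept higher than background so the exclusivity deficit is
#'   detectable at the default cohort size.
#' @param mut_burden_sd Log-normal SD of the per-sample mutation-burden
#'   multiplier.
#' @param go_depth,go_branching Shape of each GO namespace tree (depth below
#'   the root, children per internal node); `go_depth` must be at least 2.
#' @param n_ccl Cancer cell lines in the simulated pharmacogenomic panel.
#' @param auc_noise_sd Noise SD of the dose-response AUC model.
#' @param na_rate Fraction of AUC cells set missing at random.
#' @param haem_fraction Fraction of CCLs labelled as haematopoietic/lymphoid
#'   lineage (excluded later by panel preparation).
#' @param n_extra_drugs Decoy compounds added to the drug catalog beyond the
#'   one-per-planted-partner responsive compounds.
#' @param seed Integer RNG seed; identical config + seed reproduces every
#'   artifact byte for byte.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_tumor = 60, n_normal = 12, seed = 1)
#' cfg$n_tumor
sim_config <- function(n_tumor = 300L,
                       n_normal = 60L,
                       n_drivers = 15L,
                       n_druggable = 100L,
                       n_planted_pairs = 15L,
                       de_shift = 2,
                       coexpr_rho = 0.6,
                       excl_factor = 0.1,
                       base_mut_rate_range = c(0.05, 0.25),
                       planted_mut_rate_range = c(0.2, 0.3),
                       mut_burden_sd = 0.15,
                       go_depth = 3L,
                       go_branching = 3L,
                       n_ccl = 200L,
                       auc_noise_sd = 0.05,
                       na_rate = 0.05,
                       haem_fraction = 0.1,
                       n_extra_drugs = 30L,
                       seed = 1L) {
  assert_count(n_tumor, "n_tumor")
  assert_count(n_normal, "n_normal")
  assert_count(n_drivers, "n_drivers")
  assert_count(n_druggable, "n_druggable")
  assert_count(n_planted_pairs, "n_planted_pairs", min = 0L)
  assert_count(go_depth, "go_depth", min = 2L)
  assert_count(go_branching, "go_branching")
  assert_count(n_ccl, "n_ccl")
  assert_count(n_extra_drugs, "n_extra_drugs", min = 0L)
  assert_count(seed, "seed", min = 0L)
  assert_fraction(excl_factor, "excl_factor")
  assert_fraction(na_rate, "na_rate")
  assert_fraction(haem_fraction, "haem_fraction")
  assert_fraction(coexpr_rho, "coexpr_rho", closed_hi = TRUE)
  if (n_normal < 3) {
    abort("`n_normal` must be >= 3: co-expression is undefined below that")
  }
  if (n_planted_pairs > n_drivers * n_druggable) {
    abort("`n_planted_pairs` cannot exceed n_drivers * n_druggable")
  }
  if (n_planted_pairs > n_druggable) {
    abort("`n_planted_pairs` cannot exceed n_druggable (partners are distinct)")
  }
  stopifnot(length(base_mut_rate_range) == 2L, length(planted_mut_rate_range) == 2L)
  structure(
    list(
      n_tumor = as.integer(n_tumor), n_normal = as.integer(n_normal),
      n_drivers = as.integer(n_drivers), n_druggable = as.integer(n_druggable),
      n_planted_pairs = as.integer(n_planted_pairs),
      de_shift = de_shift, coexpr_rho = coexpr_rho, excl_factor = excl_factor,
      base_mut_rate_range = base_mut_rate_range,
      planted_mut_rate_range = planted_mut_rate_range,
      mut_burden_sd = mut_burden_sd,
      go_depth = as.integer(go_depth), go_branching = as.integer(go_branching),
      n_ccl = as.integer(n_ccl), auc_noise_sd = auc_noise_sd,
      na_rate = na_rate, haem_fraction = haem_fraction,
      n_extra_drugs = as.integer(n_extra_drugs), seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Simulate a tumor/normal cohort with planted synthetic-lethal structure
#'
#' Generates a full analysis cohort: log2(TPM+1)-scale expression for tumors
#' and adjacent normals, a binary functional-mutation matrix, survival-style
#' clinical annotations, and pseudo-study batch labels. Each planted
#' (driver, partner) pair carries the four SL signals the screen tests for:
#'
#' * the partner's mean log2 expression in driver-mutant tumors exceeds
#'   wild-type by `de_shift`;
#' * driver and partner share a latent factor in normal tissue calibrated so
#'   their Spearman correlation equals `coexpr_rho`;
#' * the pair's co-mutation probability is `excl_factor` times the
#'   independence product, with marginal frequencies preserved;
#' * clinical hazard increases with partner expression in driver-mutant
#'   samples (exercised by survival validation).
#'
#' Decoy pairs satisfy none of these. Mutations follow a per-gene rate times
#' per-sample burden product model — the same background family the mutual
#' exclusivity module estimates, so its calibration is well-posed.
#'
#' @param config A [sim_config()].
#' @return A list with elements `cohort` (class `sl_cohort`: `expr_tumor`,
#'   `expr_normal` gene-by-sample matrices on the log2(TPM+1) scale, binary
#'   `mut` matrix, `clinical` and `batch` tibbles) and `truth` (class
#'   `sl_truth`: planted pairs, per-gene mutation rates, expression means,
#'   driver/druggable identifier sets).
#' @export
#' @examples
#' sim <- simulate_cohort(sim_config(n_tumor = 40, n_normal = 10, seed = 7))
#' dim(sim$cohort$expr_tumor)
#' sim$truth$planted_pairs
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(child_seed(config$seed, 101L), {
    n_gene <- config$n_drivers + config$n_druggable
    genes <- sprintf("G%04d", seq_len(n_gene))
    drivers <- genes[seq_len(config$n_drivers)]
    druggable <- genes[config$n_drivers + seq_len(config$n_druggable)]
    tumors <- sprintf("S%04d", seq_len(config$n_tumor))
    normals <- sprintf("N%04d", seq_len(config$n_normal))

    partners <- sample(druggable, config$n_planted_pairs)
    pair_drivers <- rep_len(sample(drivers), config$n_planted_pairs)
    planted <- tibble::tibble(driver = pair_drivers, partner = partners)

    # per-gene mutation rates; planted genes drawn from the (higher) planted
    # range so the exclusivity deficit is visible at the default cohort size
    rate <- runif(n_gene, config$base_mut_rate_range[1], config$base_mut_rate_range[2])
    names(rate) <- genes
    planted_genes <- unique(c(planted$driver, planted$partner))
    rate[planted_genes] <- runif(
      length(planted_genes),
      config$planted_mut_rate_range[1], config$planted_mut_rate_range[2]
    )

    burden <- exp(rnorm(config$n_tumor, -config$mut_burden_sd^2 / 2, config$mut_burden_sd))
    p_mut <- pmin(outer(rate, burden), 0.95) # genes x samples

    mut <- matrix(
      rbinom(length(p_mut), 1L, p_mut),
      nrow = n_gene, dimnames = list(genes, tumors)
    )
    # couple each planted pair: redraw the partner row conditionally on the
    # driver row so P(both) = excl_factor * p_d * p_p, marginals preserved
    for (k in seq_len(nrow(planted))) {
      d <- planted$driver[k]
      p <- planted$partner[k]
      pd <- p_mut[d, ]
      pp <- p_mut[p, ]
      p_given_mut <- config$excl_factor * pp
      p_given_wt <- pp * (1 - config$excl_factor * pd) / (1 - pd)
      pr <- ifelse(mut[d, ] == 1L, p_given_mut, pmin(p_given_wt, 1))
      mut[p, ] <- rbinom(config$n_tumor, 1L, pr)
    }

    mu <- runif(n_gene, 2, 8)
    names(mu) <- genes

    expr_tumor <- matrix(
      rnorm(n_gene * config$n_tumor, mean = mu, sd = 1),
      nrow = n_gene, dimnames = list(genes, tumors)
    )
    for (k in seq_len(nrow(planted))) {
      mutant <- mut[planted$driver[k], ] == 1L
      expr_tumor[planted$partner[k], mutant] <-
        expr_tumor[planted$partner[k], mutant] + config$de_shift
    }

    expr_normal <- matrix(
      rnorm(n_gene * config$n_normal, mean = mu, sd = 1),
      nrow = n_gene, dimnames = list(genes, normals)
    )
    # shared-factor planting calibrated through the bivariate-normal ->
    # Spearman identity rho_s = (6/pi) asin(rho_p / 2)
    rho_p <- 2 * sin(pi * config$coexpr_rho / 6)
    for (k in seq_len(nrow(planted))) {
      d <- planted$driver[k]
      p <- planted$partner[k]
      z_d <- expr_normal[d, ] - mu[d]
      expr_normal[p, ] <- mu[p] + rho_p * z_d +
        sqrt(1 - rho_p^2) * rnorm(config$n_normal)
    }

    # floor keeps the TPM back-transform (2^x - 1) strictly positive
    expr_tumor <- pmax(expr_tumor, 0.01)
    expr_normal <- pmax(expr_normal, 0.01)

    # survival: hazard rises with planted-partner expression in mutant samples
    lp <- rep(0, config$n_tumor)
    for (k in seq_len(nrow(planted))) {
      mutant <- mut[planted$driver[k], ] == 1L
      lp[mutant] <- lp[mutant] +
        0.6 * (expr_tumor[planted$partner[k], mutant] - mu[planted$partner[k]])
    }
    t_event <- rexp(config$n_tumor, rate = 0.15 * exp(lp))
    t_cens <- runif(config$n_tumor, 1, 12)
    clinical <- tibble::tibble(
      sample = tumors,
      time = pmax(pmin(t_event, t_cens), 1e-3),
      event = as.integer(t_event <= t_cens)
    )

    batch <- tibble::tibble(
      sample = tumors,
      batch = rep_len(c("STUDY1", "STUDY2"), config$n_tumor)
    )

    cohort <- structure(
      list(
        expr_tumor = expr_tumor, expr_normal = expr_normal, mut = mut,
        clinical = clinical, batch = batch, scale = "log2tpm"
      ),
      class = "sl_cohort"
    )
    truth <- structure(
      list(
        planted_pairs = planted,
        drivers = drivers, druggable = druggable,
        mut_rate = rate, gene_means = mu,
        mutant_label = mut[drivers, , drop = FALSE]
      ),
      class = "sl_truth"
    )
    list(cohort = cohort, truth = truth)
  })
}

#' Simulate a GO DAG and gene annotations with planted proximity
#'
#' Builds one rooted tree per namespace (MF, CC, and a BP namespace that the
#' functional-similarity score ignores) with `go_branching` children per
#' internal node down to `go_depth` levels. Every fifth child edge is typed
#' `part_of`, the rest `is_a`. Both genes of a planted pair are annotated to
#' the same leaf (the partner additionally to a sibling leaf) in MF and CC,
#' so their Wang similarity is high; decoy genes get random leaves.
#'
#' @param config A [sim_config()].
#' @param truth The `sl_truth` object from [simulate_cohort()].
#' @return List with `graph` (class `go_graph`) and `annotation` (tibble:
#'   gene, term, aspect in F/C/P).
#' @export
simulate_go_annotation <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sl_truth"))
  with_seed(child_seed(config$seed, 202L), {
    counter <- 0L
    build_ns <- function(ns) {
      ids <- character(0)
      edges <- list()
      new_term <- function() {
        counter <<- counter + 1L
        sprintf("GO:%07d", counter)
      }
      root <- new_term()
      ids <- root
      level <- root
      edge_i <- 0L
      for (d in seq_len(config$go_depth)) {
        nxt <- character(0)
        for (parent in level) {
          for (b in seq_len(config$go_branching)) {
            child <- new_term()
            ids <- c(ids, child)
            edge_i <- edge_i + 1L
            edges[[length(edges) + 1L]] <- tibble::tibble(
              child = child, parent = parent,
              type = if (edge_i %% 5L == 0L) "part_of" else "is_a"
            )
            nxt <- c(nxt, child)
          }
        }
        level <- nxt
      }
      list(
        terms = tibble::tibble(term = ids, namespace = ns),
        edges = dplyr::bind_rows(edges),
        leaves = level,
        root = root
      )
    }
    ns_list <- lapply(c("MF", "CC", "BP"), build_ns)
    names(ns_list) <- c("MF", "CC", "BP")
    graph <- go_graph(
      terms = dplyr::bind_rows(lapply(ns_list, `[[`, "terms")),
      edges = dplyr::bind_rows(lapply(ns_list, `[[`, "edges"))
    )

    genes <- c(truth$drivers, truth$druggable)
    planted <- truth$planted_pairs
    ann <- list()
    add <- function(gene, term, aspect) {
      ann[[length(ann) + 1L]] <<- tibble::tibble(gene = gene, term = term, aspect = aspect)
    }
    for (ns in c("MF", "CC")) {
      leaves <- ns_list[[ns]]$leaves
      aspect <- if (ns == "MF") "F" else "C"
      used <- character(0)
      for (k in seq_len(nrow(planted))) {
        leaf <- sample(setdiff(leaves, used), 1L)
        used <- c(used, leaf)
        sib <- sample(setdiff(leaves, leaf), 1L)
        add(planted$driver[k], leaf, aspect)
        add(planted$partner[k], leaf, aspect)
        add(planted$partner[k], sib, aspect)
      }
      decoys <- setdiff(genes, unique(c(planted$driver, planted$partner)))
      for (g in decoys) {
        add(g, sample(leaves, 1L), aspect)
      }
    }
    bp_leaves <- ns_list[["BP"]]$leaves
    for (g in genes) add(g, sample(bp_leaves, 1L), "P")
    list(graph = graph, annotation = dplyr::bind_rows(ann))
  })
}

#' Simulate a drug-target catalog
#'
#' Gives every planted SL partner at least one responsive compound, then adds
#' `n_extra` decoy compounds targeting random non-partner druggable genes.
#' Rows are unique on (drug_id, target_gene).
#'
#' @param truth `sl_truth` from [simulate_cohort()].
#' @param n_extra Number of decoy compounds.
#' @param seed Integer seed.
#' @return Tibble: drug_id, drug_name, target_gene; attribute
#'   `responsive` marks the planted-partner compounds.
#' @export
simulate_drug_catalog <- function(truth, n_extra = 30L, seed = 1L) {
  stopifnot(inherits(truth, "sl_truth"))
  with_seed(child_seed(seed, 303L), {
    partners <- unique(truth$planted_pairs$partner)
    decoy_targets <- sample(setdiff(truth$druggable, partners), n_extra, replace = TRUE)
    catalog <- tibble::tibble(
      drug_id = sprintf("D%04d", seq_len(length(partners) + n_extra)),
      drug_name = sprintf("compound_%04d", seq_len(length(partners) + n_extra)),
      target_gene = c(partners, decoy_targets)
    )
    catalog <- dplyr::distinct(catalog, .data$drug_id, .data$target_gene, .keep_all = TRUE)
    attr(catalog, "responsive") <- catalog$drug_id[seq_along(partners)]
    catalog
  })
}

#' Simulate a cancer cell line pharmacogenomic panel
#'
#' Expression is drawn on the cohort's log2 scale (same per-gene means, so
#' expression-to-response models transfer to clinical samples). For each
#' responsive compound (one per planted partner), the dose-response AUC
#' decreases linearly in the standardized target-gene expression —
#' `AUC = 0.7 - 0.15 * z(target) + N(0, auc_noise_sd)` — so high partner
#' expression means high sensitivity (low AUC). Decoy compounds get
#' expression-independent AUC noise. Missing cells are injected at `na_rate`
#' and a `haem_fraction` of lines is labelled haematopoietic/lymphoid.
#'
#' @param config A [sim_config()].
#' @param truth `sl_truth` from [simulate_cohort()].
#' @param catalog Catalog from [simulate_drug_catalog()].
#' @return A `drug_panel` object: `ccl_expr` (genes x CCLs), `auc`
#'   (CCLs x compounds, NAs allowed), `ccl_meta` tibble, plus the noiseless
#'   AUC surface as attribute `auc_true` for recovery checks.
#' @export
simulate_ccl_panel <- function(config, truth, catalog) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sl_truth"))
  with_seed(child_seed(config$seed, 404L), {
    genes <- names(truth$gene_means)
    ccls <- sprintf("CCL%04d", seq_len(config$n_ccl))
    expr <- matrix(
      rnorm(length(genes) * config$n_ccl, mean = truth$gene_means, sd = 1),
      nrow = length(genes), dimnames = list(genes, ccls)
    )
    responsive <- attr(catalog, "responsive") %||% character(0)
    auc_true <- matrix(
      0.7, nrow = config$n_ccl, ncol = nrow(catalog),
      dimnames = list(ccls, catalog$drug_id)
    )
    for (j in seq_len(nrow(catalog))) {
      if (catalog$drug_id[j] %in% responsive) {
        z <- as.numeric(scale(expr[catalog$target_gene[j], ]))
        auc_true[, j] <- 0.7 - 0.15 * z
      }
    }
    auc <- auc_true + rnorm(length(auc_true), sd = config$auc_noise_sd)
    auc <- pmax(auc, 0.01)
    if (config$na_rate > 0) {
      auc[runif(length(auc)) < config$na_rate] <- NA_real_
    }
    n_haem <- round(config$haem_fraction * config$n_ccl)
    lineage <- rep("kidney", config$n_ccl)
    if (n_haem > 0) {
      lineage[sample(config$n_ccl, n_haem)] <- "haematopoietic_and_lymphoid_tissue"
    }
    structure(
      list(
        ccl_expr = expr,
        auc = auc,
        ccl_meta = tibble::tibble(ccl = ccls, lineage = lineage)
      ),
      class = "drug_panel",
      auc_true = auc_true
    )
  })
}

#' Simulate multi-study labeled cohorts for the mutation classifier
#'
#' Emits log2-scale expression with a planted gene signature separating
#' mutant from wild-type samples, split across pseudo-studies, for
#' exercising elastic-net training and leave-one-study-out validation.
#'
#' @param n_studies,n_per_study Study count and samples per study.
#' @param n_genes Total genes; the first `n_signature` carry the signal.
#' @param n_signature Signature size.
#' @param shift Log2 up-shift of signature genes in mutant samples.
#' @param mut_rate Mutant prevalence per study.
#' @param seed Integer seed.
#' @return List: `expr` (genes x samples), `labels` (0/1 integer, named),
#'   `study` (character, named), `signature` (gene ids).
#' @export
simulate_labeled_cohorts <- function(n_studies = 2L, n_per_study = 100L,
                                     n_genes = 300L, n_signature = 20L,
                                     shift = 3, mut_rate = 0.4, seed = 1L) {
  with_seed(child_seed(seed, 505L), {
    genes <- sprintf("G%04d", seq_len(n_genes))
    n <- n_studies * n_per_study
    samples <- sprintf("S%04d", seq_len(n))
    study <- setNames(rep(sprintf("STUDY%d", seq_len(n_studies)), each = n_per_study), samples)
    labels <- setNames(rbinom(n, 1L, mut_rate), samples)
    mu <- runif(n_genes, 2, 8)
    expr <- matrix(rnorm(n_genes * n, mean = mu, sd = 1),
      nrow = n_genes, dimnames = list(genes, samples)
    )
    sig <- genes[seq_len(n_signature)]
    expr[sig, labels == 1L] <- expr[sig, labels == 1L] + shift
    list(expr = expr, labels = labels, study = study, signature = sig)
  })
}

#' Write a simulated study to disk as plain-text fixtures
#'
#' Serializes a simulated cohort, GO structure, catalog and CCL panel as the
#' standard file set the readers in this package consume: expression TSVs
#' (TPM scale), a MAF-subset TSV (one functional-mutation row per 1 cell of
#' the binary matrix, classes cycled over frameshift/nonsense), clinical and
#' batch TSVs, OBO and GAF subsets, catalog and AUC TSVs, and a ground-truth
#' JSON manifest.
#'
#' @param sim Output of [simulate_cohort()].
#' @param go Output of [simulate_go_annotation()] (optional).
#' @param catalog,panel Optional catalog / panel objects.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, go = NULL, catalog = NULL, panel = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- sim$cohort
  write_expression(2^cohort$expr_tumor - 1, file.path(dir, "expr_tumor.tsv"))
  write_expression(2^cohort$expr_normal - 1, file.path(dir, "expr_normal.tsv"))

  idx <- which(cohort$mut == 1L, arr.ind = TRUE)
  classes <- c("Frame_Shift_Del", "Frame_Shift_Ins", "Nonsense_Mutation")
  maf <- tibble::tibble(
    Tumor_Sample_Barcode = colnames(cohort$mut)[idx[, "col"]],
    Hugo_Symbol = rownames(cohort$mut)[idx[, "row"]],
    Variant_Classification = classes[(seq_len(nrow(idx)) - 1L) %% 3L + 1L]
  ) |>
    dplyr::arrange(.data$Tumor_Sample_Barcode, .data$Hugo_Symbol)
  readr::write_tsv(maf, file.path(dir, "mutations.maf.tsv"))
  readr::write_tsv(cohort$clinical, file.path(dir, "clinical.tsv"))
  readr::write_tsv(cohort$batch, file.path(dir, "batch.tsv"))

  if (!is.null(go)) {
    write_obo_subset(go$graph, file.path(dir, "go.obo"))
    readr::write_tsv(go$annotation, file.path(dir, "annotations.gaf.tsv"))
  }
  if (!is.null(catalog)) {
    readr::write_tsv(catalog, file.path(dir, "drug_catalog.tsv"))
  }
  if (!is.null(panel)) {
    write_expression(panel$ccl_expr, file.path(dir, "ccl_expr.tsv"))
    auc_df <- tibble::as_tibble(panel$auc, rownames = "ccl")
    readr::write_tsv(auc_df, file.path(dir, "ccl_auc.tsv"))
    readr::write_tsv(panel$ccl_meta, file.path(dir, "ccl_meta.tsv"))
  }
  truth <- sim$truth
  jsonlite::write_json(
    list(
      planted_pairs = truth$planted_pairs,
      drivers = truth$drivers,
      druggable = truth$druggable
    ),
    file.path(dir, "ground_truth.json"),
    dataframe = "rows", pretty = TRUE
  )
  invisible(dir)
}
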