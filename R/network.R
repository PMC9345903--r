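#' Build the driver-target-drug network
#'
#' Joins screened SL pairs with the drug-target catalog and the per-driver
#' drug-response flags into a tripartite network. Edge types: `sl`
#' (driver - target, carrying the screen statistics and RAS when present),
#' `targets` (drug - target, for drugs whose target is an SL partner), and
#' `effective` (driver - drug, only when the compound is flagged
#' SL-associated for that driver *and* targets one of the driver's SL
#' partners — every effective edge is backed by a driver-target-drug path).
#' Drugs without a `targets` edge are omitted entirely.
#'
#' @param sl_pairs Tibble of final SL pairs: `driver`, `partner`, optional
#'   `ras`.
#' @param catalog Drug catalog (drug_id, drug_name, target_gene).
#' @param drug_flags Tibble: `driver`, `compound`, `logfc`, `p_value`,
#'   `sl_flag` (as from [differential_drug_response()] run per driver).
#' @return A `dmdg_network`: `nodes` (id, type) and `edges`
#'   (from, to, type, stat columns) tibbles.
#' @export
build_drug_network <- function(sl_pairs, catalog, drug_flags = NULL) {
  sl_pairs <- tibble::as_tibble(sl_pairs)
  stopifnot(all(c("driver", "partner") %in% names(sl_pairs)))
  sl_pairs <- dplyr::distinct(sl_pairs, .data$driver, .data$partner, .keep_all = TRUE)

  targets <- dplyr::filter(catalog, .data$target_gene %in% sl_pairs$partner) |>
    dplyr::distinct(.data$drug_id, .data$target_gene)

  sl_edges <- tibble::tibble(
    from = sl_pairs$driver, to = sl_pairs$partner, type = "sl",
    ras = if ("ras" %in% names(sl_pairs)) sl_pairs$ras else NA_real_
  )
  target_edges <- tibble::tibble(
    from = targets$drug_id, to = targets$target_gene, type = "targets",
    ras = NA_real_
  )
  effective_edges <- tibble::tibble(
    from = character(0), to = character(0), type = character(0), ras = numeric(0),
    logfc = numeric(0), p_value = numeric(0)
  )
  if (!is.null(drug_flags) && nrow(drug_flags)) {
    flagged <- dplyr::filter(tibble::as_tibble(drug_flags), .data$sl_flag)
    eff <- sl_pairs |>
      dplyr::inner_join(targets, by = c(partner = "target_gene"), relationship = "many-to-many") |>
      dplyr::inner_join(flagged, by = c("driver", drug_id = "compound"))
    effective_edges <- dplyr::distinct(tibble::tibble(
      from = eff$driver, to = eff$drug_id, type = "effective",
      ras = NA_real_, logfc = eff$logfc, p_value = eff$p_value
    ))
  }
  edges <- dplyr::bind_rows(
    dplyr::mutate(sl_edges, logfc = NA_real_, p_value = NA_real_),
    dplyr::mutate(target_edges, logfc = NA_real_, p_value = NA_real_),
    effective_edges
  )
  nodes <- dplyr::bind_rows(
    tibble::tibble(id = unique(sl_pairs$driver), type = "driver"),
    tibble::tibble(id = unique(sl_pairs$partner), type = "target"),
    tibble::tibble(id = unique(targets$drug_id), type = "drug")
  )
  structure(list(nodes = nodes, edges = edges), class = "dmdg_network")
}

#' Survival validation of an SL pair
#'
#' Within driver-mutant samples, splits patients by the partner's tumor
#' expression at the median — strictly above the median is "active",
#' at-or-below is "inactive" — and compares survival between the groups by
#' the log-rank test and a univariate Cox proportional-hazards model
#' (hazard ratio of active vs inactive, Breslow ties). Under the SL
#' hypothesis the active group (intact, highly expressed partner) does
#' worse: HR > 1.
#'
#' @param cohort An `sl_cohort` with clinical data.
#' @param driver,partner Gene identifiers of the pair.
#' @param min_mutant Minimum driver-mutant samples with survival data.
#' @return Tibble: driver, partner, n, n_active, logrank_p, cox_hr,
#'   hr_low, hr_high.
#' @export
survival_validate <- function(cohort, driver, partner, min_mutant = 10L) {
  stopifnot(inherits(cohort, "sl_cohort"))
  mutant <- colnames(cohort$mut)[cohort$mut[driver, ] == 1L]
  cl <- dplyr::filter(cohort$clinical, .data$sample %in% mutant)
  cl <- dplyr::filter(cl, .data$sample %in% colnames(cohort$expr_tumor))
  if (nrow(cl) < min_mutant) {
    abort(sprintf(
      "only %d driver-mutant samples with survival data (need >= %d)",
      nrow(cl), min_mutant
    ))
  }
  x <- cohort$expr_tumor[partner, cl$sample]
  active <- x > median(x)
  if (all(active) || !any(active)) {
    abort(sprintf("constant expression of '%s' in mutant samples: no split", partner))
  }
  surv <- survival::Surv(cl$time, cl$event)
  lr <- survival::survdiff(surv ~ active)
  logrank_p <- stats::pchisq(lr$chisq, df = 1, lower.tail = FALSE)
  cox <- survival::coxph(surv ~ active, ties = "breslow")
  ci <- suppressMessages(stats::confint(cox))
  tibble::tibble(
    driver = driver, partner = partner,
    n = nrow(cl), n_active = sum(active),
    logrank_p = logrank_p,
    cox_hr = unname(exp(coef(cox))),
    hr_low = exp(ci[1]), hr_high = exp(ci[2])
  )
}

#' Export pipeline results to a directory
#'
#' Writes the network JSON, the ranked-candidate and validation TSVs, and a
#' run manifest JSON capturing thresholds, seeds and drop counts. Output is
#' deterministic for identical inputs (no timestamps).
#'
#' @param outdir Output directory (created if needed).
#' @param network A `dmdg_network` (optional).
#' @param ranked Ranked candidate tibble (optional).
#' @param validations Survival-validation tibble (optional).
#' @param manifest Named list recorded as `manifest.json`.
#' @return `outdir`, invisibly.
#' @export
export_results <- function(outdir, network = NULL, ranked = NULL,
                           validations = NULL, manifest = list()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(network)) write_network_json(network, file.path(outdir, "network.json"))
  if (!is.null(ranked)) write_results_tsv(ranked, file.path(outdir, "ranked_pairs.tsv"))
  if (!is.null(validations)) write_results_tsv(validations, file.path(outdir, "survival_validation.tsv"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA, na = "null"
  )
  invisible(outdir)
}
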