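#' Pipeline run configuration
#'
#' One validated object holding every threshold and knob of the end-to-end
#' run; no stage reads defaults from anywhere else. Unknown keys in any
#' section are rejected; a mutual-exclusivity threshold outside the two
#' documented options (0.15, 0.1) is accepted with a warning.
#'
#' @param sim Named list of [sim_config()] overrides (seed comes from
#'   `seed` below).
#' @param screen Named list of [screen_config()] overrides.
#' @param drug Named list: `p_cut`, `na_threshold`, `knn_k`, `cv_folds`.
#' @param stages Stages to run, in order, from `simulate`, `screen`,
#'   `aggregate`, `drugs`, `network`.
#' @param seed Integer seed (mandatory: simulation and model training are
#'   stochastic).
#' @return A list of class `sl_run_config`.
#' @export
sl_config <- function(sim = list(), screen = list(),
                      drug = list(), stages = c(
                        "simulate", "screen",
                        "aggregate", "drugs", "network"
                      ),
                      seed = NULL) {
  if (is.null(seed)) abort("`seed` is mandatory (the simulate stage is stochastic)")
  assert_count(seed, "seed", min = 0L)
  known_stages <- c("simulate", "screen", "aggregate", "drugs", "network")
  bad <- setdiff(stages, known_stages)
  if (length(bad)) abort(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))

  check_keys <- function(x, allowed, section) {
    bad <- setdiff(names(x), allowed)
    if (length(bad)) {
      abort(sprintf("unknown key(s) in `%s`: %s", section, paste(bad, collapse = ", ")))
    }
    x
  }
  sim <- check_keys(sim, setdiff(names(formals(sim_config)), "seed"), "sim")
  screen <- check_keys(screen, names(formals(screen_config)), "screen")
  drug_defaults <- list(p_cut = 0.05, na_threshold = 0.2, knn_k = 10L, cv_folds = 10L)
  drug <- utils::modifyList(drug_defaults, check_keys(drug, names(drug_defaults), "drug"))

  screen_cfg <- do.call(screen_config, screen) # range-validates thresholds
  if (!screen_cfg$mutex_threshold %in% c(0.15, 0.1)) {
    warn(sprintf(
      "mutex threshold %g is outside the documented options (0.15, 0.1); accepted",
      screen_cfg$mutex_threshold
    ))
  }
  assert_fraction(drug$p_cut, "drug$p_cut", closed_hi = TRUE)

  structure(
    list(
      sim = sim, screen = screen_cfg, drug = drug,
      stages = stages, seed = as.integer(seed)
    ),
    class = "sl_run_config"
  )
}

#' Run the full SL discovery pipeline on a synthetic study
#'
#' Executes simulate, screen, aggregate, drugs and network stages in order
#' on one seeded synthetic study, writing every intermediate plus a run
#' manifest under `outdir`. Reruns with an identical config and seed
#' produce a byte-identical output tree.
#'
#' @param config An [sl_config()].
#' @param outdir Output directory.
#' @return Invisibly, a list with the in-memory stage results
#'   (`sim`, `screen`, `ranked`, `drug_screen`, `network`, `validations`).
#' @export
run_sl_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "sl_run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  run <- function(stage) stage %in% config$stages
  out <- list()
  counts <- list()

  if (!run("simulate")) abort("file-based inputs are not wired up: enable the simulate stage")
  scfg <- do.call(sim_config, c(config$sim, list(seed = config$seed)))
  sim <- simulate_cohort(scfg)
  go <- simulate_go_annotation(scfg, sim$truth)
  catalog <- simulate_drug_catalog(sim$truth, n_extra = scfg$n_extra_drugs, seed = scfg$seed)
  panel <- simulate_ccl_panel(scfg, sim$truth, catalog)
  write_simulation(sim, file.path(outdir, "sim"), go = go, catalog = catalog, panel = panel)
  out$sim <- sim
  counts$n_tumor <- ncol(sim$cohort$expr_tumor)
  counts$n_pairs_candidate <- length(sim$truth$drivers) * length(sim$truth$druggable)

  screen <- ranked <- NULL
  if (run("screen")) {
    screen <- run_sl_screen(
      sim$cohort, sim$truth$drivers, sim$truth$druggable,
      go$graph, go$annotation,
      config = config$screen
    )
    write_results_tsv(screen, file.path(outdir, "screen_candidates.tsv"))
    out$screen <- screen
    counts$n_pass_all <- sum(screen$pass_all)
    counts$n_pass_de <- sum(screen$pass_de)
    counts$n_pass_coexpr <- sum(screen$pass_coexpr)
    counts$n_pass_fss <- sum(screen$pass_fss)
    counts$n_pass_mutex <- sum(screen$pass_mutex)
  }

  if (run("aggregate") && !is.null(screen) && any(screen$pass_all)) {
    ranked <- aggregate_ranks(dplyr::filter(screen, .data$pass_all))
    write_results_tsv(
      dplyr::select(
        ranked, "driver", "partner", "fss", "log2fc", "rho",
        "mutex_padj", "stuart_p", "ras", "final_rank"
      ),
      file.path(outdir, "ranked_pairs.tsv")
    )
    out$ranked <- ranked
  }

  drug_flags <- NULL
  if (run("drugs")) {
    prepped <- prep_drug_panel(panel,
      na_threshold = config$drug$na_threshold,
      knn_k = config$drug$knn_k
    )
    models <- train_drug_models(prepped,
      cv_folds = config$drug$cv_folds,
      seed = config$seed
    )
    est <- predict_drug_response(models, sim$cohort$expr_tumor)
    flag_drivers <- if (!is.null(ranked)) unique(ranked$driver) else sim$truth$drivers
    drug_flags <- purrr::map(flag_drivers, function(d) {
      dplyr::mutate(
        differential_drug_response(est, sim$cohort$mut[d, ], p_cut = config$drug$p_cut),
        driver = d, .before = 1
      )
    }) |> dplyr::bind_rows()
    write_results_tsv(drug_flags, file.path(outdir, "drug_screen.tsv"))
    out$drug_screen <- drug_flags
    counts$n_sl_drugs <- sum(drug_flags$sl_flag)
  }

  if (run("network") && !is.null(ranked)) {
    network <- build_drug_network(ranked, catalog, drug_flags)
    validations <- purrr::map(seq_len(nrow(ranked)), function(i) {
      tryCatch(
        survival_validate(sim$cohort, ranked$driver[i], ranked$partner[i]),
        error = function(e) NULL
      )
    }) |> dplyr::bind_rows()
    export_results(
      outdir,
      network = network, validations = validations,
      manifest = list(
        seed = config$seed,
        stages = config$stages,
        thresholds = c(unclass(config$screen), config$drug),
        sim_overrides = config$sim,
        counts = counts,
        package_version = as.character(utils::packageVersion("slscreen"))
      )
    )
    out$network <- network
    out$validations <- validations
  } else {
    export_results(outdir, manifest = list(
      seed = config$seed, stages = config$stages,
      thresholds = c(unclass(config$screen), config$drug),
      sim_overrides = config$sim, counts = counts,
      package_version = as.character(utils::packageVersion("slscreen"))
    ))
  }
  invisible(out)
}
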