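# slscreen

Screening tumor cohorts for synthetic-lethal (SL) partners of driver
mutations, and turning the survivors into therapeutic hypotheses.

Two genes are synthetic-lethal when a cell tolerates losing either one but
dies when both are lost. A tumor carrying a loss-of-function driver
mutation (DM) has already lost one of the two, so a drug against the
intact partner — a druggable gene (DG) — should kill mutant tumor cells
while sparing normal tissue. `slscreen` is for computational biologists
who want to infer such DM–DG pairs from routine cohort data (expression,
somatic mutations, survival) rather than from bespoke CRISPR/RNAi screens,
and to connect the hits to compounds.

## What it computes

Every (driver, druggable gene) pair is scored by four independent
procedures and must pass all four:

1. **Differential partner expression** — Wilcoxon rank-sum test between
   driver-mutant and wild-type tumors on log2(TPM+1); pass iff
   BH-adjusted p < 0.05 *and* log2FC > 0 (compensatory up-regulation).
2. **Co-expression in adjacent normals** — Spearman ρ > 0.1 with
   BH-adjusted p < 0.05.
3. **Functional similarity** — FSS = √(SsMF · SsCC) > 0.45, where SsMF and
   SsCC are gene-level Wang semantic similarities in the GO
   molecular-function and cellular-component namespaces (is_a edges
   weighted 0.8, part_of 0.6, best-match-average combining).
4. **Mutual exclusivity** — one-sided Poisson-binomial lower-tail test of
   the observed co-mutation count against a margin-aware background
   p_ij = logistic(u_i + v_j); pass iff BH-adjusted p < 0.15 (0.1
   available via config). A curveball fixed-margin permutation oracle
   validates the analytic p-values.

Survivors are ranked by the Stuart order-statistics p-value over the four
criterion rankings, summarized as RAS = −log2(p). Per-compound ridge
models trained on a cell-line panel (AUC ~ expression; >20%-NA compounds
dropped, KNN-imputed, haematopoietic/lymphoid lines excluded) impute drug
response in patients; compounds with significantly lower estimated AUC in
mutant samples (logFC < 0, Wilcoxon p < 0.05) are SL-associated and join
the driver–target–drug network. An elastic-net classifier (α = 0.9,
|log2FC| > 1.5 gene selection) imputes mutation status for cohorts
without sequencing, validated leave-one-study-out. A synthetic-cohort
generator with planted SL structure (`sim_config()`, `simulate_cohort()`,
…) makes the whole pipeline testable end to end without external data.

## Worked example

```r
library(slscreen)

cfg    <- sim_config(seed = 42)           # 300 tumors, 60 normals, 15 planted pairs
sim    <- simulate_cohort(cfg)
go     <- simulate_go_annotation(cfg, sim$truth)
screen <- run_sl_screen(sim$cohort, sim$truth$drivers, sim$truth$druggable,
                        go$graph, go$annotation)
glance(screen)
#> # A tibble: 1 × 6
#>   n_pairs n_pass_de n_pass_coexpr n_pass_fss n_pass_mutex n_pass_all
#>     <int>     <int>         <int>      <int>        <int>      <int>
#> 1    1500        15            15         99           15         14

ranked <- aggregate_ranks(dplyr::filter(screen, pass_all))
head(tidy(ranked)[c("driver", "partner", "log2fc", "rho", "fss",
                    "mutex_padj", "stuart_p", "ras")], 3)
#> # A tibble: 3 × 8
#>   driver partner log2fc   rho   fss  mutex_padj stuart_p   ras
#>   <chr>  <chr>    <dbl> <dbl> <dbl>       <dbl>    <dbl> <dbl>
#> 1 G0007  G0057     2.01 0.641 0.755 0.000000401   0.0260  5.27
#> 2 G0014  G0087     2.10 0.627 0.802 0.000483      0.0427  4.55
#> 3 G0012  G0069     1.98 0.611 0.794 0.0000142     0.0712  3.81
```

Of 1,500 candidate pairs, 14 pass all four procedures — all of them
planted pairs (15 were planted; one misses the co-expression cut at this
seed). The ranked table reads: the top pair is up-shifted by ~2 log2
units in mutant tumors, co-expressed at ρ ≈ 0.64 in normals, functionally
close (FSS 0.76), and co-mutated far less than its margins predict; its
four ranks are jointly extreme (Stuart p 0.026, RAS 5.3).

`autoplot(screen)` draws the screening funnel, `autoplot(ranked)` the RAS
ranking, and `run_sl_pipeline(sl_config(seed = 42), "out/")` runs
simulate → screen → aggregate → drugs → network in one call, writing
every intermediate plus a manifest (byte-identical on rerun).

## Documentation

The methods vignette (`vignettes/sl-screening-methods.Rmd`) describes the
models, thresholds, generator design, numerical choices, and known
limitations (conservatism regimes of the exclusivity test, annotation
bias of the FSS filter, the decoy flag-rate behavior of the estimated-AUC
screen).
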