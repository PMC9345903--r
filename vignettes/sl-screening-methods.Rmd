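---
title: "Methods: screening for synthetic-lethal partners of driver mutations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening for synthetic-lethal partners of driver mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slscreen)
```

## The problem

Two genes are synthetic-lethal (SL) when losing either alone is tolerated
but losing both kills the cell. In tumors that carry a loss-of-function
driver mutation (DM), the intact SL partner is a drug target with a built-in
therapeutic window: inhibiting it should kill mutant tumor cells and spare
normal tissue. Direct CRISPR/RNAi screens for SL pairs are expensive and do
not scale to many drivers, so this package infers candidate pairs from
routinely collected tumor profiles — expression, somatic mutations, survival
— restricted to druggable genes (DGs, genes with at least one compound in a
drug-target catalog).

## The four-procedure screen

Every (driver, druggable gene) pair is scored by four independent
procedures; only pairs passing all four enter the final candidate set.

**1. Differential partner expression.** If the partner compensates for the
driver's loss, tumors carrying the driver mutation should up-regulate it.
Per driver, each candidate is tested by a two-sided Wilcoxon rank-sum test
between mutant and wild-type tumors on log2(TPM+1) expression, with
Benjamini-Hochberg (BH) adjustment across that driver's candidates. Pass
requires `padj < 0.05` *and* a positive log2 fold change (difference of
group means on the log2 scale). The direction rule is the substantive
criterion; the p-value threshold is this package's choice (the underlying
procedure is usually reported with the direction rule only), exposed as
`screen_config(de_padj =)`.

**2. Co-expression in normal tissue.** SL partners tend to work in related
processes and co-express in non-tumor tissue. Spearman correlation across
adjacent-normal samples, BH across all pairs; pass iff `rho > 0.1` and
`padj < 0.05`. Both cuts bind: a significant but weak correlation fails.
Constant expression leaves rho undefined and the pair fails.

**3. Functional similarity.** Pairs should sit close in the Gene Ontology.
Gene-level similarity is computed in the MF and CC namespaces with the Wang
graph-based measure: the S-value of an ancestor t for term A is the maximal
product of edge weights (0.8 per `is_a`, 0.6 per `part_of` edge) along a
path from A up to t; term similarity is the shared ancestors' combined
S-mass normalized by both terms' total S-mass; gene similarity combines
term similarities by the best-match average. The functional similarity
score is the geometric mean `FSS = sqrt(SsMF * SsCC)`; pass iff
`FSS > 0.45` strictly. A gene with no MF or no CC annotation leaves FSS
undefined, which fails the procedure — the screen retains only positive
evidence of proximity. BP annotations are parsed and stored but unused.

**4. Mutual exclusivity.** If simultaneous loss is lethal, tumors with both
genes mutated should be depleted. The background model fits
`p_ij = plogis(u_i + v_j)` by alternating Newton solves so that expected
per-gene and per-sample margins match the observed ones (tolerance 1e-8).
Under independence, the co-mutation count of a pair is Poisson-binomial
with per-sample probabilities `p_a,i * p_b,i`; the one-sided p-value
`P(C <= n_co)` is computed by an exact dynamic-programming convolution
truncated at the observed count. BH across all tested pairs; pass iff
`padj < 0.15` (a stricter 0.1 variant is kept as a config option — both
thresholds circulate in practice and the run manifest records the choice).

A curveball permutation oracle (`mutex_permutation_p()`) draws matrices
with exactly preserved margins via pair-of-rows trades and provides an
independent empirical p-value for validation.

### Calibration and known conservatism

The exact lower-tail test is conservative in two regimes. With small
expected co-counts the discrete tail cannot attain the nominal level. With
high mutation frequencies, conditioning on margins that are themselves
estimated from the tested matrix shrinks the true null variance of the
co-count below the Poisson-binomial variance (by roughly
`(1-p_a)(1-p_b)/(1-p_a p_b)`), again depressing the attained level. Both
effects fade in the sparse large-cohort regime typical of pooled mutation
panels, so calibration is assessed there: 100 genes by 1,200 samples
(comparable to a pooled multi-cohort mutation set), per-gene frequencies
U(0.04, 0.15), per-sample burden multipliers log-normal (sd 0.15). In that
regime the attained type-I error at alpha 0.05 sits near 0.04. The same
reasoning applies to the permutation oracle: with very few genes (tens),
the per-sample burden parameters overfit the realized column sums and the
analytic null drifts from the exact-margin null, so oracle-agreement
checks use panels of ~100 genes.

## Rank aggregation

Final pairs are ranked under each criterion — FSS, log2 fold change,
Spearman rho (all descending) and mutual-exclusivity adjusted p
(ascending) — with average ranks for ties, normalized to (0, 1]. The Stuart
order-statistics probability that four independent uniforms would have all
order statistics below the observed normalized ranks is evaluated with the
stable recursion `V_k = sum_{i=1..k} (-1)^(i-1) (V_{k-i}/i!) r_{m-k+1}^i`,
`p = m! V_m`. The rank aggregation score is `RAS = -log2(p)`; higher is
more concordant. The raw joint probability is used as the score without
any multiplicity rescaling — RAS orders pairs and is not interpreted as a
calibrated p-value here.

## Drug-response imputation

Per-compound ridge regressions map cell-line expression to dose-response
AUC (lower = more sensitive). Panel preparation mirrors standard
pharmacogenomic practice: haematopoietic/lymphoid lines are excluded,
compounds missing in more than 20% of lines are dropped, and remaining
gaps are K-nearest-neighbour imputed over compound profiles (k = 10,
Euclidean distance on shared observed lines, reduced with a warning when
fewer neighbours exist). Predictors are standardized on the training
lines; lambda is chosen by 10-fold cross-validated MSE over a 13-point
log grid 1e-3..1e3. Clinical predictions mean-impute model genes absent
from the cohort (at least 50% must be present) and are compared between
driver-mutant and wild-type samples: a compound is SL-associated when the
mutant group's estimated AUC is lower (`logFC = log2(mean_mut / mean_wt)
< 0`) with Wilcoxon `p < 0.05`. The logFC is computed on the AUC scale
with arithmetic means; since only its sign gates the flag, the choice of
mean is not load-bearing.

Because predictions are linear functions of expression, any gene that is
differentially expressed between mutant and wild-type samples induces a
small systematic group difference even for compounds whose training AUC
was pure noise; with hundreds of samples the Wilcoxon test can detect it.
The decoy flag rate therefore runs slightly above the nominal 5% (about
half of those also satisfy the sign rule). This is a property of the
estimated-AUC screen itself, shared with the practice it models.

## Mutation-status classifier

For cohorts lacking mutation calls, a transcriptome classifier imputes
driver-mutation status. Genes are selected by `|log2FC| > 1.5` (strict)
and BH `p < 0.05` from a two-sided Wilcoxon test — a deliberately
self-contained selector; moderated-t selection would serve equally and the
contract is the threshold rule, not the engine. A binomial elastic net at
mixing `alpha = 0.9` (mostly lasso, ridge-stabilized; the "penalty 0.9"
convention refers to the mixing weight, since the regularization strength
is cross-validated) is fit with seed-fixed folds. Validation is
leave-one-study-out: gene selection and model fitting are redone inside
each fold, so the held-out study never leaks into the model; accuracy is
reported at probability 0.5 and discrimination as the Mann-Whitney ROC
AUC with ties counted one half.

## Survival validation and the network

For each candidate pair, driver-mutant patients are split at the median of
partner expression (strictly above = "active"; ties go to the inactive
group, so sizes differ by at most one without ties). Under the SL
hypothesis the active group — an intact, highly expressed partner — does
worse: log-rank test plus univariate Cox hazard ratio (Breslow ties),
HR > 1 expected. Screen survivors, the drug catalog and the response flags
are then joined into a tripartite driver-target-drug network in which
every driver-drug "effective" edge is backed by an SL edge and a
drug-target edge.

## The synthetic-data generator

All tests run on synthetic studies with planted ground truth; the
generator's defaults define the package's reference benchmark: 300 tumors,
60 normals, 15 drivers x 100 druggable genes (1,500 candidate pairs), 15
planted pairs. Design choices, fixed once:

* **Expression** is Gaussian on the log2(TPM+1) scale (gene means
  U(2, 8), sd 1). Every downstream test is rank-based, so distributional
  realism beyond monotone signal is not needed; RNA-seq count noise,
  batch effects needing model-based correction, and copy-number variation
  are deliberately out of scope.
* **Differential expression**: planted partners gain `de_shift = 2` log2
  units in driver-mutant tumors — a strong but realistic compensatory
  shift.
* **Co-expression**: planted pairs share a latent factor in normals whose
  loading is set through the exact bivariate-normal identity
  `rho_s = (6/pi) asin(rho_p / 2)` so the *Spearman* correlation hits
  `coexpr_rho = 0.6`.
* **Mutations** follow a per-gene rate x per-sample burden product model
  (background rates U(0.05, 0.25); planted genes U(0.2, 0.3) so the
  exclusivity deficit is detectable at n = 300), with planted pairs
  co-mutated at `excl_factor = 0.1` times the independence product,
  marginals preserved exactly by conditional redrawing.
* **GO**: three-level trees with branching 3 per namespace; planted pairs
  annotated to a shared leaf (partner also to a sibling), decoys to random
  leaves; every fifth edge is `part_of`.
* **CCL panel**: 200 lines on the cohort's expression scale; responsive
  compounds follow `AUC = 0.7 - 0.15 z(target expr) + N(0, 0.05)`, decoys
  are expression-independent noise; 5% missing cells; 10% haematopoietic
  lines.
* **Survival**: exponential event times whose hazard rises with planted
  partner expression in mutant samples (log-hazard slope 0.6 per log2
  unit), uniform censoring over 1-12 years.
* Identifiers are synthetic (`G0001`, `S0001`, ...) to avoid accidental
  biological claims; batch labels alternate over two pseudo-studies so
  leave-one-study-out validation is exercisable.

What passing on these cohorts shows — and does not. The generator plants
exactly the signals the screen tests for, under clean distributions and
harmonized batches. Recovery therefore demonstrates the correctness and
calibration of the statistical machinery, not performance on real tumors,
where effect sizes are smaller, signals are correlated, annotations are
incomplete and cohorts are confounded.

## Numerical choices and degenerate inputs

* Margin fitting tolerance 1e-8 (Newton, at most 200 sweeps); all-zero or
  all-one rows/columns are dropped with a warning before fitting.
* The Poisson-binomial DP truncates at the observed count — the discarded
  upper mass is exactly the complement of the reported tail.
* Stuart recursion is numerically stable for the m <= 20 criteria counts
  used here; p-values of exactly 0 are floored at 1e-300 with a warning
  before the log transform.
* Wilcoxon/Spearman p-values come from `stats`, exact where that is the
  default (small tie-free samples) and asymptotic otherwise.
* Ridge/elastic-net fits use seed-derived fold assignments, making every
  training call reproducible; reruns of the whole pipeline are
  byte-identical.
* Problem sizes in the test-suite (cohorts of 120-300 tumors, panels of
  60-250 lines, 2,000-pair calibration studies) are chosen so the whole
  suite exercises every claim at Monte-Carlo precision appropriate to its
  tolerance.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 42)
sim <- simulate_cohort(cfg)
go <- simulate_go_annotation(cfg, sim$truth)
screen <- run_sl_screen(
  sim$cohort, sim$truth$drivers, sim$truth$druggable,
  go$graph, go$annotation
)
glance(screen)
ranked <- aggregate_ranks(dplyr::filter(screen, pass_all))
autoplot(ranked)
```

## Limitations

* The mutual-exclusivity p-value is conservative outside the sparse
  large-cohort regime (see above); treat borderline calls near the 0.15
  threshold accordingly.
* FSS depends on annotation completeness: unannotated genes can never
  pass procedure 3, which biases the screen toward well-studied genes.
* Drug-response imputation transfers cell-line models to tissue; the
  decoy flag-rate analysis above quantifies the resulting false-positive
  behavior under the generator's assumptions only.
* The pipeline ranks and filters candidates; it does not estimate causal
  effect sizes, and no output should be read as clinical evidence.
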