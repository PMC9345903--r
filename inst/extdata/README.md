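# Packaged toy fixtures

All files are tiny hand-written TSVs used by the examples and tests.

## toy_mutations.maf.tsv
32 records over three samples. Under the default filters
(`min_mutations = 10`, functional classes = frameshift + nonsense,
Silent never functional, duplicate gene-sample records merged):

- `SA` has 12 records (2 Silent, a duplicated DRVA nonsense) -> retained,
  9 functional genes (DRVA, GA1..GA8).
- `SB` has 9 records -> dropped by the burden filter.
- `SC` has 11 records (duplicated DRVB frameshift, 6 missense) -> retained,
  4 functional genes (DRVB, GC1..GC3).

Resulting binary matrix: 13 genes x 2 samples, 9 ones for SA and 4 for SC.

## toy_ccl_auc.tsv / toy_ccl_meta.tsv / toy_ccl_expr.tsv
6 cell lines x 4 compounds. `C6` is haematopoietic/lymphoid and is excluded
first, leaving 5 lines. `cpd3` is then missing in 2/5 = 40% of lines
(> 20%) -> dropped; `cpd4` is missing in 1/5 = 20% -> kept and imputed.
Prepared panel: 5 cell lines x 3 compounds, complete.

## toy_survival_expr.tsv / toy_survival_clinical.tsv
11 driver-mutant patients with partner expression 1..11 (median 6, no
ties across the median). Median split: 5 active (> median), 6 inactive.
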