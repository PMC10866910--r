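# tsescore

Immune-checkpoint inhibitors (ICI) help only a minority of patients with
urothelial cancer, and established biomarkers — PD-L1 combined positivity
score, tumor mutational burden (TMB) — predict response imperfectly. The
**T-cell-to-stroma enrichment (TSE) score** captures, from bulk RNA-seq, the
balance between tumor-infiltrating T cells and the stromal cells and products
that act as a barrier to them. `tsescore` implements that scoring methodology
as a tested, reusable R pipeline, together with the comparator classifiers and
evaluation statistics needed to benchmark it, and a synthetic cohort generator
so that every stage is testable without access to controlled patient data.

## The score

Given a normalized (e.g. variance-stabilized, log-scale) expression matrix
*X* (genes × samples):

1. **Median centering** — every gene is centered on its median across the
   cohort's samples: `x̃_gj = x_gj − median_j(x_gj)`. Scores are therefore
   *cohort-relative enrichments*; adding samples changes them.
2. **Signature scores** — for gene set *S*, the score of sample *j* is the
   unweighted mean `(1/|S|) Σ_{g∈S} x̃_gj`.
3. **Global signatures** — the mean of seven T-cell signature scores gives
   the global T-cell score *T_j*; the mean of five stromal signature scores
   gives the global stromal score *S_j*. (The published membership names ship
   with the package — `published_global_members()`; the gene lists come from
   a user-supplied GMT.)
4. **TSE score** — the arithmetic difference `TSE_j = T_j − S_j`.
5. **Categories** — `TSE ≥ 0.5` positive, `TSE ≤ −0.5` negative, otherwise
   neutral.

The protein-level analog combines immunofluorescence quantities:
`TSE-protein = log10(1+CD4) + log10(1+CD8) − log10(1+FAP%) − log10(1+PDPN%)`,
with CD4/CD8 as cell densities (cells/mm²) and FAP/PDPN as marker-positive
area percentages.

Alongside: TMB high/low (≥ 10 mut/Mb), APOBEC enrichment classes (E ≥ 3
high, 2 ≤ E < 3 medium, E < 2 low, gated by a detection flag), clonal
mutation fraction (variant copy number > 0.75), TCR clonotype size classes
(rare / infrequent / frequent / hyper-frequent) and Hill diversity, and an
evaluation layer: midrank ROC/AUC with DeLong variance, the DeLong test for
correlated AUCs, Fisher's exact test, Wilcoxon/Kruskal–Wallis, BH
adjustment, logistic regression, Kaplan–Meier / log-rank / Cox (Efron ties).

## Worked example

```r
library(tsescore)

co  <- generate_cohort(simulation_config(seed = 1))  # 300 samples, 2000 genes
res <- compute_tse(co$expression, co$signatures)
head(as.data.frame(res), 3)
#>   sample   global_T    global_S        tse category
#> 1   S001  1.0509619 -0.18554029  1.2365022 positive
#> 2   S002 -0.4672728 -0.07800666 -0.3892661  neutral
#> 3   S003  0.8241224 -0.32994591  1.1540683 positive

table(res$category)
#> positive  neutral negative
#>      124       91       85

mean(as.character(res$category) == as.character(co$truth$group))
#> [1] 0.97                      # planted-group recovery

tapply(co$clinical$response, res$category, mean)
#>   positive    neutral   negative
#> 0.61290323 0.15384615 0.04705882   # planted: 0.67 / 0.21 / 0

roc_auc(res$tse, co$clinical$response)
#> ROC: AUC = 0.8242 (DeLong SE 0.0242), 94 positives / 206 negatives

dl <- delong_test(res$tse, co$clinical$tmb, co$clinical$response)
#> DeLong TSE (AUC 0.824) vs TMB (AUC 0.634): p = 7.8e-06
```

Positive-TSE samples respond most and the score discriminates responders far
better than the weakly-informative TMB covariate — the structure the
generator plants. Survival follows suit: the OS hazard ratio for negative vs
positive TSE on this cohort is 5.25 (95% CI 3.59–7.68, `cox_fit`).

The whole chain in one call, with a JSON report:

```r
run_pipeline("report/", sim = list(), seed = 7)
```

Command line (`inst/cli/tse.R`): `simulate`, `score`, `protein`, `tcr`,
`run` subcommands, e.g.

```sh
Rscript inst/cli/tse.R simulate --out cohort --seed 3
Rscript inst/cli/tse.R score --expr cohort/expression.tsv \
    --gmt cohort/signatures.gmt --out tse.tsv
```

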