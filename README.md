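# lineagescore

Quantify how closely each patient's tumor expression profile resembles each
cell type in a reference lineage compendium, and test whether that
resemblance predicts survival.  The package was built for questions like
"do AML tumors that transcriptionally resemble hematopoietic stem cells
fare worse?", where a compendium of sorted immune-lineage profiles (e.g.
ImmGen) is scored against patient microarray or RNA cohorts with clinical
follow-up.  Its intended users are computational biologists running
signature-versus-survival screens.

## The score

For a patient whose genes are ranked by decreasing expression
`g_1 >= ... >= g_n`, and a cell type's weight vector `w` in `[0,1]^n`
(derived from the compendium: `-log10` one-sided normal tail probabilities
of relative-expression z-scores, trimmed at 10 and scaled to `[0,1]`), two
cumulative distributions are compared:

    f(i) = sum_{j<=i} |g_j| w_j       / sum_j |g_j| w_j
    b(i) = sum_{j<=i} |g_j| (1 - w_j) / sum_j |g_j| (1 - w_j)

The pre-LSS is the signed deviation `d(i) = f(i) - b(i)` of largest
magnitude.  It is normalized by the mean `|pre-LSS|` over permutations of
the gene/weight alignment (default 1000), yielding `LSS_up` and `LSS_dn`
from the up- and down-regulated weight subsets.  Two-channel (log-ratio)
cohorts use `LSS = LSS_up - LSS_dn`; one-channel (absolute-intensity)
cohorts use `LSS = LSS_up`.  Per cell type, a univariate Cox
proportional-hazards model then screens the LSS against overall survival,
with Wald tests and Benjamini-Hochberg adjustment across all cell types;
density-based dichotomization, Kaplan-Meier/log-rank comparison and
nonparametric group tests support the downstream clinical analysis.

See `vignettes/lineage-similarity.Rmd` for the full method description and
design decisions.

## Worked example

Everything below is synthetic: the generator plants one cell type whose
mixing coefficient `alpha` drives both expression and hazard, so the right
answer is known.

```r
library(lineagescore)

cfg    <- sim_config(n_genes = 1000, n_celltypes = 10, module_size = 40,
                     n_patients = 150, beta = 1.5, seed = 42)
sim    <- simulate_lineages(cfg)
weights <- build_lineage_weights(sim$expr, sim$replicate_map)
#> Lineage weight set: 1000 genes x 10 cell types (global scaling, trim = 10)

cohort <- simulate_cohort(cfg, sim)
scores <- score_all(weights, cohort$expr, n_perm = 200, seed = 42)
lss    <- lss_wide(scores)
round(lss[1:3, 1:5], 2)
#>        CT01  CT02  CT03  CT04  CT05
#> P0001  0.13 -1.67 -2.02  2.30 -1.72
#> P0002 -2.86 -0.32  1.37  1.79  0.03
#> P0003  2.15  1.64 -2.32 -0.16 -1.84

assoc <- cox_univariate_all(lss, cohort$clinical)
head(assoc[order(assoc$adj_p),
           c("cell_type", "hr", "ci_low", "ci_high", "wald_p", "adj_p")], 3)
#>   cell_type    hr ci_low ci_high   wald_p   adj_p
#> 9      CT09 1.073  1.034    1.11 0.000222 0.00222
#> 4      CT04 0.909  0.819    1.01 0.072549 0.36274
#> 7      CT07 0.917  0.824    1.02 0.113618 0.37873
```

The screen singles out `CT09` — which is exactly the planted cell type
(`cohort$truth$planted_celltype`): each unit of LSS raises the hazard by
7.3% (HR 1.073, adjusted p = 0.0022), and the score tracks the planted
mixing coefficient with Spearman correlation 0.975.  Stratifying patients
at the score's density valley and comparing survival curves agrees:

```r
di <- dichotomize_lss(setNames(lss[, "CT09"], rownames(lss)))
km_logrank(di$labels, cohort$clinical)
#> Log-rank test: chisq = 8.447 on 1 df, p = 0.003657
```

Real data enter through `read_expression_tsv()` (reference and patient
matrices), `collapse_probesets()` / `prepare_patients()`, and
`read_clinical_tsv()`; `run_pipeline()` chains the whole analysis from
files, and `inst/cli/lineagescore.R` exposes the verbs `prep`, `score`,
`associate`, `simulate` and `run` from the shell.

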