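# irlncpair

Prognostic modeling of radioresistant esophageal squamous cell carcinoma
(ESCC) from **immune-related lncRNA pairs** (ir-lncRNA pairs).

Absolute lncRNA expression is noisy and platform-dependent, which makes
single-gene prognostic signatures hard to transfer between cohorts. The
pair-based strategy sidesteps normalization entirely: for two lncRNAs *A* and
*B*, each sample is encoded as

```
indicator(A|B) = 1  if expr(A) > expr(B) in that sample,  else 0
```

a within-sample rank comparison that needs no cross-sample scaling. This
package implements the full analysis around that encoding:

1. **Screen** immune-related lncRNAs: a lncRNA is kept when it correlates
   with at least one immune gene at |rho| >= 0.4 and p <= 1e-4 (Spearman by
   default).
2. **Differential expression** between radioresistant non-responders and
   responders with an empirical-Bayes moderated t-test (per-gene variances
   shrunk toward a method-of-moments prior), calling a gene Up/Down when its
   log2 fold change falls outside mean(logFC) +/- 2 SD(logFC) with raw
   p <= 0.05.
3. **Pair encoding** of the differential ir-lncRNAs, keeping pairs with a
   matching rate strictly inside (0.2, 0.8) and intersecting pair sets across
   the discovery and survival cohorts.
4. **Model construction**: univariate Cox per pair (Efron ties), LASSO-Cox
   narrowing at the cross-validated `lambda.min`, multivariate Cox, and the
   risk score

   ```
   riskscore = sum_i coef_i x indicator_i
   ```

   with median-split stratification into high/low risk groups.
5. **Evaluation and downstream**: Kaplan-Meier / log-rank separation,
   time-dependent ROC (KM-weighted cumulative/dynamic) at 1/2/3 years,
   clinical Cox models, Wilcoxon/Kruskal-Wallis comparisons of risk score
   across clinical factors, reverse extraction of immune genes linked to the
   model lncRNAs, hypergeometric over-representation against GMT gene sets,
   and 2^-ddCt fold changes for qPCR follow-up.

A synthetic-cohort generator (`sim_config()`, `generate_discovery_cohort()`,
`generate_survival_cohort()`, `simulate_cohorts()`) produces cohorts with the
statistical structure the analysis assumes — a 28-sample two-group discovery
cohort (17 non-responders / 11 responders), a 179-sample survival cohort,
planted immune-gene/lncRNA correlations, group effects, and planted
proportional-hazards pair effects — so the whole pipeline is testable offline.
The published result tables ship as fixtures (`table1_fixture()`,
`table2_fixture()`, `table3_fixture()`, `published_risk_model()`).

## Worked example

```r
library(irlncpair)

cfg_sim <- sim_config(n_lncRNAs = 200L, n_linked_lnc = 190L, n_de_lnc = 12L,
                      n_immune_genes = 40L, de_effect = 3, noise_sd = 0.3,
                      rho_true = 0.9, seed = 7L)
paths <- simulate_cohorts(cfg_sim, "cohorts")

cfg <- pipeline_config(discovery_expr = paths[["discovery_expr"]],
                       discovery_labels = paths[["discovery_labels"]],
                       survival_expr = paths[["survival_expr"]],
                       clinical = paths[["clinical"]],
                       immune_list = paths[["immune_list"]],
                       gmt = paths[["gmt"]], seed = 11L)
rep <- run_pipeline(cfg, outdir = "report")
cat(rep$summary, sep = "\n")
```

prints

```
ir-lncRNAs screened: 140
differential ir-lncRNAs: 12 (6 up, 6 down)
pairs built: 66
pairs after ratio filter (0.2, 0.8): 45
pairs after cross-cohort intersection: 45
univariate-significant pairs (p < 0.05): 9
LASSO-selected pairs: 7
pairs in final model: 2
risk groups (cutoff median = 0.8130): 48 high / 131 low
log-rank chi-square 12.719, p = 0.000362
time-ROC AUC at 12/24/36: 0.720/0.680/0.683
reverse-extracted immune genes: 19
differential immune genes: 15
seed: 11
```

Reading the counts: all 12 planted differential ir-lncRNAs are recovered
(C(12,2) = 66 pairs), 45 pairs carry an informative matching rate in both
cohorts, 9 are univariately prognostic at n = 179, and the final multivariate
model keeps 2 pairs — two of the three planted hazard effects; the third
(true log-HR 0.419) is below reliable detection power at this cohort size.
The model separates survival (log-rank p < 0.001, high-risk group does worse)
and discriminates 1/2/3-year overall survival with AUCs near 0.7. `report/`
contains every intermediate table (DE results, pair matrices, Cox fits, risk
assignments, KM/ROC coordinates, enrichment) as TSV/JSON, bit-identical
across reruns at a fixed seed.

The published 3-pair model can be applied directly to any pair matrix:

```r
model <- published_risk_model()
#> risk_model: riskscore = 0.687 x LINC01121|FAM167A-AS1 +
#>   0.863 x ADAMTS9-AS2|MGC12916 + 0.419 x MIR124-2HG|FAM167A-AS1
scores <- risk_score(model, encode_pairs(expr, rownames(expr)))
```

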