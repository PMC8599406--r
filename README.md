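# evodet — determinants of sequence-evolution constraint

`evodet` is an R package for a classic question in molecular evolution:
**which gene-level variables determine how strongly a protein's sequence is
constrained by purifying selection?** It targets the study design used for
single-celled organisms such as the fission yeast *Schizosaccharomyces
pombe*: a table of ~170 genomic, proteomic and functional variables per gene
(expression, gene/protein size, amino-acid composition, GO-slim membership,
chromosome), augmented with protein–protein interaction network
centralities, and modelled against one or two measures of constraint — a
dN-like substitution rate (higher = less constrained) and/or a per-gene
conservation score such as average phyloP (higher = more conserved).

Because the candidate determinants are many and collinear, the package
implements the three complementary approaches used in this field, all
driven by one pipeline:

* **partial least squares regression (PLS)** — single-response NIPALS,
  components chosen to maximize covariance with the response — interpreted
  through **VIP scores** (`vip_scores`), where the mean squared VIP is 1 by
  construction and variables below 1 are conventionally removable;
* **principal-components regression (PCR)** interpreted through a
  **per-variable variance decomposition** (`pcr_variance_decomposition`):
  each variable's squared loading on every retained component, scaled by
  that component's share of response variance, summing exactly to the
  model's training R²;
* **grouped Spearman partial correlations** (`grouped_partial_correlations`):
  each variable vs. constraint given all variables in the *other* variable
  groups as covariates, Bonferroni-adjusted per response panel.

Component counts are selected by seeded 10-fold cross-validation with the
one-standard-error rule (`select_components`); holdout performance is
scored as RMSE and pseudo-R² = 1 − MSE(Y, Ŷ)/variance(Y)
(`score_predictions`); a 500-tree random forest with mtry = p/3
(`fit_rf_baseline`) serves as a nonparametric baseline. Network
centralities (degree, closeness, betweenness, eigenvector; functional and
physical networks) are computed from STRING-format `protein.links` files
thresholded at combined score ≥ 0.400 (`load_string_edges`,
`compute_centrality`).

A fully parameterized synthetic-study generator
(`generate_synthetic_study`) emulates the shape of the real inputs with
planted ground truth — 15 informative variables routed through group-level
latent factors, a degree-linked network effect, two responses of opposite
sign convention, and noise calibrated analytically to a target holdout R²
— so the entire pipeline is testable end to end without any downloads
(`evaluate_recovery` scores how well an analysis recovered the plant).

## Worked example

```r
library(evodet)

# a synthetic constraint study at the default scale:
# 2576 genes, ~170 variables, planted holdout R^2 = 0.5
ds <- generate_synthetic_study(synthetic_spec(), seed = 1)
paths <- write_synthetic_study(ds, "study/")   # TSV + STRING-format links

cfg <- analysis_config(table = ds$table,
                       functional = paths[["functional"]],
                       physical = paths[["physical"]],
                       strip_prefix = "4896.")
report <- run_analysis(cfg)
print(report)
#> analysis_report: 2576 genes, 168 variables modelled
#>   dN: PLS 46.5% / PCR 45.7% / RF 44.4% of holdout variance explained (A = 2 / 5)
#>   phyloP: PLS 19.3% / PCR 18.2% / RF 18.2% of holdout variance explained (A = 1 / 3)

head(importance_table(report), 3)
#>   variable      group      vip pct_variance
#> 1  expr_01 expression 3.062175     1.324384
#> 2  expr_02 expression 3.059349     1.351916
#> 3  expr_03 expression 3.009586     1.313584

evaluate_recovery(ds, report)[c("recall_at_k", "sign_flip")]
#> $recall_at_k
#> [1] 1
#> $sign_flip
#> [1] 1
```

Reading the output: the latent models explain ~45–47% of holdout variance
in the dN-like response (the planted ceiling is 50%; cross-validated
component selection trades a little fit for stability), and less for the
noisier conservation-score response — the familiar pattern that dN is the
better-behaved target. All 15 planted variables score VIP > 1
(`recall_at_k = 1`), and every planted effect's partial correlation flips
sign between the two responses (`sign_flip = 1`), as it must when one
response counts substitutions and the other counts conservation.

## Package layout

* `R/feature-table.R` — feature-table container, TSV I/O, one-hot encoding,
  amino-acid proportion scaling, centring/scaling, iterative k-NN
  imputation, train/test split
* `R/network.R` — STRING-format parsing, interaction networks, centralities
* `R/latent-models.R` — PLS, PCR, CV component selection, VIP, variance
  decomposition, scoring
* `R/association.R` — Spearman partial correlations with grouped covariates
* `R/rf-baseline.R`, `R/pipeline.R` — forest baseline and the orchestrated
  analysis with seeded determinism
* `R/synthetic.R` — synthetic-study generator and recovery scoring
* `vignettes/constraint-determinants.Rmd` — the model, its assumptions, and
  every numerical design choice
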