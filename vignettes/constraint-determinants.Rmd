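---
title: "Modelling the determinants of sequence-evolution constraint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the determinants of sequence-evolution constraint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evodet)
```

## The scientific question

Which gene-level properties determine how strongly purifying selection
constrains a protein's sequence? Candidate determinants are numerous —
expression level (the expression–rate anticorrelation is the most robust
pattern in molecular evolution), position in the protein–protein
interaction network, amino-acid composition, subcellular location, gene
and protein size, functional importance — and they are heavily
intercorrelated, so the question is intrinsically a high-dimensional
regression problem with collinear predictors.

`evodet` implements the full analysis pipeline for this question: a
gene-by-variable feature table (~170 variables in named groups) is
augmented with network centralities from STRING-style interaction data and
modelled against one or two constraint responses. Two response conventions
are supported simultaneously: a dN-like rate (larger = less constrained)
and a conservation score such as per-gene average phyloP (larger = more
conserved). Because the conventions are opposite, a genuine determinant is
expected to show partial correlations of opposite sign with the two
responses.

## Models and importance measures

**Latent-variable regressions.** Both workhorse models regress a centred
response on a small number of orthogonal components of the standardized
predictor matrix $X$:

* *PCR* uses the leading principal axes of $X$ (eigenvectors of its
  covariance, descending eigenvalue order) and regresses $y$ on the
  component scores.
* *PLS* (single-response NIPALS, exact for one $y$) chooses each unit-norm
  weight vector to maximize the covariance of its score with the response,
  deflating $X$ by the loading projection after each round. With $A$ equal
  to the predictor rank both models reproduce ordinary least squares; the
  interest is in small $A$, where they are stable under collinearity.

**Component selection.** The number of components is chosen by 10-fold
cross-validation with the one-standard-error rule: the smallest $A$ whose
RMSEP is within one standard error of the minimum. $A = 0$ (intercept
only) is a candidate, so a pure-noise response is most often assigned no
components at all. Folds are contiguous blocks of a seeded permutation,
making selection reproducible.

**Variable importance.** Two complementary decompositions are reported:

* *VIP scores* (PLS): $\mathrm{VIP}_j = \sqrt{p \sum_a SS_a
  (w_{ja}/\lVert w_a \rVert)^2 / \sum_a SS_a}$, where $SS_a$ is component
  $a$'s share of training response variance. The mean of $\mathrm{VIP}^2$
  over variables is exactly 1, giving the conventional "VIP < 1 is
  removable" reading; this identity is asserted in the test suite for
  every fitted model.
* *Per-variable percent variance* (PCR): $c_j = \sum_a p_{ja}^2 SS_a$,
  which by orthonormality of the loadings sums exactly to the model's
  training $R^2$ — also asserted as an invariant.

**Scoring.** Holdout performance uses RMSE and the pseudo-$R^2$
$1 - \mathrm{MSE}(Y,\hat Y)/\mathrm{variance}(Y)$ with the population
(1/n) variance, so predicting the training mean scores exactly 0 and
worse-than-mean predictors go negative. The default holdout is 30% of the
genes carrying the primary response; the same held-out genes (intersected
with availability) score the second response, so the two panels are
comparable.

**Partial correlations.** Each variable's Spearman partial correlation
with each response is computed given all variables in the *other* variable
groups as covariates — adjusting for between-group confounding while not
letting a group's internal redundancy cancel its signal. Ranks use average
ties; residual projection on ranked covariates is equivalent to the
inverse-covariance definition for a single pair. p-values come from the
t-approximation on $n - 2 - k$ degrees of freedom and are Bonferroni
adjusted within each response panel (family = number of variables tested).
Under a global null the unadjusted test holds its size — the suite checks
the rejection rate at $\alpha = 0.05$ over 1000 replicates against the
exact binomial 99% interval.

**Random-forest baseline.** A 500-tree forest with mtry = p/3 (delegated
to `ranger`, single-threaded and seed-deterministic) provides a
nonparametric comparison. Out-of-bag predictions give a training-side
pseudo-$R^2$ with the same formula. On a purely linear signal the forest
holds no advantage over the latent models; with a planted non-linear term
(squared expression, behind the generator's `nonlinear` flag) it does —
the pipeline test checks this direction, not magnitudes.

## Network centralities

Two graphs are built from STRING-format edge lists (`protein1 protein2
combined_score`, integer scores 0–999): one functional (all evidence), one
physical. Edges with score/1000 ≥ 0.400 are kept (inclusive, the
conventional STRING confidence cutoff); graphs are simple, undirected and
unweighted — degree is a neighbour count, which matches the unweighted
reading of the other metrics. Four centralities per network are appended
as a `network_centrality` variable group:

* degree (unnormalized neighbour count);
* closeness $(r-1)/\sum_u d(v,u)$ within the node's connected component
  ($r$ = component size; isolated nodes score 0) — the whole-graph
  definition is undefined for unreachable nodes, and the harmonic variant
  was rejected as a different statistic;
* betweenness over unordered pairs within the component, endpoints
  excluded, shortest paths counted with multiplicity;
* eigenvector centrality: the principal eigenvector of the whole graph's
  adjacency matrix, non-negative, scaled to maximum 1. It is computed by
  power iteration on $A + I$: the spectral shift leaves eigenvectors
  unchanged but guarantees convergence on bipartite graphs, whose extreme
  eigenvalues are otherwise tied in magnitude. Deterministic all-ones
  start, sup-norm tolerance 1e-10, at most 1000 iterations.

Genes absent from a network receive centrality 0 with a presence flag of
`FALSE` rather than a missing value: absence of interaction evidence in a
well-studied interactome is itself informative, and imputing a dominant
variable group would manufacture spurious centrality. The flags are kept
so users can audit or re-do this choice.

All four metrics are validated against brute-force oracles (all-pairs BFS
with path counting; dense eigendecomposition) on 100 random small graphs
per run of the suite.

## Preprocessing

* **One-hot encoding** expands categorical and membership columns
  (chromosome, GO slims) into named 0/1 variables, keeping every level —
  the latent models tolerate the collinearity and each level keeps its own
  interpretable column.
* **Amino-acid composition** is rescaled to per-gene proportions (row sum
  1 within 1e-12), separating residue usage from protein length.
* **Centring and scaling** statistics are computed on the training genes
  only and applied to all genes, preventing leakage into holdout scores.
  Variables with zero sample variance on the training side (tolerance
  1e-12 on the variance) are dropped and recorded.
* **Imputation** fills missing entries of continuous variables by
  iterative chained k-NN regression (k = 10, distance-weighted, predictors
  standardized, columns visited in order of increasing missingness, up to
  10 rounds with early stop below 1e-4 relative change). GO-slim and
  amino-acid variables are excluded — both as targets and as inputs — as
  are the responses; this mirrors the practice of imputing the bulky
  sparse blocks never, and keeps the response out of its own predictors.
  A k-NN regressor was preferred over a tree ensemble per column because
  it is exactly deterministic and orders of magnitude cheaper at this
  scale; the accepted seed is recorded for provenance.
* The train/test split is drawn once on the primary response's gene
  universe (test = round(0.30 n), seeded) and reused for every response.

Expression variables are modelled untransformed by default; a config flag
(`log_expression`) applies log2(x+1) first, for users whose expression
columns are raw intensities.

## The synthetic study generator

Real inputs for this analysis are large curated database extracts, so the
package ships a generator that reproduces their *statistical shape* with
known ground truth: ~2576 genes; 12 expression and 15 size variables; a
20-column Dirichlet amino-acid block (rows sum to 1); 110 sparse binary GO
columns; a 3-level chromosome column; preferential-attachment interaction
networks over 1500 genes with edge scores uniform on 150–999 (so the
0.400 threshold genuinely filters); physical edges a subset of functional
ones; 5% MCAR missingness on the expression/size columns; and two
responses of opposite sign convention with correlation ≈ −0.6.

Every planted effect flows through a group-specific latent: expression and
size factors (informative loadings scaled so each variable's implied
marginal coefficient equals its planted value, |β| between 0.15 and 0.40,
expression negative per the expression–rate anticorrelation), a
composition-tilt axis for the amino-acid block, a location latent for the
GO block, and a log(1+degree) coupling to the thresholded functional
network. Since the latents are independent and unit-variance, the
population signal variance is an exact sum of squares, and the noise SD
follows analytically from the target holdout $R^2$ (default 0.5) — no
trial-and-error calibration, and the realized $R^2$ of any draw sits
within ±0.02 of the target.

Routing effects through latents is deliberate: a latent-variable
regression can only recover signal that lives in identifiable directions
of the predictor matrix. The background loadings (weak alternating tilts
on the other residues, load-1.0 propensities on the other GO terms)
exist to make each latent recoverable from its block as a whole; with
them, the asymptotically attainable holdout $R^2$ is within about 0.02 of
the planted target, which is what makes the target a testable contract
for the pipeline. What the generator does *not* attempt: matching real
S. pombe marginal distributions, GO term hierarchy, realistic network
clustering, non-MCAR missingness, or measurement-error structure — so
passing recovery tests demonstrates correctness of the machinery, not
performance on real data.

Problem sizes in the test suite are chosen to keep the full run modest on
a single CPU: the parameter-recovery check runs the complete pipeline at
the default 2576-gene scale for ten seeds (without the forest stage, which
does not enter any recovery quantity), while structural unit tests use
toy studies of 150–900 genes. Holdout variance explained estimated on 773
test genes carries a sampling standard deviation of about 0.026, so the
recovery contract is evaluated on the across-seed mean, whose standard
error is below 0.01; per-seed checks cover importance recall and
partial-correlation sign recovery, which are far above their noise floors.

## Numerical and design choices

* NIPALS deflation stops early (with truncation) if the residual
  covariance vanishes; components carry a deterministic sign convention
  (largest-|loading| entry positive), and sign flips are a tested
  invariance of predictions, VIP and the variance decomposition.
* `max_A` defaults to min(n − fold size − 1, p, 100), bounding CV cost
  with ~170 predictors.
* The STRING threshold comparison is inclusive (≥), applied as
  score/1000 ≥ cutoff − 1e-12 to avoid float artifacts on integer scores.
* Complete-case analysis per partial-correlation test; when the predictor
  matrix is complete (the pipeline's situation after imputation), one QR
  factorization per variable group serves all its members — an exact
  algebraic shortcut, tested against the per-variable path.
* Bonferroni families are per response panel, matching the convention of
  reporting the two constraint metrics as separate panels.
* The holdout fraction is 0.30 by default and configurable; the
  alternative 20% convention some comparisons use is a config change, not
  a code change.
* All randomness (split, CV folds, imputation provenance, forest, and
  every generator draw) descends from named integer seeds; identical
  configuration yields byte-identical reports and synthetic studies.

## Known limitations

* Closeness and betweenness are computed on the unweighted thresholded
  graph; weighted variants using STRING scores are out of scope.
* The imputer assumes missingness ignorable given the observed continuous
  block (MCAR/MAR); informative missingness would bias it.
* The t-approximation for rank partial correlations is asymptotic; at
  very small n with many covariates its size drifts.
* Multi-response PLS, kernel/sparse variants, and randomization-based
  component selection are deliberately not implemented.
* FDR adjustment is available conceptually but the headline path is
  Bonferroni only, matching the reporting convention the package follows.
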