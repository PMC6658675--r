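# cascadeWx

Survival-aware gene selection for bulk transcriptome cohorts, for anyone
who needs a *prognostic* gene ranking — not just a differentially expressed
one — from a samples × genes expression matrix plus per-patient follow-up
time and a right-censoring flag.

## The method

**Cascaded selection.** Patients are stratified into high- and low-risk
groups at successive survival cutoffs — 3 vs 3, then 2 vs 4, then 1 vs 5
years. At each step a patient is HIGH if death was observed within the
death cutoff, LOW if follow-up demonstrably exceeds the survive cutoff, and
excluded otherwise (censored before the horizon, or deceased between the
cutoffs). A two-output softmax classifier is trained on the labeled
samples, and gene *j* is scored by its discriminating power

    DP_j = | w_HIGH,j · mean(x_j | HIGH)  −  w_LOW,j · mean(x_j | LOW) |

combining the trained class weights with the class means of the normalized
inputs. After each non-final step the top quarter of genes survives
(1600 → 400 → 100); the final output is a total ranking of *all* input
genes, with survivors first. Any per-gene scorer plugs into the cascade —
a two-class Fisher score ships as the built-in alternative.

**Evaluation stack.** Selected genes are assessed with a Faraggi–Simon
proportional-hazards network — a one-hidden-layer feed-forward log-hazard
f(X, θ) fitted full-batch with Adam on the negative log partial likelihood

    −log L(θ) = Σ_{i: C_i=0} [ log Σ_{j: S_j ≥ S_i} exp f(X_j) − f(X_i) ]

— plus Harrell's c-index, the two-group log-rank test, Kaplan–Meier
curves, and stratified five-fold cross-validation whose per-fold rankings
are merged by gene ranking points, Point_j = Σ_k (N − R_jk).

Preprocessing follows the standard RNA-seq recipe: drop zero-variance
genes, log2(x + 1), per-gene min–max normalization.

## Worked example

Everything below runs in a few seconds on a laptop; the synthetic cohort
has 400 patients, 300 genes of which the first 10 are causal with
|β| = 2 on the normalized scale, and ~50% right censoring.

```r
library(cascadeWx)

sim <- generateCohort(syntheticConfig(nSamples = 400, nGenes = 300,
                                      nCausal = 10, causalBeta = 2,
                                      seed = 42))
sim$cohort
#> SurvivalCohort: 300 genes x 400 samples (199 events, 201 censored, 50.2% censored)
#>   follow-up: 5-3262 days (median 815)

res <- cwxCrossValidatedRanking(sim$cohort, cascadeConfig(), k = 5,
                                seed = 42)
head(res$merged, 5)
#>   rank  gene_id points
#> 1    1 gene0002   1483
#> 2    2 gene0008   1481
#> 3    3 gene0003   1477
#> 4    4 gene0001   1435
#> 5    5 gene0173   1395

sum(sim$truth$gene_id %in% res$merged$gene_id[1:20])
#> [1] 7

ev <- evaluateTopK(res$cohortPreprocessed, res$foldRankings, res$folds,
                   ks = c(5, 10), seed = 42)
ev$summary
#>    k mean_c_index
#> 1  5    0.6233694
#> 2 10    0.6369847
```

Four of the five top-ranked genes are planted causal genes, 7 of 10 sit in
the merged top 20, and the cross-validated test c-index of the top-10
signature is ≈ 0.64 (0.5 = chance): the selector finds prognostic genes and
the survival model turns them into risk scores that generalise across
folds.

File-based workflows (`runSimulateWorkflow`, `runRankWorkflow`,
`runEvaluateWorkflow`) read/write firehose-style TSV tables and write a
JSON manifest per run; `inst/scripts/cascadex` wraps them as a
`simulate | rank | evaluate` command line. A fixed master seed makes every
output byte-identical across reruns.

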