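---
title: "Cascaded survival-aware gene selection: models and methods"
author: "cascadeWx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cascaded survival-aware gene selection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cascadeWx)
```

# The problem

Bulk transcriptome cohorts with clinical follow-up pose a hard selection
problem: tens of thousands of genes, a few hundred patients, and an outcome
(overall survival) that is right-censored for roughly half of them. Generic
feature selectors ignore censoring; Cox-based selectors handle it but work
one gene at a time or need heavy regularisation. `cascadeWx` implements a
cascaded, classification-driven selector that converts survival into a
sequence of increasingly extreme risk-group contrasts, plus the standard
survival machinery needed to evaluate any gene ranking.

# Risk-group construction

Each cascade step is parameterised by a cutoff pair $(t_d, t_s)$ in years,
$t_d \le t_s$. A patient with follow-up $S_i$ (days) and censoring flag
$C_i$ is labeled

* **HIGH** if $C_i = 0$ and $S_i \le t_d$ — death observed within $t_d$;
* **LOW** if $S_i > t_s$ — demonstrably alive beyond $t_s$, censored or not;
* **EXCLUDED** otherwise — censored too early to know the outcome at the
  horizon, or deceased inside the $(t_d, t_s]$ gap.

Two boundary conventions are deliberate: death exactly *at* $t_d$ counts as
"within", and surviving exactly *to* $t_s$ does not count as "beyond". A
censored patient whose follow-up already exceeds $t_s$ carries a known
outcome at that horizon, so it is kept as LOW rather than discarded; only
censoring before the horizon destroys information. Deaths between the two
cutoffs of a widened pair are excluded by symmetry with the
censored-exclusion rule. The default schedule is (3, 3), (2, 4), (1, 5)
years: each later step contrasts more extreme phenotypes on fewer patients.

# The softmax scorer and discriminating power

At each step a two-output softmax classifier (no hidden layer) is trained on
the labeled samples, inputs being the per-gene min–max-normalized
$\log_2(x+1)$ expression. Gene $j$ is then scored by its discriminating
power

$$\mathrm{DP}_j = \left| w^{\mathrm{HIGH}}_j \, \bar{x}_{j,\mathrm{HIGH}}
  - w^{\mathrm{LOW}}_j \, \bar{x}_{j,\mathrm{LOW}} \right|,$$

where $w^{c}_j$ is the trained input-to-output weight for class $c$ and
$\bar{x}_{j,c}$ the class mean of the classifier's own inputs. Bias terms
are trained but do not enter DP. A two-class Fisher score
($\sum_c n_c(\mu_{jc}-\mu_j)^2 / \sum_c \sum_{i \in c}(x_{ij}-\mu_{jc})^2$)
is provided behind the same scorer contract (`getScorer("fisher")`), so the
cascade can be driven by any per-gene scorer.

**Training protocol.** Full-batch Adam on the cross-entropy, at most 100
epochs, early stopping after 20 epochs without validation improvement,
weights restored from the best epoch. The learning rate is chosen from
$\{10^{-1}, 10^{-2}, 10^{-3}, 10^{-4}\}$ by the best cross-entropy on a
stratified 20% validation holdout. The split and the initial weights are
drawn once per seed and shared across candidate rates, so rate selection
compares like with like and the whole fit is reproducible bit for bit.

# The cascade

Let $d_s$ be the number of genes entering step $s$. After every step except
the last, the top $\lfloor 0.25\, d_s \rfloor$ genes (at least one) survive;
the final step scores its input genes without a further cut. With 1,600
input genes the step sizes are therefore 1600 → 400 → 100, and 100 genes
carry provenance 0 ("survived to the final step"). The output is a total
ranking of *all* input genes: final-step survivors first, ordered by their
final-step score, then each eliminated block, later eliminations above
earlier ones, ordered by their elimination-step scores. This totality is
what makes rank merging across folds well defined. Ties are always broken
by ascending gene identifier. Each step retrains the scorer from scratch
with a step-specific seed derived from the master seed.

The alternative reading — quartering *after* the final step too, i.e.
ranking only 25 survivors of a 1,600-gene run — is recoverable from the
provenance column; the implemented reading keeps the final step's full
score-ordered input, which is what the quarter-wise bookkeeping tests pin
down.

# The survival evaluation model

Selected genes are assessed with a Faraggi–Simon nonlinear proportional
hazards model: a feed-forward network $f(X,\theta)$ with one hidden layer
(default 8 sigmoid units) and a scalar log-hazard output, fitted by
minimising the negative log partial likelihood

$$-\log L(\theta) = \sum_{i : C_i = 0} \left[
  \log \!\! \sum_{j : S_j \ge S_i} \!\! e^{f(X_j,\theta)} - f(X_i,\theta)
  \right].$$

Risk sets use $S_j \ge S_i$ exactly — Breslow-style handling of tied times.
The sum is stabilised by max-subtraction; the gradient is computed
analytically via group-wise cumulative sums over the time-sorted samples,
so a fit costs $O(n \log n)$ per epoch beyond the matrix products.
"Single hidden layer" rather than a zero-hidden-layer linear model is the
deliberate architecture choice: the linear case is exactly Cox regression
and is used as the verification oracle (the partial likelihood of a linear
$f = X\beta$ must match an independent Breslow implementation), while the
hidden layer provides the nonlinearity the model family is named for.

Training mirrors the classifier protocol — full-batch Adam, 100 epochs,
patience 20, shared split/init across the rate grid — except that the
monitored metric is the *validation concordance index* (maximised), which
is also the rate-selection criterion. Early stopping on c-index rather than
loss matches that selection rule; with a degenerate validation split the
fit falls back to monitoring training loss.

# Evaluation machinery

* **Harrell's c-index** is implemented by direct comparable-pair
  enumeration (vectorised): pairs where the shorter follow-up ended in an
  observed event and the times differ; risk ties earn half credit. The
  implementation is checked against exhaustive enumeration and against
  `survival::concordance`.
* **Log-rank test and Kaplan–Meier** wrap `survival::survdiff` and
  `survival::survfit`; the log-rank p-value is $\chi^2_1$.
* **Stratified k-fold CV** stratifies on the censoring indicator (the only
  binary clinical attribute in scope), dealing shuffled samples round-robin
  so per-fold event counts are balanced to within one.
* **Rank merging**: gene $j$ collects $\sum_k (N - R_{jk})$ points over the
  $k$ fold rankings ($N$ genes, $R_{jk}$ its rank in fold $k$); the merged
  list sorts by descending points, ties by gene id.
* **Top-k curves** (`evaluateTopK`) follow the nested protocol: the
  selector is trained per CV training split only, the survival model is
  refitted per fold and per signature size, and the held-out fold provides
  the test c-index. When a log-rank readout is requested, test samples are
  dichotomised at the median predicted risk — the conventional
  Kaplan–Meier split; the merged list is for reporting, never for
  evaluation on folds it saw.

Min–max normalization is fitted on the whole cohort before splitting by
default, matching the published pipeline's preprocessing-then-split order;
`normalizeWithinTrain = TRUE` refits ranges per training split for
leakage-sensitive use.

# The synthetic cohort generator

`generateCohort()` emulates the data regime the selector targets:

* **Expression**: per-gene log-normal values, `meanlog` uniform on
  $[\log 5, \log 2000]$ and `sdlog` on $[0.4, 1.2]$ — non-negative,
  heavily right-skewed, spanning the orders of magnitude typical of
  RSEM-normalized counts.
* **Survival**: the first `nCausal` genes act through a proportional
  hazards model, $T_i \sim \mathrm{Exp}\{h_0 \exp(\sum_g \beta_g
  (z_{ig} - \bar z_g))\}$, where $z$ is the cohort min–max-normalized
  $\log_2(x+1)$ value — the same scale the pipeline operates on, so
  $\beta$ is unit-comparable across genes. Causal signs alternate.
  The baseline hazard defaults to 0.15 events/year (median survival
  ≈ 4.6 years), chosen so that a cohort calibrated to ~50% censoring
  retains patients beyond five years and all three cascade cutoffs are
  trainable, with 3-year event counts resembling a real lung-cancer
  cohort.
* **Censoring**: each sample draws an independent uniform censoring time on
  $(0, f_{\max})$; $f_{\max}$ is found by bisection (deterministic, since
  the underlying uniforms are fixed) so the realised censoring fraction
  hits `censorRateTarget`. Default target 0.5, within the 36–86% range of
  real cohorts.

What the generator does *not* model: negative-binomial count noise,
batch effects, and correlated gene blocks/pathways. Passing tests on this
generator therefore demonstrate correctness of the machinery and
recoverability of independent planted signals, not performance under
co-expression or technical artefacts.

# Numerical and reproducibility choices

* Quarter sizes use `floor`, minimum one gene.
* Zero-variance filtering uses exact equality — count data make exact ties
  meaningful, and "no variance" is taken literally.
* All randomised stages (fold split, per-step classifier init, simulation,
  per-fold/per-k survival fits) draw seeds via `deriveSeed(master, stage)`,
  a 31-bit polynomial hash, so a single master seed reproduces every file
  byte-identically.
* Non-finite losses during training mark a learning rate as diverged; if
  every rate diverges the fit is a hard error naming the grid.
* Times are days internally; cutoffs are specified in years and converted
  at 365.25 days/year.

# Problem sizes used in the shipped checks

The package's own verification uses desk-scale cohorts chosen to exercise
every code path: oracle comparisons at $n \le 50$, cascade bookkeeping at
1,600 genes, signal-recovery studies at $n = 400$, $d = 1000$, 20 causal
genes with $|\beta| = 1$ and ~50% censoring over five seeds, and an
end-to-end determinism run at $n = 120$, $d = 60$. These sizes are the
package's choice of a thorough-but-quick test design; all of them
regenerate their data in code at run time.

# Known limitations

* The DP scorer inherits the variance of its trained softmax weights. With
  ~200 labeled samples and $10^3$ or more genes, the validation-loss-based
  learning-rate selection on a small holdout favours conservatively trained
  models, and the recovery of *weak* planted signals (per-gene hazard
  effects near the detection floor) is partial — the shipped recovery study
  reports the measured counts. Deterministic filters such as the built-in
  Fisher score are competitive in that regime and plug into the same
  cascade.
* Only right censoring is modelled; no competing risks, interval censoring,
  or time-varying covariates.
* The log-rank dichotomisation at the median predicted risk is a
  convention, not an optimised split.
* Efron's tie correction is not implemented; risk sets are Breslow
  throughout, which is exact when times are distinct.
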