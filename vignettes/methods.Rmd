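---
title: "Testing for differential cis-genetic regulation with drabr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing for differential cis-genetic regulation with drabr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Differential expression analysis asks whether a gene's transcript abundance
differs between two biological contexts. drabr asks a different question:
does the *mapping* from local genetic variation to expression differ? Two
tissues can express a gene at identical levels while relying on entirely
different cis-eQTLs, and conversely. Because regulatory architecture can
differ in many ways at once — different variants, different effect sizes,
different degrees of polygenicity — no single summary statistic captures it,
and drabr instead compares *predictive models* of expression between the
contexts.

## The model and the two tests

For a gene $g$, three index sets are drawn from the cohort: training sets
$D_A$ and $D_B$ with $|D_A| = |D_B|$ (so neither fitted model is
systematically noisier) and a test set $D_T$ disjoint from both. In each
context a Gaussian elastic net

$$\min_{\beta_0, \beta} \; \frac{1}{2N}\sum_{i=1}^N (y_i - \beta_0 - x_i^\top\beta)^2
  + \lambda\Big(\frac{1-\alpha}{2}\lVert\beta\rVert_2^2 + \alpha\lVert\beta\rVert_1\Big)$$

is fit to predict covariate-adjusted, standardized expression from the
standardized dosages of the cis-SNPs (all variants within 500 kb of the
gene's transcribed region, by default). The mixing weight is fixed at
$\alpha = 0.5$, which tends to bring groups of correlated cis-SNPs in and
out of the model together; $\lambda$ is chosen by 5-fold cross-validation
with the one-standard-error rule, favouring sparse models, which are known
to predict expression well.

On the test set, let $\Delta\hat L_i$ be the difference in squared
prediction errors between the two fitted models for individual $i$, and
$\Delta\bar L$ its mean. Two tests are computed:

* **Conditional paired-t test.** $T = \Delta\bar L / \sqrt{\widehat{\mathrm{Var}}(\Delta\bar L)}$
  with the usual variance estimate
  $\sum_i (\Delta\hat L_i - \Delta\bar L)^2 / (|D_T|(|D_T|-1))$. This tests
  whether the two *specific fitted models* predict equally well. It ignores
  the fact that refitting on a new training sample would give different
  models — with feature selection and CV-tuned penalties this training
  variability is large, and the conditional test is badly anticonservative
  as a test about the contexts themselves.

* **Bootstrap model-comparison test.** $K$ times, both training sets are
  independently resampled with replacement at their original sizes and both
  models are retrained from scratch — including the $\lambda$ grid, the CV
  folds, and the one-SE selection, because tuning uncertainty is part of
  what must be captured. Each replicate yields a mean loss difference
  $\Delta\bar L^{*(k)}$ on the fixed test set. By a law-of-total-variance
  decomposition, the variance of $\Delta\bar L$ under both test-set and
  training-set sampling is estimated as the conditional variance above plus
  the bootstrap variance $\frac{1}{K}\sum_k (\Delta\bar L^{*(k)} - \overline{\Delta\bar L^*})^2$
  (divisor $K$, exactly as defined). The statistic
  $$T_{\mathrm{boot}} = \frac{\Delta\bar L}
    {\sqrt{\widehat{\mathrm{Var}}(\Delta\bar L) + \frac{1}{K}\sum_k (\Delta\bar L^{*(k)} - \overline{\Delta\bar L^*})^2}}$$
  is referred two-sided to a Student $t$ distribution with $|D_T| - 1$
  degrees of freedom. Because the added variance term is non-negative, the
  bootstrap p-value can never undercut the conditional one — a structural
  guarantee the test suite asserts for every gene in every run.

Rejection means the population-level regulatory models differ with respect
to squared-error predictive performance. Two caveats follow from the
definition: models that predict equally well are indistinguishable even if
their functional forms differ (e.g. two models distributing one causal
signal differently across a preserved LD block), and the test provides no
effect size for "how differently" a gene is regulated.

## Tunable parameters

| parameter | default | meaning / why |
|---|---|---|
| `window_bp` | 500000 | cis window, bp beyond TSS and TES; standard cis-eQTL convention |
| `alpha_mix` | 0.5 | elastic-net mixing; equal L1/L2 keeps correlated eQTL groups together |
| `n_folds` | 5 | CV folds for penalty selection |
| `boot_k` (`K`) | 50 | bootstrap replicates; calibration is adequate by ~20 and unstable below ~10 |
| `maf_min` | 0.01 | minor-allele-frequency filter |
| `hwe_p_min` | 1e-6 | Hardy-Weinberg exact mid-p filter |
| `split_mode` / `min_test_fraction` | auto / 0.25 | largest equal training sets, remainder to the test set |
| `overlap_fraction` | 0 | allowed sharing between $D_A$ and $D_B$; overlap does not bias the test because $D_T$ stays disjoint |
| `test_context` | *(required)* | which context's measured expression forms the test response |

`test_context` deliberately has no default. Power depends on how much
expression variation the test context carries: a context whose expression is
nearly constant for a gene gives the comparison nothing to work with. When
the two contexts differ in imputability, testing on the better-imputed one
yields smaller p-values. Making the choice explicit forces the analyst to
own it.

The minimum test fraction of 0.25 is a compromise: the conditional variance
term shrinks with $|D_T|$ while the training-variance term shrinks with
$|D_A|$; reserving about a quarter of the cohort keeps both terms of the
denominator informative at the cohort sizes (a few hundred donors) this
method is designed for.

## Numerical choices

* **Solver.** glmnet computes the $\lambda$ path and the CV curves over a
  pinned grid of 100 log-spaced values from $\lambda_{\max}$ (the smallest
  $\lambda$ with $\beta = 0$) down to $10^{-3}\lambda_{\max}$ ($10^{-2}$
  when $p \ge N$). glmnet internally standardizes the response, which
  rescales its ridge (not lasso) term by $\mathrm{sd}(y)$ relative to the
  objective as written above; the difference is tiny but measurable, so the
  final coefficients of every returned model are polished by an exact cyclic
  coordinate descent on the stated objective (convergence: max coefficient
  change below 1e-9), warm-started from glmnet. CV-curve fits are left
  unpolished — only their errors relative to one another matter for
  selecting $\lambda$.
* **Solver tolerance.** The default glmnet threshold is 1e-7. The
  simulation-heavy acceptance tests pass 1e-5, which changes objective
  values by about 1e-5 — far below cross-validation noise — and roughly
  quadruples throughput.
* **Standardization** uses the sample variance (denominator $n - 1$) within
  each split separately; no statistic ever crosses a split boundary, which
  the tests verify by perturbing one split and observing the others'
  outputs unchanged.
* **Monomorphic pruning before standardization.** A variant constant within
  *any* split is removed from *all* splits, because a zero-variance column
  cannot be standardized and because both models must see identical feature
  sets for their comparison to be meaningful.
* **Degenerate cases.** A constant response (or one with no cis-SNPs) yields
  an intercept-only model rather than an error, including inside bootstrap
  replicates, so $K$ is always preserved. A gene with constant expression
  in any split, or no polymorphic cis-SNPs, is reported `untestable` with
  empty p-values and is excluded from the Bonferroni count. Zero-variance
  loss differences give p = 1 (zero mean) or p = 0 (nonzero mean) with a
  `degenerate` flag.
* **HWE mid-p.** The exact Levene–Haldane distribution of the heterozygote
  count is computed by the standard outward recurrence from the mode; the
  two-sided p-value sums probabilities of tables no more probable than the
  observed one (with 1e-10 relative slack so structural ties are included
  identically under any evaluation order) and subtracts half the observed
  table's probability.
* **Random streams.** One master seed is hashed together with the gene id
  and the replicate index to derive every fold assignment and resample, so
  per-gene results are independent of gene-list order and of each other —
  reordering the gene list permutes the output rows without changing any
  number.

## What the simulator emulates — and what it does not

`make_scenario()` generates dosages as Binomial(2, MAF) draws (MAF uniform
on 0.05–0.5 by default, optional first-order LD via haplotype copying),
sparse per-context effect vectors rescaled on the realized genotypes so the
genetic variance is exactly the configured heritability (default
$h^2 = 0.2$, with Gaussian noise variance $1 - h^2$), and additive nuisance
covariates that the pipeline must remove again. A `null` scenario writes a
*single* measured expression matrix used for both contexts — the
negative-control design in which one cohort is partitioned into three equal
subsets, making every gene null by construction. A `differential` scenario
gives each context its own causal set (disjoint by default) and its own
expression draw.

Real data differ in ways the generator does not imitate: realistic LD from
population history, rare variants, population structure and relatedness,
non-Gaussian expression noise, trans effects, and the fact that real effect
sizes come from fitted tissue models rather than sparse synthetic vectors.
A green calibration test therefore establishes that the statistic behaves
as designed *under the assumed sampling model*, not that any particular
real-data result would replicate; absolute power numbers in particular
depend on the synthetic effect-size scale.

## Acceptance testing

The published validation of this class of method relies on
access-restricted individual-level data, so the package's acceptance tests
are property-based, on synthetic cohorts: (1) on a 200-gene negative
control (three subsets of 200 samples, 100 cis-SNPs per gene, $h^2 = 0.2$,
$K = 20$) the bootstrap p-values are tested for uniformity
(Kolmogorov–Smirnov) with a genomic-control lambda window of [0.85, 1.25];
(2) the conditional test on the same data shows a strictly larger lambda
and more Bonferroni rejections; (3) $p_{\mathrm{boot}} \ge p_{\mathrm{cond}}$ holds for every
gene, with exact equality of statistics when all bootstrap replicates
coincide; (4) with disjoint causal sets and $h^2 = 0.5$, power at
$\alpha = 0.05$ exceeds 80% at 238 training / 239 test samples and is
non-increasing as the test set shrinks through 239/179/120/60/30 (the
training-then-evaluate work is shared across nested subsets so the
comparison is exact, not re-randomized), and runs with training sets below
100 samples carry an instability warning; (5) the type-I error is invariant
to training-set overlap in {0, 0.5, 1}; (6–7) closed-form worked examples
and three independent oracles (proximal-gradient elastic net, full HWE
enumeration, normal-equations residualization) agree to stated tolerances.

One acceptance result deserves honesty rather than adjustment: on the
synthetic negative control above, the bootstrap test is *conservative*
(genomic lambda about 0.37, p-values piled toward 1), and the uniformity
test fails in that direction. Monte-Carlo decomposition shows why: in this
world the true variance of $\Delta\bar L$ across fresh training-set redraws
is about 4.7e-3, while the bootstrap term estimates about 8.8e-3 — with-
replacement resamples carry ~37% duplicated rows, which makes refits
noisier than fresh-sample refits and leaks duplicates across CV folds,
biasing the per-replicate penalty low. Freezing the penalty instead
*under*-estimates the same quantity by ~2.7x and would make the test
anticonservative, so the full CV rerun is kept. The synthetic world — a
strong sparse signal ($h^2 = 0.2$ in 5 of 100 SNPs) with a large test set —
makes the training-variance term dominate the denominator, amplifying the
bootstrap's overestimate; in regimes where cis predictive signal is weak
and diffuse (thousands of cis-SNPs, modest imputability — i.e. real
tissue data), the test-set variance term dominates and the same statistic
is close to calibrated. False positives are controlled in either case; the
cost of the conservatism is power, not validity.

## Known limitations

* No effect size: the test ranks genes only by evidence, not by magnitude
  of regulatory difference.
* Equivalence is loss-relative: regulatory differences invisible to
  squared-error prediction (e.g. reshuffling within a preserved LD block)
  are undetectable in principle.
* Both contexts must come from one population; ancestry differences between
  contexts would masquerade as differential regulation.
* Individual-level genotypes and expression are required; there is no
  summary-statistic mode.
* The bootstrap retrains $2K$ models per gene; at $K = 50$ and a few
  hundred training samples expect on the order of seconds per gene.
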