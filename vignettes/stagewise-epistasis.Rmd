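---
title: "Stage-wise closed testing for pairwise genetic interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-wise closed testing for pairwise genetic interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

For a variant pair with minor-allele counts $a, b \in \{0,1,2\}$ and a binary
phenotype, the penetrance $p_{ab} = \Pr(Y = 1 \mid X_1 = a, X_2 = b)$ is
modelled by a generalized linear model

$$g(p_{ab}) = \alpha + \beta_a + \gamma_b + \delta_{ab},$$

with the identifiability constraints
$\beta_0 = \gamma_0 = \delta_{0b} = \delta_{a0} = 0$. No additive allele
effect is assumed: $\beta_2$ is free of $\beta_1$, and likewise for
$\gamma$ and $\delta$. The link $g$ fixes the scale on which effects
combine; `epistage` supports five (`link_spec()`): additive penetrance
(identity), multiplicative penetrance (log), genetic heterogeneity
(log-complement), additive odds, and multiplicative odds (logit). Nested
null models define the hypotheses of the scan:

* $H_1$: $g(p_{ab}) = \alpha$ — no association (1 parameter);
* $H_2$, $H_3$: $\alpha + \beta_a$ or $\alpha + \gamma_b$ — single main
  effect (3 parameters);
* $H_4$: $\alpha + \beta_a + \gamma_b$ — double main effect, no
  interaction (5 parameters);
* $H_A$: the saturated model (9 parameters).

$H_1$–$H_3$ and $H_A$ are saturated within their genotype stratification,
so their maximum likelihood has a closed form (cell or margin
proportions) and is identical on every link. Likelihood-ratio statistics
against $H_A$ are referred to $\chi^2$ with 8, 6, 6 and 4 degrees of
freedom respectively (`lrt()`).

Because a pair can look interactive on one scale and additive on
another, the final interaction test is made *scale-invariant*: $H_4$ is
tested on every configured link and the per-link p-values are combined
by their maximum (`scale_invariant_p()`), an intersection–union test
that requires significance on all scales.

## The stage-wise procedures

Testing all $\binom{N}{2}$ pairs directly against a Bonferroni threshold
(4.0·10⁻¹³ for 500,000 variants at $\alpha = 0.05$) is hopeless. The
stage-wise scan (`epistasis_scan()`, `run_static()`, `run_adaptive()`)
instead rejects the nested nulls in order of complexity — $H_1$, $H_2$,
$H_3$, then the scale-invariant $H_4$ — and only pairs surviving a stage
are tested at the next one. Positive weights $w_1,\dots,w_4$ summing to 1
split $\alpha$ across stages; pair $i$ survives stage $s$ iff
$p_{is} < w_s\alpha/K_s$ (strict inequality, as the procedure is
defined).

* **Static** method: $K_s$ is fixed a priori. With $N$ variants and $M$
  assumed marginally associated variants, the stage counts are
  $N(N-1)/2$, $NM$, $NM$, $M(M-1)/2$ (`static_corrections()`). Closed
  testing over the intersection-closed hypothesis family gives
  finite-sample FWER control. Adjusted p-values are
  $\tilde p_i = \min(1, \max_s K_s p_{is}/w_s)$.
* **Adaptive** method: $K_s$ is replaced by the previous stage's
  rejection count $|R_{s-1}|$, with $R_0$ the input set. FWER control is
  asymptotic and relies on alternatives being rejected; the adjusted
  p-values $\max_s |R_{s-1}| p_{is}/w_s$ are conservative. The
  family-wise error experiments below show the known finite-sample
  inflation of this method under many weak main effects — the package
  documents this behaviour rather than attempting to repair it.

Design choices where the procedure description leaves room:

* $H_2$ (first variant's main effect) is stage 2 and $H_3$ stage 3; the
  procedure is symmetric under swapping the variants (tested).
* A pair eliminated before stage 4 reports adjusted p-value 1 together
  with its elimination stage, unless all four stage p-values were
  supplied precomputed, in which case the max formula runs over all
  four. Stage p-values for eliminated pairs are otherwise never computed
  (lazy evaluation).
* If an adaptive stage rejects nothing the procedure halts with an empty
  significant set — no division by zero.
* Default weights are $(0.1, 0.3, 0.3, 0.3)$, the best combination in a
  0.1-step grid search (`weight_grid_search()`); the grid enumerator
  supports both the all-positive convention (default, 84 tuples) and the
  zeros-allowed convention (286 tuples), since a zero-weight stage can
  never be passed and is only useful for bookkeeping comparisons.

## Fitting H4: numerical choices

The only iterative fit in the scan is $H_4$. The 9 aggregated binomial
cells are maximized over $(\alpha,\beta_1,\beta_2,\gamma_1,\gamma_2)$
with the penetrance box-constrained to $[10^{-10}, 1-10^{-10}]$ — the
identity, log, log-complement and odds inverses can otherwise leave
$(0,1)$. The constraint lives inside `g_inverse` (with matching zero
derivative where the clamp is active), so iterations never throw.
Starting values come from the marginal fits pushed through the link
(deterministic, close to the optimum). The logit link gets a
hand-written IRLS on the aggregated cells with step-halving, polished by
BFGS; other links use BFGS with the analytic gradient, 200-iteration
cap, relative-change convergence. Non-converged fits are used as-is:
their log-likelihood is a lower bound, which makes the H4-vs-saturated
test conservative (fewer rejections). Tables with fewer than five
populated strata are reported saturated-equivalent (p-value 1). The
$0\log 0 = 0$ convention is applied throughout and unit-tested; empty
strata contribute nothing to any likelihood and never change the
degrees of freedom — rare-genotype pairs are instead meant to be removed
upstream by the MAF-product filter (`build_pairs()`).

A useful exactness: under retrospective case–control sampling the
sample-conditional penetrance differs from the population penetrance by
a constant multiplier on the odds, so additivity is preserved exactly on
the odds and logit scales and *not* on the identity/log/log-complement
scales. All fits are therefore performed directly on the sampled cohort
with $p_{ab}$ read as the sample-conditional probability — no prevalence
re-weighting — matching how the error-rate experiments sample their
cohorts.

## The simulation framework

`simulate` functions generate everything the package needs; no external
data is required.

* **Interaction-model enumeration.** All $2^9 = 512$ complete-penetrance
  patterns are scanned; a pattern is retained as an interaction iff it
  cannot be written as the element-wise OR of a row-constant and a
  column-constant binary matrix (`risch_decomposable()` — the genetic
  heterogeneity decomposition; 462 patterns are retained). Continuous
  models set cells to $\beta_0$ (default base risk 0.05, exposed as a
  parameter) and $\beta_0 + \beta_1$, with $\beta_1$ bisected so the
  model's heritability
  $H^2 = \sum_{ab}(K - p_{ab})^2 f_{ab} / K(1-K)$ hits a target to
  $10^{-8}$ (`calibrate_effect()`).
* **Cohort sampling.** Case genotypes follow
  $\Pr(a,b \mid Y{=}1) \propto p_{ab} f_{ab}$ (Bayes), controls the
  complement (`sample_case_control()`); loci are independent with
  Hardy–Weinberg frequencies.
* **Double-dominant model.** `double_dominant_model()` implements the
  pure-interaction benchmark: all main effects zero and a shared effect
  $x$ in the four double-carrier cells on the logit scale, baseline
  intercept 0 (baseline penetrance 0.5), $x$ calibrated to a target
  heritability.
* **Null cohorts.** `simulate_null_cohort()` generates the ten null
  kinds used for error-rate estimation: `none`, `single`,
  `double:<link>` for the five links, and `multi:L` — an additive
  logistic model over $L$ variants with $\beta_i \sim N(0.15, 0.01)$
  (variance 0.01, i.e. sd 0.1), intercept $-9.0$, on cohorts of 500
  variants with MAF uniform on $(0.2, 0.4)$ and 4000 cases + 4000
  controls. Since the implied disease probability is of order $10^{-4}$,
  sampling individuals until the quotas fill would need tens of millions
  of draws; for $L \le 11$ the package instead draws associated-variant
  genotypes from the exact Bayes conditional over all $3^L$ genotype
  combinations — distributionally identical to rejection sampling — and
  unassociated variants directly from HWE (they are independent of the
  phenotype). Literal chunked rejection sampling (capped at $10^9$
  draws) remains available via `method = "rejection"` and is the
  automatic path for larger $L$.
* **Single/double-main effect sizes.** The per-link defaults in
  `double_main_defaults()` were fixed from asymptotic noncentralities
  computed on expected cell counts, with two a-priori requirements: each
  variant's marginal test must be detected essentially always at the
  stage-1 threshold (df-8 noncentralities 100–450), and the
  identity/odds scales must deviate strongly enough from
  logit-additivity to exercise the documented breakdown of logit-only
  interaction tests (spurious df-4 noncentrality ≈ 105 on the odds
  scale, ≈ 42 on identity). The single-main null uses the logit defaults
  (the canonical case-control link); both are configurable.

What the generators deliberately do **not** emulate: linkage
disequilibrium between loci (variants are independent), genotyping
error and missingness, covariates or population stratification, and
quantitative phenotypes. Passing error-rate and power checks on these
cohorts therefore says nothing about confounding robustness on real
data — the QC and pair filters (`qc_filter()`, MAF-product ≥ 0.04,
inter-variant distance ≥ 1 Mbp) exist precisely because real data
violate these idealizations.

## Experiments

`estimate_fwer()` estimates the probability of at least one (false)
rejection among all 124,750 pairs of a 500-variant cohort, sharing
replicate cohorts across methods so contrasts are paired.
`estimate_power()` estimates detection power for a single embedded
interacting pair under chip-scale accounting: $10^{12}$ assumed pairs
for unscreened methods, screen-adjusted effective counts for screened
ones ($0.1\cdot10^6$ choose 2 for the marginal screen,
$0.39\cdot10^{12}$ and $10^{-4}\cdot10^{12}$ for the pooled-LD screens),
and static stage corrections $10^{12}, 10^8, 10^8, 4950$ for the
assumed-$M{=}100$ scenario. `exceedence_curve()` summarizes power over a
model collection as the fraction of models with power at least $t$.

Comparison methods implemented (`competitors`): the direct logistic
interaction test (H4 vs saturated on logit, df 4); marginal screening at
level 0.1 followed by the logistic test; the two pooled-cohort
composite-LD screens (CSS variant, $\chi^2 \ge 3$; R² variant,
$p \le 10^{-4}$) with a logistic main test; the LD-contrast test (case
vs control composite-LD difference, delta-method variance, df 1); and a
sixpac-style procedure (dominant/recessive recodings, within-cases LD
screen at 0.01 — the screen level is not fixed by its description and is
configurable — followed by a binary LD-contrast main test, Bonferroni
over the codings tested). LD estimators use composite LD on unphased
0/1/2 scores, since phase is unavailable. Holm–Bonferroni
(`holm_bonferroni()`) corrects the main tests, generalized to a family
larger than the computed set. One exact shortcut keeps full-cohort
error-rate estimation tractable: at least one Holm rejection is
equivalent to $\min_i p_i < \alpha/m$, and $H_1 \subset H_4$ gives
stat$_{H4} \le$ stat$_{H1}$ per pair, so the scan fits the logistic
model only for pairs whose (vectorized, closed-form) stage-1 statistic
clears the corrected $\chi^2_4$ quantile — an algebraic bound, not an
approximation.

Problem sizes used by the shipped tests and the acceptance script are
the package's chosen desk-scale defaults: 100 replicate cohorts per null
kind in the test suite (200 for the multivariate null in the acceptance
script), 60–150 replicates per power point, and a 31-model spread of the
enumerated interaction spectrum for the exceedence comparison. Estimates
carry binomial Monte-Carlo standard errors; the documented checks allow
three of them.

## Known limitations

* The adaptive method's error control is asymptotic; under many weak
  main effects its FWER is genuinely inflated (a factor ~2–3 at the
  simulated conditions). The static method keeps control there at the
  cost of power and of having to posit $M$ (which must be at least 2 so
  that every stage has a positive hypothesis count).
* The scale-invariance test is conservative by construction (maximum of
  dependent p-values); with a single configured link it degrades to that
  link's test and loses the invariance property.
* Chi-square references for the stage tests are asymptotic; very sparse
  tables (rare genotype combinations) are excluded by the MAF-product
  filter rather than modelled exactly.
* PLINK input is limited to the PLINK 1 binary triple, variant-major;
  dosage/VCF input and covariate adjustment are out of scope.
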