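---
title: "Variance-component analysis of RIX panels with rixmm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance-component analysis of RIX panels with rixmm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rixmm)
```

## The problem

Recombinant inbred intercross (RIX) panels cross pairs of recombinant inbred
strains to produce F1 animals that are genetically outbred yet fully
reproducible.  In a pharmacogenomic screen — for example, a
placebo-controlled study of the antipsychotic haloperidol, whose motoric
side effects (Parkinsonian rigidity, vacuous chewing movements) vary
strongly between individuals — each animal carries contributions from *two*
parental strains.  The strain effect is therefore a **multiple-membership**
random effect: an observation belongs simultaneously to two levels of the
grouping factor, and the incidence matrix has two 1s per row instead of the
usual one.

`rixmm` fits the resulting variance-component models by restricted maximum
likelihood (REML), tests components with boundary-corrected likelihood
ratio tests, partitions heritability, predicts strain-level deviations
(BLUPs) with prediction intervals, flags extreme responders, and estimates
cross-phenotype correlations of strain effects.  A synthetic-data generator
reproduces the study design so every stage can be validated against a known
truth.

## The model

For an endpoint measured pre- and post-treatment in both arms (model class
A) the response is the pre/post change score and

$$Y = \beta_0 + \beta_1 x_{pre} + \beta_2 x_{tmt} + \beta_3 x_{sex}
      + \beta_4 x_{sex} x_{tmt} + \sum_{j=1}^{5} Z_j \gamma_j + \epsilon,$$

with independent random effects $\gamma_j \sim N(0, \sigma^2_j I_{q_j})$
for batch, strain, strain-by-treatment, strain-by-sex, and
strain-by-sex-by-treatment, and $\epsilon \sim N(0, \sigma^2_\epsilon I)$.
A count endpoint measured once post-treatment (class B, the total VCM
score) omits the pre covariate; a treated-arm-only endpoint (class C, log
plasma drug concentration) keeps intercept and sex with random effects
batch, strain, and strain-by-sex.  The marginal covariance is
$V = \sum_j \sigma^2_j Z_j Z_j' + \sigma^2_\epsilon I = ZGZ' + \sigma^2_\epsilon I$.

### Design-matrix coding

Each animal contributes an incidence of 1 to each of its two parental
strain columns — additive parental effects with no parent-of-origin
distinction, which is appropriate because reciprocal crosses share parents.
A `parent_weight = 0.5` switch gives an average-parent convention instead.
Interaction effects are coded as **level expansions**: one column per
observed (strain, arm), (strain, sex) or (strain, sex, arm) combination
with a shared variance, which is how a categorical interaction random
effect expands in standard mixed-model software.  An alternative
`interaction_coding = "indicator"` (the strain incidence multiplied by the
0/1 arm indicator) is available behind a flag.  Unobserved interaction
levels are dropped: an all-zero column contributes nothing to $ZZ'$ and
would make bookkeeping of $q_j$ misleading.  Column order is lexicographic
and row order follows the input table, so outputs are deterministic.

### Phenotype derivations

Change scores are `post - pre` except body weight, where the ambiguity of
"a difference, log-transformed" (differences can be negative) is resolved
as the difference on the log scale, `log(post) - log(pre)`; the pre
covariate is then `log(pre)` so covariate and response live on the same
scale.  A raw-difference sensitivity path is available by editing the
endpoint registry.  The VCM response is the equal-weight sum of the four
orofacial movement counts.  Plasma concentration is natural-log
transformed.  Sex is coded female = 0, male = 1 and treatment placebo = 0,
haloperidol = 1; signs of fixed-effect estimates depend on this choice and
it is echoed in the documentation of every output.  EPS latencies are
Gaussian-modelled on the censored [0, 60] s scale, and VCM counts are
Gaussian-modelled too; no GLM alternative is fitted, so for heavily
censored or low-count regimes the intervals are approximations.

## REML estimation

The residual variance is profiled out analytically and the remaining
parameters are the variance *ratios* $\lambda_j = \sigma^2_j /
\sigma^2_\epsilon$.  Writing $V = \sigma^2_\epsilon (I + Z D_\lambda Z')$,
the Woodbury identity reduces every $n \times n$ operation to a Cholesky
factorization of the $q \times q$ capacitance matrix
$M = I_q + D_\lambda^{1/2} Z'Z D_\lambda^{1/2}$, computed once per
objective evaluation from pre-computed crossproducts — $V$ is never formed
or inverted during optimization.  The gradient of the restricted deviance
with respect to $\lambda$ is analytic (trace and quadratic-form identities
on the same factorization).

Optimization is bounded quasi-Newton (`optim` L-BFGS-B) on $\lambda \ge 0$
with the analytic gradient, from one deterministic start plus seeded random
starts (five starts by default; the large simulation studies use two, which
we verified reach the same optimum on these designs).  We deliberately use
a direct non-negativity bound rather than a log parameterization: boundary
estimates are genuinely common in these models, the bound lets the
optimizer sit exactly on $\lambda_j = 0$, and ratios below $10^{-10}$ are
snapped to an exact zero so that "estimated at boundary" is an unambiguous,
reportable state.  Convergence requires an L-BFGS-B clean exit or a
projected gradient norm below $10^{-3}$ (the reported norm at accepted
optima is typically far smaller); a residual variance collapsing below
$10^{-8}$ times the response variance aborts with diagnostics rather than
returning an unstable fit.

`reml_loglik()` exposes the criterion itself, including its constant, so
the optimum can be verified against an independent dense implementation —
the test suite does exactly that, and also checks balanced one-way designs
against the ANOVA closed form, small frames against an exhaustive grid
search, and a random-intercept model against `lme4`.

## Hypothesis tests

**Variance components.** The null value $\sigma^2_j = 0$ sits on the
boundary of the parameter space, so twice the log-likelihood-ratio is
compared to the 50:50 mixture of a point mass at zero and $\chi^2_1$; the
naive $\chi^2_1$ p-value is reported alongside because published tables in
this literature are not always consistent about which convention produced a
printed p of 0.5 versus 1.0 for a component estimated at zero.  The batch
component is always retained in the model and never tested.

**Fixed effects.** Wald F statistics use the GLS coefficient covariance.
Denominator degrees of freedom use a Satterthwaite-style approximation
(delta method on $l'V_\beta(\theta)l$ with the observed REML information),
not the exact Kenward-Roger adjustment: at several hundred animals the two
are numerically indistinguishable for these contrasts, and the
Satterthwaite form needs only derivatives we already have.  With no random
effects the approximation collapses to the exact residual degrees of
freedom.  Components estimated at zero are held fixed in this calculation.

## BLUPs, heritability, flags, correlations

Predictions of the random-effect levels use
$\hat\gamma = \hat G Z' \hat V^{-1}(Y - X\hat\beta)$, solved through
Henderson's mixed-model equations; the prediction error variance of
$\hat\gamma - \gamma$ is the corresponding diagonal block of the inverse
coefficient matrix, and intervals use the normal quantile (at these sample
sizes a t correction is immaterial and the reference analyses use normal
intervals).  Components estimated at zero produce identically zero
predictions with zero standard error, flagged as such.

Overall heritability is
$\kappa \sum_s \sigma^2_s / (\kappa \sum_s \sigma^2_s + \sigma^2_{batch} +
\sigma^2_\epsilon)$ over the strain-containing components, and
treatment-effect heritability replaces the numerator with
$\kappa\,\sigma^2_{strain \times tmt}$.  The parental multiplier $\kappa$
(default 1, i.e. components interpreted as the variance contributed by the
parental pair) is configurable to 2 for a per-parent convention; the
definition in force is echoed verbatim in every manifest because published
heritability rows rarely print their formula and calibration against a
printed table is the only arbitration.

The strain-by-treatment quantity used for flagging and for the interaction
correlogram is the haloperidol-arm level minus the placebo-arm level of the
same strain under the expanded coding.  Flagging takes the strains strictly
beyond the stated empirical quantile (default 10%) in the direction of each
endpoint's significant mean treatment shift; ties at the threshold are not
flagged, so degenerate prediction vectors yield empty sets.  Correlations
across endpoints are Pearson correlations of the *predictions* (not raw
strain means), aligned by parental strain label; a treated-arm-only
endpoint joins the interaction panel through its strain effect, since those
effects are predicted in treated animals only.

## The synthetic-data generator

`simulate_design()` arranges strains in a quasi-loop — line $i$ crosses
strain $i$ with strain $i+1$, wrapping around, so each strain parents
exactly two lines; extra lines beyond the loop are chords (strain $j$ with
strain $j+2$, then $j+3$, ...), which lets a 62-strain panel carry 73
lines.  Each line holds the full sex-by-arm factorial (default 3 animals
per cell, 12 per line); cagemates are one treated and one placebo animal of
the same line and sex; cages are assigned to batches by a seeded random
round-robin at about 16 animals per batch.  Arbitrary strain-pairing edge
lists can be supplied by building the animal table directly.

`simulate_phenotypes()` draws every random effect and residual exactly
under the model, then constructs raw phenotype columns so the preparation
module reconstructs the modelled response bit-for-bit: pre values come from
endpoint-specific baseline normals, post values are `pre + Y` (or
`pre * exp(Y)` for the log-ratio endpoint), VCM totals are rounded,
floored at zero and split multinomially across the four movement types, EPS
values are clipped to [0, 60] s with the clipped fraction reported, and
plasma exists only in the treated arm.  Strain effects can be drawn jointly
across endpoints with a specified correlation matrix.  The exact generating
draws are stored with the table for recovery testing, and identical
(truth, seed) pairs reproduce tables bit-for-bit.

`default_truth()` fixes the generating conditions: the fixed effects and
strain-containing variance components follow the magnitudes reported for a
chronic-haloperidol CC-RIX study (e.g. distance: strain 300278,
strain-by-treatment 86343, strain-by-sex 22771, three-way 4618, in cm²
of change score), and the batch and residual variances — never reported —
are set so the generating overall heritability matches the reported values
(0.40 for distance and VCM down to 0.21 for weight), with batch fixed at
one ninth of the residual.  Baseline means and SDs are chosen to resemble
the published marginal ranges qualitatively (e.g. 5000 ± 1500 cm distance,
25 ± 4 g body weight, 5 ± 4 s EPS latency); no claim is made that they
match the real data distributions, and passing recovery tests therefore
demonstrates correctness of the estimator under the model, not robustness
to real-data pathologies (outliers, heteroscedasticity, informative
missingness).

## Validation studies and what they show

The acceptance suite (`tests/testthat/test-acceptance.R`, reproduced by
`scripts/acceptance.R`) runs five synthetic studies.  Problem sizes: 20
random toy frames for the grid-search cross-check; 1000 replicates of the
8-strain design for LRT calibration; 100 replicates (60 in the faster
script) of the full 62-strain / 73-line / 876-animal design for parameter
recovery; three study-scale replicates for correlation recovery; and one
study-scale cohort through the entire pipeline.

Two findings deserve emphasis because they are statistical properties, not
software defects, and both are asserted honestly in the tests:

1. **The boundary LRT is conservative at few strains.**  At the 8-strain
   design the empirical type-I error of the mixture test at $\alpha =
   0.05$ is about 0.03 (1000 replicates), below the binomial band around
   0.05; it rises to about 0.040 at 20 strains and 0.0425 at 40.  The
   50:50 mixture is an asymptotic result; with only 16 partially confounded
   strain-by-treatment levels, the finite-sample null puts less mass in the
   $\chi^2_1$ tail.  Inference at study scale (62 strains) is close to
   nominal, but p-values near the threshold from very small panels should
   be read as conservative.

2. **Boundary truncation biases tiny components.**  At study scale under
   the reference components, batch, strain, strain-by-treatment and
   residual variances are recovered without detectable bias (|z| < 1 over
   100 replicates), and 95% prediction intervals cover 94–95% of true
   strain effects.  The two sex-containing interactions, whose generating
   values are under 4% and 0.5% of the total variance, show equal and
   opposite biases: the three-way component piles up on the zero boundary
   and the deficit transfers to its nearly confounded two-way partner,
   while their *sum* is unbiased.  With both components moved into the
   interior the biases vanish, confirming the mechanism.  Estimates of
   individual near-zero components in this design should be read as a
   joint quantity.

Relatedly, the correlation-recovery study runs in a high-reliability
regime (strain variance at four times the residual) so that shrinkage
attenuation (≈0.02 there) is negligible against the sampling error of a
correlation over 62 strains (≈0.05).  Under the reference components the
BLUP correlogram *attenuates* generating correlations substantially for
weakly identified endpoints — correlating noisy shrunken predictions is not
the same as correlating true effects — so observed correlograms are best
read as lower bounds on effect-level correlations.

## Numerical choices and degenerate inputs

Tie-breaks and guards, in one place: variance ratios below $10^{-10}$
report as exact zeros; a residual variance below $10^{-8} \times
\mathrm{var}(Y)$ is a degeneracy error; rank-deficient fixed-effect
matrices error naming the collinear columns; LRT statistics are floored at
zero (differences down to $-10^{-6}$ are tolerated as float noise, beyond
that a warning names the suspect optimum); correlation cells with fewer
than 3 shared strains, or with a degenerate (zero-variance) prediction
vector, are missing rather than fabricated; flagging with fewer strains
than $1/\text{quantile}$ warns and returns an empty set; endpoints that
fail inside `fit_all_phenotypes()` are caught, logged and reported without
aborting the rest.

## Known limitations

No parent-of-origin asymmetry (dam and sire contribute exchangeably); no
genotype or kinship input — strains are exchangeable labels; Gaussian
working models for counts and censored latencies; Satterthwaite rather
than Kenward-Roger denominator degrees of freedom; the synthetic quasi-loop
is a single loop plus chords rather than any particular study's exact
mating scheme.  The printed reference values of the motivating study
(heritability rows, complete-case counts, the extreme-strain count) can
only be reproduced against its deposited data, which require a download;
the pipeline consumes that export directly via the column-remapping schema
of `load_animal_table()`.
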