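---
title: "Methods: sterile-male-technique paternity estimation and the OLRE binomial model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sterile-male-technique paternity estimation and the OLRE binomial model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spermP2)
```

## The estimation problem

In a double-mating sperm-competition trial a focal female mates with two
males and lays a batch of eggs; the quantity of interest is P2, the
proportion of those eggs sired by the second male. The sterile male
technique assigns paternity through egg viability: one male is irradiated,
and eggs he sires almost never hatch. The observable is therefore not
paternity itself but the hatch proportion *x*, which mixes two fertilities:

$$x = P_R \, z + (1 - P_R) \, p,$$

where $P_R$ is the sterile male's paternity share, $p$ is normal-male
fertility and $z$ is the residual fertility of an irradiated male
(sterilization is incomplete). Inverting,

$$P_R = \frac{p - x}{p - z}, \qquad
  P2 = \begin{cases} P_R & \text{sterile male second (NR)} \\
                     1 - P_R & \text{sterile male first (RN)}. \end{cases}$$

Published renderings of this inversion are sometimes typographically
garbled; the algebra above is the unique linear-mixture inverse consistent
with the definitions of $x$, $p$ and $z$, and it satisfies both boundary
conditions ($x = p \Rightarrow P_R = 0$, $x = z \Rightarrow P_R = 1$). The
package asserts this round trip to machine precision rather than any
particular printed formula string.

### Stratified correction factors

Because males are irradiated at the start of a trial while females may
delay remating by 24 or 48 h, sterilization (and fertility generally) can
decay over the inter-mating interval. $p$, $z$ and the brown-egg proportion
are therefore estimated separately for each sterilization order ×
interval stratum from single-sire mating assays, by ratio-of-sums pooling:
$\hat p = \sum \text{hatched} / \sum \text{laid}$ over the stratum's
normal-male assays, and similarly for $z$ over sterile-male assays. The
ratio-of-sums rule (rather than a mean of per-assay ratios) matches how
such tables are conventionally reported and makes the estimate invariant to
how records are split. No smoothing or sharing across strata is applied:
each stratum's estimate is exactly what its own records imply.

### Brown-egg reallocation

A hatched egg can leave only a brown larval head dot and be mis-scored as
clear (unhatched) when trial eggs are scored. In the assays brown eggs are
recorded, giving a per-stratum brown proportion $b$ (denominator: all eggs
laid in the stratum, both sire types). For each trial female the expected
brown count $b \cdot N$ ($N$ = eggs laid after the second mating) is moved
from the clear to the hatched column before inversion. Two numerical
choices: the estimate stays fractional through the corrected hatch
proportion (rounding only happens at final egg attribution, avoiding double
rounding), and it is clamped at the observed clear count so the corrected
clear count cannot go negative. The correction is deliberately the simple
flat rule used in the field; it slightly over-corrects females whose true
hatch proportion is below the assay average and under-corrects the
opposite, a bias of order $b\,|x - \bar x|/(p - z)$ (at most about one
percentage point of P2 at the default parameters) that the recovery tests
quantify and tolerate.

### Exclusions and attribution

Sampling noise or fertility misestimation can push $\hat x$ outside
$[z, p]$ and hence P2 outside $[0, 1]$. The default policy excludes such
females — the appropriate default when an out-of-bounds estimate may signal
failed sperm transfer — while an explicit override list retains named
females (clamped for attribution and flagged), and a `clamp` mode keeps
everyone, which is the right choice inside simulation studies where the
truth is known. Females laying fewer than `min_eggs` (default 10) eggs are
always excluded. Attributed egg counts are $\mathrm{round}(P2 \cdot N)$
with ties rounded half away from zero — the tie-break is symmetric between
the two males, whereas round-half-even would systematically favour
whichever male happened to sit on even counts; it is configurable in the
sense that attribution operates on a clamped P2 the caller controls.
Pooled subgroup P2 is $\sum \text{(male-2 eggs)} / \sum \text{(eggs laid)}$
across kept females, not a mean of ratios, so large clutches carry
proportionally more weight.

## The binomial mixed model

Per-female counts are overdispersed relative to a binomial: latent
variation in sperm transfer, female physiology and scoring enters every
trial. The model is

$$y_i \sim \mathrm{Binomial}(n_i, \pi_i), \qquad
  \mathrm{logit}\,\pi_i = \mathbf{x}_i^\top \boldsymbol\beta + \sigma u_i,
  \qquad u_i \sim \mathcal N(0, 1),$$

with one random deviate per observation (an observation-level random
effect, OLRE). The default fixed effects are mating order and inter-mating
interval, both treated as categorical — interval enters as separate 24-h
and 48-h contrasts, never as a numeric trend.

Because the random effect is observation-specific, the marginal likelihood
factorizes exactly into one-dimensional integrals,

$$\ell(\boldsymbol\beta, \sigma) = \sum_i \log \int
  \mathrm{Binom}(y_i \mid n_i, \mathrm{logit}^{-1}(\eta_i + \sigma u))\,
  \varphi(u)\, du,$$

evaluated by adaptive Gauss–Hermite quadrature: each integral is centred at
its conditional mode (found by a damped Newton iteration on the strictly
concave integrand) and scaled by the mode's curvature, with 31 nodes by
default and log-sum-exp accumulation throughout. Adaptivity makes the rule
effectively exact here — doubling the nodes changes the log-likelihood by
less than $10^{-6}$ on the default 64-trial problem, which the test suite
asserts. At $\sigma = 0$ the expression reduces algebraically to the plain
binomial log-likelihood, giving a sharp correctness anchor against
iteratively reweighted least squares.

Optimization is quasi-Newton (BFGS) over $(\boldsymbol\beta, \log\sigma)$,
started from a plain binomial fit and $\sigma = 0.5$. The profile in
$\log\sigma$ flattens into an asymptote as $\sigma \to 0$, and a line
search can overshoot down it and stall at a spurious near-zero $\sigma$;
the fitter guards this with a coarse profile scan over $\log\sigma$ after
convergence and restarts from any grid point that beats the incumbent.
Wald standard errors come from the numerical Hessian at the optimum; when
the variance component sits essentially on its boundary the Hessian row for
$\log\sigma$ degenerates and the fitter falls back to the fixed-effect
block. Coefficients with $|\hat\beta| > 15$ trigger a separation warning.

An optional shared random intercept (e.g. female generation) is available
through a Laplace approximation nested outside the OLRE integrals: the
group-level integrand is maximized numerically per group and approximated
by its curvature. It is off by default — the OLRE-only model is the final
model of the motivating analysis, the factorized likelihood is then exact
rather than approximate, and in the simulations below a small generation
component is simply absorbed into $\hat\sigma$ with no measurable bias in
the treatment effects.

### Post hoc comparisons

Marginal (least-squares) means are formed on the link scale at each target
factor combination, averaging over the remaining factors' levels with equal
weights, with delta-method standard errors from the Wald covariance. All
pairwise contrasts are adjusted by the single-step studentized-range
(Tukey) procedure with infinite degrees of freedom, consistent with the
model's asymptotic z inference — the model supplies no finite-df theory,
and for two means the adjustment reduces exactly to the unadjusted z test.
The tests cross-check both means and adjusted p values against an
independent post hoc implementation.

### Supporting tests

The 2×2 remating comparisons use Pearson's chi-squared with Yates'
continuity correction, $\sum \max(|O - E| - 0.5,\, 0)^2 / E$; the clamp at
zero matters, since near-identical remating rows must yield a statistic of
exactly 0.00 with p = 1.00. On one published 24-h remating table
(15 remated of 44 vs 10 of 43) this formula gives 0.774 (p = 0.379) where
the source prints 0.70 (p = 0.38): the p values agree, the statistic does
not, and the package asserts the formula, not the printed statistic.
Behavioral responses (latencies, durations, ejaculate and body masses) are
compared with ordinary or single-random-intercept linear models (REML),
with optional log or square-root response transforms, and sparse gaps in
covariates are mean-imputed (the observed mean is unchanged by
construction) rather than dropping males. Paired t tests compare first
versus second ejaculates within treatment; zero-variance differences are
reported explicitly as degenerate rather than erroring.

## The synthetic experiment generator

`sim_config()` / `simulate_experiment()` emulate the study design the
package targets: 64 double-mated females by default, mating order MP/PM in
a 35:29 balance, sterilization order NR/RN in 31:33, intervals 0/24/48 h in
25:23:16 proportions, and logit-scale effects $\beta_0 = 0.09$,
$\beta_{PM} = 0.47$, $\beta_{24} = 0.82$, $\beta_{48} = 0.51$ with
$\sigma_{\mathrm{OLRE}} = 0.5$ — magnitudes taken from the motivating
experiment. Each female's true P2 is the inverse logit of her linear
predictor plus a shared generation intercept (SD 0.2 across 4 generations;
a small value, reflecting that the generation effect contributed little in
the motivating analysis) and her own OLRE deviate. Egg counts are negative
binomial (mean 45, dispersion 10, truncated at 1): the mean matches the
reported 30–65 eggs per female, while the dispersion is a generator
parameter with no published counterpart, exposed in the configuration and
never asserted. Each egg is independently sired by male 2 with probability
true-P2, hatches with its sire's stratum fertility, and, if hatched, is
brown with the stratum's brown probability — brown eggs are then recorded
as clear in the observed columns, reproducing the scoring error the
reallocation corrects. Note the parameterization gap this creates: the
generator's brown parameter is a per-hatched-egg probability, while the
assay-derived correction is a per-egg-laid proportion; the estimation
pipeline sees exactly the mismatch a real analysis sees, which is the
point.

Fertility assays are generated per stratum with a configurable egg count
(default 600 per sire type, matching the 375–660 range of the motivating
assays). Behavioral covariates are independent Gaussians per (role ×
maternal treatment) seeded from published means, with SD recovered as
SE·√33 from the reported standard errors, and 4.7% of behavioral entries
knocked out at random to exercise imputation. No correlation structure is
imposed among behaviors — none is published — so the generator cannot
validate analyses that depend on behavior–paternity covariance. Interval
assignment is an independent categorical draw, not the self-selected
remating of a real experiment; self-selection affects interpretation of
interval effects, not the estimator under test. One global seed feeds
deterministic per-stage sub-seeds, so trials, assays and behaviors are
independently reproducible and identical configurations are byte-identical.

### What the simulations do and do not show

Passing recovery tests show that, under the generator's assumptions —
independent eggs within a clutch given the latent P2, correct stratum
membership, Gaussian logit deviations — the pipeline recovers the
generating effects and holds its nominal error rate. They do not show
robustness to features real data may have and the generator lacks:
within-clutch hatch correlation beyond the OLRE, fertility drift within a
stratum, non-random remating, or covariate correlation.

## Problem sizes and numerical conventions

The validation suite runs at sizes chosen to make Monte Carlo error small
relative to the tolerances asserted: the mixture round trip on a
$50^3$ grid with $p - z \ge 0.01$ (tolerance $10^{-12}$); estimator
consistency at 200 females × 10,000 eggs (mean absolute P2 error under
0.01); effect-recovery coverage over 100 replicates of 400 females
(coverage of truth within 3 reported SEs at least 95%); and type-I error
over 1,000 replicates of 64 females (Wald rejection rate in [0.03, 0.08] at
$\alpha = 0.05$, against a naive binomial fit that exceeds 10% on the same
data — the OLRE's purpose in one number). Quadrature uses 31 nodes by
default with a 201-node stability check. All tests are two-sided;
significance handling is left to the caller.

## Known limitations

* The brown-egg correction is the field's flat expected-count rule; its
  small hatch-dependent bias is documented above rather than removed,
  because removing it would change the estimator under study.
* The shared-group layer handles one grouping factor by Laplace
  approximation; fully crossed or nested multi-factor random effects are
  out of scope — use a general mixed-model package when the design needs
  them.
* Wald inference is asymptotic; at much smaller sample sizes than the
  64-trial default, profile or bootstrap intervals would be preferable.
* The predictor-screening path of the motivating analysis (entry at
  p ≤ 0.20, collinearity pruning, stepwise AIC drops) is data-dependent and
  not reproduced; the package ships the final model plus a `compare_aic()`
  utility for explicit candidate sets.
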