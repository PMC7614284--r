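---
title: "Estimating chronic disease rates from aggregate data: the illness-death model behind chronicrates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating chronic disease rates from aggregate data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The estimation problem

Multistate lifetable models of population health need, for each disease,
age-specific **incidence** $i_a$, **case fatality** $f_a$ and (for some
diseases) **remission** $r_a$.  Direct data on case fatality — the death
rate among people who *have* the disease — are rarely published.  What is
published, by sources such as burden-of-disease studies, is aggregate
incidence, prevalence and population-level disease-specific mortality by
age group, often as estimates with 95% intervals rather than raw counts.

chronicrates treats the disease as a continuous-time, age-inhomogeneous
Markov process with three states — disease-free (1), disease (2), dead from
the disease (3) — and infers the transition rates jointly from whichever of
the four outcome series are available.  Mortality from other causes is
excluded by construction: the death state counts only deaths caused by the
disease, and diseases are modelled independently.

## From rates to observable probabilities

Rates are assumed piecewise constant within integer years of age.  Over one
year the process has intensity matrix

$$Q_a = \begin{pmatrix} -i_a & i_a & 0 \\ r_a & -(r_a+f_a) & f_a \\ 0 & 0 & 0 \end{pmatrix},$$

and annual transition probability matrix $P_a = \exp(Q_a)$.  Because death
is absorbing, the exponential reduces to the 2×2 block
$\exp(Q_2) = c_1 Q_2 + c_0 I$ with coefficients that are analytic functions
of $u = -(i+r+f)/2$ and $v = ((i-r-f)^2+4ir)/4$; the package evaluates this
closed form directly (a series expansion handles $v \to 0$), and the test
suite validates it against high-accuracy ODE integration.  Writing $S_a$
for the state-occupancy probabilities of a hypothetical birth cohort
(disease-free at age 0 by default), the recursion $S_{a+1} = S_a P_a$
yields the quantities the data are assumed to measure:

* incidence probability $1 - P_{a,11}$,
* prevalence among the living $\pi_a = S_{a,2}/(S_{a,1} + S_{a,2})$,
* annual disease-specific mortality probability
  $d_a = P_{a,23}\,\pi_a + P_{a,13}(1 - \pi_a)$,
* annual remission probability $P_{a,21}$.

Each observed count is binomial: $y_a \sim \mathrm{Bin}(n_a, p_a)$ with
$p_a$ the matching quantity above.  Expressing published estimates as
counts (see below) lets the likelihood weight each age by how much was
actually observed there — ages with small populations at risk contribute
proportionately weak information.

When the living probability of the hypothetical cohort underflows at
extreme ages (possible under extreme parameter values during fitting), the
last well-defined prevalence is carried forward and the affected ages are
reported, rather than propagating NaN.

## Age curves

Each modelled rate follows a penalised spline on the log scale,
$\log f_a = \sum_{k=1}^K \beta_k g_k(a)$ with $K = 10$ basis terms by
default.  The basis is a thin-plate regression spline in the natural
parameterisation (built on mgcv), in which the smoothness penalty is the
identity: the first two columns are an intercept and a linear term, and the
remaining $K-2$ coefficients get exchangeable $N(0, \lambda_0^2)$ priors,
so the prior SD $\lambda_0$ *is* the smoothness parameter — curves shrink
towards a straight line as $\lambda_0 \to 0$.  Two deliberate choices:

* **Age is scaled to [0, 1]** before basis construction.  Slope priors are
  then on the scale "change in log rate across the whole age span", which
  is where a prior such as $N(5, 5^2)$ for a common slope is plausible;
  per raw year of age it would not be.
* **The penalised columns are residualised against the affine part**, so a
  coefficient vector that is zero beyond $k = 2$ produces an exactly
  log-linear curve, and the nonlinear coefficients cannot leak intercept or
  slope.  The affine remainder this removes is absorbed by the free
  intercept and slope, so the model space is unchanged.

Two structural constraints are available per rate: a base age $a_{base}$
below which the rate is held constant (the basis is evaluated at
$\max(a, a_{base})$), and an *increasing* constraint under which the spline
models log increments, the curve being the cumulative sum of
exponentials — nondecreasing for every coefficient vector.

Priors (defaults): single-population intercepts and slopes $N(0, 100^2)$;
each $\lambda_0 \sim$ Gamma(2, 1), which vanishes at zero and so keeps
modal estimates off the boundary; hierarchical mean intercept
$b_1 \sim N(0, 10^2)$ and common slope $b_2 \sim N(5, 5^2)$.

## Areas, genders, time

**Hierarchical areas.**  Case-fatality intercepts are partially pooled:
$\beta_{i,1} \sim N(b_1, \lambda_1^2)$ across areas $i$, with a common
slope $b_2$ and per-area nonlinear terms sharing one $\lambda_0$.
Incidence, which is usually directly observed per area, keeps independent
coefficients per area.  The between-area SD prior is elicited on an
interpretable scale: the user states a prior guess and a plausible upper
limit for the fold-ratio in case fatality between a high-risk and a
low-risk area (the 97.5% and 2.5% quantiles of the area distribution,
ratio $\exp(2 \times 1.959964\,\lambda_1)$), and a numerical search finds
the gamma prior whose mean and 97.5% quantile reproduce them.  The package
default is a 5-fold guess with a 50-fold limit.

**Gender.**  With `gender = "additive"`, male offsets
$\beta^{male}_k$ are added to the shared area coefficients on the log
scale — the gender effect is assumed independent of area.  Offsets on the
intercept and slope have $N(0, 0.82^2)$ priors, implying a 95% prior
interval of roughly 0.2 to 5 for the male/female rate ratio; offsets on the
nonlinear coefficients have scale $\lambda_0^{male}$, fixed at 1 by default
(estimating it is not supported; the data that motivate this model rarely
identify it).  `gender = "interaction"` instead gives every area–gender
combination its own coefficients; comparing the two by cross-validation
(below) tests whether gender effects differ by area.

**Calendar time.**  Current-year data inform current-year rates, but the
prevalence observed today was generated by *past* incidence and case
fatality.  Published age-specific risk ratios $\rho_{a,y}$ (year $y = 100$
is the data year, ratio 1 by definition) multiply the current rates, and
each birth cohort is pushed forward through its own calendar-specific
transition matrices: $S_{a,y} = S_{a-1,y-1} P_{a-1,y-1}$.  Ratio matrices
are supplied on any year grid; earlier years carry the earliest column
backwards and gaps are interpolated linearly on the log-ratio scale.
Remission is assumed trend-free.  With all ratios 1 the cohort pathway
reduces exactly to the stationary one (this is asserted to $10^{-12}$ in
the tests).

## Parameterisation: why non-centred

All shrinkage-prior coefficients are held **non-centred**: the free
parameter is a standard-normal score $z_k$ and the coefficient is
$\lambda_0 z_k$ (similarly area intercepts $b_1 + \lambda_1 u_i$).  With
the centred parameterisation the joint density grows without bound as
$\lambda_0 \to 0$ when the data tolerate a linear curve — the optimizer
dives into the funnel and MCMC cannot cross it.  Non-centring removes the
degeneracy: the joint mode is interior and the sampler mixes even when the
nonlinear terms are weakly identified.

## Inference engines

**Posterior mode + Laplace (`fit_mode_laplace`).**  BFGS on the
unconstrained space with an exact, hand-derived reverse-mode gradient of
the full pipeline (spline → rates → matrix exponential → occupancy
recursion → binomial likelihood).  Exact gradients matter here: the
posterior mixes curvature scales of order 1 (weakly identified scores)
and $10^8$ (well-informed directions), which defeats finite-difference
gradients with any single step size.  The fit is two-stage: the joint mode
including the smoothness SDs is found first; those SDs are then fixed at
their modal values and the normal approximation is formed over the
remaining parameters.  With the SDs fixed, the map from parameters to
log-rate curves is linear, so normal draws translate into well-calibrated
curve intervals; with them free, normally distributed SD and score draws
multiply into an overdispersed curve distribution.  (Fixing scale
hyperparameters at modal estimates is also the standard stabilisation for
these models when sampling is hard.)  Non-positive-definite curvature is
repaired by the smallest diagonal jitter in $10^{-8}..10^{-2}$ that
achieves definiteness, with eigenvalue flooring as a last resort; failures
restart from jittered initial values (4 retries) before erroring with the
starts tried.

**Full posterior sampling (`sample_posterior`).**  Markov chain Monte
Carlo mixing two Metropolis–Hastings kernels derived from the Laplace fit:
an independence proposal from a heavy-tailed multivariate $t_7$ centred at
the mode, and a random-walk proposal with Laplace-shaped covariance whose
global scale adapts during warmup towards acceptance 0.234.  A
gradient-free sampler was chosen deliberately: with the exact gradient
available only for the untrended pathway, a kernel that needs nothing but
the log density works uniformly across all model variants, and the
Laplace-preconditioned proposal gives it workable mixing.  Convergence is
summarised by split-$\hat R$ and effective sample size per parameter;
$\hat R > 1.01$ warns rather than fails, matching library use.  Chains run
sequentially from seeds derived from one seed, so results are exactly
reproducible.

Starting values: intercepts at log crude outcome ratios (for case
fatality, crude mortality over crude prevalence), slopes and scores at
zero, hyperparameters at prior means.

## Model checking

**Conflict p-values.**  For each record, the direct evidence about its
probability is the conjugate Beta$(y+0.5,\,n-y+0.5)$ posterior (Jeffreys
prior); the indirect evidence is the model posterior for the same
quantity.  The tail probability $q = \Pr(p < p^{full})$ is computed by
averaging the Beta CDF over the posterior draws of $p^{full}$ — a
Rao-Blackwellised estimate chosen over draw-vs-draw comparison to remove
Monte Carlo noise — and the two-sided conflict p-value is $2\min(q, 1-q)$.
Under a correctly specified model these are approximately uniform; the
acceptance suite checks the rate of $p < 0.05$ over 2000 simulated records
against [3%, 7%].

**LOO ELPD.**  Leave-one-out expected log predictive density via
Pareto-smoothed importance sampling, implemented in-package (the pointwise
log-likelihood matrix comes with every fit): the upper tail of the raw
importance ratios is replaced by expected order statistics of a fitted
generalised Pareto distribution and truncated at the raw maximum, with the
tail-shape $k$ returned per observation as a reliability diagnostic.
Degenerate weight vectors fall back to the plain log predictive density,
flagged.

## Data preparation

* **Estimate → counts.**  A published estimate with a 95% interval is
  inverted to the $(y, n)$ whose Beta$(y+0.5,\,n-y+0.5)$ interval best
  matches the published bounds in squared error, with
  $y = \mathrm{round}(\hat p\, n)$.  The match is tolerance-based by
  design — published intervals rarely come from an actual binomial
  experiment — and the tests require the reconstructed interval width to
  agree within 10%.
* **Age-group disaggregation.**  Five- or ten-year group counts are split
  into single years by a penalised composite-link model: latent log yearly
  counts with a second-order difference penalty, fitted to group totals by
  penalised Poisson scoring, penalty weight chosen by AIC over a log-spaced
  grid.  Yearly values are rounded by largest-remainder apportionment
  within each group, so group totals are conserved *exactly* (integers
  included); numerators are capped at denominators with any lost mass
  restored within the group.  Terminal open-ended groups are closed at the
  model's maximum age.
* **Remission from survival.**  Ten-year survival $s_{10}$ of a cancer is
  read as "remission happened within ten years", giving the annual
  remission probability $r = 1 - (1 - s_{10})^{1/10}$.
* **Area aggregation** sums numerators and denominators within regions.

## The synthetic-fixture module

`scenario_config()` / `make_true_rates()` / `simulate_dataset()` generate
datasets with exactly the statistical structure the model assumes, from
known truth — the test bed for recovery, calibration and engine-agreement
checks.  Defaults were chosen once, for realism, and define the study
conditions of the acceptance suite:

* true curves are log-quadratic in scaled age — deliberately *not* in the
  spline family the model fits — with incidence rising from about
  $2\times10^{-4}$ at age 0 to $2\times10^{-2}$ at age 100 (flattening at
  old age) and case fatality from about $5\times10^{-3}$ to $0.17$
  (steepening), the shape of a major chronic disease;
* denominators of $5\times10^4$ per year of age for incidence and
  mortality and $10^3$ for prevalence surveys, decaying exponentially
  above age 90 — so the "uncertainty is high beyond age 90" behaviour of
  real data is exercised;
* hierarchical scenarios draw area intercepts from
  $N(b_1, \lambda_1^2)$; gendered scenarios add male offsets of $0.3$
  (incidence) and $0.4$ (case fatality) on the log scale, with optional
  area-specific departures for interaction truths.

What passing these tests shows — and what it does not.  The generator
simulates independent binomial counts from the model's own structure, so
recovery and calibration results certify the inference machinery, not the
model's adequacy for real data, where the four outcome series may come
from different populations, overlapping sources induce correlated errors,
and published estimates are themselves model outputs.  The conflict
p-value and LOO tools exist precisely to probe those failures on real
data.

## Problem sizes and numerical choices

The test suite runs at reduced but non-trivial sizes chosen to exercise
every pathway: single-population fits at $A = 100$, $K = 10$ (the package
defaults); the replicate recovery study uses 50 simulated datasets with
warm-started mode fits; engine agreement uses 4 chains of 15,000 retained
iterations; the gender model comparison uses $K = 7$ with two areas.
Unit tests use $A = 40$–60 and $K = 5$–6.

Numerical details worth recording: log rates are capped at 23 (rates
$\approx 10^{10}$/year) so unconstrained samplers meet huge-but-finite
densities rather than overflow; probabilities inside fitting and
importance-weight paths are clamped to $[10^{-300}, 1 - 10^{-15}]$, while
the exported likelihood reports an honest $-\infty$ (flagged, never an
exception) for structurally impossible records; the matrix-exponential
coefficients switch to series evaluation below $v < 10^{-6}$; and the
occupancy recursion treats living probabilities below $10^{-280}$ as
extinct.

## Known limitations

* Case fatality independent of time since onset (the Markov assumption);
  diseases modelled independently, with no competing-risk coupling and no
  other-cause mortality.
* No spatial correlation between areas and no covariates beyond age,
  gender and area; between-area variation in remission is not modelled.
* Time trends are fixed inputs, not estimands.
* $\lambda_0^{male}$ is fixed, not estimated.
* The Laplace engine's intervals condition on modal smoothness SDs and so
  omit that component of uncertainty; the sampling engine retains it.
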