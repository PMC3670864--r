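---
title: "Statistical population reconstruction for two-age-class harvest data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical population reconstruction for two-age-class harvest data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sprgame)
```

## The problem

Many small-game species (turkeys, pheasants, squirrels, rabbits) are
monitored almost entirely through their harvest.  Check-station or
hunter-survey data give, for each year, the number of animals taken in two
distinguishable age classes: young-of-the-year ("juveniles") and everything
older (the pooled adult class, A+).  Statistical population reconstruction
(SPR) turns this age-at-harvest table, together with a measure of annual
hunter effort and a small amount of auxiliary data (here, radiotelemetry),
into likelihood-based estimates of abundance, natural survival, and harvest
vulnerability.

`sprgame` implements a mixed-effects SPR for exactly this two-age-class
setting, with a second-stage Horvitz–Thompson (HT) abundance estimator, a
stochastic Leslie-matrix simulator for method evaluation, and a two-season
variant applied to the packaged East Ozarks (Missouri) male wild turkey
dataset.

## The model

**Demographic process.**  In year $i$, an animal alive at the start of the
harvest season is harvested with probability
$$P_i = 1 - \exp(-c\, f_i\, e^{\nu_i}),$$
the classical catch-effort form: $c$ is the harvest vulnerability
coefficient, $f_i$ the hunter effort, and $\nu_i \sim N(0, \sigma_c^2)$ an
annual random effect acting multiplicatively on $c$.  Animals that escape
the harvest survive the following nonharvest season with probability
$$s_i = \operatorname{logit}^{-1}\!\big(\operatorname{logit}(\bar s) + \delta_i\big),
\qquad \delta_i \sim N(0, \sigma_s^2).$$
The random effects absorb unmeasured environmental variation (weather, mast
crops, disease) that moves whole-population rates from year to year; both
effects are shared by the age classes within a year.

**Cohort structure.**  With a pooled adult class, a study of $Y$ years
involves $Y+1$ cohorts: the adults already alive at the start (cohort 1),
the juvenile cohort entering each year, and the final year's juveniles.
`build_cohort_layout()` enumerates the cells each cohort occupies; the
adult cell of year $i$ pools every cohort alive then.  Given cohort entry
abundances, `expected_harvest()` propagates each cohort along its diagonal
(`harvest at` $N P_i$, `survive at` $(1-P_i) s_i$, repeat), accumulating the
pooled adult expectations additively.

**Conditional likelihood.**  The age-at-harvest likelihood conditions on
having been harvested: the probability that an ever-harvested animal falls
in a given cell is the ratio of that cell's expected count to the total.
Because per-cohort adult counts are unobservable under pooling, the product
of per-cohort conditional likelihoods is implemented in its chain-rule
equivalent form — a single multinomial over all $2Y$ observable cells with
probabilities proportional to the pooled expected counts
(`conditional_cell_probs()`, `cohort_loglik()`).  The two edge cohorts
(first-year adults, last-year juveniles) carry no timing information and
enter as plain binomial components (`edge_cohort_loglik()`).  Auxiliary
components are added on the log scale: the radiotelemetry binomials
(`telemetry_loglik()`), optionally the catch-effort binomial of total
harvest against total abundance (`catch_effort_loglik()`), and the normal
random-effects densities (`re_penalty()`).

**Abundance.**  Two families differ in how abundance enters.  The AA
("absolute abundance") family estimates every cohort entry abundance as a
likelihood parameter.  The HT family removes those $Y+1$ parameters and
instead evaluates each cohort's entry abundance as the Horvitz–Thompson
estimator $\hat N = x / P(\theta)$ at the current parameter values inside
the likelihood, with annual totals
$\hat N_i = x_{iJ}/P_{iJ} + x_{iA}/P_{iA}$ reported afterwards.  We
deliberately keep the HT abundances as smooth functions of the parameters
rather than freezing them as data between optimization rounds: when frozen,
the plug-in binomial terms anchor the harvest probability at its previous
iterate and the alternation need not converge (we observed it drifting off
the truth on zero-variation data), whereas the inline form is a single
well-behaved maximization.  Only the catch-effort auxiliary, when enabled,
holds its annual abundances fixed as data and updates them in an EM-style
outer loop (relative change in total abundance below $10^{-6}$, at most 100
rounds).

**Marginal likelihood.**  Random effects are integrated out by the Laplace
approximation.  The production path writes the joint likelihood as a
compiled TMB template (TMB is the successor of the ADMB system classically
used for this family of models) and lets its automatic differentiation
machinery locate the inner mode; the outer optimization is bounded
quasi-Newton (`nlminb`) on transformed scales — logit survival, log
vulnerability, log standard deviations — so all constraints are implicit.
A pure-R reference implementation of the same objective
(`spr_joint_negloglik()`) and a generic Newton/finite-difference Laplace
routine (`laplace_marginal()`) are exported; the test suite checks the two
paths against each other and against closed-form Gaussian marginals.

**Uncertainty.**  Parameter standard errors come from the inverse Hessian
of the marginal negative log-likelihood.  Abundance variance adds two
pieces: the delta-method variance of $\hat N(\hat\theta)$ (including
random-effect uncertainty) and the second-stage binomial component
$\sum_a x_{ia}(1-\hat P_{ia})/\hat P_{ia}^2$ of the HT estimator.
Intervals are symmetric normal, $\hat N \pm 1.96\,\mathrm{SE}$, matching
the symmetric intervals reported for this model family.  When a variance
component is estimated at its lower bound (common on zero-variation data),
the marginal Hessian can be singular; the implementation then profiles the
stuck component out at the boundary and reports the remaining standard
errors, with a warning.

### Numerical choices

* Starting values: $\bar s = 0.5$, harvest rate 0.3 at mean effort,
  $\sigma = 0.1$, cohort abundances harvest/0.3.  These are conventions,
  not data-derived quantities; fits are deterministic and reproducible.
* Random-effect standard deviations are bounded to $[10^{-3}, 3]$ on the
  log scale; $10^{-3}$ operationally means "no interannual variation".
* Binomial components with continuous (HT or estimated) sizes use the
  gamma-function form of the binomial coefficient; sizes below $x+1$ are
  softly clamped with a quadratic penalty so optimizers recover rather
  than hitting undefined likelihoods.  Impossible configurations in the
  R reference path return a $-10^{10}$ sentinel with a warning.
* The conditional multinomial retains its combinatorial constant so AIC
  values are comparable across models (the constant cancels in all
  rankings and likelihood-ratio statistics).

## The AA_FE instability

The fixed-effects absolute-abundance model estimates $Y+1$ cohort
abundances from the conditional likelihood, in which only abundance
*ratios* appear.  Without the catch-effort auxiliary the absolute scale is
informed solely by the two edge binomials, and optimization is erratic;
`model_spec()` therefore refuses `AA` + `FE` without catch-effort, which
mirrors how that family must be run in practice.

## The simulator

`simulate_population()` emulates the Monte Carlo design used to evaluate
these models: a two-class stochastic Leslie matrix with a single survival
probability (0.50) and a single vulnerability giving a 0.40 harvest rate at
mean effort; fecundity $e^2 \approx 7.39$ young per adult (the value whose
$\pm 2\sigma$ lognormal bands reproduce the design's printed endpoints);
binomial harvest and binomial nonharvest survival drawn separately per age
class; and Poisson recruitment linear in the number of breeding adults.
Stationarity requires $1/((1-P)s) - 1 = 7/3$ effective recruits per adult,
so a fixed pre-recruitment survival factor $7/3 / e^2 \approx 0.316$ scales
the fecundity; with it the expected growth rate is exactly 1 (the noiseless
projection is checked to drift under 1% across 1000 years).  The population
is evolved 75 years from a stationary start near 40,000 animals and the
final 25 years are kept.  A common $\sigma \in \{0, 0.1, 0.2, 0.3\}$ is
applied to survival (logit scale), vulnerability and fecundity (log scale).
Radiotelemetry tags 30 animals per year in the middle of the kept series
(year 12, or years 9–14 for the six-year design).

Choices the design leaves open, fixed here once: effort is constant in
expectation with mild lognormal jitter (cv 5%) — real hunter-trip series
are never exactly flat; the robustness scenarios layer a linear
$\pm 0.2$-logit survival trend, or recruitment pulses of $\times 1.5$ every
fourth year with reciprocal crashes in the alternating even years, on top
of low-variation draws.  One master seed drives everything; replicate $r$
of a study uses seed $+ r$.

Two honest caveats about what passing simulations show.  First, the effort
jitter makes total abundance a slow random walk (the per-year growth noise
it induces accumulates over 75 years), so individual realizations wander
around 40,000 rather than pinning it; estimators are always compared
against their own realization's truth.  Second, the simulator shares the
fitted model's structural skeleton (binomial harvest, logit/log-normal
effects), so good performance here demonstrates internal consistency and
robustness to the specific violations simulated (trends, pulses), not
robustness to every failure mode of real harvest data — age misclassification,
non-binomial harvest contagion, and effort measurement error are outside
its vocabulary.

## The Monte Carlo study

`run_mc_study()` crosses model families with variation levels, telemetry
designs, catch-effort usage and scenarios, fitting each simulated
replicate and reporting the across-year mean of per-year median relative
bias (MRB), aggregate 95% interval coverage over (replicate, year) pairs
(both aggregation orders are recoverable from the per-year attribute), and
the count of failed fits.  The packaged tests run 100 replicates per cell
(60 for the robustness scenarios); the original-scale 1,000-replicate grid
is reachable through the same interface by raising `n_reps`.

## The turkey model

The East Ozarks application extends the machinery to a two-season year
(`fit_turkey()`): a spring permitted harvest of males with
survey-estimated effort (units of $10^4$ hunter trips; the column times
$10^4$ is confirmed by the printed 2001 value of 76,457 trips), a fall
harvest treated as a known removal, and spring non-permittee removals
(landowner and youth seasons) occurring before the permitted season.  Age
classes get separate vulnerabilities $c_J, c_A$ with separate annual random
effects; a single annual natural survival $s$ spans the 22-week summer and
24-week winter intervals.

Event order within a year, fixed from the species' life history: spring
NPR removals → spring permitted harvest → juveniles graduate to adults →
summer survival → fall harvest (known removal) → winter survival → next
spring.  Juvenile availabilities are anchored by their HT estimates at
entry; the adult pool starts at its 1996 HT availability and is propagated
through the chain, so survival is identified by the cumulative adult
dynamics.  Fall *juvenile* removals never enter: they are confounded with
poult production, for which no data exist.  Spring abundance is
$\hat N_i = x_{iJ}/\hat P_{iJ} + x_{iA}/\hat P_{iA} + \text{spring NPR}_i$;
treating the removals as known constants slightly understates abundance
variance.

**Interval-survival parameterization.**  `interval_survival()` defaults to
scaling by the 46 survival weeks (22 + 24), under which summer and winter
recompose the annual probability exactly.  The fitted model instead scales
by the 52-week calendar year, so the likelihood exposes $s^{46/52}$ of
annual natural mortality — the harvest seasons themselves carry no natural
mortality term.  We adopted /52 after a consistency analysis: under /46,
no defensible variant of the removal chain reconciles the published annual
survival with the published data (the deterministic adult balance of the
data table implies 0.61–0.68 at the published harvest rates), while under
/52 the fitted annual value and its confidence interval match the
published ones closely.  Under /52 the composition identity becomes
$s_S \cdot s_W = s^{46/52}$.

Model selection (`turkey_model_selection()`) ranks the fixed-effect
structures by AIC and tests each variance component on its boundary with
likelihood-ratio tests against the 50:50 mixture $\chi^2_0:\chi^2_1$
reference (`mixture_chisq_pvalue()`; the p-value at a zero statistic is 1
under the convention that the mixture mass at zero can never reject).  On
the packaged data the class-specific-vulnerability structure wins and the
survival variance is unsupported, so the selected model carries random
effects on the two vulnerabilities only.

A one-year-lagged comparison of estimated spring juvenile abundance with
the poult-to-hen survey index (`poult_hen_comparison()`) gives an external
consistency check: the poults counted in early summer are the next
spring's one-year-olds.

## Problem sizes and runtimes

The packaged tests and the acceptance script use 25-year simulated studies
with 100 replicates per Monte Carlo cell (200 for the two coverage cells,
where the extra precision matters; 60 for the robustness scenarios); a
single HT_RE fit takes well under a second, the full turkey
fit (with model selection) a few seconds, and each Monte Carlo cell under
a minute on one core.  These sizes were chosen so the whole evaluation
runs comfortably at a desk; all of them scale up through function
arguments without code changes.

## Known limitations

* The fixed-effects absolute-abundance family (`AA_FE`, with catch-effort)
  reproduces the qualitative verdict against it — severe interval
  undercoverage whenever interannual variation is present — but in this
  implementation it also shows substantial positive abundance bias: with
  free cohort abundances the conditional likelihood has a near-ridge along
  constant $(1-P)s$ that overdispersed data resolve toward low harvest
  probability and high abundance.  Treat its point estimates as
  unreliable; it is retained as a comparison baseline, not as an
  estimator.

* Random effects are independent normals; correlated or multivariate
  structures (e.g. survival–vulnerability covariance) are not implemented.
* No covariates on demographic rates, no spatial effects, no age structure
  within the pooled adult class, and no overdispersed harvest likelihoods.
* Effort is treated as known; its published standard errors are carried as
  metadata only, so abundance intervals omit effort-measurement error.
* The HT abundance estimates for years far from the telemetry window rely
  on the random-effect shrinkage being correctly specified; coverage in
  the simulations degrades gracefully (toward the mid-80s percent) as
  interannual variation grows, and the same should be expected in
  applications.
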