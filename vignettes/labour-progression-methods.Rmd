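---
title: "Modelling first-stage labour progression from sparse dilatation exams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling first-stage labour progression from sparse dilatation exams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

During the first stage of labour the cervix dilates from a few centimetres to
10 cm (full dilatation). Clinically it is monitored by occasional vaginal
examinations — typically only three per woman — each recording the dilatation
rounded down to an integer centimetre. Two quantities drive labour-ward
decision making: the *sojourn time* at each centimetre (how long the cervix
stays at 4 cm before reaching 5 cm, and so on) and the *cumulative duration*
from the dilatation at admission to full dilatation. The widely used
partograph alert line assumes dilatation of at least 1 cm/hour; women falling
behind it are often augmented with oxytocin or delivered by cesarean.

Neither quantity is observed directly. The time a given centimetre is reached
lies somewhere between two exams (interval censoring), exam schedules are
irregular and sparse, and women are admitted at different dilatations. This
package implements three complementary estimation strategies for exactly this
observation pattern, together with a calibrated synthetic-cohort generator so
the whole pipeline is testable end to end without patient data.

## Interval-censored log-normal survival analysis

For each woman the time of reaching level $d$ (hours since admission) is
bracketed: the lower bound is the last exam showing less than $d$, the upper
bound the first exam showing $d$ or more. Two conventions close the system:

* the admission exam is taken as the moment the admission level is reached
  (time 0, exact). This is what makes the cumulative table's single-transition
  rows coincide with the corresponding sojourn fits, and it matches the
  empirical observation that cumulative durations from admission at level
  $a$ to $a{+}1$ are almost identical to the $a \to a{+}1$ sojourn estimates;
* the 10-cm time is recorded exactly (full dilatation is always confirmed),
  and there is no 9-cm state — 8 to 10 cm is a single transition, because
  9 cm is essentially never charted.

Sojourn brackets for $d \to d'$ combine the two reaching brackets
conservatively: $L = \max(0, L' - U)$, $U = U' - L$, exact when both reaching
times are exact. These are the widest bounds certain to contain the truth;
the likelihood below is therefore slightly conservative for sojourns (see
*Limitations*), while for cumulative durations (admission anchored at an
exact zero) the brackets are a textbook non-informative inspection scheme.

Durations are assumed log-normal. The fit maximises

$$\ell(\mu,\sigma) = \sum_{\text{exact}} \log \phi\!\left(\tfrac{\ln t - \mu}{\sigma}\right) - \ln(t\sigma)
  + \sum_{\text{interval}} \log\!\left[\Phi\!\left(\tfrac{\ln U - \mu}{\sigma}\right) - \Phi\!\left(\tfrac{\ln L - \mu}{\sigma}\right)\right],$$

with $L = 0$ handled as left censoring and $U = \infty$ as right censoring.
Optimisation is over $(\mu, \log\sigma)$ (Nelder–Mead then BFGS, objective
tolerance $10^{-8}$ or better, multistart from interval-midpoint moments).
Reported percentiles are $\exp(\mu + \sigma z_p)$ for $p = 0.05, 0.5, 0.95$.

```{r survival-example}
library(labourflow)
cohort <- generate_cohort(cohort_config(n = 2000), seed = 1)
included <- apply_inclusion(cohort)$cohort
parity0 <- stratify(included, "parity_group")[["parity_group=0"]]
sojourn_duration_table(parity0)
cumulative_duration_table(parity0)
```

## Progressive multistate Markov model

The second approach treats the exam series as panel observations of a
continuous-time Markov chain over the states 2, 3, 4, 5, 6, 7, 8, 10 cm and
an absorbing delivery state D. The chain is progressive and unidirectional:
each state has a single intensity $q_r$ to its successor, so the intensity
matrix $Q$ is upper bidiagonal and $P(t) = \exp(tQ)$ solves the forward
equations for the time-homogeneous chain. Snapshot pairs contribute
$\ln P(\Delta t)[r, s]$; the exactly-timed entries into 10 cm (full
dilatation) and D (delivery) contribute density terms
$\ln [P(\Delta t)\,Q]_{r,s}$. The log intensities are maximised by BFGS, with
standard errors from the numerical Hessian.

Two numerical choices matter. First, `transition_probability()` uses the
dense matrix exponential, but inside the optimiser the likelihood evaluates
occupancy probabilities with the closed-form hypoexponential expression for a
bidiagonal generator (a sum of exponentials with Vandermonde-type weights),
vectorised over time gaps; it falls back to the matrix exponential whenever
two rates come within $10^{-7}$ of each other, where the closed form loses
precision. The two routes agree to $10^{-10}$ and the exponential itself is
checked against direct ODE integration in the tests. Second, percentiles are
taken from simulated trajectories rather than the analytic exponential
quantiles, matching how such tables are produced in practice: trajectories
advance on a fixed 5-minute grid (0.0833 h) with one-step matrix $P(step)$,
so the smallest positive reportable sojourn is one step (0.08 h) and a state
skipped within a tick contributes a zero — exactly the pattern of 0.08 and
0.00 entries such tables show. The analytic quantiles remain available
through `exponential_sojourn_quantiles()` as a cross-check.

The average labour curve anchors every simulated trajectory at full
dilatation and averages the occupied dilatation $\tau$ hours earlier, over
the trajectories still in labour at that offset; it ends at exactly 10 cm at
$\tau = 0$ and is nonincreasing in $\tau$.

One Q is fitted per parity group, with the admission-state distribution taken
from the stratum's first exams; admission-specific tables vary the admission
distribution, not the intensities. Time-homogeneity (constant Q) is assumed
throughout.

```{r markov-example}
panels <- panels_from_cohort(parity0)
fit <- fit_intensities(panels)
traj <- simulate_markov_cohort(fit$Q, c("3" = 0.2, "4" = 0.5, "5" = 0.3),
                               n = 50000, seed = 2)
markov_sojourn_table(traj)
average_curve_markov(traj)
```

## Logistic growth mixed model

Because women enter observation at different dilatations but all reach 10 cm,
observations are anchored in reverse time: $t = 0$ at full dilatation,
negative before it (the reflected positive axis is presentation only; fitting
uses the signed axis). Dilatation follows a three-parameter logistic,

$$y_{ij} = \beta_0 + \frac{\beta_1}{1 + \exp(-(t_{ij} - (\beta_2 + b_i)))} + \varepsilon_{ij},
  \qquad b_i \sim N(0, \sigma_b^2),$$

with $\beta_0$ the level as $t \to -\infty$, $\beta_1$ the asymptotic height,
$\beta_2$ the population inflection point and a per-woman random shift $b_i$
of the inflection. A residual SD $\sigma_\varepsilon$ is part of the
measurement model — the mean equation alone admits no likelihood — so the
model has five parameters. The marginal likelihood integrates $b_i$ out per
woman by adaptive Gauss–Hermite quadrature (21 nodes by default, nodes and
weights from the Golub–Welsch eigenvalue construction; the per-woman mode is
found by a damped Newton iteration with a Gauss–Newton curvature fallback).
Against brute-force integration the 21-node rule is accurate to about
$10^{-5}$ per woman; refining to 41 nodes changes the total log-likelihood
only in the sixth significant digit. With $\sigma_b = 0$ the fit reduces
exactly to pooled nonlinear least squares, which is tested.

Initialisation: $\beta_0 = 0$, $\beta_1 = 10$, $\beta_2$ at half the 5th
percentile of the signed times, $\sigma_b = 1$, $\sigma_\varepsilon = 0.5$.
A collapse of $\sigma_b$ toward zero is reported via a boundary flag, never
silently clipped. Population curves are drawn over the observed time range
only; the fitted inflection typically falls outside that range (labour data
carry no deceleration phase), which the curve object flags.

## The synthetic cohort generator

The generator is first-class code: it defines the conditions under which
every downstream estimator is validated.

* **Sojourn laws.** Per parity group, each 1-cm transition (plus 8→10) gets
  an independent log-normal sojourn with $\mu = \ln(\text{median})$ and
  $\sigma = (\ln p_{95} - \mu)/z_{0.95}$ inverted from the published
  survival-analysis median/95th pairs, so re-evaluating the quantile
  function reproduces those pairs exactly. Independence across transitions is
  the simplest structure consistent with the marginal fits. The 2→3 cm
  transition is not tabulated anywhere; its median is set 20% above the
  3→4 cm median with the same log-SD (early labour is at least as slow).
* **Admission.** The admission dilatation (2–6 cm) follows the published
  admission-stratum sizes, with the 2-cm mass as the stratum remainder —
  consistent with a printed 10th percentile of 2 cm. Women present at the
  moment they reach their admission level; paths notionally start at 2 cm.
* **Exam schedule.** The timing of exams is not standardised in practice and
  no schedule is published; gaps are truncated normal (mean 2.5 h, SD 1 h,
  minimum 0.5 h), with at least one examination between admission and the
  full-dilatation confirmation. Under this schedule the cohort-wide median
  number of first-stage assessments is 3, matching the printed summary;
  nulliparous women (longer labours) centre on 3–4 and the upper tail is
  heavier than the printed 90th percentile of 5, a consequence of the
  log-normal duration tails. The 10-cm confirmation is recorded exactly and
  not counted as a first-stage assessment. A second-stage (10 cm to
  delivery) log-normal with parity-dependent median (40/20/15 minutes)
  provides the delivery timestamp that identifies the chain's absorbing
  transition.
* **Oxytocin.** Flags are drawn at the published per-parity rates (40.0%,
  29.8%, 26.7%), independent of the sojourns by default. A coupling switch
  instead flags the slowest `rate` fraction by true 3–5 cm sojourn,
  emulating the clinical selection of slow labours for augmentation that the
  sensitivity analysis probes; flags never alter the sojourns themselves.
* **Exclusions.** Records triggering each selection-chain criterion (preterm
  or post-term gestation, non-vertex presentation, induced onset, prior
  scar, intrapartum cesarean, severe adverse outcome, malformation, fewer
  than two assessments) are planted at configurable rates whose defaults
  mirror the overall screening attrition (~37%); exact per-criterion counts
  are kept as bookkeeping so the filter chain can be tested against a known
  answer. Cohort sizes are specified as analysis-eligible counts, so
  included stratum sizes are exact.

What the generator deliberately does **not** emulate: measurement error and
inter-observer variation in dilatation assessment, dependence between
consecutive sojourns within a woman, exam scheduling that reacts to progress,
time-varying augmentation effects on the sojourns themselves, and any
covariate structure (country, age, BMI). Passing tests therefore demonstrate
that the estimators recover the generating process under the stated
observation pattern — not that real labour satisfies these assumptions.

## Validation design and known limitations

* **Sojourn brackets are conservative.** The differencing
  $[\max(0, L'-U),\; U'-L]$ widens the true inspection interval, and for fast
  transitions observed under sparse (2.5 h) schedules most sojourn data
  collapse to left-censored $[0, U]$ intervals: the 6→7 and especially 7→8 cm
  fits are then biased low (this is visible in the shrinking-interval test,
  which compares 2 h against 0.1 h schedules). Parameter-recovery validation
  therefore runs under a frequent-assessment regime (15-minute gaps), where
  the construction is near-well-specified and all transitions recover
  $(\mu, \sigma)$ within ±0.1 at n = 2000. Cumulative durations do not
  suffer from this: their brackets come straight from the reaching times
  with an exact admission anchor. In consequence, cumulative tables produced
  from sparse schedules are trustworthy throughout, while sojourn estimates
  of the fast transitions inherit some downward bias — the main expected
  source of deviation when comparing against published sojourn tables.
* **Two models, two answers.** The survival approach fits log-normal
  sojourns; the Markov model forces exponential sojourns with a common
  intensity per state. On the same data their medians can legitimately
  differ by tens of percent, most visibly for the slow early transitions;
  agreement within a broad band (~30% mid-labour) is a sanity check, not an
  equality.
* **Problem sizes.** The test suite validates at n = 2000 women per
  estimator (500 for the mixed model), and the acceptance script analyses
  one full-size cohort (5606 included women) with 50,000 simulated
  trajectories — sizes chosen so each estimator's Monte-Carlo error is well
  inside the tolerances being asserted.
* **Attribution order.** A record failing several exclusion criteria is
  attributed to the first failing one in the documented order; the included
  set is order-invariant (tested), only the per-criterion counts move.
* **Alert line.** The crossing fraction anchors the 1 cm/h line at the first
  exam at or above 4 cm and flags any later exam strictly below it; with the
  calibrated sojourn laws (median > 1 h per cm below 5 cm) a substantial
  fraction of nulliparous women cross, which is the behaviour the partograph
  debate revolves around.
* **Out of scope.** Covariate-dependent intensities, time-inhomogeneous
  chains, backward transitions, polynomial curve models (known to behave
  incompatibly with labour data), second-stage physiology, and any clinical
  recommendation.
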