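---
title: "Estimating LE and HALE: Sullivan life tables and illness-death models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating LE and HALE: Sullivan life tables and illness-death models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`idhale` estimates life expectancy (LE) and health-adjusted life
expectancy (HALE) for a chronic disease — the motivating application is
type 2 diabetes mellitus (T2DM) in a rural elderly population — by two
complementary routes that use different kinds of data and rest on
different assumptions. This vignette explains both models, the synthetic
cohort generator used to validate them, the numerical choices, and the
limitations a user should keep in mind.

## The two estimation routes

**Sullivan route (period, cross-sectional).** An abridged life table is
built from an age-grouped mortality schedule by Chiang's method, and the
person-years of each age interval are discounted by the proportion of
that interval's population living with the disease:

$$\mathrm{HALE}(x) = \frac{1}{l_x} \sum_{y \ge x} (1 - {}_n\pi_y)\,{}_nL_y,$$

where $l_x$ is the number of survivors at exact age $x$, ${}_nL_y$ the
person-years lived in the interval $[y, y+n)$, and ${}_n\pi_y$ the
disease prevalence in that interval; the sum runs to the terminal
open-ended interval. The route needs only a mortality schedule and a
prevalence survey, but it is a period measure: it assumes the current
prevalence and mortality schedule apply to a synthetic cohort, and it
ignores the dynamics of disease onset.

**Multistate route (longitudinal).** A three-state illness-death
continuous-time Markov model — disease-free (1), diseased (2), dead (3),
with transitions 1→2, 1→3, 2→3 and no recovery — is fitted by maximum
likelihood to two-wave panel records. Transition intensities are
Gompertz, log-linear in age with proportional covariate effects:

$$q_{rs}(a, z) = \exp\{\alpha_{rs} + \xi_{rs}(a - a_0) + \beta_{rs} z\},$$

with reference age $a_0 = 65$ and $z$ an indicator of male sex (female
is the reference level). Total and state-specific life expectancies are
obtained by integrating the transition probabilities,
$e_{rs}(a) = \int_0^{\omega-a} P_{rs}(a, a+u)\,du$; HALE from the
disease-free state is $e_{11}$ and total LE is $e_{11} + e_{12}$.

### What each route actually estimates

The two routes do not target exactly the same estimand, and the package
makes the distinction explicit rather than blurring it. Sullivan HALE is
computed on the prevalence-mixed period population: in a stationary
population it estimates the *marginal* healthy expectancy
$(1-\pi_x)\,e_{11} + \pi_x \cdot 0$, averaging over the baseline state
distribution at the starting age. The multistate $e_{11}$ conditions on
being disease-free at the starting age. The two coincide when prevalence
at the starting age is small and diverge roughly in proportion to
$\pi_x$ otherwise. `marginal_life_expectancy()` converts multistate
output to the marginal scale so like can be compared with like; the test
suite verifies both the tight marginal agreement and the
low-prevalence conditional agreement on simulated cohorts. Headline
multistate outputs are reported per starting state, which avoids
over-claiming what a prevalence-based Sullivan table can identify.

## The panel likelihood

Living-state transitions are observed only at the two visits, so onset
times are interval-censored; deaths are ascertained with exact ages but
the state immediately before death is unknown. Each subject contributes

* alive at follow-up: $P_{s_0 s_1}(a_0, a_1)$, which integrates over all
  compatible onset times inside the interval;
* death at exact age $a_d$: $\sum_{r \in \{1,2\}} P_{s_0 r}(a_0, a_d)\,
  q_{r3}(a_d)$ — a density term summing over the unknown pre-death
  state;
* lost to follow-up: excluded by default, mirroring a design that drops
  them from the longitudinal analysis. A `censor_at_entry` option keeps
  them as observed only at baseline; a record observed at a single time
  point contributes probability one, so the two options give the same
  likelihood — the flag exists to make the handling explicit. Loss is
  assumed missing completely at random either way.

A recorded 2→1 transition is structurally impossible; the likelihood
returns $-\infty$ and names the offending records. Maximisation is
quasi-Newton (BFGS) on the unconstrained log-intensity scale with
numerical gradients; the covariance is the inverse of the numerically
differentiated observed information. Non-convergence and
non-identifiable configurations (no deaths, or no incident cases) are
reported explicitly, never silently.

## Transition probabilities: numerics

For this progressive model the generator is upper triangular and its
exponential has a closed two-exponential form. Over a step with
integrated hazards $H_{12}, H_{13}, H_{23}$ (closed-form Gompertz
cumulative hazards, so each step uses the exact integral of the
generator, not a quadrature of it):

$$P_{11} = e^{-(H_{12}+H_{13})},\quad P_{22} = e^{-H_{23}},\quad
P_{12} = H_{12}\, e^{-H_{23}}\,\varphi(H_{12}+H_{13}-H_{23}),$$

with $\varphi(d) = (1-e^{-d})/d$ evaluated through `expm1` so the
eigenvalue-collision limit $d \to 0$ is numerically stable. Age-constant
models are therefore computed exactly in a single step. Age-varying
models multiply per-subinterval exponentials on a grid of width at most
`grid_step`; the only error is the non-commutativity of the generator
across subintervals, which is $O(h^2)$ with a very small constant
(about $10^{-6}$ at the default likelihood grid of 0.25 y for realistic
Gompertz slopes, and about $10^{-9}$ at 0.005 y, where the test suite
compares against a high-accuracy ODE solve of the Kolmogorov forward
equations at $10^{-8}$).

Life expectancies use the trapezoid rule on a 0.1-year grid (errors
around $10^{-4}$ y for realistic hazards; halving the step is verified
to move results by less than $10^{-3}$ y). The integral is truncated at
`max_age` (default 110 y); if more than $10^{-3}$ of survival mass
remains there, a warning reports the residual so the user can raise
`max_age`. Optimiser defaults: `reltol` $10^{-10}$, maximum 500
iterations, convergence report with gradient norm attached to the fit.

## The synthetic-cohort generator

Real counterparts of the data (a national cause-of-death surveillance
schedule; individual cohort records available only on request) cannot be
redistributed, so the generator produces structurally faithful
substitutes from a known illness-death process and doubles as the truth
source for validation:

* **Burn-in.** Everyone starts disease-free at `burn_in_start_age`
  (default 50), fifteen years before the youngest enrolment age, so
  baseline prevalence *emerges* from the process rather than being
  assigned, and onset-age censoring at enrolment is structurally
  realistic.
* **Event times** are drawn by inverse transform on the closed-form
  Gompertz cumulative hazard; competing onset and death risks from the
  disease-free state are resolved by taking the earlier of the two event
  times.
* **Left truncation.** Trajectories dead before the subject's drawn
  baseline age (uniform on 65–79) are redrawn, conditioning enrolment on
  survival exactly as recruitment does.
* **Follow-up** occurs `gap_mean` $\pm$ uniform jitter years after
  baseline (default $3 \pm 1$, matching a multi-year enrolment window
  with a single follow-up wave); deaths before follow-up keep their
  exact ages; surviving subjects are lost completely at random with
  probability 0.122 (chosen so that roughly 11.5% of the cohort —
  1,185 of 10,318 in the reference accounting — is lost, given that the
  deceased are never "lost").
* **Reproducibility.** A master seed spawns a deterministic per-subject
  substream, so cohorts are bit-identical across runs and a subject's
  record does not depend on cohort size.

The default intensities were calibrated once against the reference
cohort's published margins: baseline prevalence near 12.8% overall and
higher in women (onset effect of male sex $\beta_{12} = -0.37$), higher
male mortality ($\beta_{13} = \beta_{23} = 0.40$), mortality about 60%
higher with disease than without, and remaining life expectancy at 65
of roughly 20 years for women and 17 for men. One published pair of
figures cannot be matched simultaneously under a time-homogeneous
Gompertz onset: the reported baseline prevalence (12.84% after ~20
years of onset exposure) and the reported incident count (394 over a
~3-year gap) imply onset rates that differ by roughly a factor of two.
The defaults prioritise baseline prevalence; simulated incident counts
are correspondingly lower than the reported one. This is a property of
the generator's homogeneity assumption, not of the estimators.

What the generator does **not** emulate: informative (non-random)
dropout, competing chronic diseases, calendar-period effects,
diagnostic misclassification, and any non-Gompertz age dependence.
Passing tests therefore show that the estimators recover the truth of a
correctly specified illness-death world, not that the model is correct
for any particular real cohort.

## Life-table and prevalence choices

* Chiang's conversion $q = nm/(1 + n(1-a)m)$ with $a = 0.5$ on every
  interval — standard for ages 5+, and this package's population is
  65+; per-interval $a$ is accepted for full-table use. The terminal
  open-ended interval has $q = 1$ and $L = l/m$; a terminal interval
  with zero deaths is an error rather than a silent infinity.
* Radix 100,000 by default; expectancies are radix-invariant (tested to
  $10^{-12}$).
* Default banding 65-, 70-, 75-, 80-, 85+ mirrors the three reporting
  groups (65–69, 70–74, 75–79) plus the old-age tail. The pipeline
  trims the banding to ages with observed deaths when the schedule
  comes from the cohort's own short follow-up — a two-wave cohort
  cannot furnish an old-age mortality schedule, which is exactly why an
  external surveillance schedule can be supplied instead.
* Prevalence CIs are Wilson score intervals (a Wald option exists);
  prevalence above the oldest observed group is carried forward into
  the remaining intervals, since the Sullivan sum needs $\pi$ on every
  interval up to the terminal one.
* Direct age standardisation takes user-supplied standard weights
  (census weights are external data and are not bundled).

## Validation design and problem sizes

The test suite pins every stage to an independent oracle: closed-form
occupancy probabilities of the constant-rate chain, a
`deSolve`-based solve of the forward equations (tolerances
$10^{-12}$/$10^{-14}$) for transition probabilities and for a
brute-force replication of the panel likelihood on small record sets,
and hand-evaluated Chiang/Sullivan/Wilson arithmetic. Simulation-based
checks use cohorts of 20,000 (Gompertz parameter recovery, each
log-intensity within 3 reported SEs and start-state-1 LE within 5%),
50,000–60,000 (occupancy margins within 3 Monte-Carlo SEs; dual-route
concordance), 16 replicate fits of 2,500 for the null-covariate
coverage check, and smaller cohorts elsewhere; these sizes keep the
whole suite at a few minutes on one core while leaving Monte-Carlo
noise well inside the asserted tolerances.

## Known limitations

* The Markov assumption: intensities depend on current state, age and
  sex only — no duration-in-state (semi-Markov) effects, no frailty.
* One intermediate state; remission/recovery is structurally excluded.
* Sullivan estimates inherit all period-measure caveats; with a single
  follow-up wave the multistate estimates rest on one transition's
  worth of information per subject, so age-slope parameters are the
  first to become unstable in small cohorts.
* The bootstrap CIs are parametric (asymptotic-normal parameter draws),
  not resampling of subjects.
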