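---
title: "Estimating surgical volume from aggregate restriction polls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating surgical volume from aggregate restriction polls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surgevol)
```

## The problem

During an acute healthcare disruption, hospitals restrict elective surgery
at different intensities, and no individual-level registry records which
hospital is in which state from week to week. What *is* cheaply observable
is a repeated cross-sectional poll: each week, respondents report their
facility's restriction level on a four-point ordered scale —

1. no surgical restrictions,
2. partial restrictions (more than half of usual activity),
3. extensive restrictions (less than half of usual activity),
4. no scheduled surgery.

`surgevol` turns such a poll series, plus a registry of hospitals with
pre-disruption annual general-anesthesia caseloads, into a weekly national
case-volume estimate with Monte Carlo uncertainty, and validates the trend
against an external reference series.

## Transition model and its estimation

Let $y_t \in \Delta^3$ be the week-$t$ poll distribution over the four
states, with $y_0 = (1,0,0,0)$ (before the disruption every hospital is
unrestricted). Weekly movement is modelled by a row-stochastic matrix
$P_t$ restricted to a birth–death band: in one week a facility can move
only to an adjacent severity level, so
$p_{13} = p_{14} = p_{24} = p_{31} = p_{41} = p_{42} = 0$ and the 10
remaining entries are free up to row sums of 1.

Individual transitions are never observed — this is an ecological
inference problem. The aggregate evolution
$y_{j,t+1} = \sum_i y_{i,t}\,p_{ij,t} + u_{j,t}$ is stacked over two
consecutive steps ($t{-}1 \to t$ and $t \to t{+}1$, treating $P_t$ as
locally constant across the pair), giving an $8 \times 10$ linear system
$y = X_t p_t + u_t$ in the free parameters. The estimate minimizes
$\|y - X_t p_t\|^2$ subject to the band's row-sum and $[0,1]$ constraints
— a small convex quadratic program, solved here by a dense primal
active-set method (`solve_qp()`), with an exhaustive active-set
enumeration used as an independent oracle in the test suite.

### Identifiability, and why it shapes the tests

Two facts about this inverse problem drive several design choices:

* **Information lives in change.** If $y_{t-1} \approx y_t \approx
  y_{t+1}$, any matrix with $y_t$ as a stationary distribution fits the
  window; the reduced design becomes rank-deficient and its smallest
  singular value $\sigma_{\min}$ collapses. Estimation error scales like
  (sampling noise)/$\sigma_{\min}$, so near-stationary windows are
  *unidentifiable no matter the sample size*. Consequently the package's
  parameter-recovery experiments use a persistently exciting truth matrix
  (a near-permutation whose oscillation keeps consecutive poll
  distributions far apart in every window); a damping matrix would make
  the experiment meaningless after a few weeks. This mirrors the
  persistent-excitation requirement familiar from system identification.
* **Unoccupied states say nothing.** When a source state has zero
  occupancy in both window rows, its row of $P_t$ is unconstrained. A
  vanishing ridge toward a persistence prior (the banded identity) pins
  such rows deterministically. The default ridge is
  $10^{-12}\cdot\mathrm{trace}(X_t'X_t)$ — deliberately far smaller than a
  conventional regularizer, because the window system is ill-conditioned
  ($\sigma_{\min} \sim 10^{-3}$ even with all states occupied) and a
  larger ridge visibly biases well-identified entries (a
  $10^{-6}\cdot\mathrm{trace}$ ridge shifts entries by up to ~0.06 on
  exactly consistent data). After the active-set solve, the solution is
  *polished* by a ridge-free re-solve on the optimal face whenever that
  system is nonsingular, so exactly consistent windows are recovered to
  machine precision while degenerate rows still fall back to the prior.

Accuracy statements in the tests are therefore restricted to
*identifiable entries*: free parameters whose source state has occupancy
of at least 0.05 in at least one of the two stacked window rows.

The fitted trajectory reported with a chain is one-step-ahead
($\hat{y}_{t+1} = y_t P_t$) from the *observed* previous poll, not chained
from $y_0$; chained propagation is available via `propagate_chain()`. The
one-step-ahead form is the direct reading of the estimating equation and
does not compound estimation error across weeks.

## Restriction-rate model and scenarios

Conditional on being in state $i$, a hospital's weekly output is its
pre-disruption weekly reference $N_h/52$ multiplied by a random
restriction rate $x \sim \mathrm{Gamma}(\alpha_i, \beta_i)$. The pair
$(\alpha_i, \beta_i)$ is pinned by a (median, variance) specification:
$\alpha = v\beta^2$ makes the variance exact, and the median condition is
solved by bracketed root-finding on $\beta$ (`solve_gamma_params()`,
median tolerance $10^{-9}$; the bracket centre $\beta \approx m/v$ comes
from mean $= v\beta$ with median just below the mean).

Three built-in scenarios share state 1 at level 1.0 and variance 0.005:

| scenario    | state 2 | state 3 | state 4 |
|-------------|---------|---------|---------|
| baseline    | 0.70    | 0.40    | 0.10    |
| optimistic  | 0.80    | 0.50    | 0.25    |
| pessimistic | 0.50    | 0.30    | 0.03    |

Levels are interpreted as medians throughout for internal consistency
(`interpret = "mean"` switches to mean matching; the distinction matters
little at variance 0.005, where the gamma is nearly symmetric, but is
exposed because the convention is genuinely ambiguous). The gamma support
is unbounded above by design: an unrestricted hospital may slightly exceed
its reference week, and rates are *not* clipped at 1.

## Monte Carlo volume simulation

Each of the (default 1000) iterations: every hospital draws an initial
state from the first poll's distribution $y_1$ (independently of hospital
size — no size-weighting is assumed), evolves week by week through the
estimated chain, and draws an independent gamma rate per hospital-week.
Weekly national totals are the size-weighted sums; the summary reports the
median and the 2.5th/97.5th percentiles across iterations (percentiles by
linear interpolation of order statistics, R's type-7 default — stated
because CI endpoints at 1000 iterations are sensitive to the convention),
plus the median as percent of the registry's summed weekly reference.

Because allocation is size-independent, the expected weekly total
factorizes as $\big(\sum_h N_h/52\big)\sum_i \pi_{i,t}\,\mu_i$ with
$\pi_{i,t}$ the analytic occupancy and $\mu_i = \alpha_i/\beta_i$; this
closed form is the oracle for the simulator's expectation-identity test.
Hospitals are re-allocated in every iteration (full uncertainty
propagation); `reallocate = FALSE` fixes one allocation, since the
original convention is not documented. One master seed spawns independent
per-stage sub-seeds (`derive_seeds()`), so adding a scenario never
perturbs another scenario's draws.

Weeks without a poll are not simulated; alignment with external data is
done by interpolation instead (below).

## Validation against a reference series

The percent-of-baseline estimates are piecewise-linearly interpolated (in
calendar days, no extrapolation) to the dates of an external reference
series, and the product-moment correlation $r$ is computed on the aligned
pairs. The estimate series is interpolated to the reference dates, not
vice versa (`invert = TRUE` flips this). The reported two-sided p-value
uses $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom; the original
analysis does not state its p-value method, so the output labels this
choice explicitly.

## The synthetic world

`synthetic_config()` defaults state the world the package is tested in:

* **17 weekly polls, 47–288 responses each** — the observed campaign's
  span and sample-size range; weekly sample sizes are uniform on that
  range.
* **1989 hospitals summing to 44,500 cases/week** — the eligible-registry
  size and pre-disruption national weekly volume scale. Whether the
  published baseline total was computed over all reporting hospitals or
  the eligible subset is not stated; this package computes it over the
  *filtered* registry.
* **Log-normal caseloads, top decile carrying ~40% of volume**
  (`sdlog = qnorm(0.9) - qnorm(0.6) \approx 1.03`) — no size distribution
  is published, only the count and the total; a right-skewed log-normal
  with a heavy-ish top decile is the standard shape for hospital volume
  data. Counts are truncated below at the 100-case eligibility floor, and
  the excess over the floor is rescaled affinely so the weekly total is
  met exactly without violating the floor.
* **Transition volatility 0.3** — weekly matrices are the identity plus
  exponential perturbations on the band, row-normalized; 0.3 produces
  week-over-week movement of the size seen in the observed polls (tens of
  percentage points over a few weeks). Volatility 0 gives the identity
  exactly.
* **Reference noise 3 percentage points, 3-day date shift** — emulates an
  independently run weekly survey reporting on offset dates.
* **Generator timing**: the week-1 latent distribution is
  `baseline %*% M_1` (the first poll already reflects one week of
  movement), and matrix $M_t$ maps week $t$ to $t+1$ — exactly the
  local-constancy convention the estimator's first stacked window assumes,
  so constant-matrix recovery experiments are well-specified.

What the generator does **not** emulate: respondent selection bias,
non-response, regional heterogeneity, hospital-level persistence of
restriction rates across weeks, and calendar effects (holiday dips). A
green synthetic test therefore establishes correctness of the estimation
machinery under the model's own assumptions, not robustness to survey
biases.

## Numerical choices and degenerate inputs

* Percentages parsed from rounded text are accepted when a row sums to
  within 1.5 points of 100%, then re-normalized; exact data are held to
  $10^{-6}$.
* The registry eligibility threshold is inclusive (`annual >= 100`),
  exposed as `min_annual`.
* Weekly reference is `annual / 52` (reproduces the published weekly
  baseline scale from ~2.3M annual cases).
* Post-solve transition cleanup clips entries to $[0,1]$ (violations
  beyond $10^{-8}$ are an error, not silently repaired) and re-normalizes
  rows exactly; structural zeros are kept exactly zero.
* Poll dates are calendar dates and are *not* assumed exactly 7 days
  apart.
* The free-parameter ordering of the QP (row-major over the band) is a
  canonical choice; results are invariant to it.

## Known limitations

* No standard errors or posterior for $P_t$ — uncertainty in the
  transition estimates is not propagated into the volume CIs, which
  therefore reflect allocation and gamma-draw variability only.
* Late-epidemic windows in slowly changing regimes are weakly identified
  (see above); the persistence prior, not the data, determines
  unidentified rows there.
* The three-point example reference series shipped with the package is
  illustrative only; a three-point correlation is not meaningful.
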