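---
title: "Extinction-threshold models of cancer development"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extinction-threshold models of cancer development}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncotip)
```

## The model

`oncotip` treats carcinogenesis as a noise-induced critical transition.
Three processes interact:

1. **Random mutations.** A fixed pool of $n$ healthy stem cells mutates
   independently, each with a small daily probability $p(t)$, so the
   daily influx of mutated cells is binomial, $m(t) \sim
   \mathrm{Bin}(n, p(t))$, with mean $np(t)$ and variance
   $np(t)(1-p(t))$. The probability drifts linearly over a lifetime,
   $p(t) = p_0(1 + \delta t / (100\,T))$: it starts at $p_0$ at birth and
   has risen by $\delta$ per cent at the life expectancy $T$.
2. **Deterministic growth.** A cluster of $x$ mutated cells grows by
   generalized logistic (Richards) kinetics,
   $\dot x = \nu r x - \nu\mu x^{(\nu+1)/\nu}$, with carrying capacity
   $K = (r/\mu)^\nu$. The shape parameter $\nu$ sets the asymmetry
   between early growth (rate $\nu r$) and late saturation (rate $r$).
3. **Immune removal.** The immune system removes a fixed number $s(t)$
   of mutated cells per day.

Subtracting the kill term from Richards growth gives the central
deterministic model of the package,
$$
\dot x = \begin{cases}
  \nu r x - \nu\mu x^{(\nu+1)/\nu} - s(t), & x > 0,\\
  0, & x = 0,
\end{cases}
$$
whose constant-$s$ version has three stationary points $0 < A < K$ for a
suitable $s$: a stable extinction state, an unstable **extinction
threshold** $A$, and the carrying capacity $K$. Clusters below $A$ are
cleared by immunity alone; clusters above $A$ progress. The threshold
has no closed form but, writing $A \sim 10^a$, is approximated by
$$
A \approx \frac{s}{\nu r - \mu(\nu + a\ln 10)} .
$$

### Why not the classical threshold model?

The classical way to add a threshold (a Volterra-type factorized model,
here called the classical threshold extension, `erm1`) has equilibria
$\{0, A, K\}$ with closed-form
$A = \bigl((\mu - \sqrt{\mu^2 - 4r\gamma})/(2\gamma)\bigr)^\nu$, but its
growth/saturation ratio is pinned at
$|\lambda_{grow}/\lambda_{sat}| = (A/K)^{1/\nu} < 1$: small clusters
always grow more slowly than large tumours saturate. Real cancers do the
opposite (ratio $\ge 1$), and with realistic $A \ll K$ the model
produces step-like trajectories — `first_passage_time()` on the
parameterization $\nu = 1$, $r = 0.12$, $A = 1$, $K = 10^4$ takes about
5.7 time units to reach 1% of $K$ and then only $\sim 10^{-1}$ units to
traverse from 1% to 99% (about $10^{-5}$ units when $K = 10^8$). The
kill-term model (`erm2`) keeps the threshold while allowing ratio
$\ge 1$ for $\nu \ge 1$. `asymmetry_curve()` reproduces this dichotomy;
note that for fixed $(A, K)$ its `erm2` branch converges to a finite
plateau above 1 as $\nu \to \infty$ (about 3.83 for $A = 1$,
$K = 100$), a consequence of the kill term's effect on both
linearizations.

## The complete daily-step model

With a one-day step the stochastic model becomes
$$
x(t+1) = \max\{F(x,t), 0\}, \qquad
F(x,t) = x + [\nu r x - \nu\mu x^{(\nu+1)/\nu} - s_m(t)] + m(t),
$$
an Euler–Maruyama-style discretization with the binomial mutation
increment in place of Gaussian noise. The state is kept continuous even
though mutations are integers (the drift is a rate, the influx a count).
When the immune response and the mutation influx vary, so does the
threshold:
$$
\bar A(t) \approx \frac{s_m(t) - \bar m(t)}{\nu r - \mu(\nu + a\ln 10)},
$$
where $\bar m$ is the mean of $m(t)$ over the current immune phase.
Crossings of $\bar A(t)$ are the model's carcinogenesis events; a
crossing followed by a fall back below a rising threshold is a *rescue*.

### Numerical choices

* The decade exponent $a$ is resolved self-consistently
  ($a \leftarrow \log_{10} A$, tolerance $10^{-3}$, at most 50
  iterations) because the source expression leaves the choice of $a$
  open. The approximation is first-order in $a\ln 10/\nu$, so it is
  accurate for strongly asymmetric growth and degrades gracefully at
  small $\nu$; the test suite enforces factor-of-3 agreement with the
  numerically located threshold across $A \in [10, 10^6]$ cells.
* ODE trajectories use `deSolve::lsodar` with rtol $10^{-9}$; the
  step-like transits of the classical model span four orders of
  magnitude in time and need the tight tolerance. Extinction is an
  integration event at a floor of $10^{-6}$ cells (the kill-term model
  reaches 0 with nonzero slope, so plain integration would overshoot
  negative), after which the state is clamped to 0. First-passage times
  are located by the solver's root finding, not by grid lookup.
* An overflow guard aborts at $10^{15}$ cells: strongly asymmetric
  parameterizations are stiff and a wrong parameter draw can explode.
* Linearization rates use the analytic formulas where they exist
  (Richards, classical extension) and central differences with step
  $10^{-6}\max(1, x)$ at the kill-term model's numerically located
  equilibria. The classical extension's closed-form threshold is
  evaluated in the rationalized form $2r/(\mu + \sqrt{\mu^2-4r\gamma})$
  to avoid catastrophic cancellation when $A \ll K$.
* Binomial sampling is exact (`rbinom`), never a normal or Poisson
  approximation: with $np$ of a few hundred per day the distribution
  tail drives threshold crossings.
* The daily recursion follows the bracketed evaluation order of
  $F(x,t)$ literally (and matches R's power semantics bit-for-bit in
  the compiled loop), so the mutation-free model is *exactly* the
  explicit-Euler discretization of the deterministic model — a property
  the tests assert at tolerance zero.

## A woman's immune schedule

Between menarche (age 12) and the effective menopause $M$ the immune
response alternates between $s_{\min}$ (luteal phases, high
progesterone, weaker immunity) and $s_{\max}$ (otherwise):

* luteal phases last exactly 14 days; follicular lengths are drawn per
  cycle from $\mathcal N(14, 2.4^2)$ days, rounded to whole days and
  truncated at 1 day (the truncation moves the mean by far less than
  0.01 day). Menstruation and ovulation are folded into the follicular
  ($s_{\max}$) branch, since the schedule has only two levels.
* Three scenarios: Case 1 fixes $M = 51$ y; Case 2 draws
  $M \sim \mathcal N(51, 4.86^2)$ y (truncated below at menarche + 1 y);
  Case 3 additionally extends $M$ for 26% of women by a
  hormone-replacement-therapy duration drawn from a gamma distribution
  with mode 6 y and sd 4.8 y (shape/scale solved exactly from the
  mode/sd pair). During HRT the square wave is assumed identical to
  premenopausal cycles. The last partial cycle is cut at $M$ exactly.
* Ages convert at 365 days per year throughout.

## Cohort risk and its defaults

`simulate_cohort()` runs one lifetime per woman (daily steps to the
horizon, 85 years by default) and reports the percentage with a
transition by each 5-year age-band edge, with Clopper–Pearson intervals.
A *transition* is operationalized as an upward crossing of $\bar A(t)$
whose excursion reaches $10\times$ the threshold at crossing before
dipping back below it; the simulation stops there (risk needs the onset
age only, not progression to $K$). The confirmation multiple and a
365-day rescue window for event classification are configurable; the
source narrative defines neither a diagnosis size nor a formal rescue
window, so both are documented package conventions.

Each woman owns an RNG substream derived from the master seed, and her
life history and mutation stream use separate sub-substreams. Cohorts
are therefore reproducible woman-by-woman, and immune scenarios can be
compared with common random numbers: Cases 1–3 see identical mutation
histories per woman.

The published calibration tables behind the lifetime parameters are not
part of the main source text. The package therefore ships defaults
(`breast_config()`, `colorectal_config()`) in which only the structure
is pinned to printed values — the immune offsets
$s_{\min} = np_0 + 262$ and $s_{\max} = np_0 + 354$ cells/day, the cycle
and menopause distributions — while $n = 4\times 10^7$,
$p_0 = 8.25\times 10^{-4}$ (so $np_0 = 33{,}000$ mutations/day),
$\delta = 0.5$%, $T = 82$ y, $\nu = 1$, $r = 0.1$ day$^{-1}$,
$K = 10^9$ cells were chosen once so that the simulated breast-like
curves sit on realistic scales (a few percent by age 50, a lifetime
risk near 15%). They are placeholders in that exact published values
would differ; all quantitative test assertions are directional or
structural, never pinned to the published calibrated figures (the
76%/63% luteal shares and the 1.75-fold cycle-length ratio are
reproducible only with that calibration and are deliberately not CI
assertions — the shipped defaults give a luteal share above 90% and a
short/long-cycle ratio above 1).

With these defaults the qualitative picture matches the published
narrative: constant immunity gives an exponential-like cumulative risk;
cycling immunity gives a steep premenopausal rise with a kink at
menopause; distributed menopause and HRT progressively lift the
post-menopausal tail (Case 3 ≥ Case 2 ≥ Case 1 above age 55); shorter
follicular phases raise the risk by 51 and concentrate transitions in
luteal phases.

### What the synthetic data do and do not show

The generators (`make_tumour_dataset()`, `make_incidence_table()`)
emulate the *shapes* of the real inputs: dense individual mouse
measurements with strongly asymmetric growth, sparse per-day means with
symmetric growth, registry incidence bands with exponential-like or
breast-like (polynomial-then-linear) profiles. Measurement noise is
multiplicative lognormal, the standard caliper-error model. Passing
tests demonstrate internal consistency (parameter recovery, shape
discrimination, correct transforms), not agreement with any real mouse
or registry dataset — those are optional external inputs the loaders
accept but the package does not ship.

## Fitting tumour time series

`fit_growth_model()` is a shooting fit: the trajectory starts at the
first observation and Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`) minimizes residuals at the remaining
observations. Choices worth knowing:

* Residuals are on the log scale by default. Tumour volumes span
  decades and the loss is otherwise dominated by the largest points;
  the original analysis does not state its loss, so this is a package
  decision (linear scale available).
* All parameters are optimized as logarithms with box constraints
  ($\nu \in [0.1, 10^6]$, rates positive); multi-start over
  $\nu \in \{1, 10, 10^3, 10^5\}$, a growth rate seeded by the
  early-time log-slope, and thresholds at $\{10^2, 10^4, x_0/2\}$ cells
  with $K = 2\max(\text{data})$. Published best fits reach
  $\nu \approx 10^5$, so the grid must span decades.
* The classical extension is fitted in its $(r, A, K)$ threshold
  parameterization; a fitted $K$ below the largest observation raises
  `K_below_data` (a tumour cannot exceed its carrying capacity while
  the host is alive).
* Volumes convert at $10^9$ cells/cm$^3$; individual-point datasets are
  fitted point-by-point, per-day-mean datasets as means.
* The parameter-recovery experiment in the test suite uses 41 daily
  observations from $5\times10^5$ cells (near the threshold, so the
  immune term shapes the early curve) through saturation (which pins
  $\mu$); with 10% lognormal noise the median worst-parameter error
  stays under 15%.

## Problem sizes and limitations

The test suite simulates 2,000 women per immune scenario and 2,000 per
follicular-length grid point (grid $\{8, 14, 20\}$ days), enough to
resolve risk differences of 2–3 percentage points; the examples in the
README use smaller cohorts. Known limitations: no competing mortality
or censoring (all women count in every denominator); hormone levels are
not modelled, only their net two-level effect on immunity; mutation
accumulation is single-hit (no multi-stage Markov chain); and the
cycle-length analysis holds the luteal phase fixed at 14 days by
construction.
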