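---
title: "A control-driven state-space model for sigmoid crop growth with missing data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A control-driven state-space model for sigmoid crop growth with missing data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(cropdbn)
```

## The problem

Greenhouse growth indicators such as the leaf area index (LAI) and daily
evapotranspiration (ET) follow sigmoid trajectories over a cultivation
cycle, and both are expensive or impossible to measure every day: LAI is
often obtained destructively (a handful of measurements per cycle), ET
weighings are frequently interrupted. Environment variables — temperature,
converted to growing degree days (GDD), and solar irradiance — are, in
contrast, cheap and complete. `cropdbn` learns the link between the two from
the *current* cycle alone and forecasts the indicator weeks ahead, without a
dedicated calibration cycle.

## The model

The logistic sigmoid is the solution of a nonlinear difference equation, but
its **reciprocal** obeys a linear one:

$$\frac{x_{t+1} - x_t}{\Delta} = -\mu x_t + \kappa\mu,$$

an exponential decay toward the steady state $\kappa$ at rate $\mu$. The ET
curve $\kappa'(1 - e^{-\mu' t})$ solves the same equation with a different
initial condition. This linearization is what makes exact inference
possible. The package therefore models the reciprocal LAI (or the ET
directly — the operating mode is always explicit, never inferred) as the
hidden state of a linear-Gaussian state-space model with control inputs:

$$x_{t+1} \sim N\!\big((I - A U_t)\,x_t + B u_t,\ \Sigma_n\big), \qquad
  y_t \sim N\!\big(C x_t,\ \Sigma_w\big), \qquad
  x_1 \sim N(\mu_1, \Sigma_1),$$

with $u_t \in \mathbb{R}^K$ the day's control vector, $U_t =
\mathrm{diag}(u_t)$. The control modulates the *decay* ($A U_t$) and the
*inflow* ($B u_t$): on warm days (large GDD) the crop moves faster along its
growth curve. Comparing with the difference equation, $A$ plays the role of
$\mu$ per unit control and $B = A\kappa$ ties the inflow to the steady
state.

Days without a measurement are handled by marginalization: the likelihood
$p(y^{(\mathrm{obs})} \mid \theta)$ integrates the missing measurements out,
which for missing-(completely-)at-random data is the correct ignorable
treatment. Concretely the Kalman filter simply skips the correction step on
unobserved days; nothing is ever imputed.

All seven parameters $\theta = \{A, B, C, \Sigma_n, \Sigma_w, \mu_1,
\Sigma_1\}$ are learned by exact EM:

* **E-step** — Kalman filter (innovation likelihood accumulated on observed
  days only) plus Rauch–Tung–Striebel smoothing with the time-varying
  transition $I - AU_t$, including lag-one cross-covariances via
  $\mathrm{Cov}(x_{t+1}, x_t \mid y) = \hat V_{t+1} J_t^\top$.
* **M-step** — closed forms throughout. The transition residual
  $x_{t+1} - x_t + A(u_t \odot x_t) - B u_t$ is linear in the stacked matrix
  $[A \mid B]$, so $(A, B)$ are maximized **jointly** by a single
  least-squares solve on expected moments (an alternating update would also
  be valid, but the joint solve is exact in one shot). $C$ and $\Sigma_w$
  use observed days only; $\mu_1, \Sigma_1$ come from the smoothed initial
  state; $\Sigma_n$ from expected residual outer products.

Iteration stops when the log-likelihood increases by less than 1‰ in
relative terms (`rel_tol = 1e-3`, with an absolute fallback of `1e-9` when
the log-likelihood is near zero) or after 100 iterations.

### Initialization from two points

EM climbs to a stationary point that depends on the starting point, so the
start is built deterministically from the **first two observed
measurements**:

* noise covariances at $\epsilon I$ with $\epsilon = 10^{-3}$ (the guidance
  is only "much smaller than 1"; $10^{-3}$ is small against indicator values
  of order 1–30 while keeping the first E-step numerically comfortable);
* $C$ all ones, $\mu_1 = C^\top (C C^\top)^{-1} y_1$ (minimum norm, matches
  the first datum exactly);
* reciprocal-LAI mode: the steady state is fixed at $\kappa = 1$ (MicroTom
  reciprocal LAI) and the decay has the closed form
  $\mu = [\ln(y_2/\kappa - 1) - \ln(y_1/\kappa - 1)]/(t_1 - t_2)$;
* ET mode: $(\kappa', \mu')$ solve the two-equation fixed point
  $\mu' = -\ln(1 - y_1/\kappa')/t_1$, $\kappa' = y_2/(1 - e^{-\mu' t_2})$.
  The plain alternation contracts arbitrarily slowly when the two samples
  are close, so the implementation wraps it in Aitken (Steffensen)
  acceleration — same equations, quadratic convergence — starting at
  $\kappa'^{(0)} = 1.05\,y_2$ with tolerance $10^{-8}$;
* $A^{(0)} = \mu\,\mathrm{diag}(\bar u)^{-1}$ (decay normalized
  component-wise by the sample mean of each control; for $K > 1$ the
  division is component-wise) and $B^{(0)} = A^{(0)} \kappa / K$. The
  $1/K$ is this package's choice: with the all-one measurement matrix the
  emitted measurement then settles at $\kappa$ itself rather than at
  $K\kappa$; for the scalar-state LAI mode it is the plain proportionality
  $B = A\kappa$.

The forward run of this starting point already tracks the generating curve
to within roughly 12–15% everywhere (the residual is the Euler
discretization of the decay at daily granularity), which is why EM converges
reliably from it; at desk scale its converged likelihood matches the best of
50 random restarts within 1%.

## Forecasting with frozen control

Controls are only known up to the forecast origin $T$, so the predictor
freezes $u_T$ and runs freely:

$$x_{T+q} = (I - AU_T)\,x_{T+q-1} + B u_T, \qquad
  V_{T+q} = (I - AU_T)\,V_{T+q-1}\,(I - AU_T)^\top + \Sigma_n,$$

seeded at the smoothed mean and covariance of day $T$, with
$y_{T+q} = C x_{T+q}$ and variance $C V_{T+q} C^\top$. Two readings of the
variance recursion are conceivable; the one implemented (propagate the
smoothed $V_T$ through the same frozen map, adding $\Sigma_n$ each step) is
the only self-consistent one, and it is validated against 10,000-rollout
Monte-Carlo moments in the tests. The reported variance quantifies the
uncertainty of the measurement *mean*; it deliberately excludes the
single-day measurement noise $\Sigma_w$, and the Monte-Carlo calibration
checks therefore compare against rollouts of the noiseless emission
$C x_{T+q}$.

In reciprocal-LAI mode, point predictions are mapped back as
$1/\hat y$. Because $1/x$ is convex this is a **lower bound** of the LAI
mean (Jensen), and the variance of the reciprocal of a Gaussian diverges, so
no indicator-domain variance is reported — the band lives in the reciprocal
domain only.

`rolling_forecast()` reproduces evaluation protocols without future
leakage: at every origin the model is **refit from scratch** on data up to
the origin (the deterministic initialization makes refits stable and
reproducible; whether one should refit or filter forward from a single fit
is not settled — both are supported, refitting is the default). At origins
with too few transitions to identify $(A, B)$ — e.g. an origin on day 2 —
the M-step normal equations are singular; the rolling protocol then falls
back to the two-point starting point, which at that point is the exact
interpolant of everything observed.

```{r example}
sc <- generate_growth_scenario(scenario_config(seed = 3))
fit <- cropdbn(sc, mode = "reciprocal_lai", freeze = "C")
summary(fit)
plot(fit, q = 21)
```

## What the synthetic generator emulates — and what it does not

The measurement campaigns behind the model (three MicroTom cycles in a warm
bright greenhouse, a shaded one, and an indoor LED prototype) are not
publicly deposited, so the package ships a generator that emulates their
published summary statistics:

* **Environment** — bounded AR(1) daily temperature and irradiance series
  ($\phi = 0.6$, stationary sd = range/8, deviations centred so every seed's
  sample mean matches the published mean, reflection into the published
  min/max). The indoor profile's constant irradiance (1.29 MJ m⁻² d⁻¹ for
  minimum, mean and maximum) is reproduced as a constant series. Any bounded
  process matching the published moments would do; AR(1) adds realistic
  day-to-day persistence.
* **Growth** — the truth is simulated from the state-space model whose
  deterministic part matches the mode's closed-form curve. Defaults, chosen
  once: $\kappa = 1$ (reciprocal-LAI steady state), inflection at day 32 of
  a 64-day cycle, $\mu = 0.11$ so the day-1 reciprocal LAI is about 33
  (LAI ≈ 0.03, matching the recalibrated sigmoid benchmark's lower
  asymptote); measurement sd 0.1 and state sd 0.01 in reciprocal-LAI units
  as "moderate" noise. ET defaults: $\kappa' = 2$ mm d⁻¹, $\mu' = 0.05$.
* **Missingness** — independent Bernoulli (MCAR, a strict subset of MAR;
  the mask never sees the measurements) at 94% for LAI and 50% for ET, with
  the first two measurement days always kept because initialization needs
  them; a deterministic schedule mask (days 1, 22, 43, 64) mirrors the
  destructive-sampling calendar.

What it does **not** emulate: weather fronts and multi-day irradiance
regimes, sensor drift, truly informative missingness (a scale failing
*because* of high humidity would violate MAR), or crop stress departing from
the sigmoid shape. Passing tests on these scenarios show the machinery is
correct under the model's own assumptions — not that any particular real
greenhouse satisfies them.

## Numerical choices

* Covariances are symmetrized after every update; the correction step uses
  the Joseph form.
* The scalar innovation variance is floored at $10^{-12}$ so the likelihood
  stays finite when $\Sigma_w$ is initialized tiny; $\Sigma_w$ itself is
  floored at the same value in the M-step (a floored coordinate is a
  constrained M-step, which preserves EM monotonicity).
* M-step solves check the condition number (`rcond < 1e-10` raises the
  singular-normal-equations error) rather than trusting `solve()` to fail.
* Exact-arithmetic EM is monotone; near a degenerate optimum (covariances
  collapsing on noise-free data) round-off can produce a relative dip below
  $10^{-3}$, which `fit_em` treats as numerical convergence (the dipped
  update is discarded). Larger decreases still raise an error, as they
  indicate a genuine M-step defect.
* The smoother inverts predicted covariances through a Cholesky solve with
  an eigenvalue pseudo-inverse fallback, so zero-noise models smooth
  cleanly.

## Identifiability and the `freeze` option

The emission scale is shared between $C$ and the state: scaling the state by
$s$ while dividing $C$ by $s$ (and scaling $B$, $\mu_1$ accordingly) leaves
the likelihood unchanged, so $C$ mainly anchors the scale that the all-one
initialization and the scale-bearing $(A, B)$ start already fix. The default
learns all of $\theta$; `freeze = "C"` keeps the all-one measurement map and
is what the evaluation protocols in the tests use, making $A$ and $B$
directly comparable to generating values. Any subset of
$\{A, B, C, \Sigma_n, \Sigma_w, \mu_1, \Sigma_1\}$ can be frozen.

## Scale of the shipped experiments

The test-suite and acceptance-script experiments run at the scale a single
cycle suggests: 64-day cycles for the end-to-end protocols (20 seeds,
medians reported), 200-day / 30%-observed scenarios for parameter recovery
(20 seeds), 200 random small instances for the brute-force oracle
equivalence, and 10,000 rollouts for forecast calibration. These sizes give
stable medians and 3-standard-error Monte-Carlo bands while keeping a full
run comfortably on one CPU.

## Known limitations

* Scalar measurements only; multivariate emissions are out of scope.
* Gaussian noise on the reciprocal scale means multiplicative-looking noise
  on the LAI scale near the cycle start; heavy-tailed measurement errors
  will distort $\Sigma_w$.
* The frozen-control predictor cannot anticipate weather changes by design;
  its q-step band covers state uncertainty, not future control variation.
* With only two observations before an origin, forecasts inherit the
  two-point initialization's Euler bias (order $\mu^2$ per day on the
  decaying deviation).
* The reciprocal back-transformation is a Jensen lower bound, not an
  unbiased LAI mean.
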