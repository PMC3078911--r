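---
title: "Modelling honey bee colony population dynamics with beedyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling honey bee colony population dynamics with beedyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beedyn)
```

## The model and its assumptions

A honey bee colony's workforce is socially structured: young adults work in
the protected hive (nursing, comb work) and graduate to foraging, where
mortality is one to two orders of magnitude higher. `beedyn` models the
adult worker population with two continuous compartments, hive bees $H$ and
foragers $F$, $N = H + F$:

$$\frac{dH}{dt} = E(H,F) - H\,R(H,F), \qquad
  \frac{dF}{dt} = H\,R(H,F) - m\,F,$$

$$E(H,F) = \frac{L\,N}{w + N}, \qquad
  R(H,F) = \alpha - \sigma\,\frac{F}{N}.$$

The assumptions doing the work are:

* **Hive-bee mortality is negligible.** Deaths occur only in the forager
  class, at a constant per-capita rate $m$.
* **Brood rearing saturates with workforce size.** Eclosion of new adults
  rises from 0 (no workers to rear brood) to the queen's laying rate $L$,
  with half-saturation at $N = w$. The three-week egg-to-adult lag is not
  modelled; eclosion responds instantaneously to $N$.
* **Social inhibition is proportional to the forager fraction.** Foragers
  delay hive bees' transition to foraging (ethyl-oleate transfer); the
  recruitment rate falls linearly from $\alpha$ with $F/N$. When
  $F/N > \alpha/\sigma$, $R < 0$ and the flux $H\,R$ reverses, modelling
  reversion of foragers to hive tasks. The flux is kept on $H$ exactly as
  written, so reversion moves foragers back at per-capita rate $|R|$
  applied to $H$.
* **Populations are continuous and deterministic.** No demographic
  stochasticity, age structure, brood compartment, food store, disease, or
  seasonality. Below roughly one bee the continuum description is
  meaningless, which is why extinction is assessed against small-$N$
  thresholds rather than $N = 0$.

At the origin $F/N$ is 0/0; the forager fraction is defined as 0 there so
the empty colony is a genuine fixed point. The vector field is not
differentiable at the origin, so the empty state's stability is probed by
simulation from small populations, never by a Jacobian there.

## Parameters

| symbol | default | units | meaning |
|---|---|---|---|
| $L$ | 2000 | eggs/day | queen laying rate |
| $w$ | 27 000 | bees | brood-rearing half-saturation |
| $\alpha$ | 0.25 | 1/day | uninhibited recruitment rate (foraging onset at a minimum of ~4 days of adult age) |
| $\sigma$ | 0.75 | 1/day | social-inhibition strength; $\alpha/\sigma = 1/3$ puts the reversion threshold at a one-third forager fraction |
| $m$ | 1/6.5 ≈ 0.154 | 1/day | forager death rate; the default corresponds to the ~6.5-day flightspan of foragers in healthy colonies and is the parameter every analysis varies |
| $m_l$ | 0.6 | 1/day | ceiling of the precocious-mortality response |
| $\bar\sigma^2$ | 0.059 | (1/day)² | half-saturation of that response in $R^2$ |

## Steady states and the collapse threshold

Setting $dF/dt = 0$ with $F = JH$ gives the caste-ratio quadratic
$mJ^2 + (m + \sigma - \alpha)J - \alpha = 0$, whose unique positive root
`equilibrium_ratio()` evaluates in a cancellation-safe form (and as
$\alpha/m$ when $\sigma = 0$). The eclosion balance then gives
$H_0 = L/(mJ) - w/(1+J)$, positive — a viable colony — exactly when
$m J/(1+J) < L/w$: brood production must replace forager losses. The
viability condition is implemented in this algebraic form, derived from the
steady state, and `critical_death_rate()` root-brackets it in $m$
(default tolerance $10^{-8}$/day, default scan bracket [0.05, 0.60]/day,
chosen to straddle the threshold for realistic parameter sets — callers
with unusually fecund queens pass a wider bracket). At the defaults the
threshold is $m^* = 0.355$/day: a mean foraging life of 2.8 days. The
Jacobian used for stability is analytic, including the chain rule through
the precocious death-rate feedback; finite differences appear only as a
test cross-check.

## Numerical choices

* **Integrator.** `deSolve::ode` (lsoda) with relative tolerance $10^{-8}$
  and absolute tolerance $10^{-6}$ bees. The system is two-dimensional and
  smooth except at the $R = 0$ branch switch of the optional feedback;
  stiffness is mild and lsoda handles the switch adequately (tests show
  agreement with a fine fixed-step RK4 transcription at $10^{-7}$ relative
  in smooth regimes and $10^{-4}$ across the switch).
* **Output sampling** defaults to 1 day; demography uses 0.1-day sampling
  for its hazard integrals (trapezoidal rule).
* **Clipping.** Tiny negative excursions from the integrator are clipped to
  0 and counted; the right-hand side also floors its inputs at 0 so the
  integrator never sees negative populations.
* **Ties and degenerate inputs.** $N = 0$ is a fixed point by definition;
  $\sigma = 0$ uses the degenerate ratio $\alpha/m$; $L = 0$ colonies are
  never viable.

## Demography: age at onset of foraging and lifespan

At the positive equilibrium the recruitment hazard is the constant
$R_0 = mJ$, so the mean hive-bee residence time — the average age at onset
of foraging, AAOF — is $1/(mJ)$, and worker lifespan is AAOF plus the
flightspan $1/m$. Both fall as $m$ rises: stressed colonies are staffed by
young, short-lived foragers — precisely the precocious-foraging signature.

Over a finite observation window the hazard $R(t)$ is not constant and an
estimator choice is unavoidable. `windowed_demography()` offers three,
all floored at $R = 0$ and all satisfying lifespan − AAOF = $1/m$:

* `"terminal"` (default): $1/R(T)$, the reciprocal hazard at the end of
  the window. The caste ratio relaxes within days, after which the hazard
  is quasi-constant, so this is the expected waiting time for the workforce
  observed at the end of the window; it converges exactly to $1/(mJ)$ as
  the window grows, and for the packaged 40-day reference scenarios it
  agrees with the observational-comparison table to better than 0.05 days.
* `"window_mean"`: $T/\int_0^T R\,dt$, the reciprocal time-averaged
  hazard. It weights the early transient (high $R$ while foragers are
  absent) equally with the settled phase and therefore reads 1.5–2.5 days
  younger on the same scenarios.
* `"cohort"`: the eclosion-weighted expected onset age of bees emerging
  during the window, with hive-phase survival extrapolated beyond the
  window at the terminal hazard. It lands within ~0.4 days of the terminal
  estimator and is provided for sensitivity analysis.

The default is `"terminal"` because it is the only one of the three that
both reduces to the equilibrium identity and matches the packaged
observational comparison within its ±1-day reporting precision; the spread
across estimators is the honest uncertainty of the windowed quantity.

## The precocious-mortality feedback

Foragers recruited at abnormally young ages are weaker and die faster.
`effective_death_rate()` models this by replacing $m$ with the Hill
response $m_l R^2/(\bar\sigma^2 + R^2)$, in one of three modes: `"off"`,
`"when_R_negative"` (replacement only during reversion episodes), or
`"always"`. The branch condition is deliberately left to the user because
the feedback's behaviour is subtle and, with the default constants, the
replacement does **not** uniformly accelerate collapse:

* Under `"always"`, $m_{\mathrm{eff}} \le m_l\alpha^2/(\bar\sigma^2 +
  \alpha^2) \approx 0.309$/day, *below* the collapse threshold 0.355/day,
  and at the low hazards of a settled colony the replacement death rate is
  far below any realistic baseline $m$. The modified system has no positive
  equilibrium of its own (the self-consistency condition
  $m_l R J = \bar\sigma^2 + R^2$ has no root on the feasible branch), and
  simulations show the ratio drifting to the reversion threshold with
  mortality vanishing — the population grows without bound. This mode is a
  useful ingredient for model exploration, not a collapse mechanism.
* Under `"when_R_negative"` the branch fires only while more than a third
  of the workforce forages, a self-extinguishing transient; in paired
  collapse runs entered through forager-biased states the extra forager
  deaths actually *rebalance* the colony and leave it marginally larger
  afterwards.

`decline_comparison()` therefore reports paired baseline/feedback
trajectories without asserting an ordering, and its documentation points
here. A feedback that does uniformly accelerate decline would need the
Hill response *added* to (not substituted for) the baseline death rate;
that variant is outside the present model surface and deliberately not
smuggled in.

## What the simulated conditions do and do not show

The packaged scenarios are the study conditions themselves: colonies
started from realistic post-establishment states (9000 or 4500 hive bees,
no foragers), default parameters, death rates spanning the healthy range
(~0.11–0.15/day) up to past the threshold. Problem sizes are small by
construction — two ODE states, 40–2500-day horizons, 200-point bifurcation
grids — so every analysis runs in seconds. Passing tests show internal
consistency (closed form vs integration, analytic vs numerical Jacobians,
estimator identities) and agreement with one published mark–recapture
comparison; they do not validate the model against seasonal, disease-driven
or food-limited colony dynamics, all of which are outside the model's
scope, and the "global" stability of the positive equilibrium is probed
empirically from scattered initial conditions, not proven.

## Known limitations

No age structure or egg-to-adult lag, no brood or food compartments, no
seasonality, no stochasticity, no terminal-decline mechanisms
(thermoregulatory failure, cannibalism, absconding) — the model is a
deliberately lean instrument for reasoning about one feedback: forager
mortality, social inhibition, and brood replacement.
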