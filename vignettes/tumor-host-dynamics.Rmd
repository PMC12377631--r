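---
title: "Tumor-host dynamics, therapy planning and model fitting with lvtumor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumor-host dynamics, therapy planning and model fitting with lvtumor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvtumor)
```

## The model

`lvtumor` analyses tumor-host interaction as a two-species competitive
Lotka-Volterra system,

$$\dot x = r_x x\Big(1-\frac{x}{K_x}\Big) - \alpha_{xy}\,x y, \qquad
  \dot y = r_y y\Big(1-\frac{y}{K_y}\Big) - \alpha_{yx}\,y x,$$

where $x$ is the tumor population (interchangeably, the tumor volume in
cm^3^) and $y$ the host (healthy) cell population. Each species grows
logistically with rate $r$ (per day) and carrying capacity $K$, and is
inhibited by the other through the interaction coefficients
$\alpha_{xy}$ (host on tumor) and $\alpha_{yx}$ (tumor on host). Under
the shared-capacity reading, $\alpha_{xy}$ bundles a pure kill rate
$\delta_{xy}\ge 0$ with the crowding term, which bounds
$\alpha_{xy}\ge r_x/K_x$; several useful parameter sets sit below that
bound, so the constraint is enforced only under `strict = TRUE`. Note
that the decomposition into kill and crowding parts is exact only for a
common capacity $K_x=K_y$; the simplex bound $x+\gamma y\le K_x$
likewise.

Rescaling time and populations ($\tau = r_x t$, $x = K_x u$,
$y = (r_x K_y/r_y)\,v$) reduces the system to

$$\dot u = u - u^2 - c\,uv, \qquad \dot v = d\,v - v^2 - f\,uv,$$

with the dimensionless triple
$c = K_y\alpha_{xy}/r_y$, $d = r_y/r_x$, $f = K_x\alpha_{yx}/r_x$
carrying all the dynamics. Linear stability analysis of the four fixed
points $P_1=(0,0)$, $P_2=(0,d)$, $P_3=(1,0)$,
$P_4=\big(\tfrac{1-cd}{1-cf},\tfrac{d-f}{1-cf}\big)$ splits parameter
space into four regimes:

* **I** ($cd>1$, $f<d$): tumor elimination — everything flows to $P_2$;
* **II** ($cd<1$, $f<d$, hence $cf<1$): stable coexistence at $P_4$;
* **III** ($cd>1$, $f>d$, hence $cf>1$): bistability — the stable
  manifold of the saddle $P_4$ (the separatrix, see `separatrix()`)
  divides the basins of $P_2$ and $P_3$;
* **IV** ($cd<1$, $f>d$): tumor dominance — everything flows to $P_3$.

```{r}
p <- lv_params(rx = 0.1, ry = 0.09, Kx = 1, Ky = 1,
               alpha_xy = 0.09, alpha_yx = 0.0788)
to_dimensionless(p)
equilibria(to_dimensionless(p))
```

Eigenvalues are always computed numerically from the analytic Jacobian
$J = \begin{pmatrix} 1-2u-cv & -cu \\ -fv & d-2v-fu \end{pmatrix}$
rather than from closed-form eigenvalue expressions, which are easy to
mistype for $P_4$; a finite-difference Jacobian serves as an oracle in
the test suite. Classification uses a boundary band (default `1e-12`)
mapped to `"DEGENERATE"` instead of silently picking a side of the
manifolds $cd=1$, $f=d$, $cf=1$.

A Dulac function $R = u^m v^n$ with
$m = (cf+f-2)/(1-cf)$, $n = (cf+c-2)/(1-cf)$ makes the divergence of
the rescaled field one-signed in the open quadrant whenever
$\kappa = (cd-1+f-d)/(1-cf)\neq 0$, excluding closed orbits: the
unperturbed system always settles to an equilibrium
(`dulac_certificate()`). On the degenerate manifold $cd-1 = d-f$ the
certificate is inconclusive and is reported as such.

## The particle (potential) reduction

Eliminating $v$ turns the tumor equation into the motion of a damped
particle in a quartic potential $V(u)$ with
$-V'(u) = (1/c-d)u + (d+f-2/c)u^2 + (1/c-f)u^3$ and extrema $u_1^*=0$,
$u_2^*=1$, $u_3^*=(1-cd)/(1-cf)$; the integration constant is fixed by
$V(0)=0$, which affects nothing observable. Minima of $V$ correspond to
stable rest points of the tumor component ($u_1^*$ iff $cd>1$, $u_2^*$
iff $f>d$, $u_3^*$ iff $f<d$), and the six minima/maxima patterns
across the four regimes are labelled by `potential_profile()`. One
caveat found while testing: a positive minimum of $V$ can pair with a
host-negative (non-physical) equilibrium of the planar system, so the
correspondence is asserted only from stable equilibria to minima. The
curvature at a minimum defines the proper frequency
$\Omega = \sqrt{V''(u^*)}$ (dimensionless; multiply by $r_x$ for
per-day units), which reduces to $\sqrt{f-d}$ at $u^*=1$ — the value
that matters for forced tumor-dominant systems.

## Therapy planning

Three perturbation modes are modelled through `therapy_spec()`, all
parameterised by a relative dose $D$.

**Proportional continuous therapy** subtracts $D\beta_x x$ and
$D\beta_y y$: the system stays Lotka-Volterra with
$d^*(D) = (r_y-D\beta_y)/(r_x-D\beta_x)$ and unchanged $c, f$. Therapy
is *effective* iff $r_y\beta_x - r_x\beta_y > 0$ (so $d^*$ grows with
dose). The regime conditions flip at
$D_1 = r_y(r_x-K_y\alpha_{xy})/(r_y\beta_x-\beta_yK_y\alpha_{xy})$ and
$D_2 = r_x(K_x\alpha_{yx}-r_y)/(\beta_xK_x\alpha_{yx}-r_x\beta_y)$,
and `plan_outcome()` tabulates the reachable regime on every dose
interval, up to outright extinction beyond $r_x/\beta_x$ or
$r_y/\beta_y$. Doses exactly at a threshold are labelled
`"DEGENERATE"` (the strict/non-strict boundary choice is immaterial in
practice and deliberately not hidden). The planner also records the
relapse caveat: withdrawing therapy before practical elimination
(default floor $10^{-6}K_x$) returns the system to its baseline regime.

```{r}
p4 <- lv_params(0.1, 0.066, 1, 1, 0.066, 0.07)  # regime IV
plan_outcome(p4, beta_x = 0.05, beta_y = 0.01, D = 0.5)
```

**Host-directed constant therapy** ($\beta_x=0$, $\beta_y<0$: the host
is boosted at a constant rate) adds
$A = -D\beta_y r_y/(r_x^2K_y) \ge 0$ to the dimensionless host
equation. The forced system has tumor-free states
$Q_{1,2} = (0, (d\mp\sqrt{d^2+4A})/2)$ and an interior pair $Q_{3,4}$
that exists while $\Delta = (f-d)^2 - 4A(cf-1)\ge 0$. $Q_2$ gains
stability at $A_1 = (1-cd)/c^2$ (one interior branch crossing the
$u=0$ axis through it), and for $cf>1$ the interior pair collides in a
saddle-node at $A_2 = (f-d)^2/(4(cf-1))$ — `q_equilibria()` reports
the collided point with its zero eigenvalue, and non-physical
equilibria are kept with `physical = FALSE` because the planner
reasons about their sign. The dual dose thresholds
(`dose_thresholds_additive()`) satisfy `forcing_amplitude(Di) = Ai`
identically, which the tests verify over random parameter sets.
Because $(x, 0)$ is never an equilibrium of the forced system, the
host cannot vanish under this therapy, whatever the dose.

**Periodic host-directed therapy** applies
$D|\beta_y|(1-\cos\omega t)$ — non-negative, averaging to $D|\beta_y|$
per period. The long-run behaviour is read off the stroboscopic
(Poincaré) map by `stroboscopic_classify()`: near resonance
($\omega \sim \Omega$) the attractor is a period-1 limit cycle; as
$\omega$ grows the loop shrinks toward a point attractor.

## Numerical choices

* Integration uses deSolve with `rtol = 1e-8`, `atol = 1e-10`;
  the default method is `lsoda`, which is markedly cheaper than an
  explicit Runge-Kutta pair on the long forced transients (the burn-in
  below), while `"ode45"` remains available through `method`.
* Negative undershoot is never clipped: the positive quadrant is
  invariant for the exact flow, and the tests assert non-negativity to
  solver tolerance only.
* Strobe burn-in discards the larger of 50 forcing periods and 2000
  units of dimensionless time; convergence of the strobe sequence uses
  a relative tolerance of `1e-7`, and subharmonics are checked up to
  period 8 even though none are expected.
* The amplitude floor separating "period-1 limit cycle" from
  "small-loop attractor" is `2e-3` relative to the carrying
  capacities. The high-frequency response scales like
  $2D|\beta_y|/\omega$, which for the reference forced scenario gives
  relative amplitudes of about `8e-3` at $\omega = 6$/day and `8e-4`
  at $\omega = 60$/day; the floor sits between the two decades, an
  order of magnitude below the near-resonance response.

## Lyapunov spectra

`lyapunov_spectrum()` integrates the reference trajectory of the
forced dimensionless system together with two tangent vectors under the
variational equations, renormalizing every $\tau$ (default 0.1) with a
fixed-step classical RK4 at $h = 0.02$: the raw stretch factors give
the maximum exponent via $\sigma_n = (n\tau)^{-1}\sum_i\ln(d_i/d_0)$,
and the Gram-Schmidt complement gives the second. The loop is written
in the package (rather than delegated to an ODE driver) because the
renormalization interleaves with fixed-step integration; its oracle
tests are exact constant-coefficient fields and node-attracted
trajectories, whose exponents equal Jacobian eigenvalues.
Convergence is declared when the spread of $\sigma_n$ over the final
quartile falls below `1e-3`; runs default to `n_steps = 3000`
renormalizations (300 time units), and the acceptance-level run at the
reported local maximum of the maximum exponent uses 6000. Initial
tangent vectors are the canonical basis; the sequences are provably
invariant to the tangent scale $d_0$, which the tests confirm to
`1e-10`. `search_max_lce()` adds a seed-deterministic random search
with a shrunken-box refinement phase over $(c,d,f,A,\omega)$, and
`lce_parameter_sweep()` maps the exponent one parameter at a time; the
sweep across $A$ shows the expected discontinuity at the saddle-node
amplitude $A_2$, where the interior equilibria vanish. Everywhere we
have evaluated it, the maximum exponent is negative — the forced
tumor-host system is dissipative and non-chaotic.

## Fitting tumor growth curves

`fit_lv()` estimates the full octet
$(r_x, r_y, \alpha_{xy}, \alpha_{yx}, K_x, K_y, x_0, y_0)$ from a
volume series by least squares on the tumor component only (the host is
unobserved in volume data), with the initial state placed at $t=0$.
Optimization is bounded Levenberg-Marquardt on log-parameters — the
default box spans rates $[10^{-3}, 20]$/day, interactions $[0, 20]$
(realised as $10^{-6}$ on the log scale), capacities
$[0.1, 20]$ cm^3^ — from a data-informed start (a plain logistic fit
embedded as a weakly coupled system, motivated by the near-degeneracy
$\alpha_{xy}\simeq r_x/K_x$ of realistic fits, under which the tumor
component is effectively logistic) plus Latin-hypercube draws,
basin-hopping jitters around the incumbent, and a final polish.
Unweighted linear-scale residuals are used. Raw multi-start in the
natural parameter scale was observed to stall in poor local minima on
every start, which is why the log-scale/informed-start strategy is the
default rather than an option.

Identifiability is reported, not "solved": the rank of $J^\top J$ at
the optimum flags the (typical) case where only parameter combinations
are determined. Consequently the package's own recovery tests compare
*curves*, not parameters, via the symmetric Hausdorff distance
(`hausdorff_distance()`), evaluated at the observation times. A
caution established while validating: near-interpolating refits of a
12-point noiseless series can still deviate from the generating curve
by a few $10^{-3}$ cm^3^ *between* samples, so inter-sample behaviour
should not be over-interpreted from sparse volume data. A generic
second-curve slot in `goodness_report()`/`hausdorff_distance()` lets a
user compare against any other growth model's curve (e.g. a
Gompertz-type fit) without that model being implemented here.

## Synthetic data

`generate_volume_series()` emulates unperturbed Ehrlich-tumor volume
measurements in mice: the tumor component of the fitted reference
octet rises logistic-like from about 0.5 cm^3^ toward a ~3 cm^3^
plateau, sampled by default at 12 equally spaced times over days 0-30
(day 0 included, since such experiments report the initial volume) with
multiplicative log-normal noise of scale $\sigma = 0.05$ — volume
measurement error grows with volume, and the per-time-point coefficient
of variation of replicates equals $\sigma$ to first order, which the
tests verify at $n = 1000$ replicates. What the generator does *not*
emulate: measurement-time jitter, animal-to-animal parameter
heterogeneity, detection limits near inoculation, or censoring —
passing recovery tests on this generator therefore demonstrates
correctness of the estimator on model-generated data, not robustness to
those real-data features. `generate_scenario_suite()` rejection-samples
kinetic sets per regime (covering both $cf$ sub-cases of regime IV) and
bundles effective/ineffective/host-directed therapy draws for planner
tests; draws are seed-deterministic.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run everything at the scale
the analyses need, chosen once: long-run regime convergence at
$t \le 6000$ dimensionless time units; strobe classification of the
reference forced scenario with the full default burn-in (2000
dimensionless time units, i.e. 20000 days at $r_x = 0.1$/day);
Lyapunov spectra at 1500-6000 renormalizations; fitting with 20
optimizer starts. Random-parameter property checks use a few dozen to
a few hundred draws per property.

## Known limitations

* Two species only; no spatial structure, no treatment schedules
  beyond the three modes, and no pharmacokinetic map from drug
  concentration to the relative dose $D$.
* The second-order particle equation is used only through its
  unperturbed potential; the forced dynamics are always simulated in
  first-order form.
* Boundary parameter sets ($cd=1$, $f=d$, $cf=1$) are classified as
  degenerate rather than analysed by normal forms.
* The Lyapunov search certifies negativity only where it evaluates;
  it is a numerical exploration, not a proof of non-chaos.
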