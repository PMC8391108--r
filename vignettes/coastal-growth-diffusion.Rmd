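---
title: "Growth-diffusion models of a coastal city: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-diffusion models of a coastal city}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coastdiff)
```

## The model family

`coastdiff` studies a city that emerges on a straight coastline and spreads
inland.  The population density $N(x,t)$ (dimensionless) lives on the
half-line $x \ge 0$, with $x = 0$ the coast, and obeys a one-dimensional
growth-diffusion equation

$$\frac{\partial N}{\partial t} = f(N) + D\,\frac{\partial^2 N}{\partial x^2},$$

with diffusion coefficient $D$ (km$^2$/yr) and one of three growth laws:

* **pure diffusion**, $f \equiv 0$;
* **exponential growth**, $f(N) = rN$ with growth rate $r$ (1/yr);
* **logistic growth**, $f(N) = rN(1-N)$, carrying capacity normalised to 1.

All models start from the empty state $N(x,0)=0$ and hold a prescribed
density at the coast: either a step to a constant $N_0$, or (for the
exponential model) a boundary growing as $N_0 e^{rt}$.  At infinity the
density decays (emulated by domain truncation; see below).  Units are fixed
package-wide as kilometres and years: with $\sigma^2 = 2Dt$, a city front
spreading 10 km in 50 years calibrates $D = 1$ km$^2$/yr
(`calibrate_diffusion(10, 50)`), and $r = 0.01$/yr is a typical demographic
growth rate.  For $r > 0$ the two constants combine into the single
characteristic length $x_G = \sqrt{D/r}$ (10 km at the reference values),
which controls every stationary structure in the package.

### Closed forms

*Pure diffusion* has the classical similarity solution
$N = N_0\,\mathrm{erfc}\!\big(x/(2\sqrt{Dt})\big)$, total population
$N^*(t) = 2N_0\sqrt{Dt/\pi}$, and an occupancy distribution (density
normalised by the total — the probability law of an inhabitant's location)
with mean $(\sqrt{\pi}/2)\sqrt{Dt}$, second moment $\tfrac43 Dt$ and
variance $(\tfrac43 - \tfrac{\pi}{4})Dt \approx 0.55\,Dt$; the coefficient
$0.55$ is the average inland spread rate per unit $D$.

*Exponential growth with a synchronised boundary* reduces to pure diffusion
through the substitution $N = e^{rt}\tilde N$, giving
$N = N_0 e^{rt}\,\mathrm{erfc}(x/(2\sqrt{Dt}))$ — same occupancy law, total
scaled by $e^{rt}$.

*Exponential growth with a regulated coast* ($N(0,t) = N_0$ held constant,
the "central business district" regulation) is solved by Duhamel's
principle.  In the tilde frame the boundary decays as $e^{-rt}$, and
superposing step responses yields

$$N(x,t) = \frac{N_0}{2\sqrt{\pi}}\,\frac{x}{x_G}\,
F\!\Big(rt,\ \frac{x}{x_G}\Big),\qquad
F(a,b) = \int_0^a w^{-3/2}\,e^{\,w - b^2/(4w)}\,dw .$$

$F$ is finite for finite $a$ (the Gaussian factor shields the $w^{-3/2}$
singularity) and diverges as $a\to\infty$: regulating the coast does not
stop unbounded growth inland.  The total is
$N^*(t) = N_0\,x_G\,\mathrm{erfi}(\sqrt{rt})$, which the package evaluates
both by that closed form (cancellation-free Maclaurin series for
$\mathrm{erfi}$) and by adaptive quadrature of the defining integral, the
two agreeing to $10^{-8}$ relative.

*Steady band waves.*  In a strip $0 \le x \le L$ with pinned edge densities
$A$ (coast) and $B$ (inner edge), the exponential model admits the
time-independent wave

$$N(x) = \frac{B\sin(x/x_G) + A\sin((L-x)/x_G)}{\sin(L/x_G)},\qquad
0 < L \le \pi x_G,$$

with stationary total $x_G(A+B)\tan(L/(2x_G))$ and a stationary occupancy
density $p(x;L)$ that stays well defined on the whole existence window
(including $L = \pi x_G$, where the profile and total diverge but their
ratio does not).  The band is scored by its differential entropy
$H(L) = -\int_0^L p\ln p\,dx$.

*Logistic model.*  No closed form exists in time, but the stationary front
is exact:

$$N_\infty(x) = \frac32\left(\frac{1-\kappa e^{-x/x_G}}
{1+\kappa e^{-x/x_G}}\right)^{\!2} - \frac12,\qquad
\kappa = \frac{\sqrt3 - \sqrt{1+2N_0}}{\sqrt3 + \sqrt{1+2N_0}},$$

which satisfies $D N'' + rN(1-N) = 0$ identically and $N_\infty(0)=N_0$.
Near the carrying capacity it linearises to
$N_\infty \approx 1 - (1-N_0)e^{-x/x_G}$: a transition zone of width
$x_G$ at the coast, capacity further inland.  Both the exact front and the
approximation accept $N_0$ moderately above 1 (stimulated coastal
construction); $N_0 \ge 7$ is rejected, outside the admissible range of
the constants.

### A note on the two front constant sets

The stationary logistic front for this model family is usually quoted as
$3\big((1-K_0e^{-x/x_G})/(1+K_0e^{-x/x_G})\big)^2 - 2$ with
$K_0 = (\sqrt3-\sqrt{2+N_0})/(\sqrt3+\sqrt{2+N_0})$.  That profile does
hit $N_0$ at the coast and 1 inland, but symbolic differentiation shows it
satisfies $DN'' + \tfrac r2(1-N^2) = 0$ — not the logistic equation; its
logistic residual is exactly $-\tfrac r2 (1-N)^2$, and the time-dependent
solution converges to a profile about $1.3\times10^{-2}$ away from it at
$N_0 = 0.5$.  The two reaction terms agree to first order near $N = 1$,
which is why the discrepancy is invisible at plotting scale and vanishes
as $N_0 \to 1$.  `stationary_logistic_profile()` therefore defaults to the
corrected constants (`form = "exact"`, the fixed point the dynamics
actually select, used by the convergence contracts) and retains
`form = "printed"` for comparison; the test suite asserts the residual
identity of the printed form rather than pretending it solves the model.

## The entropy-selected band width

Within the existence window the band width can be selected by a maximum
entropy principle.  The stationarity condition reduces to
$\tan\!\big(L/(2x_G)\big) = C$ with $C = x_G B/(A+B)$, i.e.

$$L^* = 2\,x_G \arctan C \in (0, \pi x_G),$$

computed by `optimal_band_width_closed()` through the two-argument
arctangent `arctan_xy()` (the angle whose sine is $2C/(C^2{+}1)$ and cosine
$(1-C^2)/(C^2{+}1)$).  For an empty coastal edge ($A=0$) the constant
reduces to $C = x_G$ and $L^*$ is a monotone function of $x_G$ alone; the
occupancy distributions at $L^*$ are coast-skewed, their mode strictly
inland of $L^*/2$.

Two caveats are deliberately left visible rather than resolved:

1. **Dimensions of $C$.**  $C = x_G B/(A+B)$ carries km units inside a
   dimensionless arctangent; equivalently, $p\ln p$ for a density with
   units 1/km depends on the length unit.  The formula is implemented
   verbatim with $x_G$ in km, the package-wide unit.
2. **Closed form vs direct maximisation.**  Direct evaluation shows
   $H(L)$ is *strictly increasing* on the whole window (widening the band
   always raises differential entropy; the closed form's stationarity
   condition drops a boundary term of $dH/dL$), so the brute-force
   maximiser `optimal_band_width_numeric()` — dense 1000-point scan plus
   golden-section refinement, fully deterministic — returns the window
   edge $\pi x_G$, not $2x_G\arctan C$.  `band_width_report()` computes
   **both** widths and their discrepancy and never reconciles them;
   downstream consumers decide which selection principle they mean.

## The numerical integrator

`rd_solve()` is a method-of-lines scheme: second-order central differences
on a uniform grid, Crank-Nicolson for diffusion, and Strang splitting for
the reaction, whose half-steps use the *exact* flow (multiplication by
$e^{r\tau}$ for exponential growth; the closed-form logistic map for
logistic growth), so the splitting error carries no reaction stiffness.
Dirichlet boundaries are imposed by row substitution in the tridiagonal
system — with the staged value pre-compensated through the inverse
half-reaction so the boundary lands exactly on its physical value each
step — and the zero-gradient condition by second-order ghost-node
elimination.  The tridiagonal factors are cached per time-step size, and
runs are bit-reproducible (no randomness anywhere).

Two refinements to the textbook scheme matter here:

* **Rannacher startup.**  The step boundary condition (density jumping to
  $N_0$ at $t=0^+$) excites the undamped oscillatory modes of
  Crank-Nicolson; the first four steps are taken with backward Euler,
  restoring smooth second-order behaviour.
* **Resolution defaults.**  The agreement contract with the closed forms
  is $10^{-3}$ max-abs at the earliest snapshot ($t = 0.1$ yr), where the
  boundary layer is $2\sqrt{Dt} \approx 0.6$ km wide.  A spacing of
  0.1 km leaves a spatial error floor of $1.4\times10^{-3}$ at that time
  regardless of the time step, so the package defaults are **0.05 km**
  spacing with a graded step schedule ($\Delta t$ = 0.001 yr until
  $t=0.1$, 0.01 until $t=1$, 0.1 after; user-set $\Delta t$ is capped at
  1 yr for reaction accuracy).  Measured: $3.5\times10^{-4}$ at $t=0.1$,
  dropping to $3\times10^{-7}$ by $t=100$; halving the spacing cuts the
  error $\approx 4\times$, confirming second order.

The half-line is truncated at $x_{\max}$ (default 100 km) with a
zero-gradient inland condition.  For the decaying models a validity
monitor warns when the inland boundary node exceeds $10^{-6}N_0$ — the
signal that truncation no longer emulates decay at infinity (it trips, for
instance, in the regulated-boundary run by $t = 300$ yr, where the
agreement contract nevertheless still holds).  For the logistic model the
wave is *supposed* to fill the domain, so the monitor is off and
convergence to the stationary front is the contract: the gap falls
monotonically and is $\sim 1.4\times10^{-4}$ by $t = 1500$ yr at default
resolution (well within the $10^{-2}$ contract), the front having to
traverse the domain at the Fisher-type speed $2\sqrt{rD} = 0.2$ km/yr
first.

## Quadrature and special functions

* `duhamel_F()` substitutes $v = b^2/(4w)$ over the whole range, mapping
  $(0,a]$ onto $[b^2/(4a),\infty)$ and turning the near-singular factor
  into a $v^{-1/2}e^{-v}$ tail whose exponent peaks at the lower limit;
  after scaling by that maximum the integrand is bounded for every $a,b$
  (a two-piece split at $w=b^2/4$ with direct quadrature on the large-$w$
  piece was tried first and misdiagnosed as divergent by the adaptive
  quadrature when $b \lesssim 10^{-6}$).  Tolerances: $10^{-10}$ relative for special-function
  quadrature, $10^{-8}$ for cross-route identities — both far below the
  PDE-comparison tolerance.  At $b = 0$ the singularity is unshielded and
  the function refuses (the physical boundary value is supplied by the
  density routine instead, which recovers $N_0$ continuously as
  $x \to 0^+$).
* Entropy integrands use the convention $0\ln 0 = 0$, required when an
  edge density vanishes.
* The occupancy variance is computed both in closed form (exact to machine
  precision) and by trapezoid quadrature (agreeing to $10^{-3}$ at the
  default grids); quadrature totals and moments are exact for the
  discrete trapezoid measure, so the reported variance is never negative.

## What the scenario presets do and do not establish

The presets (`fig2`, `fig3`, `fig4`, `fig6`, `band`, `fig5a`) encode the
reference parameterisations ($D = 1$, $r = 0.01$, $N_0 = 1$ or 0.5, five
snapshot times each).  Green cross-validation tests establish that the
integrator and the closed forms agree *with each other* at those
parameters and that the curve families have the right qualitative
structure (monotone in time, maintained boundary values, far-field decay
or saturation).  They do not validate the models against any empirical
population data — no external data enters the package — and the band
scenarios inherit the dimensional caveat on $C$ above.  The
transition-zone bound ($|N_\infty - 1| < 0.05|N_0 - 1|$ beyond $3x_G$) is
exact for the linearised front, whose decay prefactor is $|1-N_0|$; the
closed-form fronts carry a slightly larger prefactor (e.g. $6\kappa =
0.606$ at $N_0 = 0.5$), so for them the same bound is asserted from
$3.5\,x_G$ on.

## Reproducing the numbers

```{r example, eval = FALSE}
params <- model_params(D = 1, r = 0.01, N0 = 1)
model1_moments(100, params)$variance / 100   # 0.5479 ~ 0.55
band_width_report(A = 0, B = 1, x_G = 10)    # both band widths
compare_analytic_numeric("fig2")             # solver-vs-erfc gaps
```

The acceptance report (`scripts/acceptance.R`) recomputes the spread-rate
coefficient by quadrature and the logistic saturation limit by Runge-Kutta
integration from scratch against the installed package:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

Both quantities are deterministic; the seed only feeds R's RNG for
interface uniformity.
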