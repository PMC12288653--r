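---
title: "Soft modes, simple controllers, and homeostasis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Soft modes, simple controllers, and homeostasis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(softmodes)
```

## The problem

Cells face high-dimensional environmental insults -- nutrient limitations,
osmotic and heat stress, drugs -- yet many of the control systems that
restore homeostasis are strikingly low-dimensional: diverse stresses in
bacteria converge onto the concentration of a single alarmone ((p)ppGpp),
and in yeast onto cAMP. How can a controller that senses one scalar
regulate a network with thousands of interacting components? `softmodes`
implements a modeling framework for this question: a nonlinear gene
regulatory network (GRN) simulator with k-channel proportional-integral
(PI) feedback, an analytic linear theory of what such controllers can and
cannot cancel, in-silico evolution of network parameters under selection
for homeostasis, and the two simulation experiments that turn the theory
into testable predictions (dual buffering and knockout-induced
dimensionality reduction).

The central object is a *soft mode* (dynamical slow mode): an
eigendirection of the Jacobian at the fixed point whose relaxation rate
$|\mathrm{Re}\,\lambda_0|$ is much smaller than all others. The *mode gap*
$|\mathrm{Re}\,\lambda_1| / |\mathrm{Re}\,\lambda_0|$ measures how
pronounced it is. When the gap is large, arbitrary static perturbations
produce state shifts that pile up along the soft mode -- the response
becomes effectively one-dimensional -- and a one-channel integral
controller that senses and acts along that mode can cancel most of the
damage. The package's simulations show the converse as well: *selection*
for homeostasis under a low-complexity controller *creates* the soft mode.

## The nonlinear network model

Expression levels $n_a$ follow Michaelis-Menten production with linear
decay and optional multiplicative environmental forcing and controller
action:

$$\frac{dn_a}{dt} \;=\; \sum_b k_{ab}\,\frac{n_b}{n_b + K_{ab}}
\;-\; \gamma_a n_a \;+\; \delta e_a\, n_a
\;-\; \sum_{i=1}^{k} g^{(i)}_a I_i .$$

Assumptions and choices:

* **Linear decay $-\gamma_a n_a$ (default $\gamma_a = 1$).** With pure
  saturating production and no first-order loss, generic parameter draws
  have no stable interior fixed point; a decay term is the minimal
  addition that produces one. All rates are therefore measured in units of
  the decay rate, and one time unit is one protein lifetime.
* **Quenched environments.** Each forcing vector $\delta e$ is constant
  within an episode; fitness averages over many independent draws
  ($\delta e_a \sim N(0, \sigma_{env})$, default $\sigma_{env} = 0.1$,
  i.e. 10% rate perturbations). This matches the static linear-response
  theory; time-varying environments are out of scope.
* **Non-negativity.** Production terms are evaluated at
  $\max(n, 0)$, so numerically transient negative states cannot generate
  spurious fluxes, and reported trajectories are clipped at zero.
* **Random networks** draw $k_{ab} \sim U(0.5, 1.5)$ with presence
  probability 0.5 (each gene keeps at least one input), $K_{ab}$
  log-uniform on $[0.1, 10]$, and are redrawn until a stable interior
  fixed point exists. These ranges put a typical random network in the
  mildly saturated regime ($n_{wt} \sim$ a few, eigenvalues near
  $-\gamma$), which is the natural "no-gap" starting point.

The controller senses $k$ orthonormal linear projections
$s_i \cdot \delta n$ of the deviation from the wild-type fixed point and
feeds back $I_i = c_p (s_i \cdot \delta n) + c_i \int s_i \cdot \delta n \, dt$
through per-channel action vectors $g^{(i)}$ (default gains
$c_p = c_i = 1$). Per-channel actions (rather than one shared action
vector) are required for the $k = N$ controller to be genuinely complex:
with a shared action the actuation would be rank 1 no matter how many
channels sense. $k$ is the controller's complexity; $k = 1$ mimics
hub-style signaling.

## The linear theory

Linearizing about the fixed point, a static forcing $\delta e$ shifts the
state by $\delta x = -J^{-1}\delta e$. Under one integral-feedback channel
with unit sensing vector $s$ and unit action vector $a$, the closed-loop
steady state is, basis-free,

$$\delta x \;=\; \tilde{\delta e} \;-\;
\frac{s \cdot \tilde{\delta e}}{s \cdot \tilde a}\, \tilde a,
\qquad \tilde{\delta e} = -J^{-1}\delta e,\quad \tilde a = -J^{-1} a,$$

which satisfies $s \cdot \delta x = 0$ exactly (the integral term winds up
until the sensed error vanishes; the proportional gain only shapes
transients). When $s \cdot \tilde a = 0$ the sensed projection cannot be
actuated, integral windup never resolves, and the configuration is
rejected as uncontrollable.

`spectral_model()` idealizes the Jacobian as symmetric with one slow rate
$\lambda_0$ and $N-1$ fast rates $\lambda$ (gap $= \lambda/\lambda_0$).
Sensing and action vectors are parameterized in the plane spanned by the
slow mode $\hat v_0$ and the mean-perturbation direction:
$s = \alpha \hat v_0 + \sqrt{1-\alpha^2}\,\hat\mu$,
$a = \beta \hat v_0 + \sqrt{1-\beta^2}\,\hat\mu$. For $s$ and $a$ to be
unit vectors, $\hat\mu$ must be orthogonal to $\hat v_0$; the package
therefore defines $\hat\mu$ as the normalized component of the ensemble
mean orthogonal to the slow mode, and degenerates the geometry to
$s = a = \hat v_0$ when that component vanishes.

**Which norm is "the" expected deviation?** The expectation of
$\|\delta x\|$ over a Gaussian ensemble has no elementary closed form (it
is a non-central-chi-type integral), while $E\|\delta x\|^2$ is exact:
with response matrix $A$ ($\delta x = A\,\delta e$),
$E\|\delta x\|^2 = \|A\mu\|^2 + \sum_j \sigma_j^2 \|A_{\cdot j}\|^2$.
`expected_deviation()` therefore reports the rms norm
$\sqrt{E\|\delta x\|^2}$ as the primary statistic, and
`mc_expected_deviation()` provides both the rms and the plain-mean
variants by Monte-Carlo; the two routes are compared within Monte-Carlo
error in the test suite (a dual-route check, never collapsed onto one
implementation). With $s = a = \hat v_0$ the closed form reduces to
$\sqrt{\sum_{i \neq 0} (\mu_i^2 + \sigma_i^2)}\,/\,\lambda$: the soft mode
is cancelled exactly and only the fast modes remain, which is also the
large-gap limit of the optimal controller. Normalizing by the
uncontrolled expectation gives a dimensionless robustness score that
decreases monotonically with the gap; its gap-1 minus gap-100 difference
(`gap_benefit()`) grows with the dimensionality $N$, because the single
channel can protect only one direction of an ever-larger space unless the
system itself funnels perturbations into that direction.

`optimal_geometry()` minimizes the closed form over
$(\alpha, \beta) \in [0,1]^2$ with a deterministic $21 \times 21$
warm-start grid followed by bounded quasi-Newton refinement from the three
best cells (tolerance $10^{-6}$); uncontrollable corners (e.g.
$\alpha = 1, \beta = 0$) are assigned a large finite penalty so the
optimizer avoids them smoothly. At gap 100 the optimum is
$\alpha^* = \beta^* = 1$; at gap 1 the slow mode is meaningless and the
optimum aligns with the mean direction instead.

## Fitness and the stiffness normalization

The homeostasis cost of a (network, controller) pair is the mean
steady-state deviation norm over environmental draws, *normalized by the
overall stiffness of the system* so that uniformly accelerating all
dynamics ($J \to cJ$) neither helps nor hurts. Two normalizers are
implemented:

* `"uncontrolled"` (default): divide by the mean deviation norm of the
  same network with the controller knocked out, on the same draws. The
  uncontrolled response $-J^{-1}\delta e$ *is* the system's compliance,
  so this is a direct stiffness normalization, and it coincides with the
  analytic theory's normalized expected deviation -- the quantity whose
  decrease with mode gap defines the fitness benefit of a soft mode.
* `"mean_rate"`: multiply the deviation (relative to $\|n_{wt}\|$) by
  $\mathrm{mean}_i |\mathrm{Re}\,\lambda_i|$.

The default matters. Under the `"mean_rate"` normalizer the residual after
one-channel cancellation is fast-mode content, independent of
$\lambda_0$, so softening the controlled mode improves the cost only
through the mean-rate factor -- an $O(1/N)$ effect that produced no gap
growth in desk-scale annealing runs. Under the `"uncontrolled"` normalizer
the denominator grows with the gap while the numerator does not, giving
the strong, monotone selection pressure the framework describes. Both
normalizers are unit-tested; the evolution experiments use the default.

Fitness is evaluated in `"linearized"` mode (closed-form steady state of
the linearized closed loop, including a full $(N+k)$-dimensional
closed-loop stability check; unstable or uncontrollable proposals get
infinite cost) with `"ode"` mode available and cross-checked against the
linearized mode at small forcing in the tests. Linearized evaluation is
what makes 2000-step annealing runs take seconds rather than hours.

## In-silico evolution

`anneal()` runs Metropolis MCMC with geometric cooling
($T: 0.05 \to 10^{-4}$ over 2000 steps by default) on the nonzero
$k_{ab}$, the $K_{ab}$, and optionally the controller's sensing/action
vectors. Design choices that proved load-bearing:

* **Common random numbers.** Each step draws a fresh environment batch
  shared by the current and proposed parameters, so acceptance decisions
  compare like with like.
* **Bounded parameters.** Proposals are clipped to
  $k_{ab} \in [0.02, 5]$, $K_{ab} \in [0.05, 50]$. Without bounds the
  multiplicative random walk drifts to enormous interaction strengths
  whose Jacobians amplify perturbations through non-normal (shear)
  structure -- strong response channeling with *no* eigenvalue gap, an
  un-biological cheat (rates are bounded) that also decouples the
  response dimensionality from the spectrum. With bounded entries the
  singular values of $J$ are bounded, and since
  $\prod_i |\lambda_i| = \prod_i \sigma_i$, strong channeling forces a
  genuinely slow eigenvalue.
* **Proposal mixture.** With probability 0.2 a proposal rescales all of
  $k_{ab}$ or all of $K_{ab}$ by one shared log-normal factor. A global
  $K$ scale walks the network along its saturation/criticality axis:
  as the system leaves saturation, the Perron eigenvalue of the
  production Jacobian approaches the decay rate and $\lambda_0 \to 0$.
  This is the accessible route to a soft mode; pure per-entry jitter
  finds it too slowly at desk scale.
* **One component per step.** When both the network and the controller
  are evolvable, each step mutates one of them (70/30), never both: a
  joint proposal lets a bad controller move veto a good network move.
  This change alone took the k = 1 arm from roughly half to all seeds
  evolving a gap within 2000 steps.
* **Elitism.** The best-so-far parameters are retained and reported
  alongside the final state; the best-so-far cost is non-increasing by
  construction.

With $N = 10$, 20 environment draws per evaluation, and 2000 steps, the
k = 1 arm reliably drives $\lambda_0$ toward the critical boundary where
the interior fixed point would vanish (final mode gaps $10^3$--$10^5$;
the magnitude is set by how close to criticality the chain can sit, not
by a tuned target), while the k = 10 arm -- whose full-observability
controller already achieves near-perfect adaptation -- leaves the gap at
its initial value around 1.2. A side effect of full observability is that
the k = N linearized cost is already $\approx 0$ at the start, so for
that arm "selection works" can only mean the cost does not worsen; the
acceptance test encodes exactly that.

## The two experiments

**Dual buffering.** Mutations are multiplicative parameter perturbations
$(1+\varepsilon)$, $\varepsilon \sim N(0, 0.05)$ by default, and the
mutant's deviation is measured against the *ancestral* fixed point (the
deviation of interest is loss of the ancestral homeostatic state, and the
integral controller's set point stays at the ancestral value; measuring
against the mutant's own fixed point would erase precisely the effect
being studied). The experiment compares mean deviation norms with the
co-evolved controller active versus knocked out, on identical draws
(paired design), in all four cells {gap, no-gap} x {environmental,
mutational}. The no-gap arm uses the same starting network with only its
controller evolved (network mutation off), i.e. a controller selected for
environmental robustness in the absence of a gap. Expected pattern: the
gap network's controller buffers both perturbation kinds (ratios well
below 1), the no-gap controller buffers essentially neither (ratios near
$\sqrt{(N-1)/N} \approx 0.95$ at $N = 10$ -- one cancelled direction out
of ten). Mutant draws whose (closed-loop) linearization is unstable are
excluded and counted; near criticality this happens to an appreciable
fraction of draws, which is itself a faithful feature of sitting at a
critical boundary.

**Knockout dimensionality.** Many environmental draws are pushed through
the evolved (network, controller) pair and through its knockout;
`ensemble_effective_rank()` (exp of the Shannon entropy of PCA variance
fractions of the mean-centered response cloud) and the PC1 share quantify
each cloud's dimensionality. With the controller active the soft mode is
cancelled and the response spreads over fast modes; knocked out, the
response collapses onto the soft mode: PC1 share rises and effective rank
falls -- the counterintuitive prediction that *removing* a controller
*lowers* the dimensionality of the response.

## What the synthetic world does and does not establish

All data in this package are generated by its own models: random MM
networks, spectral (single-slow-mode, symmetric) linear fixtures, and
Gaussian perturbation ensembles. A green test establishes internal
consistency of the framework -- the analytic formulas, their Monte-Carlo
checks, the ODE integrator, and the evolutionary dynamics agree with each
other at stated tolerances -- and that the qualitative predictions emerge
from the stated mechanism. It does not establish anything about real
regulatory networks: real Jacobians are non-normal (the spectral fixtures
are symmetric by construction), real noise is neither Gaussian nor
quenched, gains and sensing in cells are not orthonormal projections, and
the empirical analyses that motivated the framework (yeast knockout
fitness screens, kinase-inhibition transcriptomics) are deliberately out
of scope.

## Numerical choices

* **Integrator:** no ODE-solver package exists in the supported
  dependency set, so the package ships a self-contained Dormand-Prince
  RK45 with embedded 4th/5th-order error control and PI step-size
  adaptation (`ode_rk45()`), validated against matrix-exponential
  solutions of linear systems. Tolerances: rtol $10^{-8}$, atol
  $10^{-10}$. It is adaptive but explicit; the rate ratios here (of order
  the mode gap) are within its comfortable range because steady-state
  integrations stop early at $\|\dot n\| < 10^{-8}\|n_{wt}\|$, with
  horizon $t_{max} = 10^3 / |\mathrm{Re}\,\lambda_0|$.
* **Fixed points:** damped production/decay iteration to reach the basin,
  then Newton with the analytic Jacobian and backtracking line search;
  convergence declared at residual norm $10^{-10}$, the origin flagged as
  degenerate.
* **Eigen order:** ascending $|\mathrm{Re}\,\lambda|$ (relaxation speed is
  set by real parts); complex pairs stay adjacent; the mode gap uses real
  parts only and is exactly 1 for tied slow modes.
* **Serialization:** JSON at 17 significant digits (exact double
  round-trip), matrices row-major; loading re-validates all invariants.
* **Seeding:** one global seed; every stochastic component derives a
  31-bit substream seed from it with a named salt (`derive_seed()`), so
  adding a component never shifts existing streams, and every published
  CSV is bit-reproducible from its config and seed.

## Known limitations

* The linearized fitness is exact only near the fixed point; at the
  evolved extreme gaps the linear amplification $1/\lambda_0$ of a 10%
  forcing far exceeds the linear regime, so evolved-fixture experiment
  results should be read as linear-theory statements (the regime the
  analytic framework describes), spot-checked nonlinearly at small
  forcing.
* Single slow mode only: the spectral model and the optimal-geometry
  theory do not cover several comparably slow modes.
* The annealer is a search heuristic, not a sampler of any stated
  stationary distribution; only Metropolis-consistency sanity properties
  are tested.
* Actuator saturation, sensing noise, delays, and stochastic (Langevin /
  Gillespie) dynamics are out of scope.
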