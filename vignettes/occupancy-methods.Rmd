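---
title: "Modeling calcium sensor occupancy by first-passage analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling calcium sensor occupancy by first-passage analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(occusens)
```

## The model

`occusens` computes the probability $P(t, r)$ that a single Ca$^{2+}$ ion,
released at radial distance $r$ from the centre of a presynaptic active
zone, is bound to the vesicle-fusion sensor at time $t$. The active zone
is a reflecting hemisphere of radius $R$; the sensor is a partially
absorbing hemisphere of radius $\rho$ at its centre; the ion source (a
voltage-gated calcium channel) sits on the membrane at coupling distance
$\mathrm{CD} = r - \rho$ from the sensor surface. By mirror symmetry in
the membrane plane the problem reduces to a spherical shell
$\rho < |x| < R$ and, by rotational symmetry, to the radial coordinate
alone.

The ion switches among $M + 1$ states: free (diffusivity $D_0$) or bound
to buffer $i$ (diffusivity $D_i$, possibly zero for a fixed buffer).
Buffers are linear, homogeneous reactive media: exchange happens with
rates $k_{0i} = k_{\mathrm{on},i} c_i$ and $k_{i0}$, and a buffer-bound
ion cannot touch the sensor. Sensor binding is reversible: a Robin
(radiation) condition with intrinsic rate constant $k_\mathrm{on}$
controls attachment, and a bound ion detaches after an exponential
residence time with rate $k_\mathrm{off}$.

The computation has two layers:

1. **Survival problem.** The Laplace-transformed survival probabilities
   $\tilde S_i(p, r)$ of the switching diffusion satisfy a coupled radial
   ODE system with Neumann conditions at $R$ (and at $\rho$ for bound
   states) and the Robin condition at $\rho$ for the free state. Fixed
   buffers are eliminated algebraically (they contribute a $p$-dependent
   effective exchange rate); mobile buffers are kept as extra field
   components and the coupling matrix is diagonalized per $p$, giving
   $2(M+1)$ spherical-Helmholtz radial modes whose coefficients follow
   from the boundary conditions. The first-binding density is
   $\tilde\psi_1 = 1 - p \tilde S_0$.
2. **Renewal closure.** Alternating bulk excursions and exponential
   residences give the occupancy transform
   $\tilde P(p,r) = \tilde\psi_1(p,r) / (p + k_\mathrm{off}(1 -
   \tilde\psi(p)))$, with $\tilde\psi(p) = \tilde\psi_1(p, \rho)$ the
   re-binding density (excursions restart at the sensor surface).

Returning to the time domain uses either an exact residue series over the
relaxation spectrum (poles of $\tilde P$ on the negative real axis) or
fixed-Talbot contour quadrature. Both backends are exposed and
cross-validated; `backend = "auto"` uses the closed-form series for
buffer-free configurations and Talbot otherwise.

## Parameters, units, defaults

Internally everything is expressed in nm, ms, and mM; Avogadro's constant
enters explicitly when converting bimolecular rate constants
($1\ \mathrm{mM^{-1}ms^{-1}} = 10^{27}/N_A\ \mathrm{nm^3 ms^{-1}}$).
The reference parameter set (also shipped as
`inst/extdata/reference_config.yaml`) is:

| quantity | default | unit |
|---|---|---|
| bouton radius $R$ | 300 | nm |
| sensor radius $\rho$ | 5 | nm |
| coupling distance | 15 | nm |
| $D_0$ | 0.22 | µm²/ms |
| $k_\mathrm{on}$ | $5 \times 127$ | mM⁻¹ms⁻¹ |
| $k_\mathrm{off}$ | 15.7 | ms⁻¹ |

plus three optional buffers: an endogenous fixed buffer (EFB, 4 mM,
$k_{01} = 400$ ms⁻¹, immobile), ATP (0.2 mM, mobile, $D = 0.2$ µm²/ms)
and EGTA (10 mM, slow, $D = 0.22$ µm²/ms).

### The sensor area convention

The Robin constant is $\kappa = k_\mathrm{on} / (N_A \, a \pi \rho^2)$,
and the choice of $a$ is a genuine modeling ambiguity for a hemispherical
sensor on a membrane: the radiation condition for an interaction sphere
is conventionally written with the full area $4\pi\rho^2$ ($a = 4$,
`area_convention = "sphere"`), but the physically exposed sensor surface
is the hemisphere $2\pi\rho^2$ ($a = 2$, `"hemisphere"`), which doubles
the surface reactivity and, consistently, halves the accessible volume in
the steady-state formula. The two conventions bracket published reference
values for this system: peak occupancies and peak times across coupling
distances (0.027 at 5 nm through 0.001 at 95 nm, 6.1–47.5 µs) are
reproduced by the `"sphere"` convention, while the often-quoted
steady-state levels ($10^{-3}$ at $R = 300$ nm, $3\times10^{-4}$ at 500
nm) correspond to `"hemisphere"`; no single convention reproduces both
families at once, which we read as an inconsistency in how those
reference numbers were produced rather than as physics. The package
defaults to `"sphere"` — the form in which the boundary condition is
printed and the one that matches the dynamic (peak) quantities — and
keeps `"hemisphere"` selectable per configuration.

## Numerical choices

* **Radial basis.** Each eigenmode contributes the pair
  $e^{-q(r-\rho)}/r$ and a scaled $\sinh$ mode that tends to
  $(r-\rho)/r$ as $q \to 0$; this keeps the boundary linear system
  well-conditioned from $|q| \to 0$ (late times on the Talbot contour)
  up to large $|q|$ without overflow.
* **Residue series, no buffer.** The dimensionless roots $\alpha_n$ of
  the spectrum equation are bracketed by a scan in steps of
  $\pi/(40\beta)$ and polished by bisection to residuals below
  $10^{-12}$; coefficients are closed-form. Truncation is chosen so the
  fastest retained mode has decayed by $e^{-40}$ at the earliest
  requested time (capped at 1500 roots; earlier times fall back to
  Talbot).
* **Residue series, buffered.** The poles of $\tilde P$ lie numerically
  very close to the poles of $\tilde S_0$ itself (near pole–zero pairs),
  so the pole condition $1 + k_\mathrm{off}\tilde S_0(p, \rho) = 0$ is
  multiplied by the boundary determinant to form an *entire* bordered
  determinant $E(p)$ whose sign changes are scanned safely; fixed buffers
  add a pole family accumulating at $p = -k_{i0}$, resolved by inserting
  analytically estimated scan points $p_j \approx -k_{i0} + C/j^2$.
  Residues come from Richardson-extrapolated centred differences of $E$.
  The spectrum of this detailed-balance system is real, so the search is
  restricted to the negative real axis; the series is cross-validated
  against the independent Talbot backend in the test suite (agreement
  better than $5\times10^{-7}$ for all three reference buffers across
  seven time decades). Degenerate (non-simple) poles and the
  perfectly-absorbing or $k_\mathrm{off}=0$ buffered corners are not
  covered by the series and raise an error pointing to the numeric
  backend.
* **Talbot inversion.** Fixed-Talbot with 48 nodes; more nodes amplify
  roundoff faster than they reduce truncation error in double precision.
* **Peak metrics.** Peaks are refined by a local quadratic fit in
  log-time around the grid maximum; FWHM is measured from baseline zero
  by linear interpolation of the half-peak crossings; the reported peak
  may therefore differ in the last digit from a raw grid maximum.

## Stochastic influx

A single voltage-gated channel is modeled as a sequential
Hodgkin–Huxley-type chain ($C_1 \rightleftharpoons C_2 \rightleftharpoons
C_3 \rightleftharpoons O$ with rates $3a, 2a, a$ and $b, 2b, 3b$),
exponential voltage dependence of the gate rates, and an ohmic unitary
current. The published constraints for this channel are summary
statistics — opening probability 0.3 per action potential, unitary
current 0.3 pA, mean-current FWHM 250 µs — not rate constants, so the
default parameters were calibrated once against those three targets under
the reference Gaussian action potential (110 mV above a −70 mV rest,
0.4 ms FWHM): the defaults give opening probability ≈ 0.31, unitary
current 0.3 pA, and mean-current FWHM ≈ 250 µs. `calibrate_channel()`
re-runs that procedure for user-supplied waveforms. Gating is simulated
by exact-jump thinning with piecewise-constant rate bounds, and ion
entries while open are drawn from the inhomogeneous Poisson process whose
intensity is the instantaneous current over $2e$, sampled by inverting
the integrated intensity (the expected count is preserved exactly).

Per-trial occupancies combine single-ion curves through the
Poisson-binomial complement product; an ion entering at $t_i$ contributes
its occupancy at *elapsed* time $t - t_i$ and nothing before it enters —
the only causal reading of the shifted-time formula.

## The particle-based validator

`simulate_ions()` is a Brownian-dynamics re-implementation of the kind of
particle simulation usually delegated to MCell: Gaussian steps with
state-dependent diffusivity, per-step Markov buffer switching with
probabilities $1 - e^{-k\,\Delta t}$, specular reflection at the plane
and the outer hemisphere (radial fold-back, iterated), and binding on
sensor contact with the Robin-consistent surface probability
$\kappa\sqrt{\pi\,\Delta t / D_0}$. This endpoint-crossing rule converges
to the radiation condition as $\Delta t \to 0$; its $O(\sqrt{\Delta t})$
bias is quantified by the dt-refinement test rather than corrected
ad hoc. For a *perfectly* absorbing sensor the endpoint rule alone
misses in-step contacts, so a Brownian-bridge radial excursion test
($P_\mathrm{touch} = e^{-d_1 d_2 / (D_0 \Delta t)}$) is added; with it
the empirical first-passage CDF matches the analytic curve to a
Kolmogorov–Smirnov distance below 0.005 at $10^4$ trials.

Buffers are simulated as per-ion state switching, not as explicit buffer
molecules — exactly the homogeneous-medium assumption of the analytical
model. That makes the validator a test of the *solution*, not of the
linear-buffering assumption itself; it also removes the particle-count
bottleneck that makes millimolar chelator concentrations prohibitive for
explicit-particle simulators. Saturation is available through
`sensor_capacity`: with `"single_site"` the bound count per trial cannot
exceed one, which is the mechanism excluded by the analytical
independence approximation, and the test suite checks the resulting peak
and width are bounded by the independence formula at $N = 50$ ions.

Simulation sizes in the test suite (up to $10^4$ trials, 20 ns steps,
sub-millisecond horizons) were chosen as the smallest runs whose Monte
Carlo errors are tight enough to make the 3-SEM comparisons meaningful;
they are scaled-down relative to cluster-scale campaigns but exercise the
same estimators.

## The five-state release sensor

`integrate_release()` drives the cooperative five-site sensor
($V_0 \ldots V_5$, forward rates $(5-i) k_\mathrm{on} [\mathrm{Ca}](t)$,
backward rates $(i+1) k_\mathrm{off} b^i$ with $b = 0.25$, fusion
$V_5 \xrightarrow{\gamma} F$) over an arbitrary piecewise-linear calcium
transient. The exponent convention $b^0 \ldots b^4$ on the backward rates
is followed as printed. The default integrator is an adaptive embedded
Runge–Kutta pair (`deSolve`, `ode45`) with a forward-Euler compatibility
mode; both preserve the linear conservation law
$\sum_i V_i + F = 1$ to machine precision, and the adaptive path is
checked against a matrix-exponential oracle to $10^{-8}$ on frozen-rate
segments. Spatio-temporal transients from full reaction–diffusion
simulations are deliberately out of scope: the module accepts any
user-supplied or synthetic transient (e.g.
`gaussian_ca_transient()`), so knockout experiments
($k_\mathrm{off} = 0$) are expressed as directional comparisons —
removing unbinding can only increase fusion, and the gain grows as the
transient weakens — rather than as reproductions of any specific
published ratio, which depend on unpublished input transients.

## What the synthetic conditions do and do not show

The generator-driven tests demonstrate internal consistency (series vs
contour inversion vs particle simulation vs closed forms) under the
model's own assumptions: point-like ions, linear buffering, an unlimited-
or single-site sensor, no extrusion, no baseline calcium, no electrostatics.
They cannot detect failures of those assumptions in real terminals —
saturating buffers at high flux, crowding, or channel cooperativity.
Results at times beyond ~100 ms should additionally be read with
extrusion in mind, which the model omits.

## Known limitations

* The buffered residue series truncates the fixed-buffer pole family
  accumulating at $p = -k_{i0}$; with the default budgets the residual is
  below $10^{-6}$, and the Talbot backend is free of this truncation.
* The analytical multi-ion formulas assume unlimited sensor capacity and
  overestimate occupancy when the single-site peak probability is large
  (short coupling distances, hundreds of synchronous ions); the
  single-site particle mode quantifies that gap.
* `P(t, r)` is a single-sensor quantity; multiple channels are handled by
  superposition of per-ion source positions, but multiple competing
  sensors are not modeled.
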