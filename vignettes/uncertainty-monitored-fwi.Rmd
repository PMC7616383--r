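---
title: "Uncertainty-monitored full-waveform inversion: model, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uncertainty-monitored full-waveform inversion: model, numerics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(svifwi)
```

## The model

Ultrasound computed tomography reconstructs a map of sound speed $c(x)$
from pressure recordings made around an object. Full-waveform inversion
(FWI) fits a full numerical simulation of the acoustic wave equation

$$ \frac{1}{c^2}\,\partial_t^2 u - \nabla^2 u = \varsigma(x_s, t) $$

to the observed shot gathers $d$ by minimising the data misfit
$\Gamma(m) = \tfrac12\lVert d - L(m)\rVert_2^2$, where $L(m)$ extracts the
simulated wavefield at the receivers and $m = c$ are the per-pixel sound
speeds. The gradient of $\Gamma$ is computed with the adjoint-state method:
one forward simulation, one simulation of the time-reversed residual
injected at the receivers, and a zero-lag correlation of the two fields —
two wave solves per shot instead of one per pixel.

`svifwi` treats this inversion as stochastic variational inference under a
mean-field Gaussian approximating distribution: each pixel's sound speed is
modelled as $\mathcal N(\mu, \sigma^2)$ with independent pixels, and the
variational parameters are $\lambda = \{\mu, \Sigma\}$ with $\Sigma$ the
grid of *signed* standard deviations. Using the reparameterisation trick, a
model sample is the deterministic transform

$$ m^{(i)} = \mu + \Sigma \odot \epsilon^{(i)}, \qquad
   \epsilon^{(i)} \sim \mathcal N(0, I), $$

so the pathwise derivative of the (Gaussian) data likelihood with respect
to $\mu$ is exactly the familiar FWI misfit gradient $\Delta m$ evaluated
at the sampled model, and the derivative with respect to $\Sigma$ is
$\epsilon^{(i)} \odot \Delta m$ — the *same* adjoint-state gradient,
recycled through one elementwise product. Per iteration the loop therefore:

1. draws one $\epsilon$, forms $m^{(i)} = \mathrm{clip}(\mu + \Sigma\odot\epsilon)$;
2. accumulates $\Delta m$ over the iteration's source batch (two wave
   solves per shot);
3. updates $\mu \leftarrow \mu - \alpha\,\Delta m$ and
   $\Sigma \leftarrow \Sigma - \alpha\,(\epsilon \odot \Delta m)$.

The variance image read out at any iteration is $\Sigma^2$ elementwise. The
$\Sigma$ update costs one elementwise product — no wave simulation — which
is why the uncertainty estimate is effectively free; the test suite
enforces this with a simulation counter and a wall-clock bound.

Two structural properties follow directly and are tested exactly:

* with $\Sigma \equiv 0$ (or $\epsilon$ forced to zero) the $\mu$
  trajectory is bit-identical to deterministic FWI;
* the mean-field $\Sigma^2$ ignores inter-pixel correlation; it is a
  qualitative image-quality monitor, not a calibrated posterior variance.

The regularisation weight is zero: the prior
($\mu = 1480$ m/s, $\sigma^2 = 4$ (m/s)$^2$ by default) only initialises
the iteration. Signed $\Sigma$ is never clamped; squaring happens at
read-out.

### Sign conventions

The source derivations write the mean update both as $\mu - \Delta m$ and
$\mu + \Delta m$ in different places (and drop a Gaussian minus sign once).
This package fixes the convention *descend the misfit*: $\Delta m$ is the
gradient of $\Gamma$ and both updates subtract $\alpha \Delta m$-terms.
This makes the $\epsilon = 0$ limit literally gradient-descent FWI; the
choice is internal-consistency over literal transcription.

## The wave solver

* **Discretisation.** Explicit time stepping, second order in time, with a
  centred tenth-order Laplacian (as in the reference numerical study).
  The stability limit for this stencil in 2D is
  $c_\max\,\Delta t/\Delta x \le 2/\sqrt{2 S} \approx 0.541$ with $S$ the
  alternating-sign coefficient sum; `check_stability()` reports the Courant
  number against it, and the test suite verifies by an energy probe that
  runs just under the limit stay bounded while runs above it blow up.
* **Absorbing boundary.** The grid is extended by a 40-cell sponge carrying
  a friction term $u_{tt} = c^2\nabla^2 u - 2\gamma\,u_t$ with a quadratic
  ramp $\gamma \propto (\text{depth}/W)^2\,c_\max/\Delta x$. Damping is
  defined per unit time, so absorption is independent of the time step —
  essential here because observed data are deliberately generated at a
  refined step. A multiplicative per-step taper was evaluated first and
  rejected: its absorption changes with $\Delta t$ and it reflected roughly
  10% in amplitude, versus a few tenths of a percent for the friction
  sponge.
* **Variable density.** For mismatched-physics data generation the solver
  integrates $\rho c^2 \nabla\!\cdot\!(\rho^{-1}\nabla p)$ expanded as
  $c^2\nabla^2 p - c^2\,\nabla(\ln\rho)\!\cdot\!\nabla p$ with tenth-order
  first derivatives. The expanded form is used (rather than a staggered
  flux form) so that with uniform density the operator is *identical* to
  the constant-density solver — the two agree to floating precision, which
  the tests assert.
* **Source/receiver stencils.** Nearest-grid-point injection and extraction
  by default; a bilinear stencil is available by configuration for off-grid
  positions. Note that at coarse grids (4 points per wavelength) sub-cell
  stencil differences change radiated amplitudes by tens of percent, so
  observed and predicted data must use the same gridding scheme.

## The exact discrete gradient

`imaging_condition()` implements the gradient of the *discrete* misfit, not
a discretisation of the continuous gradient. For the update
$u_{n+1} = A\,(2u_n + \Delta t^2 C\,(L u_n + s_n)) - AB\,u_{n-1}$ (with
$C = c^2$ and $A, B$ the sponge factors), transposing the full space-time
system gives a backward recursion for the adjoint field $w$, and

$$ \frac{\partial\Gamma}{\partial c} =
   -2c\,\Delta t^2 A \sum_{n} w_{n+1}\odot\big(L u_n + s_n\big). $$

Through the wave equation itself, $C(Lu + s)$ *is* $\partial_t^2 u$, so
this is the classical zero-lag correlation of the adjoint field with the
second time derivative of the forward field in the $-2c^{-3}$ weighting —
but written against the solver's own algebra it is exact to rounding. The
payoff is verifiable: the dot-product (adjoint) identity holds to machine
precision and the gradient matches central-difference misfit derivatives to
much better than the 1% test tolerance, with no tuning of probe steps.

Wavefield snapshots are stored at every time step (decimation is
configurable for diagnostics, but the imaging condition requires
undecimated stores and says so). The forward store keeps the padded grid so
the correlation can form $Lu$ near the imaging-region edge correctly; the
returned gradient covers the user grid only, the sponge being outside it.

## The optimisation loop

* **Step size.** No step-size rule is given in the source material. The
  package scales $\alpha$ once so that the first mean update's max-norm is
  `step_frac` of the mean prior speed and then holds it fixed, sharing the
  same $\alpha$ between the $\mu$ and $\Sigma$ updates so the two stay on a
  common scale. The default `step_frac` is 1%: deterministic convergence
  studies on the benchmark phantom showed that 0.5% stalls the
  low-wavenumber interior component about 10 m/s short of the true
  inclusion speed within the two-epoch budget, while 1% converges and
  remains stable.
* **Preconditioning.** The batch gradient is divided by the normalised
  source-illumination map $\sum_t u^2$ (plus $10^{-2}$), the standard
  diagonal pseudo-Hessian compensation for geometric spreading. Without it
  a fixed-step descent spends its step budget at the transducers and
  starves the domain interior. `shot_gradient()` itself always returns the
  exact misfit gradient (the oracle tests depend on that); preconditioning
  happens inside `run_inversion()`, and the $\mu$ and $\Sigma$ updates
  recycle the identical preconditioned field.
* **Batching.** One Monte-Carlo draw per iteration, exactly as in the
  reference algorithm; the source batch defaults to
  `ceiling(n_sources/51)` per iteration in a deterministic round-robin, so
  an epoch over 32 sources is 32 iterations.
* **Clipping.** Sampled models are clipped to a physical band
  (default 1300–1800 m/s) before propagation to protect solver stability;
  clip counts are logged per iteration. The clip band, not the sampled
  model, is what `check_stability()` should be budgeted against when
  choosing $\Delta t$.
* **Termination.** Fixed iteration budget (default 76), with an optional
  early stop on the flattening of the mean-variance trace.

## The synthetic study conditions

The in-silico benchmark is a circular inclusion (sound speed 1540 m/s,
density 1010 or 1220 in the matched/mismatched cases) in a 1500 m/s,
1010-density background, probed by co-located single-element
sources/receivers on a surrounding circle with a 370 kHz Ricker source,
low-pass filtered at 700 kHz; the reference discretisation is a
200 × 200 grid at 0.5 mm.

`desk_config()` keeps that grid *resolution* — about 8 grid points per
centre-frequency wavelength and 4.3 at the pass-band edge, the same
dimensionless sampling as the reference study — and halves the *domain*
instead: 100 × 100 cells (50 mm), a 25 mm inclusion, 32 elements on a
40 mm circle, two epochs over the sources. The alternative of keeping the
domain and doubling the spacing to 1 mm was evaluated and rejected: at
700 kHz that grid carries two points per wavelength, where neither the
stencil nor any point-source representation is meaningful (the residual
between two discretisations of the *same* model reaches ~40% of the data
energy). Halving the domain preserves every wavelength-per-cell ratio and
keeps each full experiment around a minute of CPU.

Problem sizes used by the tests and the acceptance script: 100 × 100 grid
(180 × 180 padded), 700 time steps of 0.05 µs (35 µs of two-way time),
32 shots, 64 iterations; the gradient-oracle and adjoint tests run on a
40 × 40 grid with 2 sources and 4 receivers.

* **Inverse-crime avoidance.** Observed data are generated at a 2× refined
  time step and decimated to the inversion's sampling, so the inversion
  never sees its own exact discretisation. With the friction sponge and
  the tenth-order stencil the remaining discrepancy at the true model is
  ~$10^{-4}$ of the data energy — real signal mismatch dominates
  everywhere it matters. A half-cell grid-shift variant is also
  implemented (`grid_shift`); it is not the default because at ring-array
  geometries the sub-cell source-stencil differences it induces are far
  larger than the discretisation effect it is meant to probe.
* **Cycle-skipping analogue.** The skip experiment starts the inversion at
  a 1400 m/s prior (a traveltime error beyond half a period across the
  array) and raises the pass-band to 1 MHz, removing the multiscale safety
  net — the desk-scale counterpart of filtering experimental data at a
  skip-inducing band.
* **Source-position artefact.** A contiguous arc of 4 of the 32 sources is
  displaced 2 mm along the array tangent in the *data generation only*;
  the inversion assumes the nominal geometry. Offset magnitude and
  affected fraction are configurable (`corruption_spec()`); the reference
  experiment's exact values are not published, so these are package
  choices.
* **Compared runs share settings.** For the mismatch/skip/artefact
  comparisons the corrupted run reuses the matched run's $\alpha$ (and the
  same seed, hence the same $\epsilon$ sequence), so the compared
  trajectories differ only through the data. Left to normalise its own
  step, a run with extra residual picks a smaller $\alpha$ that largely
  cancels the variance elevation the comparison is looking for.

### What the generator does not emulate

No electronic or thermal measurement noise, no transducer directivity or
finite aperture, no out-of-plane (2.5D) propagation, no attenuation or
elasticity, and no real excitation waveform. Passing tests demonstrate the
estimator's behaviour under controlled epistemic errors (wrong density
physics, wrong geometry, skip-inducing bands) — not performance on
experimental data, whose headline figures depend on an undeposited dataset
and are treated as reference behaviour only.

## Quality-control heuristics

`variance_trend()` reduces the mean-variance trace to peak location,
final/peak ratio, and the least-squares slope of the trailing third.
`flag_failure()` fires when the tail slope is positive *and* the final
variance exceeds twice a matched-run reference or the trace's own early
level — thresholds are explicit package heuristics (the source material
reports patterns, not rules) and are configurable. `artefact_mask()`
block-averages the variance image and thresholds at median + 5 MAD, which
makes it invariant to uniform rescaling; connected components are reported
with the mask. SSIM uses a uniform 7 × 7 window with the conventional
constants ($K_1 = 0.01$, $K_2 = 0.03$, sample covariance), cross-checked
against an independent reference implementation to $10^{-6}$ on frozen
fixtures.

## Numerical edge cases

* Degenerate inputs fail loudly: zero/negative speeds, non-finite traces,
  cutoffs at or above Nyquist, inclusions outside the grid, undecimated
  store violations, mid-run field overflow (abort with the failing step).
* A zero wavelet yields an exactly zero gather; gradients are exactly zero
  for a zero residual — both are identities of the linear solver, not
  tolerance checks.
* With `var_prior = 0` sampling degenerates to the deterministic path but
  still consumes RNG draws; `deterministic = TRUE` consumes none. The two
  $\mu$ trajectories are bit-identical, which is tested.
* Ties in the round-robin batching do not exist by construction; the batch
  schedule is a pure function of the iteration index.

## Limitations

The mean-field variance is a relative, uncalibrated diagnostic: its
absolute scale depends on the step size and the residual level, so
comparisons are meaningful between runs sharing settings (which the
experiment wrappers enforce) rather than across configurations. Second
order (Hessian) uncertainty, full-covariance Gaussians, score-function
estimators, 3D and elastic physics are out of scope.
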