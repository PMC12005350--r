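---
title: "Methods: uncertainty quantification for SEIR universal differential equations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: uncertainty quantification for SEIR universal differential equations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and algorithmic
choices: what is computed, which knobs matter, which decisions were open and
how they were settled, and what the synthetic experiments can and cannot
show.

## The model

The data-generating system is the four-compartment SEIR model with a
time-varying transmission rate β(t),

$$\dot S = -\beta(t)\,S I/N,\quad
  \dot E = \beta(t)\,S I/N - \alpha E,\quad
  \dot I = \alpha E - \gamma I,\quad
  \dot R = \gamma I,$$

observed through $h(x) = (I, R)$ at 30 time points. Two β forms are
registered: a **pulse** (0.05/day strictly inside the 15–30 day window,
0.5/day outside; a time-limited intervention) and **waves**
($0.3\cos((-1+\sqrt{1+4t})\cdot 1.5 + 0.25\pi) + 0.4$; an oscillation whose
image lies in [0.1, 0.7]). Observation noise is either additive Gaussian
with constant sd σ or negative binomial with mean $\bar y$ and dispersion
$d$ under the $\mathrm{Var} = \mu + \mu^2/d$ (Gamma–Poisson) convention —
the dominant reading of "mean and dispersion" parameterizations.

The *fitted* model replaces the unknown β(t) by a feed-forward network on
scaled time $t/t_{max}$: two hidden tanh layers of 10 units and a final
squashing $\beta_{max}(\tanh z + 1)/2$, so the rate is bounded in
$(0, \beta_{max})$ by construction ($\beta_{max} = 1$ by default). The full
parameter vector $\theta = (\theta_{mech}, \theta_{net}, \theta_{np})$
lives in unconstrained space: α and γ map into (0, 1)/day through
$lb + (ub-lb)(\tanh u + 1)/2$ and the noise parameter through $\exp u$.
Both transforms are smooth bijections, so every back-end works on all of
$\mathbb{R}^{144}$.

### Defaults of the generator

True mechanistic constants and initial states for the training scenarios
are α = 0.2/day, γ = 0.3/day, N = 1 (fractional populations),
x₀ = (0.99, 0, 0.01, 0), horizons [0, 60] days for the pulse (placing the
intervention window in the interior) and [0, 30] for the waves, with 30
equidistant observation times. These are plausible magnitudes for a slow
SEIR outbreak and every one of them is config-overridable; tests depend on
invariants and on recovery of whatever the config used, never on the
specific constants. Under these defaults the waves outbreak is shallow
(I stays near 0.01), which matters for β identifiability below.

## Numerical core

- **Truth integration** uses `deSolve::ode` (Dormand–Prince `ode45`) with
  rtol = atol = 1e-8. 1e-6 was tried first and rejected: by the end of the
  pulse horizon the accumulated global error reaches ~1.5e-4, above the
  1e-4 agreement this package demands against a dt = 1e-3 fixed-step RK4
  oracle. The pulse scenario additionally restarts the integrator at the β
  discontinuities (t = 15, 30), standard practice for piecewise-defined
  right-hand sides.
- **Fitting and sampling** use a compiled classical RK4 solver at fixed
  step dt = 0.25 days (≈ 1e-6 state error on these smooth dynamics; the
  network-β UDE has no discontinuities). Exactness of gradients is
  obtained by propagating **forward sensitivities through the same RK4
  discretization**: for explicit Runge–Kutta schemes, integrating the
  sensitivity ODE with the same steps is algebraically identical to
  differentiating the numerical solution, so the gradient of the discrete
  log-likelihood is exact to machine precision (verified against central
  finite differences at rel. error < 1e-4). The noise coordinate enters the
  likelihood only, analytically.
- **Degenerate inputs**: a simulation producing non-finite or exploding
  states yields a −∞ log-density sentinel — samplers reject, ensembles
  discard, nothing throws. Negative-binomial means are clamped at 1e-10
  (solver micro-negativity), with a zero subgradient where the clamp is
  active.

## Ensemble back-end

`m` initializations are drawn from the prior (isotropic N(0,1) on network
weights, N(0,1) on unconstrained rates, N(log 0.1, 1) on the log noise
parameter — weakly informative and finite everywhere). Each member gets its
own random 80/20 train/validation split (the second randomness source),
and is trained by Adam (step 1e-2, up to 2000 epochs) on the training NLL
plus an L2 penalty (1e-4) on the network weights only. Early stopping
monitors the *unpenalized validation NLL* with patience 100 and restores
the best-validation epoch — monitoring the penalized objective instead
would conflate the regularizer with generalization, so the unpenalized
choice is deliberate. The NLL on the combined data, used *only* for
subselection, is recorded at the restored parameters.

Subselection keeps members with
$\lambda = 2(\mathrm{NLL} - \mathrm{NLL}_{best}) \le \chi^2_{\alpha, nf}$,
defaults α = 0.95, nf = 1 (3.841). The statistic is implemented with this
sign — the likelihood-ratio statistic must be non-negative with the best
member at λ = 0 — and nf = 1 is a deliberate *lower bound* on the
uncertainty: wider nf or α is one knob of the provided
`alpha_sensitivity()` sweep. Bands are pointwise equal-tailed percentiles
across accepted members' trajectories (states, β(t), observables);
`include_noise = TRUE` convolves the observables with each member's own
noise model to form predictive bands. Epistemic bands are scored against
noiseless truth; predictive bands against noisy replicates — never mixed.

## MCMC back-end

`run_nuts()` implements the No-U-Turn sampler (recursive doubling, slice
variable, Δ_max = 1000) with dual-averaging step-size adaptation toward 0.8
acceptance and a diagonal metric estimated from the second warmup half.
`run_parallel_tempering()` runs adaptive random-walk Metropolis chains on
$p(\theta|D)^{1/T_k}$ over a geometric ladder (default 6 rungs, 1 → 50),
swapping adjacent states every 10 sweeps with probability
$\min\{1, \exp[(1/T_i - 1/T_j)(\ell_j - \ell_i)]\}$; only the cold chain is
returned. The within-chain kernel adapts a global scale toward the
Roberts–Rosenthal optimal acceptance rate (0.44 in 1-D, 0.234 in higher
dimension) with diminishing adaptation, and per-coordinate proposal sds
from a Welford variance estimate frozen after burn-in. A gradient-free
kernel was chosen for tempering because high-temperature chains visit
regions where ODE gradients are expensive and unstable. Chains are
initialized at optimization endpoints (best ensemble members) — on these
posteriors that is markedly better than prior draws. Split-R̂ and a
Geyer-truncated effective sample size are reported per parameter; on the
full UDE posterior R̂ is *reported, not asserted*: with 144 correlated
parameters and network symmetries, desk-scale chains are not expected to
mix fully, and convergence claims are restricted to the conjugate and
multimodal toys where they are checked against closed forms.

## Variational back-end

`fit_meanfield()` fits a fully factorized Gaussian over the unconstrained
parameters by stochastic gradient ascent on the reparameterized ELBO
(8 MC samples per step, 5000 steps, Adam 1e-2), initialized at an
optimization endpoint with sd 0.01. Operating on the unconstrained space
means bounded mechanistic parameters automatically receive bounded
pushforward distributions; a scaled-beta family for bounded coordinates is
out of scope. The entropy gradient is analytic (+1 per log-sd coordinate),
which removes one source of estimator variance. Mean-field cannot represent
posterior correlations and therefore *underestimates marginal variances*
wherever the posterior is correlated — the package verifies the closed-form
case (ρ = 0.9 Gaussian: optimal factorized sd $\sqrt{1-\rho^2} \approx
0.44$ versus a true marginal sd of 1), and this mechanism is precisely why
no accuracy assertion is made for VI on the full UDE: its role there is as
a qualitative comparator.

## Evaluation layer

`parameter_intervals()` (constrained scale), `trajectory_coverage()`
(fraction of grid points where the truth lies inside the band, per state
including unobserved S, E and β(t)), `generalization_experiment()` (bands
and coverage re-simulated from an unseen x₀, default (0.8, 0.1, 0.0, 0.1)),
and `method_comparison()` (aligned cross-method table) are pure functions
of stored run artifacts. β(t) coverage is reported both globally and
restricted to times with true I·S > 0.01·N: β enters the dynamics only
through the β·S·I/N flux, so outside that regime broad β bands are expected
and uninformative. Under the default waves scenario the outbreak is so
shallow that this restricted set is empty — an honest reflection that β is
then weakly identified *everywhere*.

## Desk-scale problem sizes

The full-scale study behind this design used ensembles of 10 000 and
multi-day tempering runs. This package's tests and the acceptance script
run the same machinery at desk scale: 50-member ensembles (up to 1000
epochs each), toy-target sampler checks (10–20k iterations), and
reduced-budget VI/tempering runs on the UDE for qualitative comparison.
Invariants and closed-form oracles, not wall-clock parity, are the test
surface.

## Known limitations

- With 50 members the accepted set samples the likelihood-ratio shell
  sparsely: desk-scale members converge into the same optimum basin, so the
  percentile band is much narrower than the shell itself, while the
  maximum-likelihood trajectory carries an O(σ) imprint of the particular
  noise realization. The package's own end-to-end checks find that 99%
  epistemic bands from such ensembles undercover the true observed-state
  trajectories, even though the noise sd is recovered well — at this scale
  the nf = 1 subselection is exactly what it claims to be, a lower bound on
  the uncertainty. Full-scale ensembles (thousands of heterogeneously
  stopped members) are needed for the band to fill the shell.
- The synthetic generator emulates iid observation noise on two observables
  of a deterministic epidemic; it does not emulate reporting delays,
  day-of-week effects, under-reporting, or process stochasticity, so
  passing tests speak to estimator behaviour under the stated noise models,
  not to surveillance-data robustness.
- Network symmetries leave the posterior heavily multimodal; no
  symmetry-removal post-processing is attempted.
- The quadratic-dynamics family and the full noise-scenario grid of the
  original study are expressible through `scenario_config()`'s custom β and
  noise settings but have no registered constants here.
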