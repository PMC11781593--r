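---
title: "Informed stochastic resetting: models, estimators and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Informed stochastic resetting: models, estimators and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

resetdyn accelerates first-passage sampling of Langevin dynamics by
*stochastic resetting*: trajectories are returned to their initial
condition at exponentially distributed times. In the *informed* variant
(ISR), a reset is executed only when the system is judged to be far from
the target — concretely, when a collective variable (CV) is beyond a
threshold `c` at the resetting epoch. This vignette records the models,
the estimators and every numerical decision that a user of the package
should be able to audit.

## The dynamical model

A single particle of mass $m$ moves on an analytic 2D potential
$U(x, y)$ under underdamped Langevin dynamics at temperature $T$ with
friction $\gamma$:

$$ m\,\dot v = -\nabla U \,k_BT - m\gamma v + \sqrt{2 m \gamma k_B T}\,\xi(t). $$

Potentials are expressed in multiples of $k_BT$ (so barrier heights read
directly in thermal units) and internal units are Angstrom, femtosecond
and g/mol; the Boltzmann constant enters through the single conversion
$k_BT = 8.3144621\times10^{-7}\,T$ (g/mol)(Å/fs)$^2$. The defaults —
$T = 300$ K, $\gamma = 0.01\ \mathrm{fs}^{-1}$, $\Delta t = 1$ fs,
$m = 40$ g/mol — describe an argon-like particle.

The integrator is the BAOAB splitting: half-kick, half-drift,
Ornstein–Uhlenbeck velocity update, half-drift, half-kick. In the
$\gamma \to 0$ limit it reduces to velocity Verlet; the test suite
verifies energy conservation there, equipartition
($\langle v^2\rangle = k_BT/m$ to 1%) and agreement of the sampled
position marginal with direct quadrature of $e^{-U}$. Each walker owns
an RNG stream derived from `(seed, walker_id)`, so ensembles are
reproducible bit-for-bit and independent of batch size.

## The benchmark surface

`mfe_surface()` is a modified Faradjian–Elber landscape,

$$ U(x,y) = A_1\left(x^6 + y'^6\right) +
  A_2\, e^{-x^2/\sigma_1^2}\left(1 - B\, e^{-y'^2/\sigma_2^2}\right),
  \qquad y' = s\,y, $$

with $A_1 = 1.2\times10^{-5}$, $A_2 = 12$, $B = 0.75$, $\sigma_1 = 1$ Å,
$\sigma_2 = 0.5$ Å and $s = 0.1$. The rescaling $y' = 0.1\,y$ stretches
the surface tenfold along $y$, which makes $y$ a slow, entropic degree
of freedom: the confinement turns around $|y| \approx 66$ Å while the
low saddle in the ridge (3 $k_BT$, against 12 $k_BT$ elsewhere) is only
about 5 Å wide. Trajectories start in the right minimum near
$(3, 0)$ Å and stop at $x < -1$ Å. Because most of the $y$ range sees
the full 12 $k_BT$ ridge, unbiased first passage requires diffusing back
into the narrow saddle channel — exactly the situation in which
resetting to $(3, 0)$ pays off. `analyze_landscape()` verifies the
printed geometry (the numerical minima sit at $x = \pm 2.71$ Å, which
rounds to the nominal $\pm 3$ Å).

Two further surfaces serve oracle duty: a symmetric quartic double well
(`double_well_surface()`) and a linear/flat surface
(`linear_surface()`) on which free-diffusion and drift–diffusion
first-passage results are known in closed form.

## Resetting protocols

`reset_protocol(rate_ns, threshold, cv_theta, direction)` draws
exponential waiting times with rate $r$; at each epoch the condition is
evaluated on the instantaneous state at full step resolution. Standard
SR (no threshold) always resets; ISR resets only when
$x\cos\theta + y\sin\theta$ is strictly beyond $c$. In either case the
walker returns to the exact initial position with freshly thermalized
momenta, a new waiting time is drawn (memorylessness makes the epoch
and per-step pictures equivalent), and — when Metadynamics is active —
the bias and its deposition clock are zeroed, so each segment between
resets is an independent replica. Elapsed time accumulates across
resets; first-passage times therefore include all discarded segments.
One tie-break is fixed deliberately: if a resetting epoch and the
first-passage crossing fall within the same step, the reset wins. The
reweighting predictor below uses the same convention, and the
enumeration oracle in the tests pins both to it.

## Metadynamics

`metad_engine()` implements minimal well-tempered Metadynamics on a 1D
CV: Gaussians of width $\sigma = 0.15$ Å and initial height
$0.5\,k_BT$, deposited every 100 steps, damped by
$\exp[-V(s)/(k_BT(\gamma_b - 1))]$ with bias factor $\gamma_b = 10$.
Bias and its analytic derivative are tabulated on a grid (spacing
0.01 Å) and interpolated linearly; the force error of this scheme is
$O((\Delta/\sigma)^2) \approx 0.4\%$, which the tests bound explicitly.
The default grid spans $[-12, 12]$ Å: the sextic walls of the benchmark
surface are soft enough that walkers visit $|x| > 8$ Å, and a grid edge
inside the accessible region can trap walkers behind clamped bias
forces — widening the grid is cheap insurance. Rotated-CV experiments
widen it further ($[-60, 60]$ Å) because the stretched $y$ direction
projects onto the CV. The first-passage criterion always stays the
physical target $x < -1$ Å; only the biased CV and the resetting
threshold rotate, the latter about the initial position (a threshold
$c$ on $x$ becomes $c' = x_0\cos\theta + (c - x_0)$ on the rotated CV).

## Predicting resetting performance from reset-free trajectories

A trajectory ensemble with informed resetting decomposes per trajectory
into $M_i$ segments — $M_i - 1$ ending in a reset, with mean duration
$\bar t^{\,r}_i$, and a final one of duration $t^f_i$ — so the MFPT is

$$ \langle\tau\rangle_r = (\langle M\rangle - 1)\,\langle\bar t^{\,r}\rangle
   + \langle t^f\rangle. $$

Each term is estimable from $N$ trajectories run *without* resetting.
With per-step resetting probability
$p(X) = (1 - e^{-r\Delta t})\,\mathbf 1[\mathrm{cv}(X) > c]$, the
survival of trajectory $i$ through $k$ resetting trials is
$\Psi_i(k) = \prod_{j\le k}(1 - p(X_i^j))$, and

* $\langle\Psi\rangle = N^{-1}\sum_i \Psi_i(n_i)$, the probability of
  reaching first passage unreset, gives
  $\langle M\rangle = \langle\Psi\rangle^{-1}$;
* $\langle t^f\rangle = \sum_i \tau_i \Psi_i(n_i) / \sum_i \Psi_i(n_i)$,
  the reset-free FPTs reweighted by survival;
* $\bar t^{\,r}_i = \sum_j j\Delta t\, \Psi_i(j-1) p(X_i^j) / (1 - \Psi_i(n_i))$,
  averaged over trajectories with weights $1 - \Psi_i(n_i)$.

Trajectories that could never have been reset contribute nothing to the
reset-segment average (their weight is zero), and a grid cell whose
ensemble survival underflows is reported as invalid rather than
extrapolated. The implementation (`predict_mfpt()`,
`screen_protocols()`) is validated two ways: exact agreement (to
$10^{-12}$) with brute-force enumeration over all reset realizations of
hand-sized samples, and 3-standard-error agreement with direct ISR
simulation on the fast fixture surface.

**Storage stride.** Long trajectories store the CV every $S$ steps and
treat the condition as constant within a stride, replacing $p$ by
$1 - e^{-rS\Delta t}$. The unbiased benchmark ensembles use $S = 100$
(10$^{-13}$ s between samples), which keeps the per-stride probability
below 0.1 for rates up to $10^3\ \mathrm{ns}^{-1}$; screens beyond that
rate lean on the plateau property of far thresholds (the predicted
optimum is flat there, and the reported speedups always come from
direct simulation at the chosen rate, not from the screen itself).
Short accelerated ensembles store every 2–10 steps.

## Inferring the unbiased MFPT from accelerated ensembles

Evaluating $\langle\tau\rangle_r$ for $r$ *above* the sampling rate
$r^\*$ needs no new simulations: superposing an independent exponential
clock of rate $r - r^\*$ on the $r^\*$ process yields exactly the $r$
process, because a reset restarts everything and exponential clocks are
memoryless. Each stored ISR trajectory — internal resets included — is
therefore a valid base sample for the reweighting machinery at added
rate $r - r^\*$ (`tau_at_higher_rates()`). The unbiased MFPT follows by
extrapolating $\log\langle\tau\rangle_r$, fit as a quadratic in $r$
over probes in $[r^\*, 3r^\*]$ weighted by bootstrap variances, down to
$r = 0$ (`extrapolate_to_zero()`, `infer_mfpt()`). The functional form
is a package choice, gated by a closed-form oracle: for 1D
drift–diffusion the renewal identity
$\langle\tau\rangle_r = (1/\tilde T(r) - 1)/r$ with the inverse-Gaussian
Laplace transform $\tilde T$ is exact, and the full loop — simulate
with SR at $r^\*$, probe, extrapolate — recovers $L/v$ within its
stated uncertainty in the tests. As with all such schemes there is a
speedup–accuracy trade-off: the farther $r^\*$ sits up the speedup
curve, the less the probes constrain $r = 0$.

## Direct transit times

`extract_dtt()` measures the committed crossing segment: from the
*last* stored sample beyond an upper surface to the *first* subsequent
sample beyond a lower one, with excursions that recross the upper
surface discarded and no sub-step interpolation (crossings are located
at stored samples, matching the step-resolution definition). On the
model surface the transition region is bracketed by $x = 1$ and
$x = -1$. Transit times are orders of magnitude shorter than
first-passage times and only logarithmically sensitive to barrier
height, which is why their ensemble mean is stable across Metadynamics
deposition paces even where the FPT speedup varies strongly — the tests
restate this invariance on the fixture surface.

## The synthetic fixture: what it does and does not emulate

`generate_fixture()` builds a scaled-down benchmark surface (ridge
3.5 $k_BT$, saddle 1.2 $k_BT$ before auto-adjustment, $y$ stretched
by $1/0.6$ rather than 10) whose unbiased MFPT falls in a target band
of 0.005–0.08 ns, so whole-protocol property tests run in seconds. If a
50-walker probe misses the band, the ridge is scaled geometrically and
the probe repeated — a construction rule, not a fit to any expected
test outcome. The fixture preserves the features the machinery depends
on — two threshold classes (plateau beyond the start, unimodal inside
the well), a saddle channel in a slow orthogonal coordinate, FPT
distributions with coefficient of variation near 1 — but not the deep
timescale separation of the full surface (its speedups are a few-fold,
not 50-fold), and nothing about solvated biomolecules: passing fixture
tests certifies the estimators, not force-field realism.

## Problem sizes and tolerances

Reduced ensemble sizes are used throughout: 150–400 walkers for
unbiased baselines, 200–500 for accelerated protocols, 300 for
Metadynamics ensembles — enough that every stochastic comparison is
made at 3 combined standard errors, the package's uniform criterion for
"agrees". Deterministic checks (gradients vs. central differences,
enumeration identities, survival products) use tolerances of
$10^{-6}$–$10^{-12}$ as stated per test. Walkers are censored at a
configurable `max_steps` (25x the unbiased scale in the experiment
drivers) and censoring is always reported, never silently dropped; a
protocol whose ensemble censors is reported as unresolved (`NA`
speedup) in experiment tables.

## Known limitations

* The CV is one-dimensional and linear in $(x, y)$; multi-dimensional
  or nonlinear CVs would need a generalized `cv` hook (the resetting
  probability of the predictor is the only place the threshold form
  enters, so other conditions are a small extension).
* Resetting times are exponential only; sharp (deterministic) resetting
  is not implemented.
* The reweighting screen degrades when the per-stride resetting
  probability saturates (very high rates with coarse storage), and near
  total survival collapse its variance grows — both regimes are flagged
  rather than extrapolated.
* The Metadynamics engine is deliberately minimal: fixed-width hills,
  linear-interpolation forces, no adaptive Gaussians, no reweighting of
  biased observables other than through resetting.
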